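control_target_table <- function() {
  tb <- rbind(AS = c(825, 7, 278, 286), SS = c(8, 1, 43, 60))
  colnames(tb) <- c("spine_head", "spine_neck", "aspiny_shaft", "spiny_shaft")
  contingency_table(tb)
}

test_that("expected counts follow E_ij = T_i T_j / T", {
  even <- contingency_table(rbind(c(10, 10), c(10, 10)))
  expect_true(all(expected_counts(even) == 10))

  e <- expected_counts(control_target_table())
  # direct formula oracle for SS x spine_head
  expect_equal(e["SS", "spine_head"], 833 * 112 / 1508, tolerance = 1e-12)
  expect_equal(sum(e), 1508, tolerance = 1e-9)
  expect_error(expected_counts(matrix(0, 2, 2)), "empty")
})

test_that("the Pearson statistic matches a cell-by-cell oracle and chisq.test", {
  set.seed(11)
  for (rep_ in 1:10) {
    m <- matrix(rpois(6, 40) + 1, nrow = 2)
    res <- pearson_chi2(m)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(res$statistic, sum((m - e)^2 / e), tolerance = 1e-12)
    ref <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
    expect_identical(res$df, unname(as.integer(ref$parameter)))
  }
})

test_that("proportional rows give a zero statistic and empty margins error", {
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(pearson_chi2(prop)$statistic, 0, tolerance = 1e-12)
  withzero <- rbind(c(10, 0), c(20, 0))
  expect_error(pearson_chi2(withzero), "discard or merge")
})

test_that("the chi-square statistic is invariant under row/column permutation", {
  tb <- unclass(control_target_table())
  base <- pearson_chi2(tb)$statistic
  expect_equal(pearson_chi2(tb[2:1, ])$statistic, base, tolerance = 1e-12)
  expect_equal(pearson_chi2(tb[, c(3, 1, 4, 2)])$statistic, base,
    tolerance = 1e-12)
})

test_that("partitioning discards low-count columns and reproduces conditional shares", {
  res <- partition_2x2(control_target_table(), discard_rule = 5)
  expect_identical(res$discarded$column, "spine_neck")
  expect_match(res$discarded$reason, "< 5")
  shares <- setNames(round(res$partitions$share_row1_pct, 1), res$partitions$column)
  expect_equal(unname(shares["spine_head"]), 99.0)
  expect_equal(unname(shares["aspiny_shaft"]), 86.6)
  expect_equal(unname(shares["spiny_shaft"]), 82.7)
  expect_true(all(is.finite(res$partitions$statistic)))
  expect_true(all(res$partitions$statistic >= 0))
  expect_true(all(res$partitions$df == 1L))
})

test_that("raising the discard threshold never increases retained partitions", {
  tb <- control_target_table()
  retained <- function(thr) {
    out <- tryCatch(partition_2x2(tb, discard_rule = thr),
      error = function(e) NULL)
    if (is.null(out)) 0L else nrow(out$partitions)
  }
  ns <- vapply(c(1, 5, 9, 50, 300), retained, integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("the successive partition scheme yields k-1 orthogonal 2x2 tests", {
  res <- partition_2x2(control_target_table(), scheme = "successive")
  expect_identical(nrow(res$partitions), 2L)  # 3 retained columns -> 2 tests
  expect_true(all(res$partitions$df == 1L))
})

test_that("tables built from tidy tibbles match matrix input", {
  df <- tibble::tibble(
    type = rep(c("AS", "SS"), each = 4),
    target = rep(c("spine_head", "spine_neck", "aspiny_shaft", "spiny_shaft"), 2),
    n = c(825, 7, 278, 286, 8, 1, 43, 60)
  )
  tb <- contingency_table(df, type, target, n)
  expect_equal(unclass(tb), unclass(control_target_table()),
    ignore_attr = TRUE)
  expect_error(contingency_table(rbind(c(1.5, 2), c(1, 2))), "integers")
})

test_that("tidiers expose cell residuals and one-line summaries", {
  res <- pearson_chi2(control_target_table())
  td <- tidy(res)
  expect_identical(nrow(td), 8L)
  expect_equal(sum(td$observed), 1508)
  gl <- glance(res)
  expect_equal(gl$statistic, res$statistic)
  pt <- tidy(partition_2x2(control_target_table()))
  expect_identical(nrow(pt), 3L)
})
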