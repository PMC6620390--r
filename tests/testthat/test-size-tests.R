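test_that("identical samples give a Mann-Whitney p of 1", {
  df <- tibble::tibble(
    value = rep(seq(1, 20), 2),
    group = rep(c("a", "b"), each = 20)
  )
  res <- size_comparisons(df, value, group)
  mw <- res[res$test == "mann_whitney", ]
  expect_equal(mw$p_value, 1, tolerance = 1e-9)
})

test_that("groups below the minimum n are withheld, not errored", {
  df <- tibble::tibble(
    value = c(rnorm(30), rnorm(30), rnorm(3)),
    group = c(rep("a", 30), rep("b", 30), rep("tiny", 3))
  )
  res <- size_comparisons(df, value, group, min_n = 10)
  tiny <- res[res$groups == "tiny", ]
  expect_false(tiny$tested)
  expect_true(is.na(tiny$p_value))
  expect_false(any(grepl("tiny", res$groups[res$tested])))
})

test_that("three groups trigger Kruskal-Wallis with the reference statistic", {
  set.seed(5)
  df <- tibble::tibble(
    value = c(rlnorm(40, 11, 0.5), rlnorm(40, 11.2, 0.5), rlnorm(40, 11.4, 0.5)),
    group = rep(c("macular", "perforated", "horseshoe"), each = 40)
  )
  res <- size_comparisons(df, value, group)
  kw <- res[res$test == "kruskal_wallis", ]
  ref <- kruskal.test(df$value, factor(df$group))
  expect_equal(kw$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_identical(nrow(res[res$test == "mann_whitney", ]), 3L)
  expect_identical(nrow(res[res$test == "kolmogorov_smirnov", ]), 3L)
})

test_that("a one-sigma log-normal shift is detected by the KS test", {
  set.seed(8)
  df <- tibble::tibble(
    value = c(rlnorm(300, 11, 1), rlnorm(300, 12, 1)),
    group = rep(c("control", "shifted"), each = 300)
  )
  res <- size_comparisons(df, value, group)
  ks <- res[res$test == "kolmogorov_smirnov", ]
  expect_lt(ks$p_value, 0.01)
})

test_that("Holm adjustment never lowers a p-value", {
  set.seed(13)
  df <- tibble::tibble(
    value = rnorm(90),
    group = rep(c("a", "b", "c"), each = 30)
  )
  raw <- size_comparisons(df, value, group)
  adj <- size_comparisons(df, value, group, p_adjust = "holm")
  m_raw <- raw[raw$test == "mann_whitney", ]$p_value
  m_adj <- adj[adj$test == "mann_whitney", ]$p_value
  expect_true(all(m_adj >= m_raw - 1e-12))
})
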