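test_that("bundled reference tables load with consistent totals", {
  tg <- reference_counts("targets")
  sh <- reference_counts("shapes")
  expect_identical(nrow(tg), 16L)
  expect_identical(nrow(sh), 16L)
  totals <- tg |>
    dplyr::group_by(group, type) |>
    dplyr::summarise(n = sum(count), .groups = "drop")
  expect_setequal(totals$n, c(1396, 112, 1153, 102))
  expect_equal(sum(sh$count), 4722)
})

test_that("recomputed percentages reproduce the printed tables except one known cell", {
  rep <- reproduce_reference_tables()
  pct <- rep$percentages
  # every percentage recomputes self-consistently from its own counts
  manual <- pct |>
    dplyr::group_by(.data$table, .data$group, .data$type) |>
    dplyr::mutate(check = round(100 * count / sum(count), 1)) |>
    dplyr::ungroup()
  expect_equal(pct$computed_pct, manual$check)
  # the single printed-vs-computed discrepancy is the AD symmetric macular
  # cell (printed 92.5, counts give 110/119 = 92.4)
  bad <- pct[!pct$match, ]
  expect_identical(nrow(bad), 1L)
  expect_identical(bad$group, "AD")
  expect_identical(bad$type, "SS")
  expect_identical(bad$category, "macular")
  expect_equal(bad$computed_pct, 92.4)
  expect_equal(bad$printed_pct, 92.5)
})

test_that("omnibus statistics and partitions match the published analysis", {
  rep <- reproduce_reference_tables()
  omni <- rep$omnibus
  ctrl <- omni[omni$table == "targets" & omni$group == "control", ]
  expect_equal(round(ctrl$statistic, 2), 117.06)
  expect_identical(ctrl$df, 3L)
  expect_lt(ctrl$p_value, 1e-4)
  parts <- rep$partitions$targets$control
  expect_s3_class(parts, "partition_result")
  expect_identical(parts$discarded$column, "spine_neck")
  expect_equal(rep$grand_total_shapes, 4722)
})

test_that("malformed count files raise a schema error", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1, b = 2), tmp, row.names = FALSE)
  expect_error(reference_counts("targets", path = tmp), "malformed")
})
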