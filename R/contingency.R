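#' Contingency table of synapse counts
#'
#' Builds a labeled nonnegative integer count matrix (rows: synapse types or
#' groups; columns: target or shape categories) from either a matrix or a
#' tidy tibble of counts.
#'
#' @param x A count matrix with dimnames, or a tibble.
#' @param row,col,count For tibble input: bare column names of the row
#'   label, column label and count.
#' @return An object of class `contingency_table` (a matrix with marginal
#'   attributes).
#' @examples
#' tb <- tibble::tibble(
#'   type = rep(c("AS", "SS"), each = 2),
#'   target = rep(c("head", "shaft"), 2),
#'   n = c(825, 564, 8, 103)
#' )
#' contingency_table(tb, type, target, n)
#' @export
contingency_table <- function(x, row, col, count) {
  if (is.data.frame(x)) {
    rlab <- dplyr::pull(x, {{ row }})
    clab <- dplyr::pull(x, {{ col }})
    cnt <- dplyr::pull(x, {{ count }})
    m <- tapply(cnt, list(factor(rlab, unique(rlab)), factor(clab, unique(clab))), sum)
    m[is.na(m)] <- 0
  } else {
    m <- as.matrix(x)
  }
  if (any(m < 0) || any(abs(m - round(m)) > 1e-9)) {
    abort("counts must be nonnegative integers")
  }
  m <- round(m)
  storage.mode(m) <- "double"
  structure(
    m,
    row_totals = rowSums(m),
    col_totals = colSums(m),
    total = sum(m),
    class = c("contingency_table", "matrix")
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- unclass(x)
  attr(m, "row_totals") <- NULL
  attr(m, "col_totals") <- NULL
  attr(m, "total") <- NULL
  print(m)
  cat(sprintf("total: %d\n", as.integer(attr(x, "total"))))
  invisible(x)
}

#' Expected counts under independence
#'
#' For a table with row marginals `T_i`, column marginals `T_j` and grand
#' total `T`, the expected frequency of cell (i, j) is `E_ij = T_i T_j / T`.
#'
#' @param table A [contingency_table()] or plain count matrix.
#' @return Matrix of expected counts (sums to the grand total).
#' @export
expected_counts <- function(table) {
  m <- unclass(as.matrix(table))
  total <- sum(m)
  if (total <= 0) abort("empty table: grand total is zero")
  outer(rowSums(m), colSums(m)) / total
}

#' Pearson chi-square test for a contingency table
#'
#' Computes `X^2 = sum (O - E)^2 / E` with `E_ij = T_i T_j / T`, degrees of
#' freedom `(r - 1)(c - 1)`, and the upper-tail chi-square p-value. No
#' continuity correction is applied.
#'
#' @param table A [contingency_table()] or count matrix.
#' @return An object of class `chi_sq_result` with elements `statistic`,
#'   `df`, `p_value`, `observed`, `expected`, `discarded_cells`.
#' @examples
#' tb <- rbind(AS = c(825, 7, 278, 286), SS = c(8, 1, 43, 60))
#' pearson_chi2(tb)
#' @export
pearson_chi2 <- function(table) {
  m <- unclass(as.matrix(table))
  e <- expected_counts(m)
  if (any(e == 0)) {
    abort("expected count of zero in at least one cell: discard or merge empty rows/columns first")
  }
  stat <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  structure(
    list(
      statistic = stat,
      df = df,
      p_value = pchisq(stat, df, lower.tail = FALSE),
      observed = m,
      expected = e,
      discarded_cells = tibble::tibble(column = character(0), reason = character(0))
    ),
    class = "chi_sq_result"
  )
}

#' @export
print.chi_sq_result <- function(x, ...) {
  cat(sprintf(
    "Pearson chi-square = %.2f; df = %d; p %s\n",
    x$statistic, x$df,
    if (x$p_value < 1e-4) "< 0.0001" else sprintf("= %.4g", x$p_value)
  ))
  if (nrow(x$discarded_cells)) {
    cat("discarded:", paste(x$discarded_cells$column, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Partitioned 2 x 2 chi-square tests for a 2 x k table
#'
#' Decomposes an omnibus 2 x k association test into 2 x 2 sub-tables to
#' localise which categories drive it. Columns whose minimum observed count
#' falls below `discard_rule` (default 5) are discarded first and reported
#' with the reason. Two partition schemes are available:
#' `"column_vs_rest"` (default) tests each retained column against the
#' pooled remaining retained columns, matching reports of per-category
#' conditional shares; `"successive"` forms the orthogonal sequence col 1+2
#' vs col 3, etc. Row shares within each retained column (e.g. the percent
#' of asymmetric synapses among synapses on spine heads) are returned
#' alongside each test.
#'
#' @param table A 2 x k ([contingency_table()] or matrix), k >= 3.
#' @param discard_rule Minimum observed count a column must reach in every
#'   row to be retained.
#' @param scheme Partition construction, see Details.
#' @return Object of class `partition_result`: list with `partitions`
#'   (tibble: column, statistic, df, p_value, share rows) `tests` (list of
#'   `chi_sq_result`), and `discarded` (tibble with reasons).
#' @examples
#' tb <- rbind(AS = c(825, 7, 278, 286), SS = c(8, 1, 43, 60))
#' colnames(tb) <- c("spine_head", "spine_neck", "aspiny_shaft", "spiny_shaft")
#' partition_2x2(tb)
#' @export
partition_2x2 <- function(table, discard_rule = 5,
                          scheme = c("column_vs_rest", "successive")) {
  scheme <- match.arg(scheme)
  m <- unclass(as.matrix(table))
  if (nrow(m) != 2 || ncol(m) < 3) {
    abort("partitioning expects a 2 x k table with k >= 3")
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("col", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("row", 1:2)
  low <- apply(m, 2, min) < discard_rule
  discarded <- tibble::tibble(
    column = colnames(m)[low],
    reason = sprintf(
      "observed count < %g (%s = %d)", discard_rule,
      rownames(m)[apply(m[, low, drop = FALSE], 2, which.min)],
      apply(m[, low, drop = FALSE], 2, min)
    )
  )
  keep <- which(!low)
  if (length(keep) < 2) {
    abort("fewer than two columns retained after the discard rule")
  }
  mk <- m[, keep, drop = FALSE]
  tests <- list()
  rows <- list()
  if (scheme == "column_vs_rest") {
    for (j in seq_along(keep)) {
      sub <- cbind(mk[, j], rowSums(mk[, -j, drop = FALSE]))
      colnames(sub) <- c(colnames(mk)[j], "rest")
      res <- pearson_chi2(sub)
      tests[[colnames(mk)[j]]] <- res
      shares <- 100 * mk[, j] / sum(mk[, j])
      rows[[j]] <- tibble::tibble(
        column = colnames(mk)[j],
        statistic = res$statistic, df = res$df, p_value = res$p_value,
        share_row1_pct = shares[1], share_row2_pct = shares[2]
      )
    }
  } else {
    for (j in seq_len(ncol(mk) - 1)) {
      pooled <- rowSums(mk[, seq_len(j), drop = FALSE])
      sub <- cbind(pooled, mk[, j + 1])
      colnames(sub) <- c(
        paste(colnames(mk)[seq_len(j)], collapse = "+"),
        colnames(mk)[j + 1]
      )
      res <- pearson_chi2(sub)
      tests[[colnames(mk)[j + 1]]] <- res
      shares <- 100 * mk[, j + 1] / sum(mk[, j + 1])
      rows[[j]] <- tibble::tibble(
        column = colnames(mk)[j + 1],
        statistic = res$statistic, df = res$df, p_value = res$p_value,
        share_row1_pct = shares[1], share_row2_pct = shares[2]
      )
    }
  }
  structure(
    list(
      partitions = dplyr::bind_rows(rows),
      tests = tests,
      discarded = discarded,
      row_labels = rownames(m)
    ),
    class = "partition_result"
  )
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("2 x 2 partitions (%s vs %s shares per column):\n",
    x$row_labels[1], x$row_labels[2]))
  print(as.data.frame(x$partitions), row.names = FALSE)
  if (nrow(x$discarded)) {
    for (i in seq_len(nrow(x$discarded))) {
      cat(sprintf("discarded '%s': %s\n",
        x$discarded$column[i], x$discarded$reason[i]))
    }
  }
  invisible(x)
}
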