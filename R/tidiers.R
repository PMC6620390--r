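# broom-style tidiers for the fitted/statistical objects.

#' Tidy a chi-square result into cell-level rows
#'
#' @param x A `chi_sq_result` from [pearson_chi2()].
#' @param ... Unused.
#' @return Tibble with one row per cell: row, column, observed, expected,
#'   Pearson residual.
#' @export
tidy.chi_sq_result <- function(x, ...) {
  o <- x$observed
  e <- x$expected
  rn <- rownames(o) %||% paste0("row", seq_len(nrow(o)))
  cn <- colnames(o) %||% paste0("col", seq_len(ncol(o)))
  tibble::tibble(
    row = rep(rn, times = ncol(o)),
    column = rep(cn, each = nrow(o)),
    observed = as.vector(o),
    expected = as.vector(e),
    residual = as.vector((o - e) / sqrt(e))
  )
}

#' One-row summary of a chi-square result
#'
#' @param x A `chi_sq_result`.
#' @param ... Unused.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
glance.chi_sq_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' Tidy a set of 2 x 2 partitions
#'
#' @param x A `partition_result` from [partition_2x2()].
#' @param ... Unused.
#' @return The per-column partition tibble (statistic, df, p, row shares).
#' @export
tidy.partition_result <- function(x, ...) x$partitions

#' One-row summary of a table reproduction
#'
#' @param x A `table_reproduction` from [reproduce_reference_tables()].
#' @param ... Unused.
#' @return Tibble with match bookkeeping and the shape-table grand total.
#' @export
glance.table_reproduction <- function(x, ...) {
  tibble::tibble(
    n_percentages = nrow(x$percentages),
    n_matching = sum(x$percentages$match),
    grand_total_synapses = x$grand_total_shapes
  )
}

#' Tidy a pipeline run into per-synapse rows
#'
#' @param x A `synmorph_run` from [run_pipeline()].
#' @param ... Unused.
#' @return The classified per-synapse tibble.
#' @export
tidy.synmorph_run <- function(x, ...) {
  if (x$mode == "tables") return(x$reproduction$percentages)
  x$classified
}

#' One-row summary of a pipeline run
#'
#' @param x A `synmorph_run`.
#' @param ... Unused.
#' @return Tibble of run-level counts and the recovery p-values.
#' @export
glance.synmorph_run <- function(x, ...) {
  if (x$mode == "tables") return(glance(x$reproduction))
  rec <- setNames(x$recovery$p_value, paste0("p_recovery_", x$recovery$dimension))
  dplyr::bind_cols(
    tibble::tibble(
      n_synapses = x$manifest$n_synapses,
      n_unknown_target = x$manifest$n_unknown_target,
      n_indeterminate_type = x$manifest$n_indeterminate_type
    ),
    tibble::as_tibble(as.list(rec))
  )
}
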