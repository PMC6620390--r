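#' Nonparametric comparisons of SAS size metrics between groups
#'
#' Runs the standard battery for synaptic size data, which are not normal
#' or homoscedastic: a Kruskal-Wallis test across three or more groups, the
#' unpaired two-sided Mann-Whitney U test for each pair, and a two-sided
#' Kolmogorov-Smirnov test comparing each pair's distributions. Groups
#' smaller than `min_n` are withheld from testing and reported as
#' `not_tested` (too few synapses for a robust statistical analysis) rather
#' than raising an error. Ties are handled by the usual normal
#' approximations of [stats::wilcox.test()] and [stats::kruskal.test()];
#' p-values are reported raw, with optional Bonferroni or Holm adjustment.
#'
#' @param data Data frame with one row per synapse.
#' @param value Bare column name of the metric (e.g. area).
#' @param group Bare column name of the grouping label.
#' @param min_n Minimum group size for testing (default 10).
#' @param p_adjust One of `"none"` (default, matching the usual reporting),
#'   `"bonferroni"`, `"holm"`.
#' @return Tibble: `test`, `groups`, `n`, `statistic`, `p_value`, `tested`.
#' @export
size_comparisons <- function(data, value, group, min_n = 10,
                             p_adjust = c("none", "bonferroni", "holm")) {
  p_adjust <- match.arg(p_adjust)
  vals <- dplyr::pull(data, {{ value }})
  grps <- as.character(dplyr::pull(data, {{ group }}))
  ok <- is.finite(vals) & !is.na(grps)
  vals <- vals[ok]
  grps <- grps[ok]
  sizes <- table(grps)
  tested_groups <- names(sizes)[sizes >= min_n]
  small_groups <- names(sizes)[sizes < min_n]
  rows <- list()
  for (g in small_groups) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      test = "none", groups = g, n = as.integer(sizes[[g]]),
      statistic = NA_real_, p_value = NA_real_, tested = FALSE
    )
  }
  if (length(tested_groups) >= 3) {
    sel <- grps %in% tested_groups
    kw <- kruskal.test(vals[sel], factor(grps[sel]))
    rows[[length(rows) + 1]] <- tibble::tibble(
      test = "kruskal_wallis",
      groups = paste(tested_groups, collapse = " | "),
      n = sum(sel),
      statistic = unname(kw$statistic),
      p_value = kw$p.value,
      tested = TRUE
    )
  }
  if (length(tested_groups) >= 2) {
    prs <- utils::combn(tested_groups, 2, simplify = FALSE)
    for (pr in prs) {
      xa <- vals[grps == pr[1]]
      xb <- vals[grps == pr[2]]
      mw <- suppressWarnings(wilcox.test(xa, xb, exact = FALSE))
      ks <- suppressWarnings(ks.test(xa, xb))
      rows[[length(rows) + 1]] <- tibble::tibble(
        test = c("mann_whitney", "kolmogorov_smirnov"),
        groups = paste(pr, collapse = " vs "),
        n = length(xa) + length(xb),
        statistic = c(unname(mw$statistic), unname(ks$statistic)),
        p_value = c(mw$p.value, ks$p.value),
        tested = TRUE
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (p_adjust != "none" && nrow(out)) {
    out <- out |>
      dplyr::group_by(.data$test) |>
      dplyr::mutate(p_value = ifelse(.data$tested,
        stats::p.adjust(.data$p_value, method = p_adjust), .data$p_value)) |>
      dplyr::ungroup()
  }
  out
}
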