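#' Run the full synthetic morphometry pipeline
#'
#' Orchestrates generate -> classify -> count -> test as one reproducible
#' run: generates the scene (or skips straight to the table-reproduction
#' mode), classifies every junction's type (PSD thickness), postsynaptic
#' target (adjacency + traceability) and shape (mesh topology), computes
#' SAS metrics with shrinkage correction, counts junctions inside a
#' centred unbiased counting frame, and runs the contingency statistics on
#' the classified counts. A manifest with the configuration, seed and
#' content hashes of every stage output makes reruns checkable.
#'
#' @param config A [scenario_config()] (ignored in `mode = "tables"`).
#'   May also be a path to a YAML or JSON file of [scenario_config()]
#'   arguments.
#' @param mode `"full"` (default) or `"tables"` (reference-table
#'   reproduction only, no volume generation).
#' @param frame_margin Fractional margin of the volume used for the
#'   counting frame (default 0.05 per face).
#' @param shrinkage_p2 Areal shrinkage factor for metric correction.
#' @param thickness_threshold AS/SS decision threshold in nm.
#' @param horseshoe_threshold Indentation ratio for the shape classifier.
#' @param shape_source `"truth_mesh"` (classify the ground-truth-geometry
#'   SAS meshes carried by the scene; default) or `"extracted"` (classify
#'   meshes re-extracted from the voxel volume, slower and
#'   voxelisation-limited).
#' @param output_dir Optional directory for CSV/JSON/report outputs.
#' @return Object of class `synmorph_run`.
#' @export
run_pipeline <- function(config = NULL, mode = c("full", "tables"),
                         frame_margin = 0.05, shrinkage_p2 = 0.933,
                         thickness_threshold = 24.5, horseshoe_threshold = 0.3,
                         shape_source = c("truth_mesh", "extracted"),
                         output_dir = NULL) {
  mode <- match.arg(mode)
  shape_source <- match.arg(shape_source)
  t0 <- Sys.time()
  if (mode == "tables") {
    rep <- reproduce_reference_tables()
    run <- structure(
      list(
        mode = mode, reproduction = rep,
        manifest = list(
          mode = mode, started = format(t0), finished = format(Sys.time()),
          version = as.character(utils::packageVersion("synmorph")),
          hashes = list(reproduction = rlang::hash(rep))
        )
      ),
      class = "synmorph_run"
    )
    if (!is.null(output_dir)) write_run_outputs(run, output_dir)
    return(run)
  }
  if (is.character(config)) config <- load_scenario_config(config)
  if (!inherits(config, "scenario_config")) {
    abort("`config` must be a scenario_config() or a path to one")
  }

  scene <- generate_scene(config)
  syn <- scene$synapses
  adjacency <- volume_adjacency(scene$volume)
  targets <- if (nrow(syn)) {
    assign_targets(scene$volume, syn$synapse_id, adjacency)
  } else {
    tibble::tibble(synapse_id = integer(0), target_class = character(0),
      postsynaptic_object_id = integer(0), traced_to_parent = logical(0),
      contact_area_nm2 = numeric(0))
  }
  types <- if (nrow(syn)) {
    classify_types(scene$volume, syn$synapse_id,
      thickness_threshold = thickness_threshold, sas_areas = syn$area_nm2)
  } else {
    tibble::tibble(synapse_id = integer(0), psd_thickness_nm = numeric(0),
      type = character(0))
  }
  meshes <- if (shape_source == "truth_mesh") {
    syn$mesh
  } else {
    lapply(syn$synapse_id, function(id) extract_sas(scene$volume, id))
  }
  shapes <- classify_shapes(meshes, horseshoe_threshold = horseshoe_threshold)
  metrics <- dplyr::bind_rows(lapply(meshes, sas_metrics,
    shrinkage_p2 = shrinkage_p2))

  classified <- syn |>
    dplyr::select("synapse_id",
      true_type = "type", true_shape = "shape_class",
      true_target = "target_class") |>
    dplyr::left_join(dplyr::select(types, "synapse_id", type = "type",
      "psd_thickness_nm"), by = "synapse_id") |>
    dplyr::left_join(dplyr::select(targets, "synapse_id",
      target_class = "target_class"), by = "synapse_id") |>
    dplyr::left_join(dplyr::select(shapes, "synapse_id",
      shape_class = "shape_class"), by = "synapse_id") |>
    dplyr::left_join(metrics, by = "synapse_id")

  ext <- volume_extent(scene$volume)
  frame <- counting_frame(frame_margin * ext, (1 - frame_margin) * ext)
  cf <- count_in_frame(scene, frame,
    classification = classified[c("synapse_id", "type", "shape_class", "target_class")])

  counted <- classified |>
    dplyr::left_join(cf$decisions[c("synapse_id", "cf_status")], by = "synapse_id") |>
    dplyr::filter(.data$cf_status == "counted", .data$type %in% c("AS", "SS"))
  stats_out <- classified_statistics(counted)
  occupancy <- spine_occupancy(targets, types)
  gof <- recovery_gof(scene, classified)

  run <- structure(
    list(
      mode = mode,
      scene = scene,
      classified = classified,
      targets = targets,
      occupancy = occupancy,
      frame = frame,
      cf_counts = cf$counts,
      statistics = stats_out,
      recovery = gof,
      manifest = list(
        mode = mode,
        seed = config$seed,
        config = unclass(config),
        started = format(t0),
        finished = format(Sys.time()),
        version = as.character(utils::packageVersion("synmorph")),
        n_synapses = nrow(syn),
        n_unknown_target = sum(targets$target_class == "unknown"),
        n_indeterminate_type = sum(types$type == "indeterminate"),
        hashes = list(
          labels = rlang::hash(scene$volume$labels),
          classified = rlang::hash(classified),
          cf_counts = rlang::hash(cf$counts)
        )
      )
    ),
    class = "synmorph_run"
  )
  if (!is.null(output_dir)) write_run_outputs(run, output_dir)
  run
}

load_scenario_config <- function(path) {
  args <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  # YAML maps of scalars come back as lists; fold them to named vectors
  fold <- function(x) {
    if (!is.list(x)) return(x)
    y <- lapply(x, fold)
    if (length(y) && all(vapply(y, function(e) is.numeric(e) && length(e) == 1,
      logical(1)))) {
      unlist(y)
    } else {
      y
    }
  }
  do.call(scenario_config, lapply(args, fold))
}

# Omnibus + partition statistics on classified, counted synapses.
classified_statistics <- function(counted) {
  out <- list()
  for (dim_ in c("target_class", "shape_class")) {
    tab_df <- counted |>
      dplyr::filter(.data[[dim_]] %in%
        if (dim_ == "target_class") target_classes else shape_classes) |>
      dplyr::count(.data$type, .data[[dim_]])
    if (nrow(tab_df) == 0 || length(unique(tab_df$type)) < 2) {
      out[[dim_]] <- NULL
      next
    }
    tab <- contingency_table(tab_df, "type", dim_, "n")
    omni <- tryCatch(pearson_chi2(tab), error = function(e) conditionMessage(e))
    part <- tryCatch(partition_2x2(tab), error = function(e) conditionMessage(e))
    out[[dim_]] <- list(table = tab, omnibus = omni, partitions = part)
  }
  kw <- counted |>
    dplyr::filter(.data$type == "AS")
  out$size_by_shape <- if (nrow(kw) > 0) {
    size_comparisons(kw, corrected_area_nm2, shape_class)
  } else {
    NULL
  }
  out
}

#' Goodness-of-fit of classified proportions against the configured mixes
#'
#' For each classification dimension (type, target, shape) this compares
#' the classified marginal counts with the proportions the scene was
#' configured to produce, via a chi-square goodness-of-fit test.
#' Unclassifiable junctions (`unknown` targets, `indeterminate` types) are
#' excluded from their dimension.
#'
#' @param scene The generated `synapse_scene`.
#' @param classified Tibble with `synapse_id`, `type`, `target_class`,
#'   `shape_class` (e.g. from [run_pipeline()]'s `classified` element).
#' @return Tibble: `dimension`, `statistic`, `df`, `p_value`, `n`.
#' @export
recovery_gof <- function(scene, classified) {
  cfg <- scene$config
  f <- cfg$as_fraction
  p_target <- f * cfg$target_mix$AS[target_classes] +
    (1 - f) * cfg$target_mix$SS[target_classes]
  p_shape <- f * cfg$shape_mix$AS[shape_classes] +
    (1 - f) * cfg$shape_mix$SS[shape_classes]
  gof <- function(obs_labels, classes, probs) {
    obs_labels <- obs_labels[obs_labels %in% classes]
    o <- table(factor(obs_labels, classes))
    keep <- probs > 0
    o <- as.numeric(o[keep])
    e <- sum(o) * probs[keep] / sum(probs[keep])
    stat <- sum((o - e)^2 / e)
    df <- sum(keep) - 1L
    c(stat, df, pchisq(stat, df, lower.tail = FALSE), sum(o))
  }
  res <- rbind(
    type = gof(classified$type, c("AS", "SS"), c(f, 1 - f)),
    target = gof(classified$target_class, target_classes, p_target),
    shape = gof(classified$shape_class, shape_classes, p_shape)
  )
  tibble::tibble(
    dimension = rownames(res),
    statistic = res[, 1], df = as.integer(res[, 2]),
    p_value = res[, 3], n = as.integer(res[, 4])
  )
}

write_run_outputs <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (run$mode == "full") {
    write_metrics_csv(
      run$classified[setdiff(names(run$classified), "mesh")],
      file.path(output_dir, "synapse_metrics.csv")
    )
  }
  jsonlite::write_json(run$manifest, file.path(output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, na = "null", force = TRUE)
  writeLines(make_report(run), file.path(output_dir, "report.md"))
  invisible(output_dir)
}

fmt_pct_table <- function(df, type_col, cat_col, n_col) {
  wide <- df |>
    dplyr::group_by(.data[[type_col]]) |>
    dplyr::mutate(pct = 100 * .data[[n_col]] / sum(.data[[n_col]])) |>
    dplyr::ungroup() |>
    dplyr::mutate(cell = sprintf("%.1f%% (%d)", .data$pct, .data[[n_col]])) |>
    dplyr::select(dplyr::all_of(c(type_col, cat_col)), "cell") |>
    tidyr::pivot_wider(names_from = dplyr::all_of(cat_col),
      values_from = "cell", values_fill = "0.0% (0)")
  c(
    paste0("| ", paste(names(wide), collapse = " | "), " |"),
    paste0("| ", paste(rep("---", ncol(wide)), collapse = " | "), " |"),
    vapply(seq_len(nrow(wide)), function(i) {
      paste0("| ", paste(unlist(wide[i, ]), collapse = " | "), " |")
    }, character(1))
  )
}

#' Human-readable report for a pipeline run
#'
#' Formats the classified counts the way the field's tables are printed
#' (percentages with absolute counts in parentheses), the omnibus and
#' partitioned chi-square results with any discarded cells and their
#' reason, the counting-frame bookkeeping and the recovery goodness-of-fit.
#'
#' @param run A `synmorph_run` from [run_pipeline()].
#' @return Character vector of Markdown lines, invisibly printable.
#' @export
make_report <- function(run) {
  lines <- c("# Synaptic morphometry run report", "")
  if (run$mode == "tables") {
    rep <- run$reproduction
    lines <- c(lines, "Mode: reference-table reproduction", "",
      utils::capture.output(print(rep)))
    return(lines)
  }
  man <- run$manifest
  lines <- c(lines,
    sprintf("Seed %d; %d synapses generated; %d unknown targets; %d indeterminate types.",
      man$seed, man$n_synapses, man$n_unknown_target, man$n_indeterminate_type),
    ""
  )
  counted <- run$cf_counts
  if (!is.null(counted) && nrow(counted)) {
    tt <- counted |> dplyr::count(.data$type, .data$target_class, wt = .data$n, name = "n")
    lines <- c(lines, "## Type x postsynaptic target (inside counting frame)", "",
      fmt_pct_table(tt, "type", "target_class", "n"), "")
    ts <- counted |> dplyr::count(.data$type, .data$shape_class, wt = .data$n, name = "n")
    lines <- c(lines, "## Type x shape (inside counting frame)", "",
      fmt_pct_table(ts, "type", "shape_class", "n"), "")
  }
  for (dim_ in c("target_class", "shape_class")) {
    st <- run$statistics[[dim_]]
    if (is.null(st)) next
    lines <- c(lines, sprintf("## Chi-square statistics: type x %s", dim_), "")
    lines <- c(lines, utils::capture.output({
      if (inherits(st$omnibus, "chi_sq_result")) print(st$omnibus) else cat(st$omnibus, "\n")
      if (inherits(st$partitions, "partition_result")) print(st$partitions) else cat(st$partitions, "\n")
    }), "")
  }
  lines <- c(lines, "## Recovery of configured proportions", "",
    utils::capture.output(print(as.data.frame(run$recovery), row.names = FALSE)), "")
  lines
}

#' @export
print.synmorph_run <- function(x, ...) {
  if (x$mode == "tables") {
    print(x$reproduction)
  } else {
    cat(sprintf(
      "<synmorph_run> %d synapses; %d unknown targets; frame counts over %d cells\n",
      x$manifest$n_synapses, x$manifest$n_unknown_target,
      nrow(x$cf_counts %||% tibble::tibble())
    ))
  }
  invisible(x)
}
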