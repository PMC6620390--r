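#' Unbiased 3D counting frame
#'
#' A rectangular prism whose three faces at the axis minima are acceptance
#' planes and whose three faces at the axis maxima are exclusion planes.
#' Objects inside the frame or intersecting an acceptance plane are counted;
#' objects intersecting any exclusion plane, or wholly outside, are not.
#' Which faces accept and which exclude is a convention (the construction
#' only requires three of each, meeting pairwise at edges); exclusion planes
#' are not extended beyond the face rectangles.
#'
#' @param min_nm,max_nm Numeric length-3 frame bounds in nm, `min < max`
#'   per axis.
#' @return An object of class `counting_frame`.
#' @export
counting_frame <- function(min_nm, max_nm) {
  min_nm <- as.numeric(min_nm)
  max_nm <- as.numeric(max_nm)
  if (length(min_nm) != 3 || length(max_nm) != 3 || any(min_nm >= max_nm)) {
    abort("frame bounds must satisfy min < max on all three axes")
  }
  structure(list(min = min_nm, max = max_nm), class = "counting_frame")
}

#' @export
print.counting_frame <- function(x, ...) {
  cat(sprintf(
    "<counting_frame> [%g, %g) x [%g, %g) x [%g, %g) nm (acceptance at minima, exclusion at maxima)\n",
    x$min[1], x$max[1], x$min[2], x$max[2], x$min[3], x$max[3]
  ))
  invisible(x)
}

#' Counting-frame decision for one object
#'
#' The object is a set of points in nm (voxel centres). It is counted when
#' it has a point inside the half-open frame `[min, max)` and no point
#' beyond an exclusion face within that face's cross-axis extent (the
#' "shadow" of the face, since exclusion planes are not extended).
#'
#' @param object_voxels Numeric matrix of nm coordinates, one row per voxel.
#' @param frame A [counting_frame()].
#' @return `"counted"` or `"not_counted"`.
#' @export
cf_decision <- function(object_voxels, frame) {
  p <- as.matrix(object_voxels)
  if (nrow(p) == 0) abort("empty object")
  inside <- p[, 1] >= frame$min[1] & p[, 1] < frame$max[1] &
    p[, 2] >= frame$min[2] & p[, 2] < frame$max[2] &
    p[, 3] >= frame$min[3] & p[, 3] < frame$max[3]
  if (!any(inside)) return("not_counted")
  for (k in 1:3) {
    others <- setdiff(1:3, k)
    in_shadow <- p[, k] >= frame$max[k] &
      p[, others[1]] >= frame$min[others[1]] &
      p[, others[1]] < frame$max[others[1]] &
      p[, others[2]] >= frame$min[others[2]] &
      p[, others[2]] < frame$max[others[2]]
    if (any(in_shadow)) return("not_counted")
  }
  "counted"
}

#' Count synapses of a scene inside a counting frame
#'
#' Applies [cf_decision()] to every junction object and tabulates counted
#' junctions by the grouping columns of `classification` (by default the
#' scene's ground-truth `type`, `shape_class` and `target_class`).
#'
#' @param scene A `synapse_scene` from [generate_scene()].
#' @param frame A [counting_frame()]; must lie within the volume.
#' @param classification Optional tibble with `synapse_id` plus grouping
#'   columns; defaults to the scene ground truth.
#' @return List with `decisions` (per-junction tibble) and `counts`
#'   (grouped counts of counted junctions).
#' @export
count_in_frame <- function(scene, frame, classification = NULL) {
  volume <- scene$volume
  ext <- volume_extent(volume)
  if (any(frame$min < 0) || any(frame$max > ext + 1e-9)) {
    abort("counting frame exceeds the volume bounds")
  }
  classification <- classification %||%
    scene$synapses[c("synapse_id", "type", "shape_class", "target_class")]
  ids <- classification$synapse_id
  lab <- volume$labels
  sel <- which(lab %in% ids)
  coords <- voxel_centres(volume, sel)
  by_id <- split(seq_along(sel), lab[sel])
  decision <- vapply(as.character(ids), function(key) {
    rows <- by_id[[key]]
    if (is.null(rows)) return(NA_character_)
    cf_decision(coords[rows, , drop = FALSE], frame)
  }, character(1))
  decisions <- dplyr::mutate(classification, cf_status = unname(decision))
  group_cols <- setdiff(names(classification), "synapse_id")
  counts <- decisions |>
    dplyr::filter(.data$cf_status == "counted") |>
    dplyr::count(dplyr::across(dplyr::all_of(group_cols)), name = "n")
  list(decisions = decisions, counts = counts)
}
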