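#' Labeled anisotropic voxel volume
#'
#' A 3D integer array of per-voxel object IDs (0 = background) on an
#' anisotropic grid, together with the voxel spacing in nm and an object
#' table giving each object's semantic class (`dendrite_shaft`, `spine_neck`,
#' `spine_head`, `synapse`), parent object and border-truncation flag.
#'
#' @param labels 3D integer array of object IDs.
#' @param voxel_size Numeric length-3, nm per voxel along x, y, z
#'   (default `c(5, 5, 20)`, the usual FIB/SEM imaging resolution).
#' @param objects Tibble with columns `object_id`, `class`, `parent_id`,
#'   `truncated`.
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(labels, voxel_size = c(5, 5, 20), objects = NULL) {
  if (length(dim(labels)) != 3) abort("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    abort("`voxel_size` must be three strictly positive nm spacings")
  }
  if (is.null(objects)) {
    ids <- setdiff(sort(unique(as.vector(labels))), 0L)
    objects <- tibble::tibble(
      object_id = ids,
      class = NA_character_,
      parent_id = NA_integer_,
      truncated = NA
    )
  }
  structure(
    list(labels = labels, voxel_size = voxel_size, objects = objects),
    class = "labeled_volume"
  )
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "<labeled_volume> %d x %d x %d voxels at (%g, %g, %g) nm; %d objects\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    nrow(x$objects)
  ))
  invisible(x)
}

# nm extent of the volume along each axis.
volume_extent <- function(volume) dim(volume$labels) * volume$voxel_size

# Linear voxel indices of one object; errors on unknown IDs.
object_voxel_indices <- function(volume, object_id) {
  idx <- which(volume$labels == object_id)
  if (!length(idx)) {
    abort(sprintf("object %s not present in volume", format(object_id)))
  }
  idx
}

# nm coordinates of voxel centres given linear indices.
voxel_centres <- function(volume, idx) {
  d <- dim(volume$labels)
  i <- ((idx - 1) %% d[1]) + 1
  j <- ((idx - 1) %/% d[1]) %% d[2] + 1
  k <- ((idx - 1) %/% (d[1] * d[2])) + 1
  cbind(
    (i - 0.5) * volume$voxel_size[1],
    (j - 0.5) * volume$voxel_size[2],
    (k - 0.5) * volume$voxel_size[3]
  )
}

#' Voxel centre coordinates of one object
#'
#' @param volume A [labeled_volume()].
#' @param object_id Object ID present in the volume.
#' @return Matrix of nm coordinates (one row per voxel).
#' @export
object_voxels <- function(volume, object_id) {
  voxel_centres(volume, object_voxel_indices(volume, object_id))
}

# Does the object touch any face of the volume?
object_touches_border <- function(volume, object_id) {
  d <- dim(volume$labels)
  idx <- object_voxel_indices(volume, object_id)
  i <- ((idx - 1) %% d[1]) + 1
  j <- ((idx - 1) %/% d[1]) %% d[2] + 1
  k <- ((idx - 1) %/% (d[1] * d[2])) + 1
  any(i == 1L | i == d[1] | j == 1L | j == d[2] | k == 1L | k == d[3])
}

#' Face-contact adjacency between labeled objects
#'
#' Scans the three axis directions for pairs of face-adjacent voxels with
#' different non-zero labels and accumulates the shared contact area (the
#' face area depends on the axis because voxels are anisotropic).
#'
#' @param volume A [labeled_volume()].
#' @return Tibble with columns `id_a`, `id_b` (`id_a < id_b`) and
#'   `contact_area_nm2`.
#' @export
volume_adjacency <- function(volume) {
  lab <- volume$labels
  d <- dim(lab)
  vs <- volume$voxel_size
  face_area <- c(vs[2] * vs[3], vs[1] * vs[3], vs[1] * vs[2])
  pairs_a <- list()
  pairs_b <- list()
  areas <- list()
  for (ax in 1:3) {
    if (d[ax] < 2) next
    idx1 <- switch(ax,
      list(seq_len(d[1] - 1), TRUE, TRUE),
      list(TRUE, seq_len(d[2] - 1), TRUE),
      list(TRUE, TRUE, seq_len(d[3] - 1))
    )
    idx2 <- switch(ax,
      list(seq_len(d[1] - 1) + 1, TRUE, TRUE),
      list(TRUE, seq_len(d[2] - 1) + 1, TRUE),
      list(TRUE, TRUE, seq_len(d[3] - 1) + 1)
    )
    a <- do.call(`[`, c(list(lab), idx1))
    b <- do.call(`[`, c(list(lab), idx2))
    sel <- a != b & a > 0L & b > 0L
    if (any(sel)) {
      pairs_a[[ax]] <- a[sel]
      pairs_b[[ax]] <- b[sel]
      areas[[ax]] <- rep(face_area[ax], sum(sel))
    }
  }
  if (!length(pairs_a)) {
    return(tibble::tibble(
      id_a = integer(0), id_b = integer(0), contact_area_nm2 = numeric(0)
    ))
  }
  a <- unlist(pairs_a)
  b <- unlist(pairs_b)
  ar <- unlist(areas)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- as.double(lo) * (max(hi) + 1) + as.double(hi)
  agg <- rowsum(ar, key)
  ukey <- as.double(rownames(agg))
  m <- max(hi) + 1
  tibble::tibble(
    id_a = as.integer(ukey %/% m),
    id_b = as.integer(ukey %% m),
    contact_area_nm2 = agg[, 1]
  )
}

#' Crop a labeled volume to a voxel sub-range
#'
#' Objects cut by the new border get their `truncated` flag refreshed;
#' objects that disappear are dropped from the object table.
#'
#' @param volume A [labeled_volume()].
#' @param lo,hi Integer length-3 voxel index bounds (inclusive).
#' @return A new [labeled_volume()].
#' @export
crop_volume <- function(volume, lo, hi) {
  d <- dim(volume$labels)
  lo <- as.integer(lo)
  hi <- as.integer(hi)
  if (any(lo < 1L) || any(hi > d) || any(lo > hi)) {
    abort("crop bounds outside volume")
  }
  lab <- volume$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  keep <- sort(setdiff(unique(as.vector(lab)), 0L))
  objects <- volume$objects[volume$objects$object_id %in% keep, , drop = FALSE]
  out <- labeled_volume(lab, volume$voxel_size, objects)
  out$objects$truncated <- vapply(
    out$objects$object_id,
    function(id) object_touches_border(out, id),
    logical(1)
  )
  out
}
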