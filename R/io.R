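# Fixture I/O: label volumes as multipage TIFF (uint16) with a JSON sidecar,
# ground truth as JSON, meshes as OFF/PLY, metrics as CSV.

#' Write a scene to disk as TIFF + JSON fixtures
#'
#' The label volume is serialised as a multipage 16-bit TIFF (one page per
#' z-slice) with a JSON sidecar carrying voxel size, dimensions, the object
#' table and the generator seed; the per-synapse ground truth is written as
#' JSON. The representation round-trips losslessly through [read_scene()].
#'
#' @param scene A `synapse_scene` (or a bare [labeled_volume()]).
#' @param dir Output directory (created if missing).
#' @param include_meshes Also write each ground-truth SAS mesh as an OFF
#'   file under `dir/meshes/`.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, include_meshes = FALSE) {
  volume <- if (inherits(scene, "labeled_volume")) scene else scene$volume
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lab <- volume$labels
  if (max(lab) > 65535) abort("more than 65535 objects: uint16 TIFF overflow")
  pages <- lapply(seq_len(dim(lab)[3]), function(k) {
    # tiff stores [0, 1]; scale to the uint16 range for lossless integers
    t(lab[, , k]) / 65535
  })
  ok <- tiff::writeTIFF(pages, file.path(dir, "labels.tif"),
    bits.per.sample = 16L)
  if (!isTRUE(ok) && !identical(ok, length(pages))) {
    abort(sprintf("failed to write TIFF stack under '%s'", dir))
  }
  sidecar <- list(
    voxel_size_nm = volume$voxel_size,
    dims = dim(lab),
    seed = if (!inherits(scene, "labeled_volume")) scene$config$seed else NA,
    semantic_map = volume$objects
  )
  jsonlite::write_json(sidecar, file.path(dir, "labels.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA, na = "null")
  if (!inherits(scene, "labeled_volume")) {
    truth <- scene$synapses[setdiff(names(scene$synapses), "mesh")]
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
      dataframe = "columns", auto_unbox = TRUE, digits = NA, na = "null")
    if (include_meshes) {
      mdir <- file.path(dir, "meshes")
      dir.create(mdir, showWarnings = FALSE)
      purrr::walk2(scene$synapses$mesh, scene$synapses$synapse_id, function(m, id) {
        write_mesh_off(m, file.path(mdir, sprintf("sas_%05d.off", id)))
      })
    }
  }
  invisible(dir)
}

#' Read a scene fixture written by [write_scene()]
#'
#' @param dir Directory containing `labels.tif` and `labels.json` (and
#'   optionally `truth.json`).
#' @return A list with `volume` (a [labeled_volume()]) and `synapses`
#'   (tibble or `NULL`).
#' @export
read_scene <- function(dir) {
  tif <- file.path(dir, "labels.tif")
  side <- file.path(dir, "labels.json")
  if (!file.exists(tif) || !file.exists(side)) {
    abort(sprintf("no scene fixture under '%s'", dir))
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tif, all = TRUE)
  dims <- as.integer(meta$dims)
  lab <- array(0L, dims)
  for (k in seq_len(dims[3])) {
    lab[, , k] <- as.integer(round(t(pages[[k]]) * 65535))
  }
  objects <- tibble::as_tibble(meta$semantic_map)
  vol <- labeled_volume(lab, as.numeric(meta$voxel_size_nm), objects)
  truth_path <- file.path(dir, "truth.json")
  synapses <- if (file.exists(truth_path)) {
    tibble::as_tibble(jsonlite::read_json(truth_path, simplifyVector = TRUE))
  } else {
    NULL
  }
  list(volume = vol, synapses = synapses)
}

#' Write a mesh in OFF format
#'
#' @param mesh A [sas_mesh()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  writeLines(apply(mesh$vertices, 1, function(v) {
    sprintf("%.9g %.9g %.9g", v[1], v[2], v[3])
  }), con)
  writeLines(apply(mesh$triangles, 1, function(tr) {
    sprintf("3 %d %d %d", tr[1] - 1L, tr[2] - 1L, tr[3] - 1L)
  }), con)
  invisible(path)
}

#' Read a mesh in OFF format
#'
#' @param path OFF file written by [write_mesh_off()].
#' @param synapse_id Optional ID to attach.
#' @return A [sas_mesh()].
#' @export
read_mesh_off <- function(path, synapse_id = NA_integer_) {
  lines <- readLines(path)
  if (!identical(lines[1], "OFF")) abort(sprintf("'%s' is not an OFF file", path))
  hdr <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  nv <- hdr[1]; nf <- hdr[2]
  verts <- do.call(rbind, lapply(lines[2 + seq_len(nv)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  tris <- do.call(rbind, lapply(lines[2 + nv + seq_len(nf)], function(l) {
    as.integer(strsplit(trimws(l), "\\s+")[[1]])[2:4] + 1L
  }))
  sas_mesh(verts, tris, synapse_id = synapse_id)
}

#' Write a mesh in ASCII PLY format
#'
#' @param mesh A [sas_mesh()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(mesh$triangles)),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  writeLines(apply(mesh$vertices, 1, function(v) {
    sprintf("%.9g %.9g %.9g", v[1], v[2], v[3])
  }), con)
  writeLines(apply(mesh$triangles, 1, function(tr) {
    sprintf("3 %d %d %d", tr[1] - 1L, tr[2] - 1L, tr[3] - 1L)
  }), con)
  invisible(path)
}

#' Write per-synapse metrics to CSV
#'
#' @param metrics Tibble of per-synapse rows (e.g. metrics joined with
#'   shape and target calls).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
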