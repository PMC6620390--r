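#' Extract the synaptic apposition surface of a junction from a volume
#'
#' Approximates the medial surface of the junction's voxel slab: voxel
#' centres (scaled to nm by the anisotropic voxel size) are projected onto
#' their principal plane, a fine 2D occupancy raster is built and
#' morphologically closed to bridge sampling gaps from slabs thinner than a
#' voxel, each occupied cell is lifted back to the mean offset of its voxels
#' along the plane normal (the medial position), and the cells are
#' triangulated. Boundary loops are lightly smoothed to remove voxel
#' staircasing from the perimeter.
#'
#' @param volume A [labeled_volume()].
#' @param synapse_id Object ID of the junction.
#' @param pitch Raster cell size in nm; defaults to the finest voxel axis.
#' @param smooth_iter Boundary smoothing iterations.
#' @return A [sas_mesh()] in nm coordinates.
#' @export
extract_sas <- function(volume, synapse_id, pitch = NULL, smooth_iter = 2L) {
  pts <- object_voxels(volume, synapse_id)
  pitch <- pitch %||% min(volume$voxel_size[1:2])
  if (nrow(pts) < 3) {
    # Degenerate one/two-voxel object: emit a minimal square patch at the
    # voxel location so downstream metrics stay defined.
    ctr <- colMeans(pts)
    h <- pitch / 2
    v <- rbind(
      ctr + c(-h, -h, 0), ctr + c(h, -h, 0),
      ctr + c(h, h, 0), ctr + c(-h, h, 0)
    )
    return(sas_mesh(v, rbind(c(1, 2, 3), c(1, 3, 4)), synapse_id = synapse_id))
  }
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  eg <- eigen(crossprod(d) / nrow(d), symmetric = TRUE)
  e1 <- eg$vectors[, 1]; e2 <- eg$vectors[, 2]; nrm <- eg$vectors[, 3]
  u <- d %*% e1
  v <- d %*% e2
  w <- d %*% nrm

  lo <- c(min(u), min(v)) - pitch
  nx <- max(2L, ceiling((max(u) + pitch - lo[1]) / pitch))
  ny <- max(2L, ceiling((max(v) + pitch - lo[2]) / pitch))
  ci <- pmin(nx, pmax(1L, floor((u - lo[1]) / pitch) + 1L))
  cj <- pmin(ny, pmax(1L, floor((v - lo[2]) / pitch) + 1L))
  cell <- (cj - 1L) * nx + ci
  occ <- matrix(FALSE, nx, ny)
  occ[unique(cell)] <- TRUE
  # Close gaps of up to ~ the coarsest voxel axis.
  rad <- max(1L, ceiling(0.5 * max(volume$voxel_size) / pitch))
  occ <- binary_close(occ, rad)

  # Medial offset per cell: mean w of the voxels in it; closed-in cells are
  # filled by neighbour averaging.
  wsum <- rowsum(as.numeric(w), cell)
  wcnt <- rowsum(rep(1, length(cell)), cell)
  wmat <- matrix(NA_real_, nx, ny)
  wmat[as.integer(rownames(wsum))] <- wsum[, 1] / wcnt[, 1]
  for (pass in 1:8) {
    miss <- occ & is.na(wmat)
    if (!any(miss)) break
    filled <- wmat
    filled[is.na(filled)] <- 0
    has <- !is.na(wmat)
    acc <- matrix(0, nx, ny)
    cnt <- matrix(0, nx, ny)
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      acc <- acc + shift_matrix(filled, sh[1], sh[2])
      cnt <- cnt + shift_matrix(has + 0, sh[1], sh[2])
    }
    new_vals <- acc / pmax(cnt, 1)
    wmat[miss & cnt > 0] <- new_vals[miss & cnt > 0]
  }
  wmat[occ & is.na(wmat)] <- 0

  grid_mesh <- triangulate_cells(occ, wmat, lo, pitch)
  verts3 <- sweep(
    grid_mesh$vertices[, 1, drop = FALSE] %*% t(e1) +
      grid_mesh$vertices[, 2, drop = FALSE] %*% t(e2) +
      grid_mesh$vertices[, 3, drop = FALSE] %*% t(nrm),
    2, ctr, `+`
  )
  mesh <- sas_mesh(verts3, grid_mesh$triangles, synapse_id = synapse_id)
  smooth_boundary(mesh, iterations = smooth_iter)
}

shift_matrix <- function(m, di, dj) {
  out <- matrix(0, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  rs <- max(1, 1 - di):min(nr, nr - di)
  cs <- max(1, 1 - dj):min(nc, nc - dj)
  out[rs + di, cs + dj] <- m[rs, cs]
  out
}

# Two triangles per occupied cell, vertices on the cell-corner lattice;
# corner heights average the adjacent occupied cells' medial offsets.
triangulate_cells <- function(occ, wmat, lo, pitch) {
  nx <- nrow(occ); ny <- ncol(occ)
  cells <- which(occ, arr.ind = TRUE)
  corner_id <- function(i, j) (j - 1L) * (nx + 1L) + i
  i <- cells[, 1]; j <- cells[, 2]
  c00 <- corner_id(i, j)
  c10 <- corner_id(i + 1L, j)
  c01 <- corner_id(i, j + 1L)
  c11 <- corner_id(i + 1L, j + 1L)
  used <- sort(unique(c(c00, c10, c01, c11)))
  remap <- function(x) match(x, used)
  tris <- rbind(
    cbind(remap(c00), remap(c10), remap(c11)),
    cbind(remap(c00), remap(c11), remap(c01))
  )
  ci <- ((used - 1L) %% (nx + 1L)) + 1L
  cj <- ((used - 1L) %/% (nx + 1L)) + 1L
  wpad <- matrix(NA_real_, nx + 2L, ny + 2L)
  wpad[2:(nx + 1L), 2:(ny + 1L)] <- ifelse(occ, wmat, NA_real_)
  wcorner <- numeric(length(used))
  for (k in seq_along(used)) {
    vals <- c(
      wpad[ci[k], cj[k]], wpad[ci[k] + 1L, cj[k]],
      wpad[ci[k], cj[k] + 1L], wpad[ci[k] + 1L, cj[k] + 1L]
    )
    wcorner[k] <- mean(vals, na.rm = TRUE)
  }
  wcorner[!is.finite(wcorner)] <- 0
  verts <- cbind(
    lo[1] + (ci - 1L) * pitch,
    lo[2] + (cj - 1L) * pitch,
    wcorner
  )
  list(vertices = verts, triangles = tris)
}

# Circular moving-average smoothing of boundary loop vertices; interior
# vertices are untouched.
smooth_boundary <- function(mesh, iterations = 2L, window = 2L) {
  if (iterations < 1) return(mesh)
  loops <- boundary_loops(mesh)
  v <- mesh$vertices
  for (lp in loops) {
    n <- length(lp)
    if (n < 5) next
    pos <- v[lp, , drop = FALSE]
    for (it in seq_len(iterations)) {
      acc <- pos
      for (off in seq_len(window)) {
        acc <- acc + pos[c((off + 1):n, 1:off), , drop = FALSE] +
          pos[c((n - off + 1):n, 1:(n - off)), , drop = FALSE]
      }
      pos <- acc / (2 * window + 1)
    }
    v[lp, ] <- pos
  }
  sas_mesh(v, mesh$triangles, synapse_id = mesh$synapse_id)
}
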