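# Planar mesh builders used both by generate_sas_mesh() and by the scene
# generator (which wraps the planar meshes onto the curved host surface).
# All builders return list(vertices = n x 2, triangles = m x 3) in nm.

# Smooth radial modulation r(theta) = 1 + sum a_k cos(k theta + phi_k).
# Amplitudes are kept small enough never to flip a shape class.
radial_modulation <- function(irregularity) {
  if (irregularity <= 0) return(function(theta) rep(1, length(theta)))
  ks <- 2:4
  amp <- irregularity * runif(length(ks), 0.3, 1) / ks
  phi <- runif(length(ks), 0, 2 * pi)
  function(theta) {
    out <- rep(1, length(theta))
    for (i in seq_along(ks)) out <- out + amp[i] * cos(ks[i] * theta + phi[i])
    out
  }
}

disk_mesh_2d <- function(radius, n_rings = 5, n_sectors = 48, radial_fn = NULL) {
  theta <- seq(0, 2 * pi, length.out = n_sectors + 1)[-(n_sectors + 1)]
  rmod <- if (is.null(radial_fn)) rep(1, n_sectors) else radial_fn(theta)
  verts <- matrix(0, 1 + n_rings * n_sectors, 2)
  for (i in seq_len(n_rings)) {
    r <- radius * i / n_rings
    idx <- 1 + (i - 1) * n_sectors + seq_len(n_sectors)
    verts[idx, ] <- cbind(r * rmod * cos(theta), r * rmod * sin(theta))
  }
  tris <- list()
  first <- 1 + seq_len(n_sectors)
  nxt <- c(first[-1], first[1])
  tris[[1]] <- cbind(1, first, nxt)
  for (i in seq_len(n_rings - 1)) {
    inner <- 1 + (i - 1) * n_sectors + seq_len(n_sectors)
    outer <- inner + n_sectors
    inner_n <- c(inner[-1], inner[1])
    outer_n <- c(outer[-1], outer[1])
    tris[[i + 1]] <- rbind(
      cbind(inner, outer, outer_n),
      cbind(inner, outer_n, inner_n)
    )
  }
  list(vertices = verts, triangles = do.call(rbind, tris))
}

# Annular band between radii r_in and r_out; `span` < 2*pi gives an open
# C-shaped band centred on angle `theta0`.
band_mesh_2d <- function(r_out, r_in, n_rings = 4, n_sectors = 48,
                         span = 2 * pi, theta0 = 0, radial_fn = NULL) {
  closed <- abs(span - 2 * pi) < 1e-12
  n_theta <- if (closed) n_sectors else n_sectors + 1
  theta <- if (closed) {
    seq(theta0, theta0 + 2 * pi, length.out = n_sectors + 1)[-(n_sectors + 1)]
  } else {
    seq(theta0 - span / 2, theta0 + span / 2, length.out = n_theta)
  }
  rmod <- if (is.null(radial_fn)) rep(1, n_theta) else radial_fn(theta)
  nr <- n_rings + 1
  verts <- matrix(0, nr * n_theta, 2)
  for (i in seq_len(nr)) {
    r <- r_in + (r_out - r_in) * (i - 1) / n_rings
    idx <- (i - 1) * n_theta + seq_len(n_theta)
    verts[idx, ] <- cbind(r * rmod * cos(theta), r * rmod * sin(theta))
  }
  tris <- list()
  n_quads <- if (closed) n_theta else n_theta - 1
  for (i in seq_len(n_rings)) {
    inner <- (i - 1) * n_theta + seq_len(n_quads)
    outer <- inner + n_theta
    inner_n <- if (closed) (i - 1) * n_theta + c(2:n_theta, 1) else inner + 1
    outer_n <- inner_n + n_theta
    tris[[i]] <- rbind(
      cbind(inner, outer, outer_n),
      cbind(inner, outer_n, inner_n)
    )
  }
  list(vertices = verts, triangles = do.call(rbind, tris))
}

mesh2d_area <- function(m2) {
  a <- m2$vertices[m2$triangles[, 2], ] - m2$vertices[m2$triangles[, 1], ]
  b <- m2$vertices[m2$triangles[, 3], ] - m2$vertices[m2$triangles[, 1], ]
  sum(abs(a[, 1] * b[, 2] - a[, 2] * b[, 1])) / 2
}

scale_mesh2d_to_area <- function(m2, area_target) {
  s <- sqrt(area_target / mesh2d_area(m2))
  m2$vertices <- m2$vertices * s
  m2
}

# Planar source mesh for one junction of the given shape class, scaled to
# exactly `area_target` nm^2. Geometry parameters (hole size, opening angle,
# fragment split) are fixed so classes are unambiguous under the default
# horseshoe threshold.
planar_sas_mesh <- function(shape_class, area_target, irregularity = 0.03) {
  shape_class <- match.arg(shape_class,
    c("macular", "perforated", "horseshoe", "fragmented"))
  if (!is.finite(area_target) || area_target <= 0) {
    abort("`area_target` must be a positive area in nm^2")
  }
  rf <- radial_modulation(irregularity)
  m2 <- switch(shape_class,
    macular = disk_mesh_2d(sqrt(area_target / pi), radial_fn = rf),
    perforated = {
      r_out <- sqrt(area_target / (pi * (1 - 0.35^2)))
      band_mesh_2d(r_out, 0.35 * r_out, radial_fn = rf)
    },
    horseshoe = {
      span <- 2 * pi * 0.78
      r_in_frac <- 0.45
      r_out <- sqrt(area_target / (span / 2 * (1 - r_in_frac^2)))
      band_mesh_2d(r_out, r_in_frac * r_out,
        span = span, theta0 = runif(1, 0, 2 * pi), radial_fn = rf)
    },
    fragmented = {
      a1 <- 0.6 * area_target
      a2 <- 0.4 * area_target
      d1 <- disk_mesh_2d(sqrt(a1 / pi), n_sectors = 36, radial_fn = rf)
      d2 <- disk_mesh_2d(sqrt(a2 / pi), n_sectors = 36,
        radial_fn = radial_modulation(irregularity))
      r1 <- sqrt(a1 / pi); r2 <- sqrt(a2 / pi)
      gap <- 0.6 * r2
      phi <- runif(1, 0, 2 * pi)
      off <- (r1 + r2 + gap) * c(cos(phi), sin(phi))
      d2$vertices <- sweep(d2$vertices, 2, off, `+`)
      list(
        vertices = rbind(d1$vertices, d2$vertices),
        triangles = rbind(d1$triangles, d2$triangles + nrow(d1$vertices))
      )
    }
  )
  m2 <- scale_mesh2d_to_area(m2, area_target)
  m2$vertices <- sweep(m2$vertices, 2, colMeans(m2$vertices))
  m2
}

#' Generate a synthetic SAS mesh of a given shape class
#'
#' Builds a triangulated synaptic apposition surface with the topology and
#' boundary geometry of one of the four shape classes: `macular` (a
#' topological disk), `perforated` (a disk with an interior hole),
#' `horseshoe` (a disk with a deep boundary indentation) and `fragmented`
#' (two disjoint disk components). The mesh is planar, scaled to exactly
#' `area_target`, mildly irregular in outline, and placed in a random
#' orientation.
#'
#' @param shape_class One of `"macular"`, `"perforated"`, `"horseshoe"`,
#'   `"fragmented"`.
#' @param area_target Total surface area in nm^2 (> 0).
#' @param seed Integer seed controlling outline irregularity and orientation.
#' @param irregularity Relative amplitude of the smooth outline modulation.
#' @return A [sas_mesh()].
#' @examples
#' m <- generate_sas_mesh("perforated", 2e5, seed = 1)
#' count_holes(m)
#' @export
generate_sas_mesh <- function(shape_class, area_target, seed = 1L,
                              irregularity = 0.03) {
  with_seed(seed, {
    m2 <- planar_sas_mesh(shape_class, area_target, irregularity)
    v3 <- cbind(m2$vertices, 0)
    v3 <- v3 %*% t(random_rotation())
    sas_mesh(v3, m2$triangles)
  })
}

# Rasterise a planar mesh to a logical occupancy grid (cell centres inside
# the surface by the even-odd rule over its boundary edges; holes come out
# empty automatically). Used as the junction footprint when carving voxel
# slabs.
rasterize_mesh2d <- function(m2, pitch) {
  v <- m2$vertices
  lo <- apply(v, 2, min) - pitch
  hi <- apply(v, 2, max) + pitch
  nx <- max(2L, ceiling((hi[1] - lo[1]) / pitch))
  ny <- max(2L, ceiling((hi[2] - lo[2]) / pitch))
  cx <- lo[1] + (seq_len(nx) - 0.5) * pitch
  cy <- lo[2] + (seq_len(ny) - 0.5) * pitch
  px <- rep(cx, times = ny)
  py <- rep(cy, each = nx)
  # boundary edges = edges with one incident triangle
  tr <- m2$triangles
  e1 <- c(tr[, 1], tr[, 2], tr[, 3])
  e2 <- c(tr[, 2], tr[, 3], tr[, 1])
  a <- pmin(e1, e2); b <- pmax(e1, e2)
  key <- (as.double(a) - 1) * nrow(v) + b
  ukey <- unique(key)
  idx <- match(key, ukey)
  cnt <- tabulate(idx, length(ukey))
  bnd <- which(cnt[idx] == 1L & !duplicated(key))
  cn <- integer(nx * ny)
  for (s in bnd) {
    x1 <- v[e1[s], 1]; y1 <- v[e1[s], 2]
    x2 <- v[e2[s], 1]; y2 <- v[e2[s], 2]
    if (y1 == y2) next
    crosses <- (y1 > py) != (y2 > py)
    if (!any(crosses)) next
    xint <- x1 + (py[crosses] - y1) * (x2 - x1) / (y2 - y1)
    hit <- crosses
    hit[crosses] <- px[crosses] < xint
    cn <- cn + hit
  }
  list(
    origin = lo, pitch = pitch, nx = nx, ny = ny,
    grid = matrix(cn %% 2L == 1L, nx, ny)
  )
}

# Footprint lookup: TRUE where (u, v) falls on an occupied raster cell.
raster_lookup <- function(raster, u, v) {
  i <- floor((u - raster$origin[1]) / raster$pitch) + 1
  j <- floor((v - raster$origin[2]) / raster$pitch) + 1
  ok <- i >= 1 & i <= raster$nx & j >= 1 & j <= raster$ny
  out <- rep(FALSE, length(u))
  out[ok] <- raster$grid[cbind(i[ok], j[ok])]
  out
}
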