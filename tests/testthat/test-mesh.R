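test_that("area and perimeter are invariant under rigid motions", {
  for (seed in 1:4) {
    for (shape in c("macular", "perforated", "horseshoe", "fragmented")) {
      m <- generate_sas_mesh(shape, 2e5, seed = seed)
      rot <- synmorph:::with_seed(seed + 100, synmorph:::random_rotation())
      m2 <- transform_mesh(m, rot, c(123.4, -56.7, 89))
      expect_equal(mesh_area(m2), mesh_area(m), tolerance = 1e-9)
      expect_equal(mesh_perimeter(m2), mesh_perimeter(m), tolerance = 1e-9)
    }
  }
})

test_that("Euler characteristic and boundary loops match analytic topology", {
  disk <- generate_sas_mesh("macular", 1e5, seed = 1)
  expect_identical(euler_characteristic(disk), 1L)
  expect_length(boundary_loops(disk), 1)

  annulus <- generate_sas_mesh("perforated", 1e5, seed = 1)
  expect_identical(euler_characteristic(annulus), 0L)
  expect_length(boundary_loops(annulus), 2)
})

test_that("multi-hole patches count holes via independent loop tracing", {
  # punch 3 holes into a gridded square patch
  n <- 40
  occ <- matrix(TRUE, n, n)
  punch <- function(occ, ci, cj, r) {
    for (i in seq_len(nrow(occ))) {
      for (j in seq_len(ncol(occ))) {
        if ((i - ci)^2 + (j - cj)^2 <= r^2) occ[i, j] <- FALSE
      }
    }
    occ
  }
  occ <- punch(occ, 10, 10, 4)
  occ <- punch(occ, 10, 30, 4)
  occ <- punch(occ, 30, 20, 4)
  gm <- synmorph:::triangulate_cells(occ, matrix(0, n, n), c(0, 0), 10)
  mesh <- sas_mesh(gm$vertices, gm$triangles)
  expect_identical(count_holes(mesh), 3L)
  expect_identical(oracle_loop_count(mesh), 4L)
})

test_that("component counting agrees with a union-find oracle", {
  pieces <- lapply(1:5, function(i) {
    m <- generate_sas_mesh("macular", 2e4 * i, seed = i)
    transform_mesh(m, diag(3), c(i * 5000, 0, 0))
  })
  verts <- do.call(rbind, lapply(pieces, function(m) m$vertices))
  offs <- cumsum(c(0, head(vapply(pieces, function(m) nrow(m$vertices), 1L), -1)))
  tris <- do.call(rbind, Map(function(m, o) m$triangles + o, pieces, offs))
  mesh <- sas_mesh(verts, tris)
  expect_identical(count_components(mesh), 5L)
  expect_identical(oracle_components(mesh), 5L)
})

test_that("curvature is zero for planar meshes and grows with isometric bending", {
  flat <- generate_sas_mesh("macular", pi * 500^2, seed = 3, irregularity = 0)
  expect_lt(sas_metrics(flat)$curvature, 1e-9)

  # cylindrical bend: x -> (R sin(x/R), y, R (1 - cos(x/R))) preserves lengths
  base <- synmorph:::with_seed(1, synmorph:::planar_sas_mesh("macular", pi * 500^2, 0))
  half_width <- max(abs(base$vertices[, 1]))
  curv <- vapply(seq(0.2, 1.4, by = 0.3), function(bend) {
    R <- half_width / bend
    v <- cbind(
      R * sin(base$vertices[, 1] / R),
      base$vertices[, 2],
      R * (1 - cos(base$vertices[, 1] / R))
    )
    sas_metrics(sas_mesh(v, base$triangles))$curvature
  }, numeric(1))
  expect_true(all(diff(curv) > 0))
})

test_that("curvature matches an independent plane-fit oracle on a hemisphere", {
  r <- 400
  cap <- synmorph:::band_mesh_2d(r * pi / 2, 1, n_rings = 11, n_sectors = 24)
  rho <- sqrt(rowSums(cap$vertices^2))
  ang <- atan2(cap$vertices[, 2], cap$vertices[, 1])
  v <- cbind(
    r * sin(rho / r) * cos(ang),
    r * sin(rho / r) * sin(ang),
    r * cos(rho / r)
  )
  mesh <- sas_mesh(v, cap$triangles)
  got <- sas_metrics(mesh)$curvature

  # oracle: direct area-weighted eigen plane fit on the same vertices
  ta <- synmorph:::triangle_areas(mesh)
  w <- rep(0, nrow(v))
  for (k in 1:3) {
    for (t_ in seq_len(nrow(mesh$triangles))) {
      w[mesh$triangles[t_, k]] <- w[mesh$triangles[t_, k]] + ta[t_] / 3
    }
  }
  w <- w / sum(w)
  ctr <- colSums(v * w)
  d <- sweep(v, 2, ctr)
  ev <- eigen(t(d * w) %*% d, symmetric = TRUE)$vectors[, 3]
  oracle <- sqrt(sum(w * (d %*% ev)^2)) / sqrt(mesh_area(mesh))
  expect_equal(got, oracle, tolerance = 1e-8)
  expect_gt(got, 0.05)
})

test_that("non-manifold edges are reported", {
  # three triangles sharing one edge
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))
  tr <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  expect_error(boundary_loops(sas_mesh(v, tr)), "edge-manifold")
})
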