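test_that("a flat slab extracts to its mid-plane area and zero curvature", {
  vol <- slab_volume(1000, 1000, 40)
  mesh <- extract_sas(vol, 1L)
  expect_equal(mesh_area(mesh), 1e6, tolerance = 0.05)
  met <- sas_metrics(mesh)
  expect_equal(met$perimeter_nm, 4000, tolerance = 0.05)
  expect_lt(met$curvature, 1e-3)
})

test_that("slab extraction is invariant to in-plane rotation", {
  # 45-degree rotated square slab built directly in voxels
  dims <- c(300, 300, 16)
  vs <- c(5, 5, 20)
  lab <- array(0L, dims)
  xs <- (seq_len(dims[1]) - 0.5) * vs[1]
  ys <- (seq_len(dims[2]) - 0.5) * vs[2]
  X <- matrix(xs, dims[1], dims[2])
  Y <- matrix(ys, dims[1], dims[2], byrow = TRUE)
  u <- (X - 750) / sqrt(2) + (Y - 750) / sqrt(2)
  v <- -(X - 750) / sqrt(2) + (Y - 750) / sqrt(2)
  in2d <- abs(u) < 500 & abs(v) < 500
  for (k in 6:7) lab[, , k][in2d] <- 1L
  vol <- labeled_volume(lab, vs)
  mesh <- extract_sas(vol, 1L)
  expect_equal(mesh_area(mesh), 1e6, tolerance = 0.05)
})

test_that("degenerate two-voxel objects still give a valid mesh", {
  lab <- array(0L, c(10, 10, 5))
  lab[5, 5, 2] <- 1L
  lab[6, 5, 2] <- 1L
  mesh <- extract_sas(labeled_volume(lab, c(5, 5, 20)), 1L)
  expect_s3_class(mesh, "sas_mesh")
  expect_gt(mesh_area(mesh), 0)
})

test_that("unknown IDs error on extraction", {
  vol <- slab_volume(400, 400, 40)
  expect_error(extract_sas(vol, 99L), "not present")
})

test_that("shrinkage correction divides areas by p^2 and lengths by p", {
  disk <- generate_sas_mesh("macular", pi * 500^2, seed = 2, irregularity = 0)
  met <- sas_metrics(disk, shrinkage_p2 = 0.933)
  expect_equal(met$corrected_area_nm2, met$area_nm2 / 0.933, tolerance = 1e-12)
  expect_equal(met$corrected_perimeter_nm, met$perimeter_nm / sqrt(0.933),
    tolerance = 1e-12)
  expect_error(sas_metrics(disk, shrinkage_p2 = 0), "0, 1")
})

test_that("PSD thickness separates the two synapse types on a noiseless scene", {
  cfg <- small_scene_config(seed = 77, psd_thickness_cv = 0)
  sc <- generate_scene(cfg)
  ty <- classify_types(sc$volume, sc$synapses$synapse_id,
    sas_areas = sc$synapses$area_nm2)
  expect_identical(ty$type, sc$synapses$type)
  # measured thickness clusters near the configured 40 / 15 nm means
  as_t <- ty$psd_thickness_nm[sc$synapses$type == "AS"]
  ss_t <- ty$psd_thickness_nm[sc$synapses$type == "SS"]
  expect_equal(median(as_t), 40, tolerance = 0.2)
  expect_equal(median(ss_t), 15, tolerance = 0.3)
})

test_that("junctions absent from the volume come back indeterminate", {
  vol <- slab_volume(400, 400, 40)
  res <- classify_types(vol, c(1L, 42L), sas_areas = c(160000, 160000))
  expect_identical(res$type[2], "indeterminate")
  expect_identical(res$type[1], "AS")
})

test_that("extracted SAS area tracks the ground-truth mesh area on scene junctions", {
  sc <- small_scene()
  syn <- sc$synapses
  big_as <- which(syn$type == "AS" & syn$area_nm2 > 1e5)[1:8]
  rel_err <- vapply(big_as, function(i) {
    m <- extract_sas(sc$volume, syn$synapse_id[i])
    abs(mesh_area(m) - syn$area_nm2[i]) / syn$area_nm2[i]
  }, numeric(1))
  expect_lt(median(rel_err), 0.25)
})
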