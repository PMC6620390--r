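test_that("the decision tree recovers generated shape classes", {
  for (seed in 1:8) {
    for (shape in c("macular", "perforated", "horseshoe", "fragmented")) {
      m <- generate_sas_mesh(shape, 1.2e5 + 3e4 * seed, seed = seed)
      call <- classify_shape(m)
      expect_identical(call$shape_class, shape)
    }
  }
})

test_that("exactly one class is assigned and fields obey the taxonomy invariants", {
  meshes <- lapply(1:12, function(s) {
    generate_sas_mesh(sample(c("macular", "perforated", "horseshoe",
      "fragmented"), 1), 2e5, seed = s)
  })
  calls <- classify_shapes(meshes)
  expect_true(all(calls$shape_class %in%
    c("macular", "perforated", "horseshoe", "fragmented")))
  frag <- calls$shape_class == "fragmented"
  expect_true(all(calls$n_components[frag] >= 2))
  expect_true(all(calls$n_components[!frag] == 1))
  perf <- calls$shape_class == "perforated"
  expect_true(all(calls$n_holes[perf] >= 1))
  mac <- calls$shape_class == "macular" & calls$flattened
  expect_true(all(calls$indentation_depth_ratio[mac] < 0.3))
})

test_that("classification is invariant under rigid motion and uniform scaling", {
  for (shape in c("macular", "perforated", "horseshoe", "fragmented")) {
    m <- generate_sas_mesh(shape, 2.4e5, seed = 3)
    rot <- synmorph:::with_seed(9, synmorph:::random_rotation())
    m2 <- transform_mesh(m, rot, c(1000, -400, 250))
    m3 <- sas_mesh(m2$vertices * 3.7, m2$triangles)
    expect_identical(classify_shape(m2)$shape_class, shape)
    expect_identical(classify_shape(m3)$shape_class, shape)
  }
})

test_that("multiplicity dominates topology: fragmented pieces with holes stay fragmented", {
  ann <- generate_sas_mesh("perforated", 1e5, seed = 2)
  disk <- transform_mesh(generate_sas_mesh("macular", 6e4, seed = 2),
    diag(3), c(5000, 0, 0))
  both <- sas_mesh(
    rbind(ann$vertices, disk$vertices),
    rbind(ann$triangles, disk$triangles + nrow(ann$vertices))
  )
  call <- classify_shape(both)
  expect_identical(call$shape_class, "fragmented")
  expect_identical(call$n_components, 2L)
  expect_gte(call$n_holes, 1L)
})

test_that("indentation depth is zero for convex outlines and large for C-bands", {
  disk <- generate_sas_mesh("macular", 2e5, seed = 1, irregularity = 0)
  expect_lt(indentation_depth(disk), 0.02)
  # square outline, built as a gridded quad patch
  n <- 12
  gm <- synmorph:::triangulate_cells(matrix(TRUE, n, n), matrix(0, n, n),
    c(0, 0), 100)
  sq <- sas_mesh(gm$vertices, gm$triangles)
  expect_lt(indentation_depth(sq), 1e-9)
  cband <- generate_sas_mesh("horseshoe", 2e5, seed = 1, irregularity = 0)
  expect_gt(indentation_depth(cband), 0.5)
})

test_that("the horseshoe threshold splits macular from horseshoe at the boundary", {
  h <- generate_sas_mesh("horseshoe", 2e5, seed = 6)
  r <- indentation_depth(h)
  expect_identical(classify_shape(h, horseshoe_threshold = r + 0.01)$shape_class,
    "macular")
  expect_identical(classify_shape(h, horseshoe_threshold = r - 0.01)$shape_class,
    "horseshoe")
})
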