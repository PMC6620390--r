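test_that("zero synapse density yields a dendrites-only scene", {
  cfg <- scenario_config(
    volume_shape = c(80, 80, 30), voxel_size = c(25, 25, 50),
    n_dendrites = 3, synapse_density = 0, seed = 5
  )
  sc <- generate_scene(cfg)
  expect_identical(nrow(sc$synapses), 0L)
  expect_true(all(sc$volume$objects$class != "synapse"))
  expect_gt(sum(sc$volume$labels > 0), 0)
})

test_that("scene generation is voxel-identical for a fixed seed", {
  cfg <- scenario_config(
    volume_shape = c(100, 100, 44), voxel_size = c(25, 25, 50),
    n_dendrites = 4, spines_per_micron = 3.5, fraction_aspiny_dendrites = 0.25,
    spine_head_radius_nm = c(mean = 250, sd = 20),
    synapse_density = 1.2, max_retries = 200, seed = 31
  )
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$volume$labels, b$volume$labels)
  expect_identical(
    a$synapses[setdiff(names(a$synapses), "mesh")],
    b$synapses[setdiff(names(b$synapses), "mesh")]
  )
  expect_identical(a$synapses$mesh[[1]]$vertices, b$synapses$mesh[[1]]$vertices)
})

test_that("ground truth is consistent with the label volume", {
  sc <- small_scene()
  syn <- sc$synapses
  expect_gt(nrow(syn), 100)
  lab_ids <- unique(as.vector(sc$volume$labels))
  expect_true(all(syn$synapse_id %in% lab_ids))
  # truncation flag means exactly border contact
  idx <- sample(seq_len(nrow(syn)), 25)
  for (i in idx) {
    expect_identical(
      syn$truncated[i],
      synmorph:::object_touches_border(sc$volume, syn$synapse_id[i])
    )
  }
  # voxel counts recorded at generation match the volume
  tab <- table(sc$volume$labels[sc$volume$labels %in% syn$synapse_id])
  expect_identical(unname(as.integer(tab[as.character(syn$synapse_id)])),
    syn$n_voxels)
})

test_that("the AS fraction of a generated scene sits inside its binomial interval", {
  sc <- small_scene()
  n <- nrow(sc$synapses)
  n_as <- sum(sc$synapses$type == "AS")
  expect_gte(n_as, qbinom(0.005, n, 0.95))
  expect_lte(n_as, qbinom(0.995, n, 0.95))
})

test_that("configured marginals are recovered by the ground truth labels", {
  sc <- small_scene()
  truth <- sc$synapses[c("synapse_id", "type", "target_class", "shape_class")]
  gof <- recovery_gof(sc, truth)
  expect_true(all(gof$p_value > 0.001))
})

test_that("an unplaceable density fails with a diagnostic", {
  cfg <- scenario_config(
    volume_shape = c(60, 60, 24), voxel_size = c(25, 25, 50),
    n_dendrites = 2, spines_per_micron = 2, synapse_density = 80, seed = 1,
    max_retries = 20
  )
  expect_error(generate_scene(cfg), "cannot be placed|dendrites|hosts")
})
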