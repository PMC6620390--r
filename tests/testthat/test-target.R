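test_that("targets are recovered exactly on a fully contained scene", {
  sc <- small_scene()
  tg <- assign_targets(sc$volume)
  joined <- dplyr::inner_join(
    tg, sc$synapses[c("synapse_id", "target_class")],
    by = "synapse_id", suffix = c("_pred", "_true")
  )
  expect_identical(nrow(joined), nrow(sc$synapses))
  expect_gte(mean(joined$target_class_pred == joined$target_class_true), 0.95)
  # partition property: exactly one class per synapse
  expect_false(any(duplicated(tg$synapse_id)))
  expect_true(all(tg$target_class %in%
    c("spine_head", "spine_neck", "aspiny_shaft", "spiny_shaft", "unknown")))
  # spine targets imply successful tracing
  sp <- tg$target_class %in% c("spine_head", "spine_neck")
  expect_true(all(tg$traced_to_parent[sp]))
})

test_that("shrinking the volume only converts classified targets to unknown", {
  sc <- small_scene()
  full <- assign_targets(sc$volume)
  d <- dim(sc$volume$labels)
  cropped_vol <- crop_volume(sc$volume, c(1, 1, 1), d - c(30, 30, 8))
  keep <- intersect(
    full$synapse_id,
    cropped_vol$objects$object_id[cropped_vol$objects$class == "synapse"]
  )
  cropped <- assign_targets(cropped_vol, keep)
  cmp <- dplyr::inner_join(full, cropped, by = "synapse_id",
    suffix = c("_full", "_crop"))
  changed <- cmp$target_class_full != cmp$target_class_crop
  # cropping can only lose information: a classified target becomes
  # unknown, or a spiny shaft loses its (cropped-away) spines and is read
  # as aspiny -- never the reverse
  ok <- cmp$target_class_crop[changed] == "unknown" |
    (cmp$target_class_full[changed] == "spiny_shaft" &
     cmp$target_class_crop[changed] == "aspiny_shaft")
  expect_true(all(ok))
  expect_false(any(cmp$target_class_full == "unknown" &
    cmp$target_class_crop != "unknown"))
})

test_that("AS prefer spine heads and SS prefer shafts in generated scenes", {
  sc <- small_scene()
  tg <- assign_targets(sc$volume)
  joined <- dplyr::inner_join(tg, sc$synapses[c("synapse_id", "type")],
    by = "synapse_id")
  as_head <- mean(joined$target_class[joined$type == "AS"] == "spine_head")
  n_as <- sum(joined$type == "AS")
  expect_gte(as_head, qbinom(0.005, n_as, 825 / 1396) / n_as)
  expect_lte(as_head, qbinom(0.995, n_as, 825 / 1396) / n_as)
})

test_that("spine occupancy bins single and multiple synapses correctly", {
  targets <- tibble::tibble(
    synapse_id = 1:6,
    target_class = c(rep("spine_head", 5), "aspiny_shaft"),
    postsynaptic_object_id = c(10L, 11L, 11L, 12L, 12L, 20L),
    traced_to_parent = c(rep(TRUE, 5), NA),
    contact_area_nm2 = 1
  )
  types <- tibble::tibble(
    synapse_id = 1:6,
    type = c("AS", "AS", "AS", "AS", "SS", "AS")
  )
  occ <- spine_occupancy(targets, types)
  expect_identical(nrow(occ$occupancy), 3L)
  comp <- setNames(occ$occupancy$composition, occ$occupancy$spine_head_id)
  expect_identical(comp[["10"]], "single_AS")
  expect_identical(comp[["11"]], "two_AS")
  expect_identical(comp[["12"]], "AS_SS")
  expect_equal(sum(occ$frequency$percent), 100)
})

test_that("an all-single-AS scene reports 100 percent single AS", {
  targets <- tibble::tibble(
    synapse_id = 1:4,
    target_class = "spine_head",
    postsynaptic_object_id = 21:24,
    traced_to_parent = TRUE,
    contact_area_nm2 = 1
  )
  types <- tibble::tibble(synapse_id = 1:4, type = "AS")
  occ <- spine_occupancy(targets, types)
  expect_identical(occ$frequency$composition, "single_AS")
  expect_equal(occ$frequency$percent, 100)
})
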