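# Shared fixtures built in code. The small scene is generated once per test
# run and reused across test files.

small_scene_config <- function(seed = 42, ...) {
  scenario_config(
    volume_shape = c(200, 200, 60),
    voxel_size = c(25, 25, 50),
    n_dendrites = 12,
    spines_per_micron = 3,
    fraction_aspiny_dendrites = 0.3,
    spine_head_radius_nm = c(mean = 250, sd = 20),
    synapse_density = 2,
    max_retries = 200,
    seed = seed,
    ...
  )
}

small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_scene(small_scene_config())
    cache
  }
})

# Configuration used for parameter-recovery runs: control-group mixes at
# 2000 junctions in a 10 x 10 x 6 um volume at 25 x 25 x 50 nm voxels.
recovery_config <- function(seed) {
  scenario_config(
    volume_shape = c(400, 400, 120),
    voxel_size = c(25, 25, 50),
    n_dendrites = 48,
    spines_per_micron = 3,
    fraction_aspiny_dendrites = 0.4,
    spine_head_radius_nm = c(mean = 250, sd = 20),
    synapse_density = 2000 / 600,
    max_retries = 200,
    seed = seed
  )
}

# Classify a scene with all three classifiers and return the tibble that
# recovery_gof() expects.
classify_scene <- function(scene) {
  adjacency <- volume_adjacency(scene$volume)
  tg <- assign_targets(scene$volume, scene$synapses$synapse_id, adjacency)
  ty <- classify_types(scene$volume, scene$synapses$synapse_id,
    sas_areas = scene$synapses$area_nm2)
  sh <- classify_shapes(scene$synapses$mesh)
  tibble::tibble(
    synapse_id = scene$synapses$synapse_id,
    type = ty$type,
    target_class = tg$target_class[match(scene$synapses$synapse_id, tg$synapse_id)],
    shape_class = sh$shape_class
  )
}

# A flat rectangular junction slab in a labelled volume, for extraction
# oracles: extent in nm, slab thickness centred mid-volume.
slab_volume <- function(side_x = 1000, side_y = 1000, thickness = 40,
                        voxel_size = c(5, 5, 20), margin = 250) {
  dims <- ceiling(c(side_x + 2 * margin, side_y + 2 * margin, 8 * thickness) /
    voxel_size)
  lab <- array(0L, dims)
  ctr <- dims * voxel_size / 2
  ax <- (seq_len(dims[1]) - 0.5) * voxel_size[1]
  ay <- (seq_len(dims[2]) - 0.5) * voxel_size[2]
  az <- (seq_len(dims[3]) - 0.5) * voxel_size[3]
  ix <- which(abs(ax - ctr[1]) < side_x / 2)
  iy <- which(abs(ay - ctr[2]) < side_y / 2)
  iz <- which(az >= ctr[3] & az < ctr[3] + thickness)
  lab[ix, iy, iz] <- 1L
  labeled_volume(lab, voxel_size)
}

# Independent union-find oracle over triangle edge adjacency.
oracle_components <- function(mesh) {
  tr <- mesh$triangles
  m <- nrow(tr)
  parent <- seq_len(m)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  ekey <- function(i, j) paste(min(i, j), max(i, j))
  seen <- new.env()
  for (t_ in seq_len(m)) {
    for (e in list(tr[t_, 1:2], tr[t_, 2:3], tr[t_, c(3, 1)])) {
      k <- ekey(e[1], e[2])
      if (!is.null(seen[[k]])) {
        ra <- find(seen[[k]]); rb <- find(t_)
        if (ra != rb) parent[rb] <- ra
      } else {
        seen[[k]] <- t_
      }
    }
  }
  length(unique(vapply(seq_len(m), find, integer(1))))
}

# Independent loop-count oracle: boundary edges chained with igraph.
oracle_loop_count <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bkeys <- names(tab)[tab == 1]
  if (!length(bkeys)) return(0L)
  parts <- do.call(rbind, strsplit(bkeys, " "))
  g <- igraph::graph_from_edgelist(
    cbind(as.integer(parts[, 1]), as.integer(parts[, 2])), directed = FALSE)
  comps <- igraph::components(g)
  sum(comps$csize > 1)
}
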