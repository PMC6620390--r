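#' Scenario configuration for synthetic neuropil generation
#'
#' Collects every parameter of the synthetic scene generator. Defaults encode
#' the imaging and composition conditions of 3D FIB/SEM studies of human
#' cortical neuropil: 5 x 5 x 20 nm voxels, asymmetric:symmetric ratio
#' ~95:5, target and shape mixes matching the published control tables
#' (see [reference_counts()]), synapse density ~0.5 per cubic micron, and
#' PSD thickness means of 40 nm (asymmetric, prominent PSD) versus 15 nm
#' (symmetric, thin PSD).
#'
#' @param volume_shape Integer length-3: voxels along x, y, z.
#' @param voxel_size Numeric length-3: nm per voxel (default `c(5, 5, 20)`).
#' @param n_dendrites Number of dendritic shafts; `NULL` sizes the bundle
#'   automatically from the synapse budget.
#' @param spines_per_micron Spine rate per micron of spiny dendrite.
#' @param fraction_aspiny_dendrites Proportion of dendrites without spines.
#' @param synapse_density Junctions per cubic micron.
#' @param as_fraction Proportion of asymmetric synapses (default 0.95).
#' @param target_mix Named list with elements `AS` and `SS`, each a
#'   probability vector over `spine_head`, `spine_neck`, `aspiny_shaft`,
#'   `spiny_shaft`.
#' @param shape_mix Named list with elements `AS` and `SS`, each a
#'   probability vector over `macular`, `perforated`, `horseshoe`,
#'   `fragmented`.
#' @param sas_area_lognormal Named list per shape class with `meanlog` and
#'   `sdlog` of the SAS area distribution (nm^2). The log-normal family is
#'   an assumption made from the right-skewed published area histograms.
#' @param psd_thickness Named numeric `c(AS = , SS = )`, mean PSD slab
#'   thickness in nm; kept at >= 3:1 separation so type has a physical
#'   correlate.
#' @param psd_thickness_cv Coefficient of variation of per-synapse thickness.
#' @param seed Integer seed; all generator randomness flows from it.
#' @param dendrite_radius_nm,spine_neck_radius_nm,spine_neck_length_nm,spine_head_radius_nm
#'   Geometry of the tubular/spheroid primitives (nm).
#' @param irregularity Outline irregularity of generated SAS meshes.
#' @param min_area_nm2,max_area_nm2 Truncation bounds for sampled SAS areas.
#' @param max_retries Placement retries per object before the generator
#'   gives up with a diagnostic.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(volume_shape,
                            voxel_size = c(5, 5, 20),
                            n_dendrites = NULL,
                            spines_per_micron = 1.2,
                            fraction_aspiny_dendrites = 0.5,
                            synapse_density = 0.5,
                            as_fraction = 0.95,
                            target_mix = default_target_mix(),
                            shape_mix = default_shape_mix(),
                            sas_area_lognormal = default_sas_area_lognormal(),
                            psd_thickness = c(AS = 40, SS = 15),
                            psd_thickness_cv = 0.08,
                            seed = 1L,
                            dendrite_radius_nm = c(mean = 300, sd = 30),
                            spine_neck_radius_nm = 80,
                            spine_neck_length_nm = 400,
                            spine_head_radius_nm = c(mean = 220, sd = 20),
                            irregularity = 0.03,
                            min_area_nm2 = 2e4,
                            max_area_nm2 = 1.5e6,
                            max_retries = 100L) {
  name_pair <- function(x, nms) {
    x <- as.numeric(x)
    if (is.null(names(x)) || !all(nms %in% names(x))) {
      names(x) <- nms[seq_along(x)]
    }
    x
  }
  dendrite_radius_nm <- name_pair(dendrite_radius_nm, c("mean", "sd"))
  spine_head_radius_nm <- name_pair(spine_head_radius_nm, c("mean", "sd"))
  psd_thickness <- name_pair(psd_thickness, c("AS", "SS"))
  cfg <- list(
    volume_shape = as.integer(volume_shape),
    voxel_size = as.numeric(voxel_size),
    n_dendrites = if (is.null(n_dendrites)) NULL else as.integer(n_dendrites),
    spines_per_micron = spines_per_micron,
    fraction_aspiny_dendrites = fraction_aspiny_dendrites,
    synapse_density = synapse_density,
    as_fraction = as_fraction,
    target_mix = target_mix,
    shape_mix = shape_mix,
    sas_area_lognormal = sas_area_lognormal,
    psd_thickness = psd_thickness,
    psd_thickness_cv = psd_thickness_cv,
    seed = as.integer(seed),
    dendrite_radius_nm = dendrite_radius_nm,
    spine_neck_radius_nm = spine_neck_radius_nm,
    spine_neck_length_nm = spine_neck_length_nm,
    spine_head_radius_nm = spine_head_radius_nm,
    irregularity = irregularity,
    min_area_nm2 = min_area_nm2,
    max_area_nm2 = max_area_nm2,
    max_retries = as.integer(max_retries)
  )
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

target_classes <- c("spine_head", "spine_neck", "aspiny_shaft", "spiny_shaft")
shape_classes <- c("macular", "perforated", "horseshoe", "fragmented")

# Control-group target preferences (proportions of the published control
# counts 825/7/278/286 for AS and 8/1/43/60 for SS).
default_target_mix <- function() {
  list(
    AS = setNames(c(825, 7, 278, 286) / 1396, target_classes),
    SS = setNames(c(8, 1, 43, 60) / 112, target_classes)
  )
}

# Control-group shape mixes (2145/302/98/16 for AS, 106/5/16/0 for SS).
default_shape_mix <- function() {
  list(
    AS = setNames(c(2145, 302, 98, 16) / 2561, shape_classes),
    SS = setNames(c(106, 5, 16, 0) / 127, shape_classes)
  )
}

# Log-normal SAS area parameters per shape class, chosen so the means match
# the published control-group averages (~88e3 macular, ~265e3 perforated,
# ~262e3 horseshoe, ~360e3 fragmented nm^2) with sdlog 0.6.
default_sas_area_lognormal <- function() {
  means <- c(macular = 88272, perforated = 264960,
             horseshoe = 262251, fragmented = 360245)
  sdlog <- 0.6
  lapply(as.list(means), function(m) {
    list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  })
}

check_prob_vector <- function(p, classes, what) {
  if (!all(classes %in% names(p))) {
    abort(sprintf("`%s` must name all of: %s", what, paste(classes, collapse = ", ")))
  }
  p <- p[classes]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort(sprintf("`%s` must be a probability vector summing to 1", what))
  }
  p
}

validate_scenario_config <- function(cfg) {
  if (length(cfg$volume_shape) != 3 || any(cfg$volume_shape < 2)) {
    abort("`volume_shape` must be three voxel counts >= 2")
  }
  if (length(cfg$voxel_size) != 3 || any(!is.finite(cfg$voxel_size)) ||
      any(cfg$voxel_size <= 0)) {
    abort("`voxel_size` must be strictly positive on all axes")
  }
  if (cfg$as_fraction < 0 || cfg$as_fraction > 1) {
    abort("`as_fraction` must be in [0, 1]")
  }
  if (cfg$fraction_aspiny_dendrites < 0 || cfg$fraction_aspiny_dendrites > 1) {
    abort("`fraction_aspiny_dendrites` must be in [0, 1]")
  }
  if (cfg$synapse_density < 0) abort("`synapse_density` must be >= 0")
  for (ty in c("AS", "SS")) {
    check_prob_vector(cfg$target_mix[[ty]], target_classes,
      paste0("target_mix$", ty))
    check_prob_vector(cfg$shape_mix[[ty]], shape_classes,
      paste0("shape_mix$", ty))
  }
  if (!all(shape_classes %in% names(cfg$sas_area_lognormal))) {
    abort("`sas_area_lognormal` must cover all four shape classes")
  }
  if (!all(c("AS", "SS") %in% names(cfg$psd_thickness)) ||
      any(cfg$psd_thickness <= 0)) {
    abort("`psd_thickness` must give positive AS and SS means")
  }
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  ext <- x$volume_shape * x$voxel_size / 1000
  cat(sprintf(
    "<scenario_config> %.2f x %.2f x %.2f um at (%g, %g, %g) nm, density %g um^-3, AS fraction %g, seed %d\n",
    ext[1], ext[2], ext[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$synapse_density, x$as_fraction, x$seed
  ))
  invisible(x)
}
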