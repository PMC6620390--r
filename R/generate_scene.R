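# Synthetic neuropil scene generation: capsule-swept dendritic shafts,
# ellipsoidal spine heads on cylindrical necks, and synaptic junctions carved
# as curved slabs conforming to the host surface. All geometry is computed in
# nm; voxel masks use voxel-centre membership, which keeps voxel counts an
# unbiased estimate of object volume at any grid resolution.

# Voxel index ranges covering an nm bounding box; NULL if it pokes outside
# the volume and `strict` is TRUE.
bbox_indices <- function(dims, lo_nm, hi_nm, vs, strict = FALSE) {
  lo <- floor(lo_nm / vs) + 1
  hi <- ceiling(hi_nm / vs)
  if (strict && (any(lo < 1) || any(hi > dims))) return(NULL)
  lo <- pmax(1, pmin(dims, lo))
  hi <- pmax(1, pmin(dims, hi))
  if (any(lo > hi)) return(NULL)
  list(ix = lo[1]:hi[1], iy = lo[2]:hi[2], iz = lo[3]:hi[3])
}

# Voxel-centre coordinates for a subarray, in subarray linearisation order
# (first index fastest, matching R's array indexing).
block_coords <- function(bb, vs) {
  n1 <- length(bb$ix); n2 <- length(bb$iy); n3 <- length(bb$iz)
  list(
    x = rep((bb$ix - 0.5) * vs[1], times = n2 * n3),
    y = rep(rep((bb$iy - 0.5) * vs[2], each = n1), times = n3),
    z = rep((bb$iz - 0.5) * vs[3], each = n1 * n2)
  )
}

block_touches_border <- function(bb, dims, mask) {
  # objects with an interior bounding box cannot touch a face
  if (bb$ix[1] > 1L && bb$ix[length(bb$ix)] < dims[1] &&
      bb$iy[1] > 1L && bb$iy[length(bb$iy)] < dims[2] &&
      bb$iz[1] > 1L && bb$iz[length(bb$iz)] < dims[3]) {
    return(FALSE)
  }
  n1 <- length(bb$ix); n2 <- length(bb$iy); n3 <- length(bb$iz)
  i <- rep(bb$ix, times = n2 * n3)
  j <- rep(rep(bb$iy, each = n1), times = n3)
  k <- rep(bb$iz, each = n1 * n2)
  any(mask & (i == 1L | i == dims[1] | j == 1L | j == dims[2] |
              k == 1L | k == dims[3]))
}

# Infinite-cylinder mask for a dendritic shaft spanning the volume. The
# shaft is voxelised in x-chunks so tilted lines keep tight bounding boxes;
# returns a list of chunk masks.
shaft_mask <- function(dims, vs, P, a, r, chunk = 40L) {
  L <- dims * vs
  out <- list()
  starts <- seq(1L, dims[1], by = chunk)
  for (s in starts) {
    e <- min(dims[1], s + chunk - 1L)
    x_lo <- (s - 1) * vs[1]
    x_hi <- e * vs[1]
    t0 <- (x_lo - r - P[1]) / a[1]
    t1 <- (x_hi + r - P[1]) / a[1]
    e0 <- P + t0 * a
    e1 <- P + t1 * a
    lo <- pmin(e0, e1) - r - vs
    hi <- pmax(e0, e1) + r + vs
    lo[1] <- x_lo
    hi[1] <- x_hi
    bb <- bbox_indices(dims, lo, hi, vs)
    if (is.null(bb)) next
    cc <- block_coords(bb, vs)
    wx <- cc$x - P[1]; wy <- cc$y - P[2]; wz <- cc$z - P[3]
    proj <- wx * a[1] + wy * a[2] + wz * a[3]
    dist2 <- wx^2 + wy^2 + wz^2 - proj^2
    mask <- dist2 <= r^2
    if (any(mask)) out[[length(out) + 1]] <- list(bb = bb, mask = mask)
  }
  out
}

# Capsule (finite segment, hemispherical caps) mask, e.g. a spine neck.
capsule_mask <- function(dims, vs, p0, dir, len, r, strict = FALSE) {
  p1 <- p0 + dir * len
  lo <- pmin(p0, p1) - r - vs
  hi <- pmax(p0, p1) + r + vs
  bb <- bbox_indices(dims, lo, hi, vs, strict = strict)
  if (is.null(bb)) return(NULL)
  cc <- block_coords(bb, vs)
  wx <- cc$x - p0[1]; wy <- cc$y - p0[2]; wz <- cc$z - p0[3]
  t_ <- pmin(len, pmax(0, wx * dir[1] + wy * dir[2] + wz * dir[3]))
  dist2 <- (wx - t_ * dir[1])^2 + (wy - t_ * dir[2])^2 + (wz - t_ * dir[3])^2
  list(bb = bb, mask = dist2 <= r^2)
}

sphere_mask <- function(dims, vs, centre, r, strict = FALSE) {
  bb <- bbox_indices(dims, centre - r - vs, centre + r + vs, vs, strict = strict)
  if (is.null(bb)) return(NULL)
  cc <- block_coords(bb, vs)
  d2 <- (cc$x - centre[1])^2 + (cc$y - centre[2])^2 + (cc$z - centre[3])^2
  list(bb = bb, mask = d2 <= r^2)
}

# Curved junction slab on a spherical host: voxels in the radial shell
# (R, R + t] whose geodesic patch coordinates fall on the footprint raster.
# `chk` is a slightly dilated version used for collision clearance.
sphere_patch_mask <- function(dims, vs, C, R, t, u, frame, raster, raster_chk,
                              rho_max, clear) {
  c0 <- C + R * u
  h <- rho_max + t + clear + max(vs)
  bb <- bbox_indices(dims, c0 - h, c0 + h, vs, strict = TRUE)
  if (is.null(bb)) return(NULL)
  cc <- block_coords(bb, vs)
  wx <- cc$x - C[1]; wy <- cc$y - C[2]; wz <- cc$z - C[3]
  s2 <- wx^2 + wy^2 + wz^2
  rad_chk <- s2 > R^2 & s2 <= (R + t + clear)^2
  n_all <- length(s2)
  mask <- logical(n_all)
  chk <- logical(n_all)
  sel <- which(rad_chk)
  if (length(sel)) {
    s <- sqrt(s2[sel])
    wxs <- wx[sel]; wys <- wy[sel]; wzs <- wz[sel]
    ca <- pmin(1, pmax(-1, (wxs * u[1] + wys * u[2] + wzs * u[3]) / s))
    rho <- R * acos(ca)
    p1 <- wxs * frame$e1[1] + wys * frame$e1[2] + wzs * frame$e1[3]
    p2 <- wxs * frame$e2[1] + wys * frame$e2[2] + wzs * frame$e2[3]
    phi <- atan2(p2, p1)
    uu <- rho * cos(phi)
    vv <- rho * sin(phi)
    chk[sel] <- raster_lookup(raster_chk, uu, vv)
    inner <- s <= R + t
    mask[sel] <- inner & raster_lookup(raster, uu, vv)
  }
  list(bb = bb, mask = mask, chk = chk)
}

# Curved junction slab wrapped on a cylindrical host (shaft or neck).
cylinder_patch_mask <- function(dims, vs, A0, a, Rc, t, t_c, u0, w0,
                                raster, raster_chk, rho_max, clear) {
  c0 <- A0 + t_c * a + Rc * u0
  h <- rho_max + t + clear + max(vs)
  bb <- bbox_indices(dims, c0 - h, c0 + h, vs, strict = TRUE)
  if (is.null(bb)) return(NULL)
  cc <- block_coords(bb, vs)
  wx <- cc$x - A0[1]; wy <- cc$y - A0[2]; wz <- cc$z - A0[3]
  ax <- wx * a[1] + wy * a[2] + wz * a[3]
  qx <- wx - ax * a[1]; qy <- wy - ax * a[2]; qz <- wz - ax * a[3]
  s2 <- qx^2 + qy^2 + qz^2
  rad_chk <- s2 > Rc^2 & s2 <= (Rc + t + clear)^2
  n_all <- length(s2)
  mask <- logical(n_all)
  chk <- logical(n_all)
  sel <- which(rad_chk)
  if (length(sel)) {
    pu <- qx[sel] * u0[1] + qy[sel] * u0[2] + qz[sel] * u0[3]
    pw <- qx[sel] * w0[1] + qy[sel] * w0[2] + qz[sel] * w0[3]
    phi <- atan2(pw, pu)
    uu <- ax[sel] - t_c
    vv <- Rc * phi
    chk[sel] <- raster_lookup(raster_chk, uu, vv)
    inner <- s2[sel] <= (Rc + t)^2
    mask[sel] <- inner & raster_lookup(raster, uu, vv)
  }
  list(bb = bb, mask = mask, chk = chk)
}

wrap_on_sphere <- function(m2, C, R, u, frame) {
  x <- m2$vertices[, 1]; y <- m2$vertices[, 2]
  rho <- sqrt(x^2 + y^2)
  phi <- atan2(y, x)
  alpha <- rho / R
  dirx <- cos(alpha) * u[1] +
    sin(alpha) * (cos(phi) * frame$e1[1] + sin(phi) * frame$e2[1])
  diry <- cos(alpha) * u[2] +
    sin(alpha) * (cos(phi) * frame$e1[2] + sin(phi) * frame$e2[2])
  dirz <- cos(alpha) * u[3] +
    sin(alpha) * (cos(phi) * frame$e1[3] + sin(phi) * frame$e2[3])
  cbind(C[1] + R * dirx, C[2] + R * diry, C[3] + R * dirz)
}

wrap_on_cylinder <- function(m2, A0, a, Rc, t_c, u0, w0) {
  x <- m2$vertices[, 1]; y <- m2$vertices[, 2]
  beta <- y / Rc
  px <- A0[1] + (t_c + x) * a[1] + Rc * (cos(beta) * u0[1] + sin(beta) * w0[1])
  py <- A0[2] + (t_c + x) * a[2] + Rc * (cos(beta) * u0[2] + sin(beta) * w0[2])
  pz <- A0[3] + (t_c + x) * a[3] + Rc * (cos(beta) * u0[3] + sin(beta) * w0[3])
  cbind(px, py, pz)
}

mean_sas_area <- function(config) {
  shape_means <- vapply(shape_classes, function(sc) {
    p <- config$sas_area_lognormal[[sc]]
    exp(p$meanlog + p$sdlog^2 / 2)
  }, numeric(1))
  f <- config$as_fraction
  sum(f * config$shape_mix$AS[shape_classes] * shape_means) +
    sum((1 - f) * config$shape_mix$SS[shape_classes] * shape_means)
}

#' Generate a synthetic neuropil scene
#'
#' Builds a labeled voxel volume containing dendritic shafts (a jittered
#' quasi-parallel capsule bundle), spines (spherical heads on cylindrical
#' necks, fully contained in the volume), and synaptic junctions carved as
#' curved slabs on the host surface, each with a ground-truth SAS mesh of
#' the configured shape class. Placement is by rejection sampling with a
#' retry cap; if the requested density cannot be placed the generator stops
#' with a diagnostic. All randomness flows from `config$seed`, so a fixed
#' configuration reproduces the scene exactly.
#'
#' @param config A [scenario_config()].
#' @return An object of class `synapse_scene`: a list with elements
#'   `volume` (a [labeled_volume()]), `synapses` (tibble of per-junction
#'   ground truth, including a `mesh` list-column of [sas_mesh()] objects)
#'   and `config`.
#' @export
generate_scene <- function(config) {
  if (!inherits(config, "scenario_config")) {
    abort("`config` must be a scenario_config()")
  }
  with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(config) {
  dims <- config$volume_shape
  vs <- config$voxel_size
  L <- dims * vs
  vol_um3 <- prod(L) / 1e9
  n_syn <- round(config$synapse_density * vol_um3)
  clear <- max(vs)

  lab <- array(0L, dims)
  obj_rows <- list()
  next_id <- 1L

  # --- dendritic shaft bundle -------------------------------------------
  r_mean <- unname(config$dendrite_radius_nm["mean"])
  r_sd <- unname(config$dendrite_radius_nm["sd"])
  if (is.null(config$n_dendrites)) {
    need <- 3.0 * n_syn * mean_sas_area(config)
    per_d <- 2 * pi * r_mean * L[1]
    n_d <- max(4L, as.integer(ceiling(need / per_d)))
  } else {
    n_d <- config$n_dendrites
  }
  # grid placement supports spacing down to ~2.2 radii
  cap <- floor(L[2] * L[3] / (2.2 * r_mean)^2)
  if (n_d > cap) {
    abort(sprintf(
      "requested synapse density needs %d dendrites but at most %d fit the cross-section without overlap; enlarge the volume or lower the density",
      n_d, cap
    ))
  }
  ny_g <- max(1L, ceiling(sqrt(n_d * L[2] / L[3])))
  nz_g <- ceiling(n_d / ny_g)
  sy <- L[2] / ny_g
  sz <- L[3] / nz_g
  cells <- expand.grid(gy = seq_len(ny_g), gz = seq_len(nz_g))
  cells <- cells[sample.int(nrow(cells)), , drop = FALSE][seq_len(n_d), ]

  dendrites <- vector("list", n_d)
  for (di in seq_len(n_d)) {
    placed <- FALSE
    for (try_ in seq_len(config$max_retries)) {
      # redraw the radius each try (shrinking slightly under pressure) so a
      # large draw cannot wedge a crowded lattice cell permanently
      shrink <- 1 - 0.3 * (try_ - 1) / config$max_retries
      r_d <- min(1.4 * r_mean, max(0.6 * r_mean, rnorm(1, r_mean, r_sd))) * shrink
      r_d <- max(0.55 * r_mean, r_d)
      yc <- (cells$gy[di] - 0.5) * sy + runif(1, -0.2, 0.2) * sy
      zc <- (cells$gz[di] - 0.5) * sz + runif(1, -0.2, 0.2) * sz
      a <- unit(c(1, runif(1, -0.12, 0.12), runif(1, -0.12, 0.12)))
      P <- c(L[1] / 2, yc, zc)
      sm <- shaft_mask(dims, vs, P, a, r_d)
      if (!length(sm)) next
      clash <- FALSE
      for (ch in sm) {
        sub <- lab[ch$bb$ix, ch$bb$iy, ch$bb$iz]
        if (any(sub[ch$mask] != 0L)) {
          clash <- TRUE
          break
        }
      }
      if (clash) next
      for (ch in sm) {
        sub <- lab[ch$bb$ix, ch$bb$iy, ch$bb$iz]
        sub[ch$mask] <- next_id
        lab[ch$bb$ix, ch$bb$iy, ch$bb$iz] <- sub
      }
      trunc <- TRUE  # shafts span the x faces by construction
      dendrites[[di]] <- list(id = next_id, P = P, a = a, r = r_d,
                              truncated = trunc)
      obj_rows[[length(obj_rows) + 1]] <- list(
        object_id = next_id, class = "dendrite_shaft",
        parent_id = NA_integer_, truncated = trunc
      )
      next_id <- next_id + 1L
      placed <- TRUE
      break
    }
    if (!placed) {
      abort(sprintf(
        "could not place dendrite %d of %d without overlap after %d retries",
        di, n_d, config$max_retries
      ))
    }
  }

  n_aspiny <- round(config$fraction_aspiny_dendrites * n_d)
  n_aspiny <- min(max(n_aspiny, 0L), n_d)
  # Keep both categories represented whenever the mix calls for them.
  if (n_d >= 2) {
    if (config$fraction_aspiny_dendrites > 0 && n_aspiny == 0) n_aspiny <- 1L
    if (config$fraction_aspiny_dendrites < 1 && n_aspiny == n_d) {
      n_aspiny <- n_d - 1L
    }
  }
  aspiny_ids <- sample(seq_len(n_d), n_aspiny)
  spiny_intent <- setdiff(seq_len(n_d), aspiny_ids)

  # --- spines ------------------------------------------------------------
  rn <- config$spine_neck_radius_nm
  ln <- config$spine_neck_length_nm
  rh_mean <- unname(config$spine_head_radius_nm["mean"])
  rh_sd <- unname(config$spine_head_radius_nm["sd"])
  heads <- list()
  necks <- list()
  for (di in spiny_intent) {
    den <- dendrites[[di]]
    n_sp <- rpois(1, config$spines_per_micron * L[1] / 1000)
    if (n_sp == 0) next
    fr <- orthonormal_to(den$a)
    t_lo <- (0 - den$P[1]) / den$a[1]
    t_hi <- (L[1] - den$P[1]) / den$a[1]
    # loose axial pad; exact containment is checked per candidate below
    pad <- 0.5 * (ln + 2 * rh_mean)
    if (t_hi - pad <= t_lo + pad) next
    for (si in seq_len(n_sp)) {
      rh <- min(1.4 * rh_mean, max(0.6 * rh_mean, rnorm(1, rh_mean, rh_sd)))
      for (try_ in 1:40) {
        t_c <- runif(1, t_lo + pad, t_hi - pad)
        phi <- runif(1, 0, 2 * pi)
        psi <- runif(1, -0.9, 0.9)  # tilt towards the shaft axis
        radial <- cos(phi) * fr$e1 + sin(phi) * fr$e2
        dir <- unit(cos(psi) * radial + sin(psi) * den$a)
        B <- den$P + t_c * den$a + den$r * radial
        H <- B + dir * (ln + 0.85 * rh)
        if (any(H - rh - 2 * vs < 0) || any(H + rh + 2 * vs > L)) next
        nm_chk <- capsule_mask(dims, vs, B, dir, ln, rn + clear, strict = TRUE)
        hm_chk <- sphere_mask(dims, vs, H, rh + clear, strict = TRUE)
        if (is.null(nm_chk) || is.null(hm_chk)) next
        sub_n <- lab[nm_chk$bb$ix, nm_chk$bb$iy, nm_chk$bb$iz]
        sub_h <- lab[hm_chk$bb$ix, hm_chk$bb$iy, hm_chk$bb$iz]
        if (any(!(sub_n[nm_chk$mask] %in% c(0L, den$id)))) next
        if (any(sub_h[hm_chk$mask] != 0L)) next
        nm <- capsule_mask(dims, vs, B, dir, ln, rn)
        sub <- lab[nm$bb$ix, nm$bb$iy, nm$bb$iz]
        place_n <- nm$mask & sub == 0L
        if (!any(place_n)) next
        hm <- sphere_mask(dims, vs, H, rh)
        neck_id <- next_id
        head_id <- next_id + 1L
        sub[place_n] <- neck_id
        lab[nm$bb$ix, nm$bb$iy, nm$bb$iz] <- sub
        # read the head subarray only after the neck is committed
        sub_h2 <- lab[hm$bb$ix, hm$bb$iy, hm$bb$iz]
        place_h <- hm$mask & sub_h2 == 0L
        if (!any(place_h)) {
          # undo the neck and retry elsewhere
          sub[place_n] <- 0L
          lab[nm$bb$ix, nm$bb$iy, nm$bb$iz] <- sub
          next
        }
        sub_h2[place_h] <- head_id
        lab[hm$bb$ix, hm$bb$iy, hm$bb$iz] <- sub_h2
        obj_rows[[length(obj_rows) + 1]] <- list(
          object_id = neck_id, class = "spine_neck",
          parent_id = den$id, truncated = FALSE
        )
        obj_rows[[length(obj_rows) + 1]] <- list(
          object_id = head_id, class = "spine_head",
          parent_id = neck_id, truncated = FALSE
        )
        necks[[length(necks) + 1]] <- list(
          id = neck_id, B = B, dir = dir, len = ln, r = rn,
          dendrite = den$id
        )
        heads[[length(heads) + 1]] <- list(
          id = head_id, C = H, r = rh, dir = dir, dendrite = den$id
        )
        next_id <- next_id + 2L
        break
      }
    }
  }

  dendrite_has_spine <- vapply(dendrites, function(d) {
    any(vapply(necks, function(n) n$dendrite == d$id, logical(1)))
  }, logical(1))
  spiny_shaft_ids <- which(dendrite_has_spine)
  aspiny_shaft_ids <- which(!dendrite_has_spine)

  # --- synaptic junctions -------------------------------------------------
  syn_rows <- list()
  syn_meshes <- list()
  if (n_syn > 0) {
    f <- config$as_fraction
    types <- sample(c("AS", "SS"), n_syn, replace = TRUE, prob = c(f, 1 - f))
    tcls <- character(n_syn)
    scls <- character(n_syn)
    areas <- numeric(n_syn)
    thick <- numeric(n_syn)
    # Junction areas are capped by host capacity: a neck can only carry a
    # small patch, a head roughly a third of its surface (real neck and head
    # synapses are correspondingly smaller than shaft ones).
    area_cap <- c(
      spine_head = pi * (1.05 * rh_mean)^2,
      spine_neck = pi * (0.33 * ln)^2,
      aspiny_shaft = Inf, spiny_shaft = Inf
    )
    for (i in seq_len(n_syn)) {
      ty <- types[i]
      tcls[i] <- sample(target_classes, 1, prob = config$target_mix[[ty]][target_classes])
      scls[i] <- sample(shape_classes, 1, prob = config$shape_mix[[ty]][shape_classes])
      pr <- config$sas_area_lognormal[[scls[i]]]
      areas[i] <- min(config$max_area_nm2, area_cap[[tcls[i]]],
        max(config$min_area_nm2, rlnorm(1, pr$meanlog, pr$sdlog)))
      mu_t <- unname(config$psd_thickness[[ty]])
      thick[i] <- max(5, rnorm(1, mu_t, config$psd_thickness_cv * mu_t))
    }
    host_pool <- list(
      spine_head = heads,
      spine_neck = necks,
      aspiny_shaft = lapply(aspiny_shaft_ids, function(i) dendrites[[i]]),
      spiny_shaft = lapply(spiny_shaft_ids, function(i) dendrites[[i]])
    )
    for (cls in target_classes) {
      if (any(tcls == cls) && length(host_pool[[cls]]) == 0) {
        abort(sprintf(
          "target mix requires '%s' hosts but the scene produced none; increase spine rate, dendrite count or volume",
          cls
        ))
      }
    }
    # Larger junctions are placed first: they are the hardest to fit.
    order_ <- order(areas, decreasing = TRUE)
    for (i in order_) {
      # staged rejection sampling: if a junction cannot be seated at its
      # drawn size within a share of the retry budget, it is rebuilt 40%
      # smaller (down to the minimum area). Class labels never change and
      # the recorded ground-truth area is always the realized mesh area.
      placed <- FALSE
      area_i <- areas[i]
      tries_per_stage <- max(1L, ceiling(config$max_retries / 6))
      for (stage in 1:6) {
        m2 <- planar_sas_mesh(scls[i], area_i, config$irregularity)
        raster <- rasterize_mesh2d(m2, pitch = min(vs))
        raster_chk <- raster
        raster_chk$grid <- binary_dilate(raster$grid, 1L)
        rho_max <- max(sqrt(rowSums(m2$vertices^2)))
        for (try_ in seq_len(tries_per_stage)) {
          hosts <- host_pool[[tcls[i]]]
          h <- hosts[[sample.int(length(hosts), 1)]]
          if (tcls[i] == "spine_head") {
            # keep the patch centre away from the neck attachment pole; the
            # clearance check rejects any residual overlap with the neck
            repeat {
              u <- unit(rnorm(3))
              if (sum(u * h$dir) > -0.4) break
            }
            frame <- orthonormal_to(u)
            pm <- sphere_patch_mask(dims, vs, h$C, h$r, thick[i], u, frame,
              raster, raster_chk, rho_max, clear)
            wrap <- function() wrap_on_sphere(m2, h$C, h$r, u, frame)
          } else if (tcls[i] == "spine_neck") {
            t_lo_n <- max(rho_max + clear, 0.1 * h$len)
            t_hi_n <- min(h$len - rho_max - clear, 0.9 * h$len)
            if (t_lo_n >= t_hi_n) next
            t_c <- runif(1, t_lo_n, t_hi_n)
            fr <- orthonormal_to(h$dir)
            phi <- runif(1, 0, 2 * pi)
            u0 <- cos(phi) * fr$e1 + sin(phi) * fr$e2
            w0 <- c(
              h$dir[2] * u0[3] - h$dir[3] * u0[2],
              h$dir[3] * u0[1] - h$dir[1] * u0[3],
              h$dir[1] * u0[2] - h$dir[2] * u0[1]
            )
            pm <- cylinder_patch_mask(dims, vs, h$B, h$dir, h$r, thick[i], t_c,
              u0, w0, raster, raster_chk, rho_max, clear)
            wrap <- function() wrap_on_cylinder(m2, h$B, h$dir, h$r, t_c, u0, w0)
          } else {
            t_lo <- (0 - h$P[1]) / h$a[1]
            t_hi <- (L[1] - h$P[1]) / h$a[1]
            pad <- rho_max + thick[i] + 4 * clear
            if (t_hi - t_lo < 2.5 * pad) next
            t_c <- runif(1, t_lo + pad, t_hi - pad)
            fr <- orthonormal_to(h$a)
            phi <- runif(1, 0, 2 * pi)
            u0 <- cos(phi) * fr$e1 + sin(phi) * fr$e2
            w0 <- c(
              h$a[2] * u0[3] - h$a[3] * u0[2],
              h$a[3] * u0[1] - h$a[1] * u0[3],
              h$a[1] * u0[2] - h$a[2] * u0[1]
            )
            pm <- cylinder_patch_mask(dims, vs, h$P, h$a, h$r, thick[i], t_c,
              u0, w0, raster, raster_chk, rho_max, clear)
            wrap <- function() wrap_on_cylinder(m2, h$P, h$a, h$r, t_c, u0, w0)
          }
          if (is.null(pm) || !any(pm$mask)) next
          sub <- lab[pm$bb$ix, pm$bb$iy, pm$bb$iz]
          if (any(sub[pm$chk] != 0L)) next
          syn_id <- next_id
          sub[pm$mask] <- syn_id
          lab[pm$bb$ix, pm$bb$iy, pm$bb$iz] <- sub
          v3 <- wrap()
          mesh <- sas_mesh(v3, m2$triangles, synapse_id = syn_id)
          host_id <- h$id
          parent_dendrite <- if (tcls[i] %in% c("aspiny_shaft", "spiny_shaft")) {
            h$id
          } else {
            h$dendrite
          }
          trunc <- block_touches_border(pm$bb, dims, pm$mask)
          obj_rows[[length(obj_rows) + 1]] <- list(
            object_id = syn_id, class = "synapse",
            parent_id = host_id, truncated = trunc
          )
          syn_meshes[[length(syn_meshes) + 1]] <- mesh
          syn_rows[[length(syn_rows) + 1]] <- list(
            synapse_id = syn_id,
            type = types[i],
            shape_class = scls[i],
            target_class = tcls[i],
            host_object_id = host_id,
            parent_dendrite_id = parent_dendrite,
            area_nm2 = mesh_area(mesh),
            thickness_nm = thick[i],
            n_voxels = sum(pm$mask),
            truncated = trunc
          )
          next_id <- next_id + 1L
          placed <- TRUE
          break
        }
        if (placed) break
        area_i <- max(config$min_area_nm2, 0.6 * area_i)
        }
      if (!placed) {
        abort(sprintf(
          "requested synapse density cannot be placed: junction of %.3g nm^2 on '%s' failed after %d retries (%d of %d placed)",
          areas[i], tcls[i], config$max_retries, length(syn_rows), n_syn
        ))
      }
    }
  }

  pluck_col <- function(rows, field) {
    vals <- lapply(rows, `[[`, field)
    unlist(vals, use.names = FALSE)
  }
  objects <- tibble::tibble(
    object_id = pluck_col(obj_rows, "object_id"),
    class = pluck_col(obj_rows, "class"),
    parent_id = pluck_col(obj_rows, "parent_id"),
    truncated = pluck_col(obj_rows, "truncated")
  )
  objects$spiny <- NA
  objects$spiny[match(vapply(dendrites, `[[`, integer(1), "id"), objects$object_id)] <-
    dendrite_has_spine
  synapses <- if (length(syn_rows)) {
    tb <- tibble::tibble(
      synapse_id = pluck_col(syn_rows, "synapse_id"),
      type = pluck_col(syn_rows, "type"),
      shape_class = pluck_col(syn_rows, "shape_class"),
      target_class = pluck_col(syn_rows, "target_class"),
      host_object_id = pluck_col(syn_rows, "host_object_id"),
      parent_dendrite_id = pluck_col(syn_rows, "parent_dendrite_id"),
      area_nm2 = pluck_col(syn_rows, "area_nm2"),
      thickness_nm = pluck_col(syn_rows, "thickness_nm"),
      n_voxels = pluck_col(syn_rows, "n_voxels"),
      truncated = pluck_col(syn_rows, "truncated"),
      mesh = syn_meshes
    )
    dplyr::arrange(tb, .data$synapse_id)
  } else {
    tibble::tibble(
      synapse_id = integer(0), type = character(0),
      shape_class = character(0), target_class = character(0),
      host_object_id = integer(0), parent_dendrite_id = integer(0),
      area_nm2 = numeric(0), thickness_nm = numeric(0),
      n_voxels = integer(0), truncated = logical(0), mesh = list()
    )
  }
  structure(
    list(
      volume = labeled_volume(lab, vs, objects),
      synapses = synapses,
      config = config
    ),
    class = "synapse_scene"
  )
}

#' @export
print.synapse_scene <- function(x, ...) {
  cat(sprintf(
    "<synapse_scene> %d synapses (%d AS / %d SS), %d objects, seed %d\n",
    nrow(x$synapses),
    sum(x$synapses$type == "AS"), sum(x$synapses$type == "SS"),
    nrow(x$volume$objects), x$config$seed
  ))
  invisible(x)
}
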