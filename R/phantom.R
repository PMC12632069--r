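# Run expr under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

#' Specification of the synthetic thoracic phantom
#'
#' A geometric stand-in for a thoracic planning CT: elliptical-cylinder
#' body, two ellipsoidal lungs, a spherical PTV inside the left lung, a
#' spherical heart and a cylindrical spinal cord, each with a nominal HU.
#' Everything is a deterministic function of the spec; the seed governs
#' only downstream randomized steps (plan modulation, log perturbations).
#'
#' @param dims Cubic grid dimension (default 64; 24 for desk-scale work).
#' @param spacing Isotropic voxel spacing in cm (default 0.4).
#' @param body_semi_axes Lateral/vertical semi-axes (cm) of the body ellipse.
#' @param body_half_length Longitudinal half-extent of the body (cm).
#' @param lung_semi_axes Semi-axes (cm) of each lung ellipsoid.
#' @param lung_centers 2 x 3 matrix of lung centres (left, right; cm).
#' @param ptv_center,ptv_radius PTV sphere (cm), inside the left lung.
#' @param heart_center,heart_radius Heart sphere (cm).
#' @param cord_center_xz,cord_radius Spinal-cord cylinder (axis along y; cm).
#' @param hu Named HU values per tissue.
#' @param seed Integer seed propagated to randomized generators.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dims = 64L, spacing = 0.4,
                         body_semi_axes = c(11, 9), body_half_length = 11,
                         lung_semi_axes = c(3.6, 8, 5),
                         lung_centers = rbind(left = c(-5.5, 0, 0.5),
                                              right = c(5.5, 0, 0.5)),
                         ptv_center = c(-5, 1, 1), ptv_radius = 2,
                         heart_center = c(1.5, 0, -1.5), heart_radius = 3,
                         cord_center_xz = c(0, -7), cord_radius = 0.5,
                         hu = c(body = 0, lung = -700, ptv = 20,
                                heart = 50, cord = 300),
                         seed = 1L) {
  structure(list(dims = as.integer(dims), spacing = spacing,
                 body_semi_axes = body_semi_axes,
                 body_half_length = body_half_length,
                 lung_semi_axes = lung_semi_axes, lung_centers = lung_centers,
                 ptv_center = ptv_center, ptv_radius = ptv_radius,
                 heart_center = heart_center, heart_radius = heart_radius,
                 cord_center_xz = cord_center_xz, cord_radius = cord_radius,
                 hu = hu, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Build the synthetic thoracic phantom
#'
#' Voxelizes the phantom spec (a voxel belongs to an ROI iff its centre is
#' inside the shape) into a CT volume and binary masks for PTV, left/right/
#' total lung, heart, spinal cord and body. Deterministic: the same spec
#' always yields bitwise-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return List with `ct` ([image_volume()]) and `masks`
#'   ([structure_mask()]).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  n <- spec$dims
  grid <- voxel_grid(origin = rep(-(n - 1) / 2 * spec$spacing, 3),
                     spacing = spec$spacing, dims = rep(n, 3))
  ax <- grid_axes(grid)
  X <- array(ax[[1]], grid$dims)
  Y <- array(rep(ax[[2]], each = n), grid$dims)
  Z <- array(rep(ax[[3]], each = n * n), grid$dims)
  inside_ellipsoid <- function(c0, s)
    ((X - c0[1]) / s[1])^2 + ((Y - c0[2]) / s[2])^2 + ((Z - c0[3]) / s[3])^2 <= 1
  body <- (X / spec$body_semi_axes[1])^2 + (Z / spec$body_semi_axes[2])^2 <= 1 &
    abs(Y) <= spec$body_half_length
  lungL <- inside_ellipsoid(spec$lung_centers[1, ], spec$lung_semi_axes)
  lungR <- inside_ellipsoid(spec$lung_centers[2, ], spec$lung_semi_axes)
  ptv <- inside_ellipsoid(spec$ptv_center, rep(spec$ptv_radius, 3))
  heart <- inside_ellipsoid(spec$heart_center, rep(spec$heart_radius, 3))
  cord <- (X - spec$cord_center_xz[1])^2 + (Z - spec$cord_center_xz[2])^2 <=
    spec$cord_radius^2 & abs(Y) <= spec$body_half_length
  for (m in list(lungL, lungR, ptv, heart, cord))
    if (any(m & !body)) stop("phantom structure extends outside the body")
  if (any(ptv & heart) || any(ptv & cord) || any(heart & cord))
    stop("phantom PTV/heart/cord must be disjoint")
  ct <- array(-1000, grid$dims)
  ct[body] <- spec$hu["body"]
  ct[lungL | lungR] <- spec$hu["lung"]
  ct[heart] <- spec$hu["heart"]
  ct[cord] <- spec$hu["cord"]
  ct[ptv] <- spec$hu["ptv"]
  masks <- structure_mask(grid, list(
    PTV = ptv * 1, left_lung = lungL * 1, right_lung = lungR * 1,
    total_lung = pmin(lungL + lungR, 1), heart = heart * 1,
    spinal_cord = cord * 1, body = body * 1))
  list(ct = image_volume(grid, ct, kind = "ct_hu"), masks = masks)
}

#' Isocenter convention: the PTV mask centroid
#'
#' @param masks A [structure_mask()] with a `PTV` label.
#' @return Length-3 point (cm).
#' @export
plan_isocenter <- function(masks) {
  ptv <- masks$labels$PTV
  if (is.null(ptv) || !any(ptv > 0)) stop("masks carry no non-empty PTV")
  idx <- which(ptv > 0, arr.ind = TRUE)
  ax <- grid_axes(masks$grid)
  c(mean(ax[[1]][idx[, 1]]), mean(ax[[2]][idx[, 2]]), mean(ax[[3]][idx[, 3]]))
}

#' Specification of the synthetic step-and-shoot plan
#'
#' @param n_beams Number of coplanar beams (default 7, equi-spaced in
#'   gantry angle over 360 degrees).
#' @param segments_per_beam Step-and-shoot segments per beam (default 5).
#' @param total_mu Total plan monitor units (default 600, a typical
#'   per-fraction output for a 2 Gy fraction).
#' @param prescription Prescription dose in Gy (default 60, as 60 Gy in 30
#'   fractions).
#' @param aperture_margin Margin (cm) added around the PTV's BEV projection.
#' @param segment_jitter_sd Per-segment leaf modulation SD (cm) emulating
#'   step-and-shoot aperture variation (default 0.1).
#' @param seed Integer seed for the modulation.
#' @return A `plan_spec` list.
#' @export
plan_spec <- function(n_beams = 7L, segments_per_beam = 5L, total_mu = 600,
                      prescription = 60, aperture_margin = 0.5,
                      segment_jitter_sd = 0.1, seed = 1L) {
  stopifnot(n_beams >= 1, segments_per_beam >= 1, total_mu > 0, prescription > 0)
  structure(list(n_beams = as.integer(n_beams),
                 segments_per_beam = as.integer(segments_per_beam),
                 total_mu = total_mu, prescription = prescription,
                 aperture_margin = aperture_margin,
                 segment_jitter_sd = segment_jitter_sd, seed = as.integer(seed)),
            class = "plan_spec")
}

# Project points into the BEV isocenter plane of a beam frame, with
# divergence scaling (points upstream of the isocenter magnify).
bev_project <- function(points, frame) {
  w <- sweep(points, 2, frame$isocenter)
  bhat <- (frame$isocenter - frame$source) / frame$sad
  depth <- frame$sad + as.numeric(w %*% bhat)
  fac <- frame$sad / depth
  cbind(u = as.numeric(w %*% frame$ex) * fac,
        v = as.numeric(w %*% frame$ey) * fac)
}

#' Generate the synthetic step-and-shoot delivery plan
#'
#' Per beam, the aperture is conformal to the PTV's beam's-eye-view
#' projection (with divergence) plus a margin, per leaf pair; leaf pairs
#' whose width band the projection misses stay closed. Each segment applies
#' a seeded Gaussian leaf modulation around the conformal aperture.
#' Cumulative MU increases strictly and uniformly. Leaf positions are
#' rounded to 4 decimals, matching the CSV interchange precision.
#'
#' @param phantom Output of [make_phantom()].
#' @param spec A [plan_spec()].
#' @param geometry A [machine_geometry()] (default [hd120_geometry()]).
#' @return A valid [plan_delivery()] with attribute `isocenter`.
#' @export
make_plan <- function(phantom, spec = plan_spec(), geometry = hd120_geometry()) {
  masks <- phantom$masks
  iso <- plan_isocenter(masks)
  ptv_idx <- which(masks$labels$PTV > 0, arr.ind = TRUE)
  ax <- grid_axes(masks$grid)
  pts <- cbind(ax[[1]][ptv_idx[, 1]], ax[[2]][ptv_idx[, 2]], ax[[3]][ptv_idx[, 3]])
  edges <- leaf_band_edges(geometry)
  angles <- (seq_len(spec$n_beams) - 1) * 360 / spec$n_beams
  beam_mu <- spec$total_mu / spec$n_beams
  with_seed(spec$seed, {
    beams <- lapply(seq_len(spec$n_beams), function(bi) {
      frame <- beam_frame(angles[bi], sad = geometry$sad, isocenter = iso)
      uv <- bev_project(pts, frame)
      if (max(abs(uv[, 2])) > max(abs(edges)))
        stop("PTV projects outside the leaf bank extent")
      conf_a <- conf_b <- numeric(geometry$n_pairs)
      for (i in seq_len(geometry$n_pairs)) {
        sel <- uv[, 2] >= edges[i] & uv[, 2] < edges[i + 1]
        if (any(sel)) {
          conf_b[i] <- min(uv[sel, 1]) - spec$aperture_margin
          conf_a[i] <- max(uv[sel, 1]) + spec$aperture_margin
        }
      }
      cps <- lapply(seq_len(spec$segments_per_beam + 1L), function(j) {
        jit_a <- stats::rnorm(geometry$n_pairs, 0, spec$segment_jitter_sd)
        jit_b <- stats::rnorm(geometry$n_pairs, 0, spec$segment_jitter_sd)
        open <- conf_a > conf_b
        a <- round(ifelse(open, conf_a + jit_a, 0), 4)
        b <- round(ifelse(open, conf_b + jit_b, 0), 4)
        swap <- a < b
        mid <- (a + b) / 2
        a[swap] <- round(mid[swap], 4); b[swap] <- round(mid[swap], 4)
        control_point(index = j,
                      mu_cumulative = round(beam_mu * (j - 1) /
                                              spec$segments_per_beam, 4),
                      gantry_deg = angles[bi], bank_a = a, bank_b = b)
      })
      beam_delivery(sprintf("beam%02d", bi), geometry, cps)
    })
    plan <- plan_delivery("synthetic_phantom_plan", spec$prescription, beams)
    stop_if_invalid(plan)
    attr(plan, "isocenter") <- iso
    plan
  })
}

# Separable 3D Gaussian smoothing; sigma in cm, zero-padded borders.
gaussian_smooth3 <- function(values, sigma_cm, spacing) {
  if (sigma_cm <= 0) return(values)
  out <- values
  for (a in 1:3) {
    s_vox <- sigma_cm / spacing[a]
    r <- max(1L, ceiling(3 * s_vox))
    k <- exp(-((-r:r)^2) / (2 * s_vox^2))
    k <- k / sum(k)
    d <- dim(out)
    perm <- c(a, setdiff(1:3, a))
    m <- matrix(aperm(out, perm), nrow = d[a])
    npad <- nrow(m) + 2L * r
    K <- matrix(0, nrow(m), npad)
    for (i in seq_len(nrow(m))) K[i, i:(i + 2L * r)] <- k
    mp <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    sm <- K %*% mp
    out <- aperm(array(sm, d[perm]), order(perm))
  }
  out
}

#' Analytic pseudo-reference dose for the phantom plan
#'
#' Projects the plan's fluence through the phantom grid
#' ([accumulate_plan()]), smooths with an isotropic 3D Gaussian to give
#' dose-like gradients, and scales globally so that the PTV D95 equals the
#' prescription exactly (the plan-normalization rule: 95% of the PTV
#' receives 100% of the prescription). A dose-shaped stand-in, not a
#' physical dose calculation.
#'
#' @param plan A [plan_delivery()] from [make_plan()].
#' @param phantom Output of [make_phantom()].
#' @param sigma_cm Gaussian smoothing SD in cm (default 0.8).
#' @param fluence_pitch Fluence pixel spacing in cm (default 0.25).
#' @return An [image_volume()] of kind `"dose_gy"`.
#' @export
make_reference_dose <- function(plan, phantom, sigma_cm = 0.8,
                                fluence_pitch = 0.25) {
  grid <- phantom$ct$grid
  iso <- attr(plan, "isocenter")
  if (is.null(iso)) iso <- plan_isocenter(phantom$masks)
  maps <- plan_fluence(plan, fluence_grid(pixel_spacing = fluence_pitch))
  sad <- plan$beams[[1]]$geometry$sad
  proj <- accumulate_plan(maps, grid, sad = sad, isocenter = iso)
  if (max(proj$values) <= 0) stop("all-zero projection: cannot normalize")
  sm <- gaussian_smooth3(proj$values, sigma_cm, grid$spacing)
  d95 <- d_index(sm, phantom$masks$labels$PTV, 95)
  if (d95 <= 0) stop("PTV D95 of the unscaled dose is zero")
  image_volume(grid, sm * (plan$prescription_dose / d95), kind = "dose_gy")
}

#' Perturb a plan into an "as-delivered" log
#'
#' Emulates delivery deviations recorded in a log file: seeded Gaussian MLC
#' leaf-position errors (clamped so each pair keeps `a >= b`), a global MU
#' scale, and per-beam gantry-angle jitter. The perturbed plan remains
#' valid; a perturbation that closes every aperture is rejected.
#'
#' @param plan A valid [plan_delivery()].
#' @param mlc_sd_cm SD of leaf-position noise (cm).
#' @param mu_scale Multiplier on every cumulative MU.
#' @param gantry_sd_deg SD of per-beam gantry jitter (degrees).
#' @param seed Integer seed.
#' @return A perturbed [plan_delivery()].
#' @export
make_actual_log <- function(plan, mlc_sd_cm = 0, mu_scale = 1,
                            gantry_sd_deg = 0, seed = 1L) {
  stop_if_invalid(plan)
  with_seed(seed, {
    beams <- lapply(plan$beams, function(b) {
      dg <- if (gantry_sd_deg > 0) stats::rnorm(1, 0, gantry_sd_deg) else 0
      cps <- lapply(b$control_points, function(cp) {
        a <- cp$bank_a; bb <- cp$bank_b
        if (mlc_sd_cm > 0) {
          a <- a + stats::rnorm(length(a), 0, mlc_sd_cm)
          bb <- bb + stats::rnorm(length(bb), 0, mlc_sd_cm)
          swap <- a < bb
          mid <- (a + bb) / 2
          a[swap] <- mid[swap]; bb[swap] <- mid[swap]
        }
        control_point(cp$index, cp$mu_cumulative * mu_scale,
                      cp$gantry_deg + dg, a, bb, cp$collimator_deg)
      })
      beam_delivery(b$beam_id, b$geometry, cps)
    })
    out <- plan_delivery(plan$plan_id, plan$prescription_dose, beams)
    attr(out, "isocenter") <- attr(plan, "isocenter")
    open <- sum(vapply(out$beams, function(b)
      sum(vapply(b$control_points, function(cp)
        aperture_open_area(cp, b$geometry), numeric(1))), numeric(1)))
    if (open <= 0) stop("perturbation closed every aperture")
    stop_if_invalid(out)
    out
  })
}
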