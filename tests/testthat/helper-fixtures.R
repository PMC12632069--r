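# Shared fixtures, built once per test run.

# Small uniform-leaf geometry for hand-computable aperture examples.
toy_geometry <- function(n_pairs = 44, width = 0.5, sad = 100)
  machine_geometry(sad = sad, leaf_pair_widths = rep(width, n_pairs))

# Rectangular aperture of x-extent [-hx, hx] over pairs whose band centre
# lies within [-hy, hy].
rect_aperture_cp <- function(geom, hx, hy, index = 1, mu = 0, gantry = 0) {
  edges <- leaf_band_edges(geom)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  open <- abs(mid) <= hy
  control_point(index, mu, gantry,
                bank_a = ifelse(open, hx, 0), bank_b = ifelse(open, -hx, 0))
}

# Random valid plan whose numbers survive the CSV dialect (4-decimal
# positions) for round-trip property tests.
random_plan <- function(seed, n_beams = 2, n_cp = 3, geom = toy_geometry()) {
  set.seed(seed)
  beams <- lapply(seq_len(n_beams), function(bi) {
    mu <- round(cumsum(c(0, runif(n_cp - 1, 0, 50))), 4)
    gantry <- round(runif(1, 0, 359), 4)
    cps <- lapply(seq_len(n_cp), function(j) {
      b <- round(runif(geom$n_pairs, -5, 0), 4)
      a <- round(b + runif(geom$n_pairs, 0, 5), 4)
      control_point(j, mu[j], gantry, a, b)
    })
    beam_delivery(paste0("B", bi), geom, cps)
  })
  plan_delivery(paste0("plan", seed), 60, beams)
}

# Pure-R slab intersection of a ray with a grid's bounding box; independent
# of the compiled traversal.
ray_box_span <- function(entry, dir, grid) {
  dir <- dir / sqrt(sum(dir^2))
  b <- logdoseqa:::grid_bounds(grid)
  tmin <- 0; tmax <- Inf
  for (i in 1:3) {
    if (dir[i] == 0) {
      if (entry[i] < b$lo[i] || entry[i] >= b$hi[i]) return(NULL)
    } else {
      tt <- sort(c((b$lo[i] - entry[i]) / dir[i], (b$hi[i] - entry[i]) / dir[i]))
      tmin <- max(tmin, tt[1]); tmax <- min(tmax, tt[2])
    }
  }
  if (tmin >= tmax) return(NULL)
  c(tmin, tmax)
}

# Dense-sampling traversal oracle: voxels hit by points sampled every
# step_frac of the smallest voxel size along the in-grid span.
dense_ray_voxels <- function(entry, dir, grid, step_frac = 1e-3) {
  span <- ray_box_span(entry, dir, grid)
  if (is.null(span)) return(integer(0))
  dir <- dir / sqrt(sum(dir^2))
  step <- step_frac * min(grid$spacing)
  t <- seq(span[1] + step / 2, span[2] - step / 2, by = step)
  if (!length(t)) return(integer(0))
  b <- logdoseqa:::grid_bounds(grid)
  idx <- sapply(1:3, function(i)
    pmin(pmax(floor((entry[i] + t * dir[i] - b$lo[i]) / grid$spacing[i]), 0),
         grid$dims[i] - 1))
  lin <- idx[, 1] + grid$dims[1] * (idx[, 2] + grid$dims[2] * idx[, 3])
  unique(lin) + 1L
}

dda_linear <- function(tr, grid)
  (tr$index[, 1] - 1L) + grid$dims[1] * ((tr$index[, 2] - 1L) +
                                           grid$dims[2] * (tr$index[, 3] - 1L)) + 1L

# Full-scale phantom case shared by the acceptance suite; memoized.
.acc_env <- new.env()
acc_case64 <- function() {
  if (is.null(.acc_env$case64)) {
    ph <- make_phantom(phantom_spec(dims = 64, spacing = 0.4))
    plan <- make_plan(ph, plan_spec())
    ref <- make_reference_dose(plan, ph, sigma_cm = 0.8)
    .acc_env$case64 <- list(phantom = ph, plan = plan, reference = ref)
  }
  .acc_env$case64
}

# Desk-scale phantom case shared by the slower tests; memoized.
.case_env <- new.env()
tiny_case <- function() {
  if (is.null(.case_env$case)) {
    ph <- make_phantom(phantom_spec(dims = 24, spacing = 1.0))
    pl <- make_plan(ph)
    ref <- make_reference_dose(pl, ph, sigma_cm = 1.2)
    maps <- plan_fluence(pl, fluence_grid())
    proj <- accumulate_plan(maps, ph$ct$grid,
                            isocenter = attr(pl, "isocenter"))
    smp <- assemble_sample(ph$ct, ph$masks, proj, ref,
                           pl$prescription_dose, n = 24)
    .case_env$case <- list(phantom = ph, plan = pl, reference = ref,
                           maps = maps, projected = proj, sample = smp)
  }
  .case_env$case
}
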