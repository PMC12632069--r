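test_that("the phantom is deterministic and anatomically consistent", {
  ph1 <- make_phantom(phantom_spec(dims = 32, spacing = 0.8))
  ph2 <- make_phantom(phantom_spec(dims = 32, spacing = 0.8))
  expect_identical(ph1$ct$values, ph2$ct$values)
  expect_identical(ph1$masks$labels, ph2$masks$labels)
  lb <- ph1$masks$labels
  expect_identical(lb$total_lung, pmin(lb$left_lung + lb$right_lung, 1))
  expect_true(all(lb$PTV <= lb$body))
  expect_setequal(names(lb), c("PTV", "left_lung", "right_lung", "total_lung",
                               "heart", "spinal_cord", "body"))
  # voxelized PTV volume within 10% of the analytic sphere at default scale
  ph <- make_phantom(phantom_spec())
  vox <- prod(ph$masks$grid$spacing)
  analytic <- 4 / 3 * pi * phantom_spec()$ptv_radius^3
  expect_lt(abs(sum(ph$masks$labels$PTV) * vox - analytic) / analytic, 0.1)
  # overlapping required-disjoint structures are rejected
  expect_error(make_phantom(phantom_spec(heart_center = c(-5, 1, 1))),
               "disjoint")
})

test_that("the generated plan is valid, counted, and conformal", {
  case <- tiny_case()
  expect_identical(nrow(validate_delivery(case$plan)), 0L)
  expect_length(case$plan$beams, 7)
  for (b in case$plan$beams) expect_length(b$control_points, 6)
  # same spec, same seed -> identical plan file
  ph <- case$phantom
  p1 <- make_plan(ph, plan_spec(seed = 5))
  p2 <- make_plan(ph, plan_spec(seed = 5))
  f1 <- tempfile(); f2 <- tempfile()
  write_delivery(p1, f1, "csv"); write_delivery(p2, f2, "csv")
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
  # zero margin, zero modulation: aperture rows match the PTV BEV rows
  p0 <- make_plan(ph, plan_spec(aperture_margin = 0, segment_jitter_sd = 0))
  geom <- p0$beams[[1]]$geometry
  iso <- attr(p0, "isocenter")
  edges <- leaf_band_edges(geom)
  for (b in p0$beams[c(1, 4)]) {
    cp <- b$control_points[[1]]
    fr <- beam_frame(cp$gantry_deg, geom$sad, iso)
    idx <- which(ph$masks$labels$PTV > 0, arr.ind = TRUE)
    ax <- logdoseqa:::grid_axes(ph$masks$grid)
    pts <- cbind(ax[[1]][idx[, 1]], ax[[2]][idx[, 2]], ax[[3]][idx[, 3]])
    uv <- logdoseqa:::bev_project(pts, fr)
    open_rows <- which(cp$bank_a > cp$bank_b)
    ptv_rows <- which(vapply(seq_len(geom$n_pairs), function(i)
      any(uv[, 2] >= edges[i] & uv[, 2] < edges[i + 1]), logical(1)))
    # agreement within one leaf row at each edge
    expect_lte(abs(min(open_rows) - min(ptv_rows)), 1)
    expect_lte(abs(max(open_rows) - max(ptv_rows)), 1)
    expect_identical(setdiff(open_rows, seq(min(ptv_rows) - 1, max(ptv_rows) + 1)),
                     integer(0))
  }
})

test_that("the reference dose satisfies the plan normalization rule", {
  case <- tiny_case()
  ref <- case$reference
  ptv <- case$phantom$masks$labels$PTV
  rx <- case$plan$prescription_dose
  expect_lt(abs(d_index(ref, ptv, 95) / rx - 1), 1e-6)
  expect_gte(min(ref$values), 0)
  # the hottest voxel lies inside the body
  body <- case$phantom$masks$labels$body
  expect_equal(max(ref$values), max(ref$values[body > 0]))
  # sigma 0 skips smoothing: projection is only rescaled
  ref0 <- make_reference_dose(case$plan, case$phantom, sigma_cm = 0)
  ratio <- ref0$values[case$projected$values > 0] /
    case$projected$values[case$projected$values > 0]
  expect_lt(diff(range(ratio)), 1e-9)
})

test_that("log perturbation behaves as an identity / linear / noisy map", {
  case <- tiny_case()
  plan <- case$plan
  # zero perturbation: identical plan
  same <- make_actual_log(plan, mlc_sd_cm = 0, mu_scale = 1, seed = 3)
  f1 <- tempfile(); f2 <- tempfile()
  write_delivery(plan, f1, "csv"); write_delivery(same, f2, "csv")
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
  # MU scale multiplies every cumulative MU exactly
  sc <- make_actual_log(plan, mu_scale = 1.05, seed = 3)
  for (bi in seq_along(plan$beams))
    for (ci in seq_along(plan$beams[[bi]]$control_points))
      expect_equal(sc$beams[[bi]]$control_points[[ci]]$mu_cumulative,
                   plan$beams[[bi]]$control_points[[ci]]$mu_cumulative * 1.05)
  # MLC noise keeps the plan valid and is seed-reproducible
  n1 <- make_actual_log(plan, mlc_sd_cm = 0.3, seed = 17)
  n2 <- make_actual_log(plan, mlc_sd_cm = 0.3, seed = 17)
  expect_identical(nrow(validate_delivery(n1)), 0L)
  expect_identical(n1$beams[[2]]$control_points[[2]]$bank_a,
                   n2$beams[[2]]$control_points[[2]]$bank_a)
})

test_that("the full synthetic chain self-compares perfectly", {
  case <- tiny_case()
  ref <- case$reference
  masks <- case$phantom$masks
  body <- masks$labels$body
  expect_equal(dose_mae(ref, ref, body), 0)
  expect_equal(dose_rmse(ref, ref, body), 0)
  dc <- isodose_dice(ref, ref, case$plan$prescription_dose,
                     seq(5, 100, 5), body)
  expect_true(all(dc$dsc == 1))
})
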