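mk_vol <- function(values) {
  v <- as.array(values)
  image_volume(voxel_grid(0, 1, dim(v)), v, "dose_gy")
}
all_mask <- function(v) array(1, dim(as.array(v)))

test_that("MAE and RMSE match hand computations and obey mae <= rmse", {
  p <- array(c(1, 2, 3), c(3, 1, 1)); r <- array(c(2, 2, 1), c(3, 1, 1))
  m <- all_mask(p)
  expect_equal(dose_mae(p, r, m), 1.0)
  expect_equal(dose_rmse(array(c(1, 2), c(2, 1, 1)),
                         array(c(2, 4), c(2, 1, 1)),
                         array(1, c(2, 1, 1))), sqrt(5 / 2))
  expect_equal(dose_mae(p, p, m), 0); expect_equal(dose_rmse(p, p, m), 0)
  # constant offset: equality case
  expect_equal(dose_mae(p + 1.5, p, m), dose_rmse(p + 1.5, p, m))
  expect_error(dose_mae(p, r, m * 0), "empty")
  # mae <= rmse on randomized volumes
  set.seed(21)
  for (i in 1:100) {
    a <- array(runif(64, 0, 70), c(4, 4, 4))
    b <- array(runif(64, 0, 70), c(4, 4, 4))
    msk <- array((runif(64) < 0.7) * 1, c(4, 4, 4))
    if (!any(msk > 0)) msk[1] <- 1
    expect_lte(dose_mae(a, b, msk), dose_rmse(a, b, msk) + 1e-12)
  }
})

test_that("DVH curves are proper cumulative distributions", {
  u <- array(60, c(3, 3, 3)); m <- all_mask(u)
  cv <- dvh(u, m, bin_width = 1)
  expect_equal(cv$cum_volume_fraction[cv$dose_bins <= 60],
               rep(1, sum(cv$dose_bins <= 60)))
  expect_equal(cv$cum_volume_fraction[cv$dose_bins > 60],
               rep(0, sum(cv$dose_bins > 60)))
  two <- array(c(10, 30), c(2, 1, 1))
  cv2 <- dvh(two, all_mask(two), bin_width = 1)
  mid <- cv2$dose_bins > 10 & cv2$dose_bins <= 30
  expect_equal(cv2$cum_volume_fraction[mid], rep(0.5, sum(mid)))
  expect_equal(cv2$cum_volume_fraction[1], 1.0)
  expect_true(all(diff(cv2$cum_volume_fraction) <= 0))
})

test_that("D_x and V_x match brute-force definitions", {
  u <- array(60, c(3, 3, 3)); m <- all_mask(u)
  for (x in c(95, 98, 99)) expect_equal(d_index(u, m, x), 60)
  expect_equal(d_max(u, m), 60); expect_equal(d_mean(u, m), 60)
  # linear ramp: D_50 near the midpoint
  ramp <- array(seq(0, 100, length.out = 1000), c(10, 10, 10))
  expect_lt(abs(d_index(ramp, all_mask(ramp), 50) - 50), 0.2)
  expect_error(d_index(u, m, 0), "0, 100")
  expect_error(d_index(u, m, 101), "0, 100")
  # V_x hand cases
  ten <- array(10, c(4, 1, 1))
  expect_equal(v_index(ten, all_mask(ten), 5), 1.0)
  expect_equal(v_index(ten, all_mask(ten), 20), 0.0)
  half <- array(c(25, 25, 15, 15), c(4, 1, 1))
  expect_equal(v_index(half, all_mask(half), 20), 0.5)
  expect_equal(v_index(half, all_mask(half), 0), 1.0)
  # monotonicity of D_x and sort-oracle agreement on random volumes
  set.seed(31)
  for (i in 1:100) {
    v <- array(runif(125, 0, 70), c(5, 5, 5))
    msk <- all_mask(v)
    xs <- sort(runif(4, 1, 100))
    ds <- vapply(xs, function(x) d_index(v, msk, x), numeric(1))
    expect_true(all(diff(ds) <= 1e-12))
    # oracle: scan all candidate doses for the definition's maximizer
    x <- xs[2]
    cand <- sort(unique(as.numeric(v)))
    ok <- cand[vapply(cand, function(d) mean(v >= d) >= x / 100, logical(1))]
    expect_equal(d_index(v, msk, x), max(ok))
  }
})

test_that("isodose Dice matches set arithmetic", {
  m <- array(1, c(4, 1, 1))
  p <- array(c(10, 10, 0, 0), c(4, 1, 1))
  r <- array(c(10, 0, 10, 0), c(4, 1, 1))
  # at 50% of prescription 10: A = {1,2}, B = {1,3}, overlap 1 -> 0.5
  dc <- isodose_dice(p, r, prescription = 10, levels = 50, region_mask = m)
  expect_equal(dc$dsc, 0.5)
  expect_equal(dc$thresholds, 5)
  # identity -> 1 at every level; disjoint -> 0; both-empty -> 1
  dci <- isodose_dice(p, p, 10, seq(5, 100, 5), m)
  expect_true(all(dci$dsc == 1))
  pd <- array(c(10, 0, 0, 0), c(4, 1, 1)); rd <- array(c(0, 10, 0, 0), c(4, 1, 1))
  expect_equal(isodose_dice(pd, rd, 10, 50, m)$dsc, 0)
  expect_equal(isodose_dice(pd * 0, rd * 0, 10, 50, m)$dsc, 1.0)
})

test_that("Bland-Altman limits follow the 1.96 SD construction", {
  expect_equal(unlist(bland_altman(c(1, 2, 3), c(1, 2, 3))[1:3]),
               c(mean_diff = 0, lower_limit = 0, upper_limit = 0))
  ba <- bland_altman(c(5, 6, 7), c(3, 4, 5))   # constant difference 2
  expect_equal(c(ba$mean_diff, ba$lower_limit, ba$upper_limit), c(2, 2, 2))
  ba2 <- bland_altman(c(0, 2), c(1, 1))        # d = c(-1, 1)
  expect_equal(ba2$mean_diff, 0)
  expect_equal(ba2$upper_limit, 1.96 * sqrt(2))
  expect_equal(ba2$lower_limit, -1.96 * sqrt(2))
  expect_error(bland_altman(1, 1), "at least 2")
  # empirical coverage of the 95% limits on a large Gaussian sample
  set.seed(41)
  d <- rnorm(20000)
  ba3 <- bland_altman(d, numeric(20000))
  expect_gte(mean(d >= ba3$lower_limit & d <= ba3$upper_limit), 0.93)
})

test_that("the DVH table reports the clinical index set with deviations", {
  case <- tiny_case()
  ref <- case$sample$reference_dose
  masks <- case$sample$masks
  tab <- dvh_table(ref, ref, masks)
  # ROIs too thin to survive the coarse desk-scale voxels (the 0.5-cm cord
  # at 1-cm spacing) are flagged absent; everything else must be present
  nonempty <- vapply(masks$labels, function(m) any(m > 0), logical(1))
  expect_true(all(tab$present == nonempty[tab$roi]))
  expect_true(any(tab$present))
  expect_true(all(tab$mean_relative_deviation[tab$present] == 0))
  expect_true(all(is.na(tab$p_value)))  # single case: no test applicable
  expect_setequal(unique(tab$roi),
                  c("PTV", "total_lung", "right_lung", "left_lung",
                    "spinal_cord", "heart"))
  expect_setequal(tab$index[tab$roi == "PTV"],
                  c("D95", "D98", "D99", "Dmax", "Dmean"))
  # 10 synthetic cases with pred = 1.01 * ref: every deviation is 0.01
  pred10 <- replicate(10, image_volume(ref$grid, ref$values * 1.01, "dose_gy"),
                      simplify = FALSE)
  ref10 <- replicate(10, ref, simplify = FALSE)
  m10 <- replicate(10, masks, simplify = FALSE)
  tab10 <- dvh_table(pred10, ref10, m10)
  # dose-valued indices scale with the dose; V_x counts need not
  dose_ix <- grepl("^D|MLD|MHD", tab10$index)
  dev <- tab10$mean_relative_deviation[tab10$present & dose_ix]
  expect_equal(dev, rep(0.01, length(dev)), tolerance = 1e-9)
  # a missing ROI is flagged absent, not fatal
  partial <- structure_mask(masks$grid, masks$labels[c("PTV", "body")])
  tabp <- dvh_table(ref, ref, partial)
  expect_false(any(tabp$present[tabp$roi == "heart"]))
})

test_that("dose profiles track the grid line through a point", {
  flat <- mk_vol(array(3, c(5, 6, 7)))
  pr <- dose_profile(flat, 2, c(2, 2, 2))
  expect_identical(nrow(pr), 6L)
  expect_true(all(pr$value == 3))
  expect_error(dose_profile(flat, 1, c(100, 0, 0)), "outside")
  # phantom reference dose peaks inside the PTV x-extent
  case <- tiny_case()
  iso <- attr(case$plan, "isocenter")
  prx <- dose_profile(case$reference, 1, iso)
  ptv_idx <- which(case$phantom$masks$labels$PTV > 0, arr.ind = TRUE)
  xr <- range(logdoseqa:::grid_axes(case$reference$grid)[[1]][ptv_idx[, 1]])
  peak_x <- prx$position_cm[which.max(prx$value)]
  expect_gte(peak_x, xr[1] - 1); expect_lte(peak_x, xr[2] + 1)
})
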