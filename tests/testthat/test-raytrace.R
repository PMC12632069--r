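test_that("beam frame places the source on the gantry circle", {
  fr <- beam_frame(0, sad = 100, isocenter = c(0, 0, 0))
  expect_equal(fr$source, c(0, 0, 100))
  expect_equal(beam_frame(90, 100)$source, c(100, 0, 0))
  # antipodal sources at opposed angles; orthonormal BEV axes always
  for (g in c(0, 37.5, 122, 270)) {
    a <- beam_frame(g, 100, c(1, 2, 3))
    b <- beam_frame(g + 180, 100, c(1, 2, 3))
    expect_equal(a$source - c(1, 2, 3), -(b$source - c(1, 2, 3)))
    expect_equal(sum(a$ex * a$ey), 0)
    expect_equal(sum(a$ex^2), 1)
    beam_dir <- (a$isocenter - a$source) / a$sad
    expect_equal(sum(a$ex * beam_dir), 0, tolerance = 1e-12)
    expect_equal(sum(a$ey * beam_dir), 0, tolerance = 1e-12)
  }
})

test_that("axis-aligned traversal walks the full column with uniform chords", {
  vg <- voxel_grid(origin = c(0, 0, 0), spacing = 0.2, dims = c(1, 1, 128))
  tr <- dda_traverse(c(0, 0, -10), c(0, 0, 1), vg)
  expect_identical(nrow(tr$index), 128L)
  expect_identical(tr$index[, 3], 1:128)
  expect_equal(tr$chord, rep(0.2, 128), tolerance = 1e-12)
  # reversed direction visits the reversed sequence
  rv <- dda_traverse(c(0, 0, 40), c(0, 0, -1), vg)
  expect_identical(rv$index[, 3], 128:1)
  # a miss is an empty result, not an error
  miss <- dda_traverse(c(10, 10, -10), c(0, 0, 1), vg)
  expect_identical(nrow(miss$index), 0L)
})

test_that("traversal agrees with a dense-sampling oracle on random rays", {
  set.seed(11)
  n_rays <- 200
  mismatches <- 0
  for (r in seq_len(n_rays)) {
    dims <- sample(4:16, 3, replace = TRUE)
    sp <- runif(3, 0.3, 1.5)
    org <- runif(3, -2, 2)
    vg <- voxel_grid(org, sp, dims)
    ctr <- org + (dims - 1) / 2 * sp
    entry <- ctr + runif(3, -1, 1) * dims * sp  # random point near the grid
    target <- ctr + runif(3, -0.4, 0.4) * dims * sp
    dir <- target - entry
    if (sqrt(sum(dir^2)) < 1e-6) next
    tr <- dda_traverse(entry, dir, vg)
    got <- sort(dda_linear(tr, vg)[tr$chord > 2e-3 * min(sp)])
    want <- sort(dense_ray_voxels(entry, dir, vg))
    # every sampled voxel must be visited; every non-sliver chord sampled
    if (!all(want %in% dda_linear(tr, vg)) || !all(got %in% want))
      mismatches <- mismatches + 1
  }
  expect_identical(mismatches, 0)
})

test_that("chord lengths conserve the in-grid path length", {
  set.seed(13)
  for (r in 1:100) {
    vg <- voxel_grid(runif(3, -1, 1), runif(3, 0.2, 1), sample(3:12, 3, TRUE))
    entry <- runif(3, -15, -5)
    dir <- runif(3, 0.1, 1)
    tr <- dda_traverse(entry, dir, vg)
    span <- ray_box_span(entry, dir, vg)
    if (is.null(span)) {
      expect_identical(nrow(tr$index), 0L)
    } else {
      expect_lt(abs(sum(tr$chord) - (span[2] - span[1])),
                1e-9 * max(1, span[2] - span[1]))
    }
  }
})

test_that("projection deposits inverse-square attenuated pixel weights", {
  # single open central pixel, gantry 0: ray straight down the z axis
  g <- fluence_grid(0.5, 1, 1)  # single pixel centred on the beam axis
  fmap <- list(grid = g, values = matrix(5, 1, 1),
               gantry_deg = 0, beam_id = "b")
  class(fmap) <- "fluence_map"
  # column of voxels down the central axis
  vg <- voxel_grid(origin = c(0, 0, -50), spacing = c(0.5, 0.5, 1),
                   dims = c(1, 1, 101))
  fr <- beam_frame(0, sad = 100)
  pv <- project_fluence_map(fmap, vg, fr)
  # voxel at z = 0 sits at distance sad: factor exactly 1
  expect_equal(pv$values[1, 1, 51], 5 * 1.0, tolerance = 1e-9)
  # voxel 50 cm beyond the isocenter: (100/150)^2 = 4/9
  expect_equal(pv$values[1, 1, 1], 5 * 4 / 9, tolerance = 1e-9)
  # factors strictly decrease with distance from the source along the ray
  expect_true(all(diff(pv$values[1, 1, ]) > 0))  # z increasing -> closer
  # all-zero map -> all-zero volume
  fmap0 <- fmap; fmap0$values[] <- 0
  expect_true(all(project_fluence_map(fmap0, vg, fr)$values == 0))
  # source inside the grid is degenerate
  big <- voxel_grid(c(-10, -10, 90), c(5, 5, 5), c(5, 5, 5))
  expect_error(project_fluence_map(fmap, big, fr), "degenerate")
})

test_that("plan accumulation is additive, order-independent and symmetric", {
  geom <- toy_geometry()
  cp <- rect_aperture_cp(geom, hx = 2, hy = 2)
  g <- fluence_grid(0.5, 16, 16)
  mk_map <- function(gantry) {
    m <- segment_fluence(list(cp = cp, delta_mu = 10), geom, g)
    m$gantry_deg <- gantry
    m
  }
  vg <- voxel_grid(c(-4.5, -4.5, -4.5), 0.5, c(19, 19, 19))  # symmetric about 0
  maps <- list(mk_map(0), mk_map(180))
  acc <- accumulate_plan(maps, vg)
  # opposed identical beams: volume symmetric under z-reflection
  expect_lt(max(abs(acc$values - acc$values[, , 19:1])), 1e-9)
  # additivity and commutativity
  s1 <- accumulate_plan(maps[1], vg)$values
  s2 <- accumulate_plan(maps[2], vg)$values
  expect_equal(acc$values, s1 + s2, tolerance = 1e-12)
  expect_equal(accumulate_plan(rev(maps), vg)$values, acc$values)
})

test_that("zero fluence and MU scaling propagate through projection", {
  case <- tiny_case()
  maps <- case$maps
  vg <- case$phantom$ct$grid
  iso <- attr(case$plan, "isocenter")
  scaled <- lapply(maps, function(m) { m$values <- 2 * m$values; m })
  p1 <- accumulate_plan(maps, vg, isocenter = iso)
  p2 <- accumulate_plan(scaled, vg, isocenter = iso)
  expect_equal(p2$values, 2 * p1$values, tolerance = 1e-12)
})
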