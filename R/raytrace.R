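#' Patient-space voxel grid
#'
#' Axis-aligned regular grid in the fixed patient frame (x lateral, y
#' longitudinal, z up; all lengths cm). `origin` is the centre of voxel
#' (1,1,1); voxel (i,j,k) occupies the half-open box
#' `[origin + (idx - 1.5) * spacing, origin + (idx - 0.5) * spacing)`.
#'
#' @param origin Centre of the first voxel, length-3 numeric (cm).
#' @param spacing Voxel spacing per axis, length-3 (or scalar) positive (cm).
#' @param dims Voxel counts per axis, length-3 integer.
#' @return A `voxel_grid` object.
#' @export
voxel_grid <- function(origin, spacing, dims) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  dims <- rep_len(as.integer(dims), 3L)
  stopifnot(all(spacing > 0), all(dims >= 1), all(is.finite(origin)))
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid ", paste(x$dims, collapse = "x"), " @ ",
      paste(signif(x$spacing, 4), collapse = "x"), " cm, origin (",
      paste(signif(x$origin, 4), collapse = ", "), ") cm\n", sep = "")
  invisible(x)
}

grid_axes <- function(grid)
  lapply(1:3, function(a) grid$origin[a] + (seq_len(grid$dims[a]) - 1) * grid$spacing[a])

grid_bounds <- function(grid)
  list(lo = grid$origin - 0.5 * grid$spacing,
       hi = grid$origin + (grid$dims - 0.5) * grid$spacing)

same_grid <- function(a, b, tol = 1e-9) {
  all(a$dims == b$dims) && all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Beam frame for a gantry angle
#'
#' Places the radiation source on the gantry circle and maps the beam's-eye
#' view axes into the patient frame. Gantry 0 puts the source directly above
#' the isocenter (`source = iso + sad * (sin g, 0, cos g)` with g in the
#' lateral/vertical plane); the BEV x axis (leaf travel) rotates with the
#' gantry, the BEV y axis (leaf width) is the longitudinal patient axis.
#' Couch and collimator rotations are assumed zero (coplanar step-and-shoot).
#'
#' @param gantry_deg Gantry angle in degrees.
#' @param sad Source-axis distance in cm.
#' @param isocenter Isocenter position in the patient frame (cm).
#' @return A `beam_frame`: `source`, orthonormal `ex`/`ey` BEV axes,
#'   `gantry_deg`, `sad`, `isocenter`.
#' @export
beam_frame <- function(gantry_deg, sad = 100, isocenter = c(0, 0, 0)) {
  stopifnot(sad > 0)
  g <- gantry_deg * pi / 180
  structure(list(gantry_deg = gantry_deg %% 360, sad = sad,
                 isocenter = as.numeric(isocenter),
                 source = as.numeric(isocenter) + sad * c(sin(g), 0, cos(g)),
                 ex = c(cos(g), 0, -sin(g)),
                 ey = c(0, 1, 0)),
            class = "beam_frame")
}

#' Enumerate voxels along a ray (3D-DDA)
#'
#' Incremental digital-differential-analyzer traversal: visits exactly the
#' voxels whose boxes the ray from `entry` along `direction` intersects, in
#' order of increasing ray parameter, with the chord length (cm) of the ray
#' inside each voxel. Chords sum to the total in-grid path length. A ray that
#' misses the grid returns zero rows.
#'
#' @param entry Ray origin, length-3 (cm); may lie outside the grid.
#' @param direction Ray direction, length-3, non-zero (normalized internally).
#' @param grid A [voxel_grid()].
#' @return List with `index` (n x 3 matrix of 1-based voxel indices) and
#'   `chord` (length-n numeric, cm).
#' @export
dda_traverse <- function(entry, direction, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (sum(direction^2) == 0) stop("direction must be non-zero")
  dda_traverse_cpp(as.numeric(entry), as.numeric(direction),
                   grid$origin, grid$spacing, grid$dims)
}

#' Project one fluence map through the patient grid
#'
#' For every open fluence pixel, casts a ray from the source through the
#' pixel's isocenter-plane position and deposits the pixel weight into every
#' traversed voxel, attenuated by the inverse square law
#' `w * (sad / d)^2` with `d` the source-to-voxel-centre distance. Rays from
#' multiple pixels accumulate additively. Deposition is evaluated at voxel
#' centres by default (`deposit_mode = "point"`); `"chord"` additionally
#' weights by the in-voxel chord length.
#'
#' @param fmap A `fluence_map` (see [segment_fluence()]).
#' @param grid A [voxel_grid()].
#' @param frame A [beam_frame()] sharing the map's gantry angle.
#' @param deposit_mode `"point"` or `"chord"`.
#' @param supersample Sub-pixel ray factor per axis (1, 2 or 4).
#' @return An [image_volume()] of kind `"projected"`.
#' @export
project_fluence_map <- function(fmap, grid, frame,
                                deposit_mode = c("point", "chord"),
                                supersample = 1L) {
  deposit_mode <- match.arg(deposit_mode)
  if (abs((fmap$gantry_deg - frame$gantry_deg) %% 360) > 1e-6)
    stop("fluence map gantry (", fmap$gantry_deg,
         ") does not match frame gantry (", frame$gantry_deg, ")")
  b <- grid_bounds(grid)
  if (all(frame$source >= b$lo) && all(frame$source <= b$hi))
    stop("degenerate frame: source lies inside the voxel grid")
  ctr <- grid_pixel_centers(fmap$grid)
  vol <- numeric(prod(grid$dims))
  vol <- project_rays_cpp(fmap$values, ctr$x, ctr$y, frame$source,
                          frame$ex, frame$ey, frame$isocenter, frame$sad,
                          grid$origin, grid$spacing, grid$dims,
                          identical(deposit_mode, "chord"),
                          as.integer(supersample), vol)
  image_volume(grid, array(vol, grid$dims), kind = "projected")
}

#' Composite projected volume of a whole plan
#'
#' Sums [project_fluence_map()] over all fluence maps (all beams, all
#' segments, all gantry angles), yielding the composite 3D volume that
#' spatially encodes the logged delivery: the network input channel standing
#' in for the delivery parameters.
#'
#' @param maps List of `fluence_map`s (one machine geometry).
#' @param grid A [voxel_grid()].
#' @param sad Source-axis distance in cm (default 100).
#' @param isocenter Isocenter in the patient frame (cm).
#' @param deposit_mode,supersample Passed to [project_fluence_map()].
#' @return An [image_volume()] of kind `"projected"`.
#' @export
accumulate_plan <- function(maps, grid, sad = 100, isocenter = c(0, 0, 0),
                            deposit_mode = "point", supersample = 1L) {
  acc <- array(0, grid$dims)
  for (m in maps) {
    fr <- beam_frame(m$gantry_deg, sad = sad, isocenter = isocenter)
    acc <- acc + project_fluence_map(m, grid, fr, deposit_mode, supersample)$values
  }
  image_volume(grid, acc, kind = "projected")
}
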