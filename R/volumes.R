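#' Scalar image volume in patient space
#'
#' @param grid A [voxel_grid()].
#' @param values 3D numeric array matching `grid$dims`.
#' @param kind One of `"ct_hu"`, `"dose_gy"`, `"projected"`. Dose and
#'   projected volumes must be non-negative.
#' @return An `image_volume` object.
#' @export
image_volume <- function(grid, values, kind = c("ct_hu", "dose_gy", "projected")) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "voxel_grid"))
  values <- as.array(values)
  if (!all(dim(values) == grid$dims))
    stop("values dims (", paste(dim(values), collapse = "x"),
         ") do not match grid dims (", paste(grid$dims, collapse = "x"), ")")
  if (any(!is.finite(values))) stop("values must be finite")
  if (kind != "ct_hu" && any(values < 0)) stop(kind, " volume must be non-negative")
  structure(list(grid = grid, values = values, kind = kind),
            class = "image_volume")
}

#' Binary region-of-interest masks on a shared grid
#'
#' Named list of binary 3D arrays on one grid. Canonical ROI names for the
#' thoracic workflow: `PTV`, `left_lung`, `right_lung`, `total_lung`,
#' `heart`, `spinal_cord`, `body`. When left, right and total lung are all
#' present, `total_lung` must equal their union; `PTV` must lie inside
#' `body`.
#'
#' @param grid A [voxel_grid()].
#' @param labels Named list of arrays with values in `{0, 1}`.
#' @return A `structure_mask` object.
#' @export
structure_mask <- function(grid, labels) {
  stopifnot(inherits(grid, "voxel_grid"), is.list(labels), length(names(labels)) > 0)
  labels <- lapply(labels, function(m) {
    m <- as.array(m * 1)
    if (!all(dim(m) == grid$dims)) stop("mask dims do not match grid dims")
    if (!all(m %in% c(0, 1))) stop("masks must be binary")
    m
  })
  if (all(c("left_lung", "right_lung", "total_lung") %in% names(labels))) {
    un <- pmin(labels$left_lung + labels$right_lung, 1)
    if (!all(un == labels$total_lung))
      stop("total_lung must equal left_lung OR right_lung")
  }
  if (all(c("PTV", "body") %in% names(labels)) &&
      any(labels$PTV > labels$body))
    stop("PTV must lie inside body")
  structure(list(grid = grid, labels = labels), class = "structure_mask")
}

# Map target-axis voxel centres onto continuous (1-based) source indices.
# Grids are axis-aligned and parallel, so resampling is separable per axis.
axis_index <- function(src_origin, src_spacing, src_n, tgt_centers)
  (tgt_centers - src_origin) / src_spacing + 1

resample_array <- function(values, src, tgt, mode, fill) {
  ax <- grid_axes(tgt)
  f <- lapply(1:3, function(a)
    axis_index(src$origin[a], src$spacing[a], src$dims[a], ax[[a]]))
  if (mode == "nearest") {
    idx <- lapply(1:3, function(a) {
      i <- round(f[[a]])
      i[f[[a]] < 0.5 - 1e-9 | f[[a]] > src$dims[a] + 0.5 + 1e-9] <- NA
      i
    })
    out <- array(fill, tgt$dims)
    ok <- lapply(idx, function(i) !is.na(i))
    ii <- idx[[1]][ok[[1]]]; jj <- idx[[2]][ok[[2]]]; kk <- idx[[3]][ok[[3]]]
    if (length(ii) && length(jj) && length(kk))
      out[ok[[1]], ok[[2]], ok[[3]]] <- values[ii, jj, kk]
    return(out)
  }
  # trilinear with fill outside the voxel-centre hull
  out <- array(0, tgt$dims)
  i0 <- list(); fr <- list(); inside <- list()
  for (a in 1:3) {
    i0a <- floor(f[[a]])
    fra <- f[[a]] - i0a
    ins <- f[[a]] >= 1 - 1e-12 & f[[a]] <= src$dims[a] + 1e-12
    i0a <- pmin(pmax(i0a, 1), src$dims[a] - if (src$dims[a] > 1) 1 else 0)
    fra <- f[[a]] - i0a
    fra <- pmin(pmax(fra, 0), 1)
    i0[[a]] <- i0a; fr[[a]] <- fra; inside[[a]] <- ins
  }
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wx <- if (cx == 0) 1 - fr[[1]] else fr[[1]]
    wy <- if (cy == 0) 1 - fr[[2]] else fr[[2]]
    wz <- if (cz == 0) 1 - fr[[3]] else fr[[3]]
    ix <- pmin(i0[[1]] + cx, src$dims[1])
    iy <- pmin(i0[[2]] + cy, src$dims[2])
    iz <- pmin(i0[[3]] + cz, src$dims[3])
    w <- outer(outer(wx, wy), wz)
    if (any(w > 0)) out <- out + w * values[ix, iy, iz, drop = FALSE]
  }
  out_mask <- outer(outer(inside[[1]], inside[[2]]), inside[[3]])
  out[!out_mask] <- fill
  out
}

#' Resample a volume or mask onto a target grid
#'
#' Registration-by-resampling within a shared frame of reference: scalar
#' volumes are interpolated trilinearly, masks with nearest neighbour (so
#' they stay binary). Points outside the source grid take a kind-dependent
#' fill value: -1000 HU for CT, 0 for dose/projected volumes and masks.
#'
#' @param x An [image_volume()] or [structure_mask()].
#' @param target Target [voxel_grid()].
#' @param mode `"trilinear"` or `"nearest"`; defaults to trilinear for
#'   volumes and nearest for masks. Masks only accept `"nearest"`.
#' @return Same type as `x`, on `target`.
#' @export
resample <- function(x, target, mode = NULL) UseMethod("resample")

#' @export
resample.image_volume <- function(x, target, mode = NULL) {
  mode <- if (is.null(mode)) "trilinear" else match.arg(mode, c("trilinear", "nearest"))
  fill <- if (x$kind == "ct_hu") -1000 else 0
  if (same_grid(x$grid, target) && mode == "nearest")
    return(image_volume(target, x$values, x$kind))
  image_volume(target, resample_array(x$values, x$grid, target, mode, fill), x$kind)
}

#' @export
resample.structure_mask <- function(x, target, mode = NULL) {
  mode <- if (is.null(mode)) "nearest" else match.arg(mode, c("nearest", "trilinear"))
  if (mode != "nearest")
    stop("masks must be resampled with mode = 'nearest' to stay binary")
  structure_mask(target, lapply(x$labels, function(m)
    resample_array(m, x$grid, target, "nearest", 0)))
}

#' Co-registered model sample on a common cubic grid
#'
#' @param ct,projected,reference_dose [image_volume()]s on one grid.
#' @param masks A [structure_mask()] on the same grid.
#' @param prescription_dose Prescription in Gy.
#' @return A `model_sample` object.
#' @export
model_sample <- function(ct, projected, reference_dose, masks, prescription_dose) {
  g <- ct$grid
  if (length(unique(g$dims)) != 1L) stop("model sample grid must be cubic")
  for (v in list(projected, reference_dose))
    if (!same_grid(v$grid, g)) stop("all sample volumes must share one grid")
  if (!same_grid(masks$grid, g)) stop("masks must share the sample grid")
  stopifnot(prescription_dose > 0)
  structure(list(ct = ct, projected = projected, reference_dose = reference_dose,
                 masks = masks, prescription_dose = prescription_dose),
            class = "model_sample")
}

#' Assemble a co-registered model sample
#'
#' Builds the common cubic grid from the body mask: the cube side is the
#' largest physical extent of the body's bounding box (plus one voxel of
#' slack), centred on the body-mask centroid, divided into `n` voxels per
#' axis. CT, projected volume and reference dose are resampled trilinearly,
#' masks with nearest neighbour. Inputs must share one frame of reference;
#' an input whose extent does not reach the body region is rejected. When
#' all inputs already sit on a shared cubic `n`-grid the sample is returned
#' as-is (idempotent).
#'
#' @param ct [image_volume()] of kind `"ct_hu"`.
#' @param masks [structure_mask()] containing a `body` label.
#' @param projected [image_volume()] of kind `"projected"`.
#' @param reference_dose [image_volume()] of kind `"dose_gy"`.
#' @param prescription_dose Prescription in Gy.
#' @param n Cubic dimension (default 128; use 24-32 for desk-scale work).
#' @return A [model_sample()] with all arrays `n^3`.
#' @export
assemble_sample <- function(ct, masks, projected, reference_dose,
                            prescription_dose, n = 128L) {
  n <- as.integer(n)
  if (is.null(masks$labels$body)) stop("masks must include a 'body' label")
  already <- all(ct$grid$dims == n) &&
    same_grid(ct$grid, masks$grid) && same_grid(ct$grid, projected$grid) &&
    same_grid(ct$grid, reference_dose$grid)
  if (already)
    return(model_sample(ct, projected, reference_dose, masks, prescription_dose))
  body <- masks$labels$body
  if (!any(body > 0)) stop("body mask is empty")
  idx <- which(body > 0, arr.ind = TRUE)
  ax <- grid_axes(masks$grid)
  world <- cbind(ax[[1]][idx[, 1]], ax[[2]][idx[, 2]], ax[[3]][idx[, 3]])
  centroid <- colMeans(world)
  extent <- apply(world, 2, function(w) diff(range(w))) + masks$grid$spacing
  side <- max(extent)
  spacing <- side / n
  target <- voxel_grid(origin = centroid - (n - 1) / 2 * spacing,
                       spacing = spacing, dims = c(n, n, n))
  tb <- grid_bounds(target)
  for (inp in list(ct, projected, reference_dose)) {
    b <- grid_bounds(inp$grid)
    if (any(b$hi < tb$lo) || any(b$lo > tb$hi))
      stop("input '", inp$kind, "' does not overlap the body region: ",
           "frame of reference mismatch?")
  }
  model_sample(resample(ct, target), resample(projected, target),
               resample(reference_dose, target),
               resample(masks, target), prescription_dose)
}

#' Normalize a model sample for network input
#'
#' CT is clipped to `[-1000, 1000]` HU and mapped to `[0, 1]`; the projected
#' volume is scaled by its own maximum (kept in the output so the transform
#' inverts); dose is divided by the prescription. Masks are passed through
#' unchanged (already in `{0, 1}`).
#'
#' @param sample A [model_sample()].
#' @return List with `ct`, `projected`, `dose` (normalized arrays), `masks`
#'   (list of binary arrays), `projected_max`, `prescription_dose`.
#' @export
normalize_for_model <- function(sample) {
  if (sample$prescription_dose <= 0) stop("prescription_dose must be > 0")
  pmx <- max(sample$projected$values)
  list(ct = (pmin(pmax(sample$ct$values, -1000), 1000) + 1000) / 2000,
       projected = if (pmx > 0) sample$projected$values / pmx
                   else sample$projected$values,
       dose = sample$reference_dose$values / sample$prescription_dose,
       masks = sample$masks$labels,
       projected_max = pmx,
       prescription_dose = sample$prescription_dose)
}

#' Convert a normalized dose array back to Gy
#'
#' Exact inverse of the dose branch of [normalize_for_model()].
#'
#' @param normalized Normalized dose array (dose / prescription).
#' @param prescription_dose Prescription in Gy.
#' @return Dose array in Gy.
#' @export
denormalize_dose <- function(normalized, prescription_dose) {
  stopifnot(prescription_dose > 0)
  normalized * prescription_dose
}
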