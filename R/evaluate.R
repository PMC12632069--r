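masked_values <- function(vol, mask) {
  v <- if (inherits(vol, "image_volume")) vol$values else vol
  m <- if (is.list(mask)) stop("mask must be a binary array") else mask
  if (!all(dim(v) == dim(m))) stop("volume and mask dims differ")
  out <- v[m > 0]
  if (!length(out)) stop("mask is empty")
  out
}

#' Mean absolute voxel error between two dose distributions
#'
#' `MAE = (1/vxl) * sum_v |pred(v) - ref(v)|` over the masked voxels.
#'
#' @param pred,ref Dose volumes ([image_volume()] or arrays) on one grid, Gy.
#' @param mask Binary array selecting the voxels to score (e.g. an ROI).
#' @return MAE in Gy.
#' @export
dose_mae <- function(pred, ref, mask) {
  mean(abs(masked_values(pred, mask) - masked_values(ref, mask)))
}

#' Root mean squared voxel error between two dose distributions
#'
#' `RMSE = sqrt((1/vxl) * sum_v (pred(v) - ref(v))^2)`; always >= the MAE on
#' the same voxels.
#'
#' @inheritParams dose_mae
#' @return RMSE in Gy.
#' @export
dose_rmse <- function(pred, ref, mask) {
  sqrt(mean((masked_values(pred, mask) - masked_values(ref, mask))^2))
}

#' Cumulative dose-volume histogram of an ROI
#'
#' Fraction of the ROI receiving at least each bin dose; starts at 1 at
#' 0 Gy, non-increasing, 0 beyond the ROI maximum. The binned curve is for
#' plotting/reporting; point indices ([d_index()], [v_index()]) are computed
#' on the unbinned voxel doses to avoid binning bias.
#'
#' @param dose Dose volume ([image_volume()] or array), Gy.
#' @param mask Binary ROI array.
#' @param bin_width Histogram bin width in Gy (default 0.05).
#' @param roi Optional ROI name carried on the curve.
#' @return A `dvh_curve`: list with `roi`, `dose_bins`, `cum_volume_fraction`.
#' @export
dvh <- function(dose, mask, bin_width = 0.05, roi = NA_character_) {
  d <- masked_values(dose, mask)
  bins <- seq(0, max(d) + bin_width, by = bin_width)
  frac <- vapply(bins, function(b) mean(d >= b), numeric(1))
  structure(list(roi = roi, dose_bins = bins, cum_volume_fraction = frac),
            class = "dvh_curve")
}

#' Dose covering the hottest x% of an ROI (D_x)
#'
#' The greatest dose `d` such that at least `x`% of the ROI receives `>= d`:
#' the `ceil(x/100 * n)`-th largest voxel dose. Computed on the empirical
#' voxel distribution, not a binned curve.
#'
#' @param dose Dose volume or array, Gy.
#' @param mask Binary ROI array.
#' @param x Percent of volume, in `(0, 100]`.
#' @return D_x in Gy.
#' @export
d_index <- function(dose, mask, x) {
  if (!is.numeric(x) || x <= 0 || x > 100) stop("x must be in (0, 100]")
  d <- sort(masked_values(dose, mask), decreasing = TRUE)
  d[ceiling(x / 100 * length(d))]
}

#' Maximum and mean ROI dose
#'
#' @param dose Dose volume or array, Gy.
#' @param mask Binary ROI array.
#' @return D_max / D_mean in Gy.
#' @export
d_max <- function(dose, mask) max(masked_values(dose, mask))

#' @rdname d_max
#' @export
d_mean <- function(dose, mask) mean(masked_values(dose, mask))

#' Fractional ROI volume receiving at least x Gy (V_x)
#'
#' @param dose Dose volume or array, Gy.
#' @param mask Binary ROI array.
#' @param x Dose threshold in Gy (>= 0).
#' @return Volume fraction in `[0, 1]`.
#' @export
v_index <- function(dose, mask, x) {
  if (!is.numeric(x) || x < 0) stop("x must be >= 0 Gy")
  mean(masked_values(dose, mask) >= x)
}

#' Dice agreement of isodose volumes across dose levels
#'
#' For each level `k` (percent of the prescription `D_P`), thresholds both
#' distributions at `h = k * D_P / 100` within the region mask and computes
#' the Dice similarity coefficient `2|A n B| / (|A| + |B|)` between the two
#' isodose volumes (1 = perfect match; defined as 1 when both are empty).
#'
#' @param pred,ref Dose volumes or arrays on one grid, Gy.
#' @param prescription Prescription dose `D_P` in Gy.
#' @param levels Isodose levels in percent of `D_P` (default 5..100 by 5).
#' @param region_mask Binary array bounding the comparison (typically the
#'   body mask; a PTV-bounded variant is obtained by passing the PTV mask).
#' @return An `isodose_dice_curve`: `levels` (%), `thresholds` (Gy), `dsc`.
#' @export
isodose_dice <- function(pred, ref, prescription, levels = seq(5, 100, by = 5),
                         region_mask) {
  stopifnot(prescription > 0)
  p <- masked_values(pred, region_mask)
  r <- masked_values(ref, region_mask)
  levels <- sort(levels)
  dsc <- vapply(levels, function(k) {
    h <- k * prescription / 100
    a <- p >= h; b <- r >= h
    denom <- sum(a) + sum(b)
    if (denom == 0) 1.0 else 2 * sum(a & b) / denom
  }, numeric(1))
  structure(list(prescription = prescription, levels = levels,
                 thresholds = levels * prescription / 100, dsc = dsc),
            class = "isodose_dice_curve")
}

#' Bland-Altman agreement statistics
#'
#' Mean of the paired differences `pred - ref` and the 95% limits of
#' agreement `mean(d) +/- 1.96 * sd(d)` (sample SD, n - 1).
#'
#' @param pred_values,ref_values Equal-length paired numeric vectors (n >= 2).
#' @return List with `mean_diff`, `lower_limit`, `upper_limit`, `sd_diff`, `n`.
#' @export
bland_altman <- function(pred_values, ref_values) {
  if (length(pred_values) != length(ref_values))
    stop("paired samples must have equal length")
  if (length(pred_values) < 2L) stop("need at least 2 pairs")
  d <- pred_values - ref_values
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, lower_limit = m - 1.96 * s, upper_limit = m + 1.96 * s,
       sd_diff = s, n = length(d))
}

# The clinically reported index set per structure.
dvh_index_set <- function() list(
  PTV = list(c("D95", "d", 95), c("D98", "d", 98), c("D99", "d", 99),
             c("Dmax", "max", NA), c("Dmean", "mean", NA)),
  total_lung = list(c("V5", "v", 5), c("V20", "v", 20), c("MLD", "mean", NA)),
  right_lung = list(c("V5", "v", 5), c("V20", "v", 20), c("Dmean", "mean", NA)),
  left_lung  = list(c("V5", "v", 5), c("V20", "v", 20), c("Dmean", "mean", NA)),
  spinal_cord = list(c("Dmax", "max", NA)),
  heart = list(c("V30", "v", 30), c("V40", "v", 40), c("MHD", "mean", NA)))

eval_dvh_index <- function(dose, mask, kind, arg) {
  switch(kind,
         d = d_index(dose, mask, arg),
         v = v_index(dose, mask, arg),
         max = d_max(dose, mask),
         mean = d_mean(dose, mask))
}

#' DVH index comparison table across cases
#'
#' Evaluates the clinical index set (PTV D95/D98/D99/Dmax/Dmean; lung V5/
#' V20/mean dose per lung and combined; spinal cord Dmax; heart V30/V40/mean
#' heart dose) on predicted and reference dose for one or more cases and
#' summarizes: mean predicted value, mean reference value, mean relative
#' deviation `|pred - ref| / ref` (0/0 counted as 0) and a paired two-sided
#' Wilcoxon signed-rank p-value across cases (NA when fewer than 2 cases or
#' when all differences are zero). Missing ROIs are flagged absent, not
#' fatal.
#'
#' @param pred,ref A dose volume/array, or a list of them (one per case), Gy.
#' @param masks A [structure_mask()] or list of them (one per case).
#' @return Data frame with columns `roi`, `index`, `predicted`, `reference`,
#'   `mean_relative_deviation`, `p_value`, `n_cases`, `present`.
#' @export
dvh_table <- function(pred, ref, masks) {
  as_cases <- function(x) if (inherits(x, c("image_volume", "structure_mask")) ||
                              is.array(x)) list(x) else x
  pred <- as_cases(pred); ref <- as_cases(ref); masks <- as_cases(masks)
  n_cases <- length(pred)
  stopifnot(length(ref) == n_cases, length(masks) == n_cases)
  rows <- list()
  for (roi in names(dvh_index_set())) {
    for (ix in dvh_index_set()[[roi]]) {
      nm <- ix[1]; kind <- ix[2]; arg <- suppressWarnings(as.numeric(ix[3]))
      pv <- rv <- rep(NA_real_, n_cases)
      present <- TRUE
      for (cs in seq_len(n_cases)) {
        m <- masks[[cs]]$labels[[roi]]
        if (is.null(m) || !any(m > 0)) { present <- FALSE; break }
        pv[cs] <- eval_dvh_index(pred[[cs]], m, kind, arg)
        rv[cs] <- eval_dvh_index(ref[[cs]], m, kind, arg)
      }
      if (!present) {
        rows[[length(rows) + 1L]] <- data.frame(
          roi = roi, index = nm, predicted = NA_real_, reference = NA_real_,
          mean_relative_deviation = NA_real_, p_value = NA_real_,
          n_cases = n_cases, present = FALSE, stringsAsFactors = FALSE)
        next
      }
      rel <- ifelse(pv == rv, 0, abs(pv - rv) / rv)
      pval <- if (n_cases >= 2L && any(pv != rv))
        suppressWarnings(stats::wilcox.test(pv, rv, paired = TRUE,
                                            exact = FALSE)$p.value)
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        roi = roi, index = nm, predicted = mean(pv), reference = mean(rv),
        mean_relative_deviation = mean(rel), p_value = pval,
        n_cases = n_cases, present = TRUE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' 1D dose profile along a grid axis
#'
#' Values along the grid line parallel to `axis` passing through the voxel
#' nearest to `through_point`, with physical positions in cm.
#'
#' @param volume An [image_volume()].
#' @param axis 1 (x, lateral), 2 (y, longitudinal) or 3 (z, vertical).
#' @param through_point Length-3 point (cm) inside the grid.
#' @return Data frame with `position_cm` and `value`.
#' @export
dose_profile <- function(volume, axis, through_point) {
  g <- volume$grid
  axis <- as.integer(axis)
  stopifnot(axis %in% 1:3)
  b <- grid_bounds(g)
  if (any(through_point < b$lo) || any(through_point > b$hi))
    stop("through_point lies outside the grid")
  idx <- round((as.numeric(through_point) - g$origin) / g$spacing) + 1
  idx <- pmin(pmax(idx, 1), g$dims)
  sel <- as.list(idx)
  sel[[axis]] <- seq_len(g$dims[axis])
  vals <- do.call(`[`, c(list(volume$values), sel))
  data.frame(position_cm = grid_axes(g)[[axis]], value = as.numeric(vals))
}

#' Full predicted-vs-reference comparison report
#'
#' Bundles per-ROI MAE/RMSE, the DVH index table, the isodose Dice curve
#' over the body, Bland-Altman statistics over the PTV voxels, and central
#' dose profiles.
#'
#' @param pred,ref Dose [image_volume()]s on one grid, Gy.
#' @param masks A [structure_mask()] on the same grid.
#' @param prescription Prescription dose in Gy.
#' @param dice_levels Isodose levels (% of prescription).
#' @return A `comparison_report` list.
#' @export
comparison_report <- function(pred, ref, masks, prescription,
                              dice_levels = seq(5, 100, by = 5)) {
  rois <- names(masks$labels)
  per_roi <- do.call(rbind, lapply(rois, function(r) {
    m <- masks$labels[[r]]
    if (!any(m > 0)) return(NULL)
    data.frame(roi = r, mae = dose_mae(pred, ref, m),
               rmse = dose_rmse(pred, ref, m), stringsAsFactors = FALSE)
  }))
  region <- if (!is.null(masks$labels$body)) masks$labels$body
            else array(1, dim(pred$values))
  ptv <- masks$labels$PTV
  ba <- if (!is.null(ptv) && sum(ptv) >= 2)
    bland_altman(pred$values[ptv > 0], ref$values[ptv > 0]) else NULL
  center <- pred$grid$origin + (pred$grid$dims - 1) / 2 * pred$grid$spacing
  profiles <- lapply(1:3, function(a) dose_profile(pred, a, center))
  structure(list(
    per_roi = per_roi,
    dvh_indices = dvh_table(pred, ref, masks),
    dice_curve = isodose_dice(pred, ref, prescription, dice_levels, region),
    bland_altman = ba,
    profiles = profiles,
    prescription = prescription), class = "comparison_report")
}

#' Serialize a comparison report to JSON (plus CSV tables)
#'
#' @param report A `comparison_report`.
#' @param path Output JSON path; `<path>_roi.csv` and `<path>_dvh.csv` are
#'   written alongside.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  j <- list(per_roi = report$per_roi,
            dvh_indices = report$dvh_indices,
            dice = list(levels = report$dice_curve$levels,
                        thresholds = report$dice_curve$thresholds,
                        dsc = report$dice_curve$dsc),
            bland_altman = report$bland_altman,
            prescription = report$prescription)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", dataframe = "rows")
  base <- sub("\\.json$", "", path)
  utils::write.csv(report$per_roi, paste0(base, "_roi.csv"), row.names = FALSE)
  utils::write.csv(report$dvh_indices, paste0(base, "_dvh.csv"), row.names = FALSE)
  invisible(path)
}
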