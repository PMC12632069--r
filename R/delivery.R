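#' Machine geometry of a multi-leaf collimator
#'
#' Describes the MLC fitted to the accelerator: source-axis distance, the
#' per-pair leaf widths projected to the isocenter plane (ordered along the
#' leaf-width axis), and optional jaw limits. All lengths are centimetres at
#' the isocenter plane.
#'
#' @param sad Source-axis distance in cm (default 100, standard C-arm linac).
#' @param leaf_pair_widths Numeric vector of per-pair leaf widths (cm at
#'   isocenter), ordered along the leaf-width axis.
#' @param jaw_limits Optional jaw rectangle as
#'   `c(x_min, x_max, y_min, y_max)` in cm at isocenter, or `NULL`.
#' @return A `machine_geometry` object.
#' @seealso [hd120_geometry()] for the high-definition 120-leaf profile.
#' @export
machine_geometry <- function(sad = 100, leaf_pair_widths, jaw_limits = NULL) {
  stopifnot(is.numeric(sad), length(sad) == 1L, sad > 0)
  leaf_pair_widths <- as.numeric(leaf_pair_widths)
  if (length(leaf_pair_widths) < 1L || any(leaf_pair_widths <= 0))
    stop("leaf_pair_widths must be positive lengths (cm)")
  if (!is.null(jaw_limits)) {
    jaw_limits <- as.numeric(jaw_limits)
    if (length(jaw_limits) != 4L || jaw_limits[1] >= jaw_limits[2] ||
        jaw_limits[3] >= jaw_limits[4])
      stop("jaw_limits must be c(x_min, x_max, y_min, y_max) with min < max")
  }
  structure(list(
    sad = sad,
    leaf_pair_widths = leaf_pair_widths,
    n_pairs = length(leaf_pair_widths),
    jaw_limits = jaw_limits
  ), class = "machine_geometry")
}

#' High-definition 120-leaf MLC geometry
#'
#' The HD120 head: two banks of 60 leaf pairs, the outer 2x14 pairs 0.5 cm
#' wide and the inner 32 pairs 0.25 cm wide at isocenter, spanning 22 cm in
#' total along the leaf-width axis.
#'
#' @param sad Source-axis distance in cm.
#' @return A `machine_geometry` with 60 leaf pairs.
#' @export
hd120_geometry <- function(sad = 100) {
  machine_geometry(sad = sad,
                   leaf_pair_widths = c(rep(0.5, 14), rep(0.25, 32), rep(0.5, 14)))
}

#' Edges of the leaf-width bands
#'
#' Band i of pair i spans `[edges[i], edges[i + 1]]` on the leaf-width axis,
#' centred about the beam central axis.
#'
#' @param geom A `machine_geometry`.
#' @return Numeric vector of length `n_pairs + 1` (cm at isocenter).
#' @export
leaf_band_edges <- function(geom) {
  total <- sum(geom$leaf_pair_widths)
  cumsum(c(-total / 2, geom$leaf_pair_widths))
}

#' One logged machine state (control point)
#'
#' @param index Ordinal index of the control point within its beam.
#' @param mu_cumulative Cumulative monitor units delivered up to this state.
#' @param gantry_deg Gantry angle in degrees, `[0, 360)`.
#' @param bank_a,bank_b Leaf positions (cm at isocenter) along the leaf-travel
#'   axis, one per pair; pair i is open on the interval
#'   `[bank_b[i], bank_a[i]]` (closed when equal).
#' @param collimator_deg Collimator angle in degrees (default 0).
#' @return A `control_point` object.
#' @export
control_point <- function(index, mu_cumulative, gantry_deg, bank_a, bank_b,
                          collimator_deg = 0) {
  bank_a <- as.numeric(bank_a); bank_b <- as.numeric(bank_b)
  if (length(bank_a) != length(bank_b))
    stop("bank_a and bank_b must have the same number of leaf pairs (",
         length(bank_a), " vs ", length(bank_b), ")")
  structure(list(
    index = as.integer(index),
    mu_cumulative = as.numeric(mu_cumulative),
    gantry_deg = as.numeric(gantry_deg) %% 360,
    bank_a = bank_a,
    bank_b = bank_b,
    collimator_deg = as.numeric(collimator_deg)
  ), class = "control_point")
}

#' One beam's ordered delivery record
#'
#' @param beam_id Beam label (unique within a plan).
#' @param geometry A `machine_geometry`.
#' @param control_points List of [control_point()]s in delivery order.
#' @return A `beam_delivery` object.
#' @export
beam_delivery <- function(beam_id, geometry, control_points) {
  stopifnot(inherits(geometry, "machine_geometry"), is.list(control_points))
  for (cp in control_points) {
    if (!inherits(cp, "control_point")) stop("control_points must be control_point objects")
    if (length(cp$bank_a) != geometry$n_pairs)
      stop("control point ", cp$index, " carries ", length(cp$bank_a),
           " leaf positions but geometry has ", geometry$n_pairs, " pairs")
  }
  structure(list(beam_id = as.character(beam_id), geometry = geometry,
                 control_points = control_points),
            class = "beam_delivery")
}

#' A full plan's delivery record
#'
#' @param plan_id Plan label.
#' @param prescription_dose Prescription dose in Gy (e.g. 60 Gy in 30
#'   fractions for the thoracic plans this tool targets).
#' @param beams List of [beam_delivery()]s.
#' @return A `plan_delivery` object.
#' @export
plan_delivery <- function(plan_id, prescription_dose, beams) {
  stopifnot(is.list(beams))
  for (b in beams) if (!inherits(b, "beam_delivery")) stop("beams must be beam_delivery objects")
  structure(list(plan_id = as.character(plan_id),
                 prescription_dose = as.numeric(prescription_dose),
                 beams = beams),
            class = "plan_delivery")
}

#' @export
print.plan_delivery <- function(x, ...) {
  cat("plan_delivery '", x$plan_id, "': ", length(x$beams), " beam(s), ",
      "prescription ", x$prescription_dose, " Gy\n", sep = "")
  for (b in x$beams)
    cat("  beam '", b$beam_id, "': ", length(b$control_points),
        " control points, gantry ",
        if (length(b$control_points)) b$control_points[[1]]$gantry_deg else NA,
        " deg\n", sep = "")
  invisible(x)
}

#' Validate a plan delivery against all record invariants
#'
#' Checks every type invariant (positive prescription, unique beam ids, at
#' least two control points per beam, non-decreasing cumulative MU, leaf
#' interval ordering `bank_a >= bank_b`, non-negative MU) and reports rather
#' than throws.
#'
#' @param plan A `plan_delivery`.
#' @return A data frame with columns `beam`, `control_point`, `rule`,
#'   `message`; zero rows iff the plan is valid.
#' @export
validate_delivery <- function(plan) {
  v <- list()
  add <- function(beam, cp, rule, msg)
    v[[length(v) + 1L]] <<- data.frame(beam = beam, control_point = cp,
                                       rule = rule, message = msg,
                                       stringsAsFactors = FALSE)
  if (!is.finite(plan$prescription_dose) || plan$prescription_dose <= 0)
    add(NA_character_, NA_integer_, "prescription_positive",
        "prescription_dose must be > 0")
  ids <- vapply(plan$beams, function(b) b$beam_id, character(1))
  for (dup in unique(ids[duplicated(ids)]))
    add(dup, NA_integer_, "beam_id_unique",
        sprintf("beam_id '%s' appears more than once", dup))
  for (b in plan$beams) {
    cps <- b$control_points
    if (length(cps) < 2L)
      add(b$beam_id, NA_integer_, "min_control_points",
          "beam needs at least 2 control points")
    prev_mu <- -Inf
    for (k in seq_along(cps)) {
      cp <- cps[[k]]
      if (cp$mu_cumulative < 0)
        add(b$beam_id, k, "mu_nonnegative",
            sprintf("control point %d has negative cumulative MU", k))
      if (cp$mu_cumulative < prev_mu)
        add(b$beam_id, k, "mu_nondecreasing",
            sprintf("cumulative MU decreases at control point %d (%g < %g)",
                    k, cp$mu_cumulative, prev_mu))
      prev_mu <- max(prev_mu, cp$mu_cumulative)
      bad <- which(cp$bank_a < cp$bank_b)
      if (length(bad))
        add(b$beam_id, k, "leaf_interval",
            sprintf("control point %d: bank_a < bank_b for pair(s) %s",
                    k, paste(bad, collapse = ",")))
    }
  }
  if (!length(v))
    return(data.frame(beam = character(), control_point = integer(),
                      rule = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}

stop_if_invalid <- function(plan) {
  viol <- validate_delivery(plan)
  if (nrow(viol))
    stop("invalid plan delivery: ", paste(viol$message, collapse = "; "))
  invisible(plan)
}

#' Split a beam into MU-weighted delivery segments
#'
#' Step-and-shoot delivery: each consecutive control-point pair is one static
#' segment whose intensity weight is the monitor-unit increment
#' `delta_mu = mu[j] - mu[j-1]`. The segment carries the aperture and gantry
#' angle of its starting control point (the gantry is static while the beam
#' is on).
#'
#' @param beam A valid `beam_delivery`.
#' @return A list of segments, each `list(cp, delta_mu)` where `cp` is the
#'   starting [control_point()].
#' @export
segment_mu <- function(beam) {
  cps <- beam$control_points
  if (length(cps) < 2L)
    stop("beam '", beam$beam_id, "' has fewer than 2 control points; no segment definable")
  mu <- vapply(cps, function(cp) cp$mu_cumulative, numeric(1))
  if (any(diff(mu) < 0))
    stop("cumulative MU decreases within beam '", beam$beam_id, "'")
  lapply(seq_len(length(cps) - 1L), function(j)
    list(cp = cps[[j]], delta_mu = mu[j + 1L] - mu[j]))
}
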