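#' Read a plan delivery from the text interchange dialects
#'
#' Two documented dialects carry delivery records extracted from accelerator
#' log files. The CSV dialect holds one plan per file: a `plan,<id>,<Gy>`
#' header row, then for each beam a `beam,<id>` row followed by one row per
#' control point,
#' `cp,<index>,<mu_cumulative>,<gantry_deg>,<collimator_deg>,<a_1..a_n>,<b_1..b_n>`
#' with positions in cm. The JSON dialect mirrors the delivery types
#' field-for-field (including the machine geometry). Binary vendor trajectory
#' logs are out of scope; an upstream extractor is expected to emit one of
#' these dialects.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"json"`; inferred from the file extension when
#'   omitted.
#' @param geometry `machine_geometry` used for CSV files (which do not encode
#'   it); ignored for JSON. Default [hd120_geometry()].
#' @return A validated [plan_delivery()].
#' @export
read_delivery <- function(path, dialect = c("auto", "csv", "json"),
                          geometry = hd120_geometry()) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("delivery file not found: ", path)
  plan <- if (dialect == "csv") read_delivery_csv(path, geometry)
          else read_delivery_json(path)
  stop_if_invalid(plan)
  plan
}

read_delivery_csv <- function(path, geometry) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1], "plan,"))
    stop("parse error at line 1: expected 'plan,<id>,<prescription_Gy>' header")
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(hdr) != 3L)
    stop("parse error at line 1: plan header needs 3 fields, got ", length(hdr))
  plan_id <- hdr[2]
  rx <- suppressWarnings(as.numeric(hdr[3]))
  if (is.na(rx)) stop("parse error at line 1: prescription is not numeric")
  n <- geometry$n_pairs
  beams <- list(); cur_id <- NULL; cur_cps <- list()
  flush_beam <- function() {
    if (!is.null(cur_id))
      beams[[length(beams) + 1L]] <<- beam_delivery(cur_id, geometry, cur_cps)
  }
  for (i in seq_along(lines)[-1]) {
    f <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (f[1] == "beam") {
      if (length(f) != 2L) stop("parse error at line ", i, ": beam row needs 2 fields")
      flush_beam(); cur_id <- f[2]; cur_cps <- list()
    } else if (f[1] == "cp") {
      if (is.null(cur_id)) stop("parse error at line ", i, ": 'cp' row before any 'beam' row")
      want <- 5L + 2L * n
      if (length(f) != want)
        stop("parse error at line ", i, ": control point row has ",
             length(f) - 5L, " leaf positions, expected ", 2L * n,
             " (", n, " per bank)")
      num <- suppressWarnings(as.numeric(f[-1]))
      if (anyNA(num)) stop("parse error at line ", i, ": non-numeric field")
      cur_cps[[length(cur_cps) + 1L]] <- control_point(
        index = num[1], mu_cumulative = num[2], gantry_deg = num[3],
        collimator_deg = num[4],
        bank_a = num[4 + seq_len(n)], bank_b = num[4 + n + seq_len(n)])
    } else stop("parse error at line ", i, ": unknown row type '", f[1], "'")
  }
  flush_beam()
  plan_delivery(plan_id, rx, beams)
}

read_delivery_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  for (f in c("plan_id", "prescription_dose", "beams"))
    if (is.null(j[[f]])) stop("parse error: missing field '", f, "'")
  beams <- lapply(j$beams, function(b) {
    g <- b$geometry
    geom <- machine_geometry(sad = g$sad, leaf_pair_widths = g$leaf_pair_widths,
                             jaw_limits = g$jaw_limits)
    cps <- lapply(b$control_points, function(cp)
      control_point(cp$index, cp$mu_cumulative, cp$gantry_deg,
                    cp$bank_a, cp$bank_b,
                    collimator_deg = if (is.null(cp$collimator_deg)) 0 else cp$collimator_deg))
    beam_delivery(b$beam_id, geom, cps)
  })
  plan_delivery(j$plan_id, j$prescription_dose, beams)
}

#' Write a plan delivery in a text interchange dialect
#'
#' Inverse of [read_delivery()]; `read_delivery(write_delivery(p))` is the
#' identity for valid plans (positions serialized with 4 decimals in CSV).
#'
#' @param plan A [plan_delivery()].
#' @param path Output path.
#' @param dialect `"csv"` or `"json"` (inferred from extension by default).
#' @return `path`, invisibly.
#' @export
write_delivery <- function(plan, path, dialect = c("auto", "csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (dialect == "csv") {
    lines <- c(sprintf("plan,%s,%.17g", plan$plan_id, plan$prescription_dose))
    for (b in plan$beams) {
      lines <- c(lines, sprintf("beam,%s", b$beam_id))
      for (cp in b$control_points)
        lines <- c(lines, paste(c("cp", cp$index,
                                  sprintf("%.17g", cp$mu_cumulative),
                                  sprintf("%.17g", cp$gantry_deg),
                                  sprintf("%.17g", cp$collimator_deg),
                                  sprintf("%.4f", cp$bank_a),
                                  sprintf("%.4f", cp$bank_b)),
                                collapse = ","))
    }
    writeLines(lines, path)
  } else {
    j <- list(plan_id = plan$plan_id, prescription_dose = plan$prescription_dose,
              beams = lapply(plan$beams, function(b) list(
                beam_id = b$beam_id,
                geometry = list(sad = b$geometry$sad,
                                leaf_pair_widths = b$geometry$leaf_pair_widths,
                                jaw_limits = b$geometry$jaw_limits),
                control_points = lapply(b$control_points, function(cp)
                  list(index = cp$index, mu_cumulative = cp$mu_cumulative,
                       gantry_deg = cp$gantry_deg, bank_a = cp$bank_a,
                       bank_b = cp$bank_b, collimator_deg = cp$collimator_deg)))))
    jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
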