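#' Configuration for a pipeline run
#'
#' Collects every path and tuning knob the preprocessing/QA chain needs.
#' Referenced input paths must exist when the config is built.
#'
#' @param log Delivery record (CSV/JSON dialect, see [read_delivery()]).
#' @param ct CT NIfTI path.
#' @param masks Directory of ROI masks (see [read_mask_set()]).
#' @param reference Reference dose NIfTI path.
#' @param out_dir Output directory for intermediates, reports, manifest.
#' @param pred Optional precomputed predicted-dose NIfTI (QA without a
#'   model).
#' @param checkpoint Optional model checkpoint ([save_wingsnet()]).
#' @param n Cubic sample dimension (default 128; desk scale 24-32).
#' @param fluence_pitch Fluence pixel spacing, cm.
#' @param sad Source-axis distance, cm.
#' @param deposit_mode,supersample Ray-deposit options
#'   (see [project_fluence_map()]).
#' @param dice_levels Isodose Dice levels (% of prescription).
#' @param seed Integer seed governing any randomness downstream.
#' @param verbose Log stage timings to stderr.
#' @return A `run_config` list.
#' @export
run_config <- function(log, ct, masks, reference, out_dir, pred = NULL,
                       checkpoint = NULL, n = 128L, fluence_pitch = 0.25,
                       sad = 100, deposit_mode = "point", supersample = 1L,
                       dice_levels = seq(5, 100, by = 5), seed = 1L,
                       verbose = FALSE) {
  for (p in c(log, ct, masks, reference, pred, checkpoint))
    if (!file.exists(p)) stop("configured path does not exist: ", p)
  structure(list(log = log, ct = ct, masks = masks, reference = reference,
                 out_dir = out_dir, pred = pred, checkpoint = checkpoint,
                 n = as.integer(n), fluence_pitch = fluence_pitch, sad = sad,
                 deposit_mode = deposit_mode, supersample = as.integer(supersample),
                 dice_levels = dice_levels, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

stage <- function(config, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(force(expr), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  if (config$verbose)
    message(sprintf("[%s] %.2fs", name, proc.time()[["elapsed"]] - t0))
  out
}

write_manifest <- function(config, out_dir) {
  cfgjson <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(config), cfgjson, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest <- list(config = unclass(config),
                   config_md5 = unname(tools::md5sum(cfgjson)),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("logdoseqa")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Run the log-to-sample preprocessing chain
#'
#' Read the delivery record, build MU-weighted fluence maps, project them
#' through the CT grid (3D-DDA + inverse square), and assemble the
#' co-registered cubic model sample. Intermediate volumes and a
#' reproducibility manifest (config, config hash, seed, versions) land in
#' `out_dir`; any stage failure aborts naming the stage.
#'
#' @param config A [run_config()].
#' @return A [model_sample()].
#' @export
run_preprocess <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  plan <- stage(config, "read_log", read_delivery(config$log))
  ct <- stage(config, "read_ct", read_nifti(config$ct, kind = "ct_hu"))
  masks <- stage(config, "read_masks", read_mask_set(config$masks))
  ref <- stage(config, "read_reference",
               read_nifti(config$reference, kind = "dose_gy"))
  iso <- plan_isocenter(masks)
  maps <- stage(config, "fluence",
                plan_fluence(plan, fluence_grid(pixel_spacing = config$fluence_pitch)))
  proj <- stage(config, "project",
                accumulate_plan(maps, ct$grid, sad = config$sad,
                                isocenter = iso,
                                deposit_mode = config$deposit_mode,
                                supersample = config$supersample))
  sample <- stage(config, "assemble",
                  assemble_sample(ct, masks, proj, ref,
                                  plan$prescription_dose, n = config$n))
  stage(config, "write_intermediates", {
    write_nifti(proj, file.path(config$out_dir, "projected.nii.gz"))
    write_nifti(sample$projected,
                file.path(config$out_dir, "projected_sample.nii.gz"))
  })
  write_manifest(config, config$out_dir)
  sample
}

#' Run a full patient-specific QA comparison
#'
#' Preprocesses the inputs, obtains the predicted dose (from a model
#' checkpoint, or a precomputed dose file resampled onto the sample grid),
#' and evaluates it against the reference dose: per-ROI MAE/RMSE, DVH index
#' table, isodose Dice curve, Bland-Altman, profiles. The report bundle
#' (JSON + CSV) and manifest are written to `out_dir`.
#'
#' @param config A [run_config()] with `checkpoint` or `pred` set.
#' @return A `comparison_report`.
#' @export
run_qa <- function(config) {
  if (is.null(config$checkpoint) && is.null(config$pred))
    stop("run_qa needs a model checkpoint or a precomputed predicted dose")
  sample <- run_preprocess(config)
  pred <- if (!is.null(config$checkpoint)) {
    model <- stage(config, "load_model", load_wingsnet(config$checkpoint))
    stage(config, "predict", predict_dose(model, sample))
  } else {
    stage(config, "load_pred",
          resample(read_nifti(config$pred, kind = "dose_gy"),
                   sample$reference_dose$grid))
  }
  report <- stage(config, "evaluate",
                  comparison_report(pred, sample$reference_dose, sample$masks,
                                    sample$prescription_dose,
                                    dice_levels = config$dice_levels))
  write_report(report, file.path(config$out_dir, "report.json"))
  write_nifti(pred, file.path(config$out_dir, "predicted_dose.nii.gz"))
  report
}

#' Write a complete synthetic phantom case to disk
#'
#' Generates the phantom CT, masks, step-and-shoot plan and pseudo-reference
#' dose and writes them in the standard interchange formats (NIfTI volumes,
#' per-ROI mask files, CSV delivery record), ready for [run_config()].
#'
#' @param dir Output directory.
#' @param spec A [phantom_spec()].
#' @param plan A [plan_spec()].
#' @param sigma_cm Reference-dose smoothing SD, cm.
#' @return Named list of the written paths, invisibly.
#' @export
save_phantom_case <- function(dir, spec = phantom_spec(), plan = plan_spec(),
                              sigma_cm = 0.8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- make_phantom(spec)
  pd <- make_plan(ph, plan)
  ref <- make_reference_dose(pd, ph, sigma_cm = sigma_cm)
  paths <- list(ct = file.path(dir, "ct.nii.gz"),
                masks = file.path(dir, "masks"),
                log = file.path(dir, "plan.csv"),
                reference = file.path(dir, "reference_dose.nii.gz"))
  write_nifti(ph$ct, paths$ct)
  write_mask_set(ph$masks, paths$masks)
  write_delivery(pd, paths$log)
  write_nifti(ref, paths$reference)
  invisible(paths)
}
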