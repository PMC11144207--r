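#' Run the end-to-end functional dosimetry pipeline
#'
#' Orchestrates phantom generation, demons registration, Jacobian
#' ventilation mapping, fLung segmentation, functional dose-volume
#' extraction, cohort simulation, model selection and evaluation from a
#' single YAML configuration, writing every intermediate artifact and a
#' manifest of MD5 file hashes. All stochastic stages take explicit seeds
#' from the configuration, so rerunning a config reproduces identical
#' hashes.
#'
#' @param config path to a YAML file or an equivalent named list. See
#'   \code{system.file("extdata", "pipeline-smoke.yaml", package =
#'   "ventidose")} for the schema; unknown top-level keys are rejected
#'   before any stage runs.
#' @param out_dir output directory (created if absent); overrides the
#'   config's \code{output.dir} when given.
#' @return invisibly, the manifest list (also written as
#'   \code{manifest.json}): per-artifact MD5 hashes plus summary
#'   statistics (fLung fraction, AUC, selected covariates).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- validate_pipeline_config(cfg)
  if (!is.null(out_dir)) cfg$output$dir <- out_dir
  dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
  odir <- cfg$output$dir
  art <- function(name) file.path(odir, name)

  ph_spec <- phantom_spec(
    grid_shape = cfg$phantom$grid_shape, spacing = cfg$phantom$spacing,
    motion_amplitude = cfg$phantom$motion_amplitude,
    motion_decay = cfg$phantom$motion_decay,
    noise_sd = cfg$phantom$noise_sd, seed = cfg$phantom$seed)
  ph <- generate_phantom_pair(ph_spec)
  write_volume(ph$exhale, art("exhale.nii.gz"))
  write_volume(ph$inhale, art("inhale.nii.gz"))
  write_volume(ph$truth, art("dvf_truth.nii.gz"))
  write_volume(ph$lung, art("lung.nii.gz"))

  dvf <- if (isTRUE(cfg$registration$use_truth_field)) {
    ph$truth
  } else {
    register_demons(ph$inhale, ph$exhale,
                    levels = cfg$registration$levels,
                    iterations_per_level = cfg$registration$iterations,
                    smoothing_sigma_mm = cfg$registration$smoothing_sigma_mm)
  }
  write_volume(dvf, art("dvf.nii.gz"))

  vent <- jacobian_determinant(dvf)
  flung <- segment_high_function(vent, ph$lung,
                                 threshold = cfg$ventilation$threshold)
  write_volume(image_grid(vent$jacobian, vent$spacing, vent$origin),
               art("jacobian.nii.gz"))
  write_volume(flung, art("flung.nii.gz"))

  extent <- (ph_spec$grid_shape - 1) * ph_spec$spacing
  target <- if (is.null(cfg$dose$target_center)) extent * c(0.35, 0.5, 0.45)
            else as.numeric(cfg$dose$target_center)
  dose <- generate_dose_grid(ph_spec, target,
                             prescription = cfg$dose$prescription,
                             falloff_mm = cfg$dose$falloff_mm)
  write_volume(dose, art("dose.nii.gz"))
  fv <- if (sum(flung$inside) > 0) extract_fv_vector(dose, flung)
        else stats::setNames(rep(NA_real_, 12), fv_names())
  utils::write.csv(as.data.frame(as.list(unclass(fv))), art("fv.csv"),
                   row.names = FALSE)

  co_spec <- cohort_sim_spec(n_patients = cfg$cohort$n_patients,
                             seed = cfg$cohort$seed)
  cohort <- simulate_cohort(co_spec)
  write_cohort_csv(cohort, art("cohort.csv"))

  sel <- switch(cfg$selection$method,
    stepwise = stepwise_select(cohort),
    best_subset = best_subset_select(cohort),
    lasso = lasso_select(cohort, seed = cfg$selection$seed),
    forest = ensemble_importance(cohort, seed = cfg$selection$seed))
  model <- if (!is.null(sel$final_model)) sel$final_model
           else fit_logistic(cohort, utils::head(sel$selected, 3))
  model_json <- list(method = sel$method, intercept = model$intercept,
                     coefficients = as.list(model$coefficients),
                     scale = model$covariate_scale,
                     selected = as.list(sel$selected))
  jsonlite::write_json(model_json, art("model.json"), auto_unbox = TRUE,
                       digits = NA)

  scores <- predict_risk(model, as.data.frame(cohort))$probability
  roc <- roc_auc(scores, cohort$rp_grade2plus)
  cal <- calibrate_bootstrap(cohort, names(model$coefficients),
                             n_boot = cfg$evaluation$n_boot,
                             seed = cfg$evaluation$seed)
  rng <- lapply(names(model$coefficients), function(nm)
    range(as.data.frame(cohort)[[nm]]))
  names(rng) <- names(model$coefficients)
  nomo <- if (length(model$coefficients) &&
              all(vapply(rng, function(r) diff(r) > 0, logical(1)))) {
    nomogram_points(model, rng)
  } else NULL
  report <- list(
    auc = roc$auc, ci_low = roc$ci_low, ci_high = roc$ci_high,
    calibration_slope = cal$slope, calibration_intercept = cal$intercept,
    nomogram_top_variable = if (is.null(nomo)) NA else nomo$top_variable)
  jsonlite::write_json(report, art("report.json"), auto_unbox = TRUE,
                       digits = NA)

  files <- c("exhale.nii.gz", "inhale.nii.gz", "dvf_truth.nii.gz",
             "lung.nii.gz", "dvf.nii.gz", "jacobian.nii.gz", "flung.nii.gz",
             "dose.nii.gz", "fv.csv", "cohort.csv", "model.json",
             "report.json")
  manifest <- list(
    hashes = as.list(tools::md5sum(file.path(odir, files))),
    stats = list(
      lung_voxels = sum(ph$lung$inside),
      flung_voxels = sum(flung$inside),
      flung_fraction = sum(flung$inside) / max(1, sum(ph$lung$inside)),
      auc = roc$auc, selected = as.list(sel$selected)))
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

# Fill defaults and fail fast on malformed configuration.
validate_pipeline_config <- function(cfg) {
  if (!is.list(cfg)) stop("pipeline config must be a list or YAML file")
  known <- c("phantom", "registration", "ventilation", "dose", "cohort",
             "selection", "evaluation", "output")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config section(s): ", paste(extra, collapse = ", "))
  dflt <- list(
    phantom = list(grid_shape = c(32, 32, 32), spacing = c(4, 4, 4),
                   motion_amplitude = 10, motion_decay = 1.5,
                   noise_sd = 0, seed = 20240601),
    registration = list(use_truth_field = FALSE, levels = 3,
                        iterations = 50, smoothing_sigma_mm = 2),
    ventilation = list(threshold = 1.2),
    dose = list(target_center = NULL, prescription = 60, falloff_mm = 30),
    cohort = list(n_patients = 41, seed = 20240601),
    selection = list(method = "stepwise", seed = 20240601),
    evaluation = list(n_boot = 200, seed = 20240601),
    output = list(dir = "ventidose-output"))
  for (sec in names(dflt)) {
    user <- if (is.null(cfg[[sec]])) list() else cfg[[sec]]
    bad <- setdiff(names(user), names(dflt[[sec]]))
    if (length(bad))
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "))
    dflt[[sec]][names(user)] <- user
    cfg[[sec]] <- dflt[[sec]]
  }
  if (!cfg$selection$method %in% c("stepwise", "best_subset", "lasso", "forest"))
    stop("selection.method must be stepwise, best_subset, lasso or forest")
  if (!is.numeric(cfg$ventilation$threshold))
    stop("ventilation.threshold must be numeric")
  cfg
}
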