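# End-to-end experiment orchestration: simulate -> preprocess -> derive
# patterns -> extract both feature sets -> ensemble -> metrics -> explain.

#' Experiment configuration
#'
#' Validated configuration for [run_experiment()]. Defaults reproduce the
#' study design: a 206-subject four-class cohort, 10 mm FWHM smoothing with
#' global-mean scaling, four derived patterns (three disease-related plus a
#' pooled dementia-vs-control stand-in for the healthy resting-state
#' pattern), both feature sets classified with the same split scheme, and the
#' reduced-dataset evaluation excluding pattern-derivation subjects from
#' testing.
#'
#' @param cohort A [cohort_spec()].
#' @param topographies Named list of [class_topography()].
#' @param fwhm_mm Smoothing kernel FWHM in mm.
#' @param pattern A [pattern_config()].
#' @param n_derivation Named counts of pattern-derivation subjects per class
#'   (flagged as leakage).
#' @param n_iterations,train_fraction Resampling scheme parameters.
#' @param classifier A [classifier_config()].
#' @param explain List: `enabled`, `n_runs`, `n_samples`, `dependent`,
#'   `subjects_per_run`.
#' @param seed Master seed for the split schemes (required; every random
#'   stage of the experiment derives from this and the cohort seed).
#' @param out_dir Optional output directory for per-stage files.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_spec(),
                              topographies = default_topographies(),
                              fwhm_mm = 10,
                              pattern = pattern_config(),
                              n_derivation = c(AD = 20, DLB = 20, FTD = 10,
                                               NC = 29),
                              n_iterations = 500,
                              train_fraction = 0.7,
                              classifier = classifier_config(),
                              explain = list(enabled = FALSE, n_runs = 5,
                                             n_samples = 100,
                                             dependent = FALSE,
                                             subjects_per_run = 20),
                              seed = NULL,
                              out_dir = NULL) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("config validation: `seed` must be a single integer", call. = FALSE)
  stopifnot(inherits(cohort, "cohort_spec"), inherits(pattern, "pattern_config"),
            inherits(classifier, "classifier_config"))
  if (fwhm_mm < 0) stop("config validation: `fwhm_mm` must be >= 0", call. = FALSE)
  if (!all(names(n_derivation) %in% CLASS_ORDER))
    stop("config validation: `n_derivation` names must be classes", call. = FALSE)
  structure(list(cohort = cohort, topographies = topographies,
                 fwhm_mm = fwhm_mm, pattern = pattern,
                 n_derivation = n_derivation,
                 n_iterations = n_iterations, train_fraction = train_fraction,
                 classifier = classifier, explain = explain,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Scalar fields of [experiment_config()] can be overridden from a YAML file
#' (`seed`, `fwhm_mm`, `n_iterations`, `train_fraction`, cohort counts and
#' noise levels, explanation budget).
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort %||% list()
  if (!is.null(cohort_args$n_per_class))
    cohort_args$n_per_class <- unlist(cohort_args$n_per_class)
  cohort <- do.call(cohort_spec, cohort_args)
  experiment_config(cohort = cohort,
                    fwhm_mm = y$fwhm_mm %||% 10,
                    n_iterations = y$n_iterations %||% 500,
                    train_fraction = y$train_fraction %||% 0.7,
                    explain = utils::modifyList(
                      list(enabled = FALSE, n_runs = 5, n_samples = 100,
                           dependent = FALSE, subjects_per_run = 20),
                      y$explain %||% list()),
                    seed = y$seed,
                    out_dir = y$out_dir)
}

#' Run the full classification experiment
#'
#' Executes every stage in order: cohort simulation, preprocessing
#' (smooth then globally scale), SSM/PCA pattern derivation from the flagged
#' derivation subjects, pattern-expression and ROI feature extraction, the
#' repeated stratified SVM ensemble on both feature sets (sharing one split
#' scheme seed so the comparison is split-for-split), metric reports --
#' including the reduced-dataset ROI evaluation in which pattern-derivation
#' subjects are excluded from testing -- and optionally the Shapley
#' explanation of the ROI model. Returns all stage outputs plus a manifest
#' (seeds, sizes, and checksums of any files written).
#'
#' @param config An [experiment_config()].
#' @return List with `cohort`, `patterns`, `features`, `ensembles`,
#'   `reports`, `explain`, `manifest`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- Sys.time()

  # -- simulate ---------------------------------------------------------
  cohort <- simulate_cohort(config$cohort, config$topographies)
  cohort$subjects <- flag_derivation_subjects(cohort$subjects,
                                              config$n_derivation)

  # -- preprocess -------------------------------------------------------
  volumes <- lapply(cohort$volumes, preprocess_volume, fwhm_mm = config$fwhm_mm)

  # -- derive patterns --------------------------------------------------
  deriv_ids <- split(cohort$subjects$id[cohort$subjects$leakage],
                     cohort$subjects$class[cohort$subjects$leakage])
  nc_vols <- volumes[deriv_ids$NC]
  patterns <- list(
    derive_pattern(volumes[deriv_ids$AD], nc_vols, config$pattern, "ADRP"),
    derive_pattern(volumes[deriv_ids$DLB], nc_vols, config$pattern, "DLBRP"),
    derive_pattern(volumes[deriv_ids$FTD], nc_vols, config$pattern, "FTDRP"),
    derive_pattern(volumes[c(deriv_ids$AD, deriv_ids$DLB, deriv_ids$FTD)],
                   nc_vols, config$pattern, "DMN"))

  # -- features ---------------------------------------------------------
  pattern_fm <- pattern_feature_matrix(volumes, patterns, cohort$subjects)
  roi_fm <- roi_feature_matrix(volumes, cohort$atlas, cohort$subjects)

  # -- ensembles --------------------------------------------------------
  leakage <- cohort$subjects$id[cohort$subjects$leakage]
  scheme_leak <- split_scheme(config$n_iterations, config$train_fraction,
                              leakage_ids = leakage,
                              master_seed = config$seed)
  scheme_full <- split_scheme(config$n_iterations, config$train_fraction,
                              leakage_ids = character(),
                              master_seed = config$seed)
  ens <- list(
    pattern = run_ensemble(pattern_fm, scheme_leak, config$classifier),
    roi_full = run_ensemble(strip_leakage(roi_fm), scheme_full,
                            config$classifier),
    roi_reduced = run_ensemble(roi_fm, scheme_leak, config$classifier))
  reports <- list(
    pattern = evaluate_ensemble(ens$pattern, pattern_fm),
    roi_full = evaluate_ensemble(ens$roi_full, roi_fm),
    roi_reduced = evaluate_ensemble(ens$roi_reduced, roi_fm))

  # -- explain ----------------------------------------------------------
  explain <- NULL
  if (isTRUE(config$explain$enabled)) {
    shap <- ensemble_shap_importance(
      roi_fm, scheme_full, config$classifier,
      n_runs = config$explain$n_runs,
      n_samples = config$explain$n_samples,
      seed = config$seed + 1L,
      dependent = isTRUE(config$explain$dependent),
      subjects_per_run = config$explain$subjects_per_run)
    explain <- list(shapley = shap,
                    importance = class_importance_map(shap, cohort$atlas))
  }

  # -- outputs + manifest ----------------------------------------------
  files <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_experiment_outputs(config$out_dir, cohort, pattern_fm,
                                      roi_fm, ens, reports, explain)
  }
  manifest <- list(
    seed = config$seed, cohort_seed = config$cohort$seed,
    n_subjects = nrow(cohort$subjects),
    n_leakage = sum(cohort$subjects$leakage),
    n_iterations = config$n_iterations,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    checksums = if (length(files)) tools::md5sum(files) else character())

  list(cohort = cohort, patterns = patterns,
       features = list(pattern = pattern_fm, roi = roi_fm),
       ensembles = ens, reports = reports, explain = explain,
       manifest = manifest)
}

strip_leakage <- function(fm) {
  feature_matrix(fm$values, fm$class_labels, FALSE)
}

write_experiment_outputs <- function(out_dir, cohort, pattern_fm, roi_fm,
                                     ens, reports, explain) {
  p <- function(...) file.path(out_dir, ...)
  write_subject_table(cohort$subjects, p("subjects.csv"))
  write_feature_matrix(pattern_fm, p("features_pattern.csv"))
  write_feature_matrix(roi_fm, p("features_roi.csv"))
  files <- c(p("subjects.csv"), p("features_pattern.csv"), p("features_roi.csv"))
  for (nm in names(ens)) {
    f <- p(sprintf("predictions_%s.csv", nm))
    utils::write.csv(ens[[nm]]$per_iteration, f, row.names = FALSE)
    files <- c(files, f)
  }
  summary <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    list(model = nm, overall_accuracy = r$overall_accuracy, n = r$n,
         per_class = r$per_class)
  })
  jf <- p("metrics.json")
  jsonlite::write_json(summary, jf, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  files <- c(files, jf)
  if (!is.null(explain)) {
    f <- p("shapley.csv")
    utils::write.csv(explain$shapley, f, row.names = FALSE)
    imp <- explain$importance$values
    f2 <- p("importance.csv")
    utils::write.csv(data.frame(feature = rownames(imp), imp,
                                check.names = FALSE), f2, row.names = FALSE)
    files <- c(files, f, f2)
  }
  files
}
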