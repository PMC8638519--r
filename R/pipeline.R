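#' Pipeline configuration
#'
#' Assembles the settings of a full analysis run. Exactly one input source is
#' used: either a simulation config (`simulation`) or file paths
#' (`spectra_file`, `cohort_file`, plus a water spectrum inside the spectral
#' table or none). A YAML (or JSON) file with the same field names can be
#' passed to [run_pipeline()] directly.
#'
#' The global `seed` fans out deterministically to the stages:
#' `seed` drives the simulation and `seed + 1` the cross-validation fold
#' assignments, so either stage can be rerun standalone and reproduce the
#' pipeline's results.
#'
#' @param simulation A [synthetic_config()], or `NULL` when reading files.
#' @param spectra_file,cohort_file Input paths (ignored when simulating).
#' @param preprocess A [preprocess_params()].
#' @param covariates Matching covariates.
#' @param d0,p0 Significance thresholds for [significant_regions()].
#' @param folds,repeats,cost Cross-validation settings.
#' @param seed Global integer seed.
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as CSV plus a `manifest.yaml`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = synthetic_config(),
                            spectra_file = NULL, cohort_file = NULL,
                            preprocess = preprocess_params(),
                            covariates = c("age", "bmi"),
                            d0 = 1, p0 = NULL,
                            folds = 10, repeats = 10, cost = 1,
                            seed = 1, out_dir = NULL) {
  if (is.null(simulation) && (is.null(spectra_file) || is.null(cohort_file))) {
    abort("provide either `simulation` or both `spectra_file` and `cohort_file`")
  }
  if (!is.null(simulation) && !is.null(spectra_file)) {
    abort("provide exactly one input source: simulation or files, not both")
  }
  structure(list(simulation = simulation, spectra_file = spectra_file,
                 cohort_file = cohort_file, preprocess = preprocess,
                 covariates = covariates, d0 = d0, p0 = p0,
                 folds = folds, repeats = repeats, cost = cost,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# Build a pipeline_config from a YAML/JSON file (flat field names).
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation)) {
    args <- y$simulation
    for (f in c("bands", "effect_bands")) {
      if (!is.null(args[[f]])) args[[f]] <- as_tibble(args[[f]])
    }
    do.call(synthetic_config, args)
  } else if (is.null(y$spectra_file)) {
    synthetic_config()
  }
  pp <- if (!is.null(y$preprocess)) do.call(preprocess_params, y$preprocess)
        else preprocess_params()
  pipeline_config(
    simulation = sim,
    spectra_file = y$spectra_file, cohort_file = y$cohort_file,
    preprocess = pp,
    covariates = y$covariates %||% c("age", "bmi"),
    d0 = y$d0 %||% 1, p0 = y$p0,
    folds = y$folds %||% 10, repeats = y$repeats %||% 10,
    cost = y$cost %||% 1, seed = y$seed %||% 1, out_dir = y$out_dir)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes, in order: input acquisition (simulation or file reading),
#' spectral preprocessing, QC drift assessment, case-control matching,
#' differential-fingerprint statistics with significant-region detection,
#' stage-stratified comparison (when both strata are populated), and
#' repeated-CV linear-SVM classification. When `out_dir` is set, every result
#' table is written as CSV together with a run manifest.
#'
#' @param config A [pipeline_config()], or the path of a YAML/JSON file.
#' @return A list of class `pipeline_result` with elements `qc`, `match`,
#'   `fingerprint`, `regions`, `stage`, `cv`, `cv_summary`, `correction_log`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  if (!is.null(config$simulation)) {
    sim <- simulate_cohort(config$simulation, seed = config$seed)
    spectra <- sim$spectra
    cohort <- sim$cohort
  } else {
    spectra <- read_spectrum_table(config$spectra_file)
    cohort <- read_cohort(config$cohort_file)
  }

  prep <- preprocess_spectra(spectra, params = config$preprocess)
  qc <- if (sum(prep$role == "qc") >= 2) qc_drift(prep) else NULL

  cases_tbl <- filter(cohort, .data$group == "case")
  cand_tbl <- filter(cohort, .data$group == "reference")
  mres <- match_controls(cases_tbl, cand_tbl, covariates = config$covariates)

  subset_set <- function(ids) {
    out <- prep[prep$sample_id %in% ids, ]
    class(out) <- class(prep)
    out
  }
  case_sp <- subset_set(cases_tbl$subject_id)
  ref_sp <- subset_set(mres$pairs$control_id)

  fp <- differential_fingerprint(case_sp, ref_sp)
  regions <- significant_regions(fp, d0 = config$d0, p0 = config$p0)

  m_states <- cohort$m_status[match(case_sp$sample_id, cohort$subject_id)]
  stage <- if (sum(m_states == "M0") >= 2 && sum(m_states == "M1") >= 2) {
    stage_stratified(case_sp, ref_sp, cohort)
  } else {
    NULL
  }

  analysis_cohort <- bind_rows(cases_tbl, mres$controls)
  keep_sp <- subset_set(analysis_cohort$subject_id)
  fm <- build_feature_matrix(keep_sp, analysis_cohort)
  cv <- repeated_cv_svm(fm, k = config$folds, repeats = config$repeats,
                        cost = config$cost, seed = config$seed + 1L)

  manifest <- list(
    seed = config$seed,
    input = if (is.null(config$simulation)) "files" else "simulation",
    normalize = config$preprocess$normalize,
    flatness_window = config$preprocess$flatness_window,
    keep_windows = config$preprocess$keep_windows,
    covariates = config$covariates, d0 = config$d0, p0 = config$p0,
    folds = config$folds, repeats = config$repeats, cost = config$cost,
    n_cases = nrow(cases_tbl), n_candidates = nrow(cand_tbl),
    n_wavenumbers = length(wavenumbers(prep)),
    package_version = as.character(utils::packageVersion("imfp")),
    r_version = R.version.string
  )

  res <- structure(list(
    qc = qc, match = mres, fingerprint = fp, regions = regions,
    stage = stage, cv = cv,
    cv_summary = summarize_cv(cv, normalized = config$preprocess$normalize),
    correction_log = correction_log(prep), manifest = manifest
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_outputs(res, prep, config$out_dir)
  res
}

write_pipeline_outputs <- function(res, prep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spectrum_table(prep, file.path(dir, "preprocessed_spectra.csv"))
  readr::write_csv(res$match$pairs, file.path(dir, "match_pairs.csv"))
  balance <- bind_rows(mutate(res$match$balance_before, when = "before"),
                       mutate(res$match$balance_after, when = "after"))
  readr::write_csv(balance, file.path(dir, "balance.csv"))
  readr::write_csv(as_tibble(res$fingerprint), file.path(dir, "fingerprint.csv"))
  readr::write_csv(res$regions, file.path(dir, "significant_regions.csv"))
  if (!is.null(res$stage)) {
    readr::write_csv(as_tibble(res$stage$fp_m0), file.path(dir, "fingerprint_m0.csv"))
    readr::write_csv(as_tibble(res$stage$fp_m1), file.path(dir, "fingerprint_m1.csv"))
  }
  readr::write_csv(res$cv$per_split, file.path(dir, "cv_auc.csv"))
  readr::write_csv(res$cv$mean_roc, file.path(dir, "cv_mean_roc.csv"))
  if (!is.null(res$correction_log)) {
    readr::write_csv(res$correction_log, file.path(dir, "water_correction.csv"))
  }
  yaml::write_yaml(res$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Human-readable pipeline summary
#'
#' @param res A [run_pipeline()] result.
#' @return A character vector of report lines (also used by the print
#'   method).
#' @export
pipeline_report <- function(res) {
  stopifnot(inherits(res, "pipeline_result"))
  lines <- c(
    "== infrared fingerprint pipeline report ==",
    sprintf("seed: %d | input: %s | normalization: %s",
            res$manifest$seed, res$manifest$input,
            if (res$manifest$normalize) "L2 vector norm" else "none"),
    sprintf("cohort: %d cases, %d candidates -> %d matched controls",
            res$manifest$n_cases, res$manifest$n_candidates,
            nrow(res$match$pairs)),
    "-- covariate balance (SMD before -> after) --",
    vapply(seq_len(nrow(res$match$balance_before)), function(i) {
      sprintf("  %s: %+.3f -> %+.3f",
              res$match$balance_before$covariate[i],
              res$match$balance_before$smd[i], res$match$balance_after$smd[i])
    }, "")
  )
  if (!is.null(res$qc)) {
    g <- glance(res$qc)
    lines <- c(lines, sprintf(
      "QC: %d pooled spectra | median CV %.2f%% | trend %.2e absorbance/index",
      g$n_qc, g$median_cv_pct, g$trend_slope))
  }
  lines <- c(lines, "-- significant regions (|effect| criterion) --")
  if (nrow(res$regions) == 0) {
    lines <- c(lines, "  none")
  } else {
    lines <- c(lines, vapply(seq_len(nrow(res$regions)), function(i) {
      sprintf("  %g-%g cm-1 (max |d| = %.2f)", res$regions$wn_start[i],
              res$regions$wn_end[i], res$regions$max_abs_effect[i])
    }, ""))
  }
  if (!is.null(res$stage)) {
    lines <- c(lines, sprintf(
      "stage strata: M0 n=%d, M1 n=%d | enclosed-area ratio M1:M0 = %.2f",
      res$stage$n_m0, res$stage$n_m1, res$stage$area_ratio))
  }
  lines <- c(lines, sprintf(
    "classification (%s spectra): AUC = %.3f +- %.3f (%d-fold x %d repeats, linear SVM C = %g)",
    if (res$manifest$normalize) "normalized" else "non-normalized",
    res$cv$mean_auc, res$cv$sd_auc,
    res$manifest$folds, res$manifest$repeats, res$manifest$cost))
  lines
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(pipeline_report(x), sep = "\n")
  invisible(x)
}
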