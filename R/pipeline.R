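#' Compute age-adjusted feature summaries for a cohort
#'
#' Runs segment selection, beat detection, per-beat feature extraction,
#' baroreflex estimation and five-statistic summarisation for every
#' recording, then divides each summary by the patient's age.
#'
#' @param recordings list of [bp_recording()] objects.
#' @param meta manifest-style data.frame (`patient_id`, `age`, `label`,
#'   `bsa`, ...) aligned with `recordings`.
#' @param config a [pipeline_config()].
#' @param progress print one line per 25 recordings.
#' @return List of age-adjusted [feature_summary()] objects.
#' @export
cohort_features <- function(recordings, meta, config = pipeline_config(),
                            progress = FALSE) {
  stopifnot(length(recordings) == nrow(meta))
  out <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    ex <- extract_recording_features(recordings[[i]], meta[i, ], config)
    s <- summarize_features(ex$series, patient_id = meta$patient_id[i],
                            age = meta$age[i], label = meta$label[i],
                            config = config)
    out[[i]] <- age_adjust(s)
    if (progress && i %% 25 == 0) {
      message("features: ", i, "/", length(recordings))
    }
  }
  out
}

#' Run the detection-model stage
#'
#' From age-adjusted summaries to an evaluated classifier: builds the
#' design matrix, performs the stratified 75/25 split, SMOTE-balances the
#' training set, fits the min-max normalizer on the balanced training
#' data, grid-searches the classifier families by 4-fold cross-validated
#' AUROC, and evaluates the refitted best model on the held-out test set.
#'
#' @param summaries list of age-adjusted [feature_summary()] objects.
#' @param seed integer seed driving split, SMOTE, folds and stochastic
#'   fits.
#' @param config a [pipeline_config()].
#' @param subset optional summary-column subset for the design matrix.
#' @param families optional subset of classifier families to search.
#' @param paranoid also run the leakage-conservative variant that fits the
#'   min-max normalizer on the *original* training rows before SMOTE
#'   (scale-then-SMOTE) and report both results; the default order is
#'   SMOTE-then-scale.
#' @return A list with `model` (the fitted `"aos_model"`), `report` (the
#'   test-set `"evaluation_report"`), `normalizer`, `split`, and the
#'   design matrix pieces.  With `paranoid = TRUE`, also `paranoid`
#'   (`model` and `report` of the scale-then-SMOTE variant).
#' @export
train_detection_model <- function(summaries, seed = 1,
                                  config = pipeline_config(),
                                  subset = NULL, families = NULL,
                                  paranoid = FALSE) {
  dm <- build_design_matrix(summaries, subset = subset)
  split <- stratified_split(dm$y, config$train_fraction, seed = seed)
  x_tr <- dm$x[split$train, , drop = FALSE]
  y_tr <- dm$y[split$train]
  x_te_raw <- dm$x[split$test, , drop = FALSE]
  y_te <- dm$y[split$test]

  sm <- smote_oversample(x_tr, y_tr, k = config$smote_k, seed = seed + 1)
  norm <- fit_normalizer(sm$x)
  x_bal <- apply_normalizer(norm, sm$x)
  model <- grid_search_train(x_bal, sm$y, cv_folds = config$cv_folds,
                             seed = seed + 2, families = families)
  report <- evaluate_classifier(model, y_te, threshold = config$threshold,
                                x = apply_normalizer(norm, x_te_raw))
  out <- list(model = model, report = report, normalizer = norm,
              split = split, x = dm$x, y = dm$y,
              patient_id = dm$patient_id)

  if (paranoid) {
    norm2 <- suppressWarnings(fit_normalizer(x_tr))
    sm2 <- smote_oversample(apply_normalizer(norm2, x_tr), y_tr,
                            k = config$smote_k, seed = seed + 1)
    model2 <- grid_search_train(sm2$x, sm2$y, cv_folds = config$cv_folds,
                                seed = seed + 2, families = families)
    report2 <- evaluate_classifier(model2, y_te,
                                   threshold = config$threshold,
                                   x = apply_normalizer(norm2, x_te_raw))
    out$paranoid <- list(model = model2, report = report2,
                         normalizer = norm2)
  }
  out
}

#' Full pipeline on an in-memory cohort
#'
#' Convenience wrapper chaining [cohort_features()] and
#' [train_detection_model()].
#'
#' @param cohort a list with `recordings` and `meta` (as returned by
#'   [simulate_cohort()] or assembled from [read_cohort_manifest()]).
#' @param seed integer seed.
#' @param config a [pipeline_config()].
#' @param subset,families forwarded to [train_detection_model()].
#' @return See [train_detection_model()]; additionally carries
#'   `summaries`.
#' @export
run_detection_pipeline <- function(cohort, seed = 1,
                                   config = pipeline_config(),
                                   subset = NULL, families = NULL) {
  summaries <- cohort_features(cohort$recordings, cohort$meta, config)
  out <- train_detection_model(summaries, seed = seed, config = config,
                               subset = subset, families = families)
  out$summaries <- summaries
  out
}

#' Serialise an evaluation report to JSON
#'
#' @param report an `"evaluation_report"`.
#' @param path output path.
#' @param seed,config optional provenance stamped into the file.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path, seed = NULL, config = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  obj <- list(
    confusion = list(tp = report$tp, fp = report$fp, tn = report$tn,
                     fn = report$fn),
    metrics = as.list(report$metrics),
    metrics_2dp = as.list(report$metrics_2dp),
    auroc = report$auroc,
    threshold = report$threshold)
  if (!is.null(seed)) obj$seed <- seed
  if (!is.null(config)) obj$config_hash <- config_hash(config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
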