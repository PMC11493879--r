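#' Construct a feature summary
#'
#' Container for one recording's 135 summary values (27 base features
#' times 5 statistics) plus patient metadata.
#'
#' @param values named numeric vector in [feature_column_names()] order.
#' @param patient_id,age,label patient metadata.
#' @param age_adjusted whether the values have been divided by age.
#' @return Object of class `"feature_summary"`.
#' @export
feature_summary <- function(values, patient_id = "anon", age = NA_real_,
                            label = NA_character_, age_adjusted = FALSE) {
  cols <- feature_column_names()
  stopifnot(identical(names(values), cols))
  structure(list(patient_id = patient_id, age = age, label = label,
                 values = values, age_adjusted = age_adjusted),
            class = "feature_summary")
}

#' @export
print.feature_summary <- function(x, ...) {
  cat(sprintf("<feature_summary> %s (label %s, age %s, %s): %d values, %d missing\n",
              x$patient_id, x$label, format(x$age),
              if (x$age_adjusted) "age-adjusted" else "unadjusted",
              length(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Five-statistic summary of one series
#'
#' `median`, `iqr` (q75 - q25) and the 10th/90th percentile of the change
#' use linear-interpolation quantiles (type 7); `variance` uses the n - 1
#' denominator.  The "change" deciles are computed on the first-difference
#' series `x[i+1] - x[i]` when `deciles_of = "diff"` (the default), or on
#' the levels when `"level"`.
#'
#' @param x numeric series (one base feature, one value per beat/window).
#' @param min_n minimum number of non-missing entries (default 10); below
#'   it all five statistics are `NA`.
#' @param deciles_of `"diff"` or `"level"`.
#' @return Named numeric vector `median`, `iqr`, `variance`, `decile1`,
#'   `decile9`.
#' @export
#' @examples
#' summary_stats(1:100)
summary_stats <- function(x, min_n = 10L, deciles_of = "diff") {
  x <- x[!is.na(x)]
  if (length(x) < min_n) {
    return(c(median = NA_real_, iqr = NA_real_, variance = NA_real_,
             decile1 = NA_real_, decile9 = NA_real_))
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  d <- if (deciles_of == "diff") diff(x) else x
  dq <- stats::quantile(d, c(0.1, 0.9), names = FALSE, type = 7)
  c(median = q[2], iqr = q[3] - q[1], variance = stats::var(x),
    decile1 = dq[1], decile9 = dq[2])
}

#' Summarise a recording's feature series
#'
#' Collapses the 27 base feature series of one recording into the
#' 135-value summary vector (five statistics per feature, feature-major
#' order).
#'
#' @param series named list of numeric series; names must be
#'   [feature_names()].
#' @param patient_id,age,label patient metadata carried into the summary.
#' @param config a [pipeline_config()] (supplies `min_series_n` and
#'   `deciles_of`).
#' @return A [feature_summary()] (unadjusted).
#' @export
summarize_features <- function(series, patient_id = "anon", age = NA_real_,
                               label = NA_character_,
                               config = pipeline_config()) {
  stopifnot(identical(names(series), feature_names()))
  vals <- unlist(lapply(series, summary_stats, min_n = config$min_series_n,
                        deciles_of = config$deciles_of))
  names(vals) <- feature_column_names()
  feature_summary(vals, patient_id = patient_id, age = age, label = label,
                  age_adjusted = FALSE)
}

#' Age-adjust a feature summary
#'
#' Divides every summary statistic by the patient's age (years) to remove
#' age-dependent level differences.  Idempotence is guarded: adjusting an
#' already-adjusted summary is an error.
#'
#' @param summary a [feature_summary()].
#' @param age age in years; defaults to the summary's own `age` field.
#' @return The adjusted [feature_summary()].
#' @export
age_adjust <- function(summary, age = summary$age) {
  stopifnot(inherits(summary, "feature_summary"))
  if (isTRUE(summary$age_adjusted)) {
    stop("summary is already age-adjusted")
  }
  if (!is.finite(age) || age <= 0) stop("age must be a positive number")
  summary$values <- summary$values / age
  summary$age <- age
  summary$age_adjusted <- TRUE
  summary
}

#' Build the cohort design matrix
#'
#' Stacks per-recording feature summaries into a patients x features
#' matrix with a parallel label vector.  Rows containing any missing value
#' among the selected columns are dropped (with a message reporting the
#' count).
#'
#' @param summaries list of [feature_summary()] objects (normally
#'   age-adjusted).
#' @param subset optional character vector of summary column names (e.g.
#'   [default_feature_subset()]); `NULL` selects all 135.
#' @return A list with `x` (numeric matrix), `y` (factor with levels
#'   `noAoS`, `AoS`), `patient_id`, and `dropped` (patient ids removed for
#'   missingness).
#' @export
build_design_matrix <- function(summaries, subset = NULL) {
  stopifnot(length(summaries) > 0)
  cols <- feature_column_names()
  if (!is.null(subset)) {
    if (length(subset) == 0) stop("empty feature subset")
    unknown <- setdiff(subset, cols)
    if (length(unknown)) {
      stop("unknown feature column(s): ", paste(unknown, collapse = ", "),
           "; valid names are those of feature_column_names()")
    }
    cols <- subset
  }
  x <- do.call(rbind, lapply(summaries, function(s) s$values[cols]))
  colnames(x) <- cols
  rownames(x) <- vapply(summaries, function(s) s$patient_id, character(1))
  y <- vapply(summaries, function(s) s$label, character(1))
  keep <- stats::complete.cases(x)
  if (any(!keep)) {
    message(sum(!keep), " recording(s) dropped for missing feature values")
  }
  list(x = x[keep, , drop = FALSE],
       y = factor(y[keep], levels = c("noAoS", "AoS")),
       patient_id = rownames(x)[keep],
       dropped = rownames(x)[!keep])
}
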