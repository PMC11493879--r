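#' Pipeline configuration
#'
#' Builds the configuration list that controls every tunable constant of the
#' waveform pipeline.  Each entry has a documented default; any entry can be
#' overridden by name.  The same structure is consumed by the command-line
#' interface (via `--set key=value`) and by the programmatic entry points.
#'
#' Main groups of settings:
#' * smoothing: Savitzky-Golay `sg_window` (samples, odd) and `sg_order`
#'   for the pressure signal, plus `deriv_window`/`deriv_order` for the
#'   least-squares second-derivative estimate used in notch detection.
#' * beat detection: `upstroke_frac` (fraction of the rolling 95th-percentile
#'   first derivative that defines an upstroke event), `upstroke_roll_s`
#'   (rolling window, s), `refractory_s`, and the valid inter-beat interval
#'   range `ibi_range` (s).
#' * segment selection: `min_duration_s` (admission rule), `max_duration_s`
#'   (recordings are truncated to their first `max_duration_s` seconds of
#'   artefact-free data), artefact thresholds `pressure_range` (mmHg) and
#'   `max_jump` (mmHg between adjacent samples).
#' * notch search: `notch_window_s` after the systolic peak.
#' * derivative source: `use_smoothed` (derivatives from the smoothed beat;
#'   set `FALSE` to use the raw beat).
#' * pulse contour: `sv_k` (mL per mmHg s), the global calibration constant
#'   of the stroke-volume surrogate; `NULL` means calibrate from the
#'   reference beat template via [calibrate_sv_constant()].
#' * notch AUC variant: `notch_auc` is `"area"` (area above the horizontal
#'   line at the notch pressure, as a percentage of total beat area) or
#'   `"time"` (notch time as a percentage of the inter-beat interval).
#' * summaries: `deciles_of` is `"diff"` (deciles of the beat-to-beat first
#'   difference of each feature series, the default reading of "change") or
#'   `"level"` (deciles of the raw series).
#' * xBRS: `xbrs_window_s`, `xbrs_rate` (resampling rate, Hz),
#'   `xbrs_delays` (s), `xbrs_alpha` (two-sided significance level).
#' * model: `train_fraction`, `smote_k`, `cv_folds`, `threshold`.
#'
#' @param ... named overrides of the defaults.
#' @return A named list of class `"aos_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config(sg_window = 11)
#' cfg$sg_window
pipeline_config <- function(...) {
  cfg <- list(
    sample_rate    = 200,
    sg_window      = 15L,
    sg_order       = 3L,
    deriv_window   = 21L,
    deriv_order    = 3L,
    use_smoothed   = TRUE,
    upstroke_frac  = 0.4,
    upstroke_roll_s = 10,
    refractory_s   = 0.3,
    ibi_range      = c(0.3, 2.0),
    min_beats      = 60L,
    min_duration_s = 180,
    max_duration_s = 600,
    pressure_range = c(20, 300),
    max_jump       = 60,
    notch_window_s = 0.35,
    notch_min_post_s = 0.25,
    sv_k           = NULL,
    notch_auc      = "area",
    deciles_of     = "diff",
    min_series_n   = 10L,
    xbrs_window_s  = 10,
    xbrs_rate      = 1,
    xbrs_delays    = 0:5,
    xbrs_alpha     = 0.01,
    train_fraction = 0.75,
    smote_k        = 5L,
    cv_folds       = 4L,
    threshold      = 0.5
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration entries: ", paste(unknown, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  if (cfg$sg_window %% 2 == 0 || cfg$sg_window <= cfg$sg_order) {
    stop("sg_window must be odd and greater than sg_order")
  }
  if (is.null(cfg$sv_k)) cfg$sv_k <- calibrate_sv_constant()
  class(cfg) <- "aos_config"
  cfg
}

#' Short stable hash of a configuration
#'
#' Used to stamp metric reports and model artifacts so that results can be
#' traced back to the exact configuration that produced them.
#'
#' @param cfg a configuration list.
#' @return A 32-character hexadecimal string.
#' @export
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(cfg[order(names(cfg))]), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' Base hemodynamic feature names
#'
#' The 27 per-beat/per-window hemodynamic quantities the pipeline extracts
#' from an arterial pressure recording, in their canonical column order.
#' The first 25 are computed per beat; `xbrs_gain` and `xbrs_tau` are
#' computed per 10-s window of the beat-to-beat systolic-pressure and
#' inter-beat-interval series.
#'
#' @return Character vector of length 27.
#' @export
#' @examples
#' length(feature_names())
feature_names <- function() {
  c("ibi", "hr", "lvet", "sap", "dap", "map",
    "sv", "co", "svr", "svi", "ci", "svri",
    "dpdt", "pp", "sw",
    "sap_time", "auc_sap_pct", "auc_dap_pct",
    "notch_time", "notch_pressure", "auc_notch_pct",
    "max_upstroke_p", "max_upstroke_time",
    "max_downstroke_p", "max_downstroke_time",
    "xbrs_gain", "xbrs_tau")
}

#' Summary statistic names
#'
#' The five statistics computed per base feature: median, interquartile
#' range, variance, and the 1st and 9th decile of the beat-to-beat change.
#'
#' @return Character vector of length 5.
#' @export
summary_stat_names <- function() {
  c("median", "iqr", "variance", "decile1", "decile9")
}

#' Full feature column names
#'
#' All `27 * 5 = 135` summary columns, ordered feature-major
#' (`ibi_median`, `ibi_iqr`, ..., `xbrs_tau_decile9`).
#'
#' @return Character vector of length 135.
#' @export
feature_column_names <- function() {
  as.vector(t(outer(feature_names(), summary_stat_names(), paste, sep = "_")))
}

#' Default model feature subset
#'
#' A curated subset of summary columns that concentrates on the summary
#' statistics with the strongest group contrasts (all medians of the
#' hemodynamic panel plus selected spread and change statistics).  Used as
#' the optional `subset` argument of [build_design_matrix()].
#'
#' @return Character vector of summary column names.
#' @export
default_feature_subset <- function() {
  med <- c("ibi", "hr", "sap", "dap", "map", "sv", "co", "svi", "ci",
           "dpdt", "sw", "sap_time", "notch_time", "notch_pressure",
           "auc_sap_pct", "auc_dap_pct", "max_upstroke_time",
           "max_upstroke_p", "max_downstroke_p", "xbrs_tau")
  iqr <- c("map", "dpdt", "sw", "notch_time", "max_upstroke_time",
           "max_upstroke_p")
  vr  <- c("svr", "svri", "dpdt", "pp", "max_downstroke_time",
           "max_upstroke_p")
  d1  <- c("sap", "dpdt", "notch_pressure", "max_upstroke_p",
           "max_downstroke_p")
  d9  <- c("sap", "dpdt", "notch_pressure", "max_upstroke_p")
  c(paste0(med, "_median"), paste0(iqr, "_iqr"), paste0(vr, "_variance"),
    paste0(d1, "_decile1"), paste0(d9, "_decile9"))
}

#' Body surface area (Du Bois)
#'
#' `bsa = 0.007184 * height_cm^0.725 * weight_kg^0.425`, the clinical
#' standard used to index stroke volume, cardiac output and vascular
#' resistance.
#'
#' @param height_cm height in centimetres.
#' @param weight_kg weight in kilograms.
#' @return Body surface area in square metres.
#' @export
#' @examples
#' bsa_du_bois(176, 83)
bsa_du_bois <- function(height_cm, weight_kg) {
  stopifnot(all(height_cm > 0), all(weight_kg > 0))
  0.007184 * height_cm^0.725 * weight_kg^0.425
}
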