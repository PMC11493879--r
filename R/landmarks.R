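#' Locate the dicrotic notch of a single beat
#'
#' The notch marks aortic valve closure.  It is located by averaging the
#' times of the second local maximum of the first derivative and of the
#' second local maximum of the second derivative of the pressure beat.
#' The first maximum of each derivative belongs to the systolic upstroke,
#' so the second is identified as the earliest local maximum after the
#' point of steepest systolic decline, searched within
#' `(t_sap, t_sap + notch_window_s]` (default 0.35 s); candidates must have
#' positive derivative value (the notch sits on a rising, convex shoulder).
#'
#' @param beat numeric vector: one beat's pressure, onset first sample.
#' @param t_sap systolic-peak time, onset-referenced (s).
#' @param rate sampling rate (Hz).
#' @param config a [pipeline_config()].
#' @param d1,d2 optional precomputed first/second derivative of `beat`
#'   (mmHg/s and mmHg/s^2); computed internally when `NULL`.
#' @return A list with `t_notch` (s) and `p_notch` (mmHg).
#' @export
#' @examples
#' b <- render_beat(beat_template("control"), ibi = 0.88)
#' locate_dicrotic_notch(smooth_pressure(b), t_sap = 0.17, rate = 200)
locate_dicrotic_notch <- function(beat, t_sap, rate = 200,
                                  config = pipeline_config(),
                                  d1 = NULL, d2 = NULL) {
  n <- length(beat)
  tt <- (seq_len(n) - 1) / rate
  if (tt[n] - t_sap < config$notch_min_post_s) {
    stop(structure(class = c("notch_not_found", "error", "condition"),
                   list(message = sprintf(
                     "beat has only %.3f s of signal after the systolic peak (need %g s)",
                     tt[n] - t_sap, config$notch_min_post_s),
                     call = sys.call())))
  }
  if (is.null(d1)) d1 <- .d1_centred(beat, rate)
  if (is.null(d2)) d2 <- .d2_sgolay(beat, rate, config$deriv_window,
                                    config$deriv_order)
  win_end <- t_sap + config$notch_window_s
  in_sys <- tt > t_sap & tt <= win_end
  if (!any(in_sys)) .notch_fail("empty notch search window")
  i_md <- which(in_sys)[which.min(d1[in_sys])]
  t_md <- tt[i_md]
  cand1 <- .second_deriv_max(d1, tt, t_md, win_end)
  cand2 <- .second_deriv_max(d2, tt, t_md, win_end)
  if (is.na(cand1) || is.na(cand2)) {
    .notch_fail("no dicrotic shoulder: fewer than two derivative maxima in the search window")
  }
  t_notch <- (cand1 + cand2) / 2
  p_notch <- stats::approx(tt, beat, xout = t_notch)$y
  list(t_notch = t_notch, p_notch = p_notch)
}

.notch_fail <- function(msg) {
  stop(structure(class = c("notch_not_found", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# earliest positive local maximum of a derivative after t_md, within window
.second_deriv_max <- function(d, tt, t_md, win_end) {
  lm <- .local_maxima(d)
  lm <- lm[tt[lm] > t_md & tt[lm] <= win_end & d[lm] > 0]
  if (length(lm) == 0) NA_real_ else tt[lm[1]]
}

#' Extract the landmarks of a single beat
#'
#' Identifies the systolic peak (maximum pressure, first occurrence on
#' ties), the diastolic pressure (onset sample), the dicrotic notch
#' ([locate_dicrotic_notch()]), and the maximum up- and down-stroke slopes
#' of the systolic part of the beat (maximum and minimum of the first
#' derivative restricted to the interval from onset to notch).
#'
#' @param beat numeric vector: one beat's pressure, onset first sample.
#'   Supply the smoothed beat (the default pipeline convention).
#' @param rate sampling rate (Hz).
#' @param config a [pipeline_config()].
#' @return An object of class `"beat_landmarks"`: a list with `sap`,
#'   `t_sap`, `dap`, `t_notch`, `p_notch`, `t_max_up`, `p_max_up`,
#'   `max_up_slope`, `t_max_down`, `p_max_down`, `max_down_slope` and the
#'   beat `duration` (s).
#' @export
extract_landmarks <- function(beat, rate = 200, config = pipeline_config()) {
  n <- length(beat)
  tt <- (seq_len(n) - 1) / rate
  i_sap <- which.max(beat)
  sap <- beat[i_sap]
  t_sap <- tt[i_sap]
  dap <- beat[1]
  if (sap - dap < 1e-9 || i_sap == 1) {
    .invalid_beat("no systolic upstroke (flat or non-increasing beat)")
  }
  d1 <- .d1_centred(beat, rate)
  d2 <- .d2_sgolay(beat, rate, config$deriv_window, config$deriv_order)
  notch <- locate_dicrotic_notch(beat, t_sap, rate, config, d1 = d1, d2 = d2)
  sys_idx <- which(tt > 0 & tt < notch$t_notch)
  if (length(sys_idx) < 3) .invalid_beat("systolic interval too short")
  i_up <- sys_idx[which.max(d1[sys_idx])]
  i_dn <- sys_idx[which.min(d1[sys_idx])]
  lm <- structure(list(
    sap = sap, t_sap = t_sap, dap = dap,
    t_notch = notch$t_notch, p_notch = notch$p_notch,
    t_max_up = tt[i_up], p_max_up = beat[i_up], max_up_slope = d1[i_up],
    t_max_down = tt[i_dn], p_max_down = beat[i_dn],
    max_down_slope = d1[i_dn],
    duration = n / rate), class = "beat_landmarks")
  .check_landmarks(lm)
  lm
}

.invalid_beat <- function(msg) {
  stop(structure(class = c("invalid_beat", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.check_landmarks <- function(lm) {
  ok <- lm$t_max_up > 0 && lm$t_max_up < lm$t_sap &&
    lm$t_sap < lm$t_max_down && lm$t_max_down < lm$t_notch &&
    lm$t_notch < lm$duration &&
    lm$dap <= lm$p_notch + 1e-9 && lm$p_notch <= lm$sap + 1e-9 &&
    lm$max_up_slope > 0 && lm$max_down_slope < 0
  if (!ok) .invalid_beat("landmark ordering invariant violated")
  invisible(lm)
}

#' @export
print.beat_landmarks <- function(x, ...) {
  cat(sprintf(
    paste0("<beat_landmarks> SAP %.1f mmHg at %.3f s; DAP %.1f; ",
           "notch %.1f at %.3f s; dP/dt max %.0f at %.3f s\n"),
    x$sap, x$t_sap, x$dap, x$p_notch, x$t_notch, x$max_up_slope, x$t_max_up))
  invisible(x)
}

#' Compute per-beat hemodynamic features
#'
#' Derives the per-beat feature panel from a beat's landmarks:
#' timing features (IBI, heart rate, left ventricular ejection time
#' defined as the onset-to-notch time), pressures (SAP, DAP, MAP as the
#' true time average, pulse pressure), area fractions (beat area before
#' and after the notch as percentages of total beat area, and the area
#' above the horizontal line through the notch pressure), contractility
#' (`dpdt`, the maximum systolic upstroke slope), and the pulse-contour
#' panel: a stroke-volume surrogate `sv = k * integral of (P - DAP) over
#' systole`, with cardiac output `co = sv * hr / 1000`, stroke work
#' `sw = sv * map`, systemic vascular resistance `svr = 80 * map / co`
#' (dyn s cm^-5), and their body-surface-area-indexed forms.
#' All integrals are trapezoidal.
#'
#' @param landmarks a `"beat_landmarks"` object from [extract_landmarks()].
#' @param beat the beat pressure vector the landmarks came from.
#' @param rate sampling rate (Hz).
#' @param meta list or one-row data.frame with at least `bsa` (m^2); when
#'   absent, indexed features are `NA`.
#' @param k stroke-volume calibration constant (mL per mmHg s); default
#'   from the active configuration.
#' @param config a [pipeline_config()].
#' @param ibi inter-beat interval (s); defaults to the beat duration.
#' @return Named numeric vector with the per-beat features (all base
#'   features except the xBRS pair).
#' @export
compute_beat_features <- function(landmarks, beat, rate = 200, meta = NULL,
                                  k = NULL, config = pipeline_config(),
                                  ibi = NULL) {
  stopifnot(inherits(landmarks, "beat_landmarks"))
  if (is.null(k)) k <- config$sv_k
  n <- length(beat)
  tt <- (seq_len(n) - 1) / rate
  if (is.null(ibi)) ibi <- tt[n]   # beat span: onset to next onset
  lm <- landmarks

  w <- rep(1 / rate, n); w[c(1, n)] <- 0.5 / rate  # trapezoid weights
  total_area <- sum(beat * w)
  map <- total_area / tt[n]

  # cumulative trapezoid for partial integrals up to t_notch
  ctp <- c(0, cumsum((beat[-n] + beat[-1]) / (2 * rate)))
  area_to <- function(t0) {
    i <- findInterval(t0, tt)
    if (i >= n) return(ctp[n])
    frac <- (t0 - tt[i]) * rate
    pa <- beat[i] + frac * (beat[i + 1] - beat[i])
    ctp[i] + (beat[i] + pa) / 2 * (t0 - tt[i])
  }
  a_sys <- area_to(lm$t_notch)
  auc_sap_pct <- 100 * a_sys / ctp[n]
  auc_dap_pct <- 100 - auc_sap_pct
  excess <- pmax(beat - lm$p_notch, 0)
  auc_notch_pct <- if (config$notch_auc == "time") {
    100 * lm$t_notch / ibi
  } else {
    100 * sum(excess * w) / total_area
  }

  hr <- 60 / ibi
  sv <- k * (a_sys - lm$dap * lm$t_notch)
  co <- sv * hr / 1000
  sw <- sv * map
  svr <- if (co > 0) 80 * map / co else NA_real_
  if (co <= 0) sv <- co <- sw <- NA_real_
  bsa <- if (!is.null(meta) && !is.null(meta$bsa)) meta$bsa else NA_real_
  out <- c(
    ibi = ibi, hr = hr, lvet = lm$t_notch,
    sap = lm$sap, dap = lm$dap, map = map,
    sv = sv, co = co, svr = svr,
    svi = sv / bsa, ci = co / bsa, svri = svr * bsa,
    dpdt = lm$max_up_slope, pp = lm$sap - lm$dap, sw = sw,
    sap_time = lm$t_sap, auc_sap_pct = auc_sap_pct,
    auc_dap_pct = auc_dap_pct,
    notch_time = lm$t_notch, notch_pressure = lm$p_notch,
    auc_notch_pct = auc_notch_pct,
    max_upstroke_p = lm$p_max_up, max_upstroke_time = lm$t_max_up,
    max_downstroke_p = lm$p_max_down, max_downstroke_time = lm$t_max_down)
  out
}
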