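#' Extract all per-beat features of a recording
#'
#' Runs the full single-recording stage of the pipeline: artefact-free
#' segment selection, Savitzky-Golay smoothing, beat detection, per-beat
#' landmarking and feature computation, and windowed baroreflex
#' sensitivity.  This is the batch (vectorised) implementation; it yields
#' the same numbers as chaining [extract_landmarks()] and
#' [compute_beat_features()] beat by beat.
#'
#' @param rec a [bp_recording()].
#' @param meta optional list/one-row data.frame with `bsa` (m^2) for the
#'   indexed features.
#' @param config a [pipeline_config()].
#' @param select run [select_segment()] first (default `TRUE`).
#' @return A list with elements
#'   `beats` (the beat table with validity flags),
#'   `features` (a `data.table`, one row per valid beat, landmark and
#'   feature columns),
#'   `xbrs` (the per-window baroreflex estimates), and
#'   `series` (named list of the 27 base feature series, ready for
#'   [summarize_features()]).
#' @export
extract_recording_features <- function(rec, meta = NULL,
                                       config = pipeline_config(),
                                       select = TRUE) {
  stopifnot(inherits(rec, "bp_recording"))
  rate <- rec$sample_rate
  if (select) {
    rec <- select_segment(rec, config$max_duration_s, config$min_duration_s,
                          config)
  }
  raw <- rec$pressure
  ps <- smooth_pressure(raw, config$sg_window, config$sg_order)
  src <- if (config$use_smoothed) ps else raw
  srec <- rec; srec$pressure <- ps
  beats <- detect_beats(srec, config, smoothed = TRUE)
  vb <- beats[beats$valid, , drop = FALSE]
  nvb <- nrow(vb)
  n <- length(src)
  d1 <- .d1_centred(src, rate)
  d2 <- .d2_sgolay(src, rate, config$deriv_window, config$deriv_order)
  ctp <- c(0, cumsum((src[-n] + src[-1]) / (2 * rate)))

  len <- vb$end_idx - vb$onset_idx           # samples before the next onset
  gidx <- sequence(len, from = vb$onset_idx)
  sid <- rep(seq_len(nvb), len)
  rel <- (sequence(len) - 1L) / rate
  pv <- src[gidx]; d1v <- d1[gidx]

  ## systolic peak: first occurrence of the per-beat maximum
  o <- vb$onset_idx
  e <- vb$end_idx
  dt <- data.table::data.table(b = sid, g = gidx, rel = rel, p = pv, d1 = d1v)
  pk <- dt[, .(i = g[which.max(p)], sap = max(p)), by = b]
  t_sap <- (pk$i - o) / rate
  sap <- pk$sap
  dap <- src[o]
  ibi <- vb$ibi

  ## max downstroke search region and notch candidates
  win_end <- t_sap + config$notch_window_s
  sys <- dt[rel > t_sap[b] & rel <= win_end[b]]
  md <- sys[, .(i = g[which.min(d1)]), by = b]
  t_md <- rep(NA_real_, nvb)
  t_md[md$b] <- (md$i - o[md$b]) / rate

  cand_first <- function(lmi, dval) {
    bid <- integer(n); bid[gidx] <- sid
    cb <- bid[lmi]
    keep <- cb > 0L & dval[lmi] > 0
    lmi <- lmi[keep]; cb <- cb[keep]
    ct <- (lmi - o[cb]) / rate
    keep2 <- !is.na(t_md[cb]) & ct > t_md[cb] & ct <= win_end[cb]
    cd <- data.table::data.table(b = cb[keep2], cand_time = ct[keep2])
    first <- cd[, .(cand_time = cand_time[1]), by = b]
    outv <- rep(NA_real_, nvb)
    outv[first$b] <- first$cand_time
    outv
  }
  c1 <- cand_first(.local_maxima(d1), d1)
  c2 <- cand_first(.local_maxima(d2), d2)
  t_notch <- (c1 + c2) / 2
  has_notch <- !is.na(t_notch) & t_notch < ibi &
    (ibi - t_sap) >= config$notch_min_post_s

  ## notch pressure by linear interpolation
  p_notch <- rep(NA_real_, nvb)
  ok <- which(has_notch)
  if (length(ok)) {
    fi <- o[ok] + floor(t_notch[ok] * rate)
    frac <- t_notch[ok] * rate - floor(t_notch[ok] * rate)
    p_notch[ok] <- src[fi] + frac * (src[pmin(fi + 1L, n)] - src[fi])
  }

  ## steepest upstroke over the whole rise (notch-independent), used as
  ## the sharp timing fiducial for baroreflex inter-beat intervals: the
  ## pressure foot sits in a flat valley whose localisation error follows
  ## the slow baseline slope, which would masquerade as zero-delay
  ## SAP-IBI coupling
  rise <- dt[rel <= t_sap[b]]
  upall <- rise[, .(i = g[which.max(d1)]), by = b]
  t_up_all <- rep(NA_real_, nvb)
  t_up_all[upall$b] <- (upall$i - o[upall$b]) / rate

  ## systolic slopes restricted to (onset, notch)
  tn_b <- t_notch[sid]
  sysr <- dt[!is.na(tn_b) & rel > 0 & rel < tn_b]
  up <- sysr[, .(iu = g[which.max(d1)], idn = g[which.min(d1)]), by = b]
  t_max_up <- p_max_up <- up_slope <- rep(NA_real_, nvb)
  t_max_down <- p_max_down <- down_slope <- rep(NA_real_, nvb)
  t_max_up[up$b] <- (up$iu - o[up$b]) / rate
  p_max_up[up$b] <- src[up$iu]
  up_slope[up$b] <- d1[up$iu]
  t_max_down[up$b] <- (up$idn - o[up$b]) / rate
  p_max_down[up$b] <- src[up$idn]
  down_slope[up$b] <- d1[up$idn]

  valid <- has_notch & !is.na(t_max_up) &
    t_max_up > 0 & t_max_up < t_sap & t_sap < t_max_down &
    t_max_down < t_notch & t_notch < ibi &
    dap <= p_notch + 1e-9 & p_notch <= sap + 1e-9 &
    up_slope > 0 & down_slope < 0

  ## integral features (trapezoidal)
  total_area <- ctp[e] - ctp[o]
  map <- total_area / ibi
  a_sys <- rep(NA_real_, nvb)
  if (length(ok)) {
    fi <- o[ok] + floor(t_notch[ok] * rate)
    frac <- t_notch[ok] * rate - floor(t_notch[ok] * rate)
    pa <- src[fi] + frac * (src[pmin(fi + 1L, n)] - src[fi])
    a_sys[ok] <- ctp[fi] - ctp[o[ok]] +
      (src[fi] + pa) / 2 * (frac / rate)
  }
  auc_sap_pct <- 100 * a_sys / total_area
  auc_dap_pct <- 100 - auc_sap_pct

  pn_s <- p_notch[sid]
  ex1 <- pmax(pv - pn_s, 0)
  ex2 <- pmax(src[pmin(gidx + 1L, n)] - pn_s, 0)
  dt[, exsum := (ex1 + ex2) / (2 * rate)]
  exc <- dt[, .(a = sum(exsum)), by = b]
  a_above <- rep(NA_real_, nvb)
  a_above[exc$b] <- exc$a
  auc_notch_pct <- if (config$notch_auc == "time") {
    100 * t_notch / ibi
  } else {
    100 * a_above / total_area
  }

  hr <- 60 / ibi
  k <- config$sv_k
  sv <- k * (a_sys - dap * t_notch)
  co <- sv * hr / 1000
  sw <- sv * map
  svr <- ifelse(co > 0, 80 * map / co, NA_real_)
  bad_co <- !is.na(co) & co <= 0
  sv[bad_co] <- co[bad_co] <- sw[bad_co] <- NA_real_
  bsa <- if (!is.null(meta) && !is.null(meta$bsa)) meta$bsa else NA_real_

  feats <- data.table::data.table(
    beat = seq_len(nvb), onset_time = vb$onset_time, valid = valid,
    ibi = ibi, hr = hr, lvet = t_notch,
    sap = sap, dap = dap, map = map,
    sv = sv, co = co, svr = svr,
    svi = sv / bsa, ci = co / bsa, svri = svr * bsa,
    dpdt = up_slope, pp = sap - dap, sw = sw,
    sap_time = t_sap, auc_sap_pct = auc_sap_pct, auc_dap_pct = auc_dap_pct,
    notch_time = t_notch, notch_pressure = p_notch,
    auc_notch_pct = auc_notch_pct,
    max_upstroke_p = p_max_up, max_upstroke_time = t_max_up,
    max_downstroke_p = p_max_down, max_downstroke_time = t_max_down)

  ## xBRS on the beat-to-beat SAP / IBI series; the IBI here is measured
  ## between consecutive steepest-upstroke instants (foot-based IBI stays
  ## the per-beat feature)
  up_abs <- vb$onset_time + t_up_all
  ibi_up <- c(diff(up_abs), NA_real_)
  contiguous <- c(vb$end_idx[-nvb] == vb$onset_idx[-1], FALSE)
  ibi_up[!contiguous] <- NA_real_
  xb <- tryCatch({
    rs <- beat_series_resample(up_abs, sap, ibi_up,
                               rate = config$xbrs_rate)
    xbrs_windows(rs$sap, rs$ibi, rate = config$xbrs_rate,
                 window = config$xbrs_window_s, delays = config$xbrs_delays,
                 alpha = config$xbrs_alpha)
  }, error = function(e) {
    data.frame(window_start = numeric(0), gain = numeric(0),
               tau = numeric(0), correlation = numeric(0))
  })

  vf <- feats[valid == TRUE]
  series <- c(
    lapply(setdiff(feature_names(), c("xbrs_gain", "xbrs_tau")),
           function(f) vf[[f]]),
    list(xb$gain, xb$tau))
  names(series) <- feature_names()

  list(beats = beats, features = feats, xbrs = xb, series = series)
}
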