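## Synthetic hemodynamic cohort generation.
##
## Beats are built from four "velocity lobes" (scaled beta densities for
## the systolic rise, systolic decline and dicrotic wave, plus a smooth
## diastolic relaxation) so that every landmark the extraction stage
## measures -- steepest-upstroke time, systolic-peak time, maximum
## downstroke, notch time, peak slope -- is an explicit, invertible
## parameter of the generator.

.pkg_cache <- new.env(parent = emptyenv())

#' Beat template parameters
#'
#' Returns the parameter set describing one beat's morphology.  Group
#' defaults reproduce the median waveform contrasts of the two study
#' groups: patients with aortic stenosis have a delayed steepest upstroke
#' and systolic peak, longer ejection time and lower peak dP/dt than
#' controls.
#'
#' @param group `"control"` or `"aos"`.
#' @param ... named overrides of individual fields: `dap`, `pp` (mmHg),
#'   `t_peak`, `t_max_up`, `t_max_down`, `lvet` (s, onset-referenced),
#'   `notch_depth` (mmHg below the systolic peak), `dicrotic_wave_amp`
#'   (mmHg), `diastolic_decay_tau` (s), `dpdt` (mmHg/s, peak upstroke
#'   slope), `peak_cap` and `peak_cap_width` (the rounded systolic summit),
#'   `true_sv` (mL, ground-truth stroke volume carried in the log).
#' @return Object of class `"beat_template"`.
#' @export
#' @examples
#' beat_template("aos")$t_peak
beat_template <- function(group = c("control", "aos"), ...) {
  group <- match.arg(group)
  par <- if (group == "control") {
    list(dap = 76, pp = 80, t_peak = 0.17, t_max_up = 0.060,
         t_max_down = 0.285, lvet = 0.325, notch_depth = 40,
         dicrotic_wave_amp = 6, diastolic_decay_tau = 0.9,
         dpdt = 1185, peak_cap = 3, peak_cap_width = 0.03, true_sv = 77)
  } else {
    list(dap = 75, pp = 84, t_peak = 0.20, t_max_up = 0.075,
         t_max_down = 0.305, lvet = 0.345, notch_depth = 44,
         dicrotic_wave_amp = 6, diastolic_decay_tau = 0.9,
         dpdt = 858, peak_cap = 3, peak_cap_width = 0.03, true_sv = 71)
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(par))
  if (length(unknown)) stop("unknown template field(s): ",
                            paste(unknown, collapse = ", "))
  par[names(dots)] <- dots
  .validate_template(par)
  structure(par, class = "beat_template")
}

.validate_template <- function(p) {
  if (!(p$t_max_up > 0 && p$t_max_up < p$t_peak && p$t_peak < p$t_max_down &&
        p$t_max_down < p$lvet)) {
    stop("infeasible timing: need 0 < t_max_up < t_peak < t_max_down < lvet")
  }
  if (p$notch_depth <= p$peak_cap) {
    stop("notch_depth must exceed peak_cap")
  }
  if (p$notch_depth >= p$pp) stop("notch_depth must be below pp")
  dreq <- p$dpdt * p$t_peak / (p$pp - p$peak_cap)
  if (dreq <= 1.05) {
    stop(sprintf(
      "dpdt %.0f is infeasibly low for pp %.0f over t_peak %.3f s",
      p$dpdt, p$pp, p$t_peak))
  }
  invisible(p)
}

# concentration c of a beta density with mode m whose value at the mode is d
.solve_mode_density <- function(m, d) {
  stats::uniroot(function(cc) {
    stats::dbeta(m, 1 + m * cc, 1 + (1 - m) * cc) - d
  }, c(1e-3, 5000), tol = 1e-10)$root
}

# later inflection point (fraction of support) of a beta density
.beta_infl2 <- function(a, b) {
  al <- a - 1; be <- b - 1
  g <- function(x) al * (al - 1) * (1 - x)^2 - 2 * al * be * x * (1 - x) +
    be * (be - 1) * x^2
  m <- al / (al + be)
  stats::uniroot(g, c(m + 1e-9, 1 - 1e-9), tol = 1e-12)$root
}

# shape constants reused across all beats of one patient (invariant under
# joint time scaling and amplitude scaling of the template)
.beat_shape <- function(p) {
  m1 <- p$t_max_up / p$t_peak
  c1 <- .solve_mode_density(m1, p$dpdt * p$t_peak / (p$pp - p$peak_cap))
  ## keep the systolic velocity lobe at least quadratically flat at the
  ## peak (b1 >= 2.5); for extreme low-dP/dt requests the rendered slope
  ## then slightly exceeds the request instead of smearing the peak
  c1 <- max(c1, 1.5 / (1 - m1))
  a1 <- 1 + m1 * c1; b1 <- 1 + (1 - m1) * c1
  w2 <- p$lvet - p$t_peak
  m2 <- (p$t_max_down - p$t_peak) / w2
  c2 <- 8
  a2 <- 1 + m2 * c2; b2 <- 1 + (1 - m2) * c2
  x2 <- .beta_infl2(a2, b2)
  m3 <- 0.10; c3 <- 6  # wide, gentle dicrotic wave (peak offset = m3*w3)
  list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, x2 = x2,
       m3 = m3, a3 = 1 + m3 * c3, b3 = 1 + (1 - m3) * c3)
}

#' Render one beat
#'
#' Generates one cardiac cycle of arterial pressure at the requested rate.
#' The curve is a composite of smooth basis functions: a systolic rise
#' whose steepest point and peak land exactly at `t_max_up` and `t_peak`
#' (a small Gaussian cap makes the summit rounded rather than flat), a
#' systolic decline to the notch pressure at `lvet` with its steepest
#' descent at `t_max_down`, a dicrotic wave whose peak offset mirrors the
#' downstroke inflection about the notch (this centres derivative-based
#' notch estimates on `lvet`), and a smooth diastolic relaxation that
#' reaches `dap` exactly at the end of the cycle.
#'
#' @param params a [beat_template()].
#' @param ibi cycle length (s); must exceed `lvet + 0.05`.
#' @param rate sampling rate (Hz).
#' @param shape optional cached result of the internal shape solver (used
#'   by [simulate_recording()] to avoid re-solving per beat).
#' @param n_samples optional explicit sample count (defaults to
#'   `ceiling(ibi * rate)`).
#' @return Numeric vector of pressures (mmHg), onset first.
#' @export
#' @examples
#' b <- render_beat(beat_template("control"), ibi = 0.88)
#' max(b) - (76 + 80)  # peak reaches dap + pp
render_beat <- function(params, ibi, rate = 200, shape = NULL,
                        n_samples = NULL) {
  p <- params
  .validate_template(p)
  if (ibi <= p$lvet + 0.05) {
    stop("ibi must exceed lvet + 0.05 s")
  }
  if (is.null(shape)) shape <- .beat_shape(p)
  if (is.null(n_samples)) n_samples <- ceiling(ibi * rate)
  t <- (seq_len(n_samples) - 1) / rate
  ppb <- p$pp - p$peak_cap
  p_n <- p$dap + p$pp - p$notch_depth
  ndb <- p$notch_depth - p$peak_cap
  w2 <- p$lvet - p$t_peak
  d1off <- w2 * (1 - shape$x2)
  w3 <- d1off / shape$m3
  w3 <- min(w3, 0.6 * (ibi - p$lvet))
  out <- numeric(n_samples)

  i1 <- t <= p$t_peak
  out[i1] <- p$dap + ppb * stats::pbeta(t[i1] / p$t_peak, shape$a1, shape$b1)
  i2 <- t > p$t_peak & t <= p$lvet
  out[i2] <- p$dap + ppb -
    ndb * stats::pbeta((t[i2] - p$t_peak) / w2, shape$a2, shape$b2)
  i3 <- t > p$lvet & t <= p$lvet + w3
  out[i3] <- p_n + p$dicrotic_wave_amp *
    stats::pbeta((t[i3] - p$lvet) / w3, shape$a3, shape$b3)
  i4 <- t > p$lvet + w3
  if (any(i4)) {
    u <- t[i4] - (p$lvet + w3)
    U <- ibi - (p$lvet + w3)
    q <- function(u) u^2 / (0.15^2 + p$diastolic_decay_tau * u)
    EU <- exp(-q(U))
    out[i4] <- p$dap + (p_n + p$dicrotic_wave_amp - p$dap) *
      (exp(-q(u)) - EU) / (1 - EU)
  }
  out + p$peak_cap * exp(-(t - p$t_peak)^2 / (2 * p$peak_cap_width^2))
}

#' Default within-recording coupling and noise settings
#'
#' Beat-to-beat dynamics of the simulator: respiratory modulation of
#' systolic pressure, white beat-to-beat pressure and timing jitter, the
#' baroreflex coupling (a rise in systolic pressure lengthens the
#' following inter-beat intervals, `gain` ms/mmHg after `delay` s), and
#' additive observation noise.
#'
#' @param ... named overrides: `resp_amp` (mmHg), `resp_freq` (Hz),
#'   `sap_jitter_sd` (mmHg), `pp_cv`, `time_cv` (unitless coefficients of
#'   variation), `ibi_jitter_sd` (s), `brs_gain` (ms/mmHg), `brs_delay`
#'   (s), `noise_sd` (mmHg).
#' @return Named list of coupling settings.
#' @export
coupling_params <- function(...) {
  cp <- list(resp_amp = 3, resp_freq = 0.25, sap_jitter_sd = 2,
             pp_cv = 0.03, time_cv = 0.02, ibi_jitter_sd = 0.006,
             brs_gain = 5, brs_delay = 2.6, noise_sd = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cp))
  if (length(unknown)) stop("unknown coupling field(s): ",
                            paste(unknown, collapse = ", "))
  cp[names(dots)] <- dots
  cp
}

#' Simulate one recording
#'
#' Concatenates rendered beats with per-beat parameter jitter, respiratory
#' systolic-pressure modulation, baroreflex coupling
#' `IBI_n = IBI0 + G * (SAP(t_n - delay) - SAP0) / 1000`, and additive
#' observation noise.  A ground-truth log records every beat's onset,
#' systolic pressure, notch time and inter-beat interval.
#'
#' @param params a [beat_template()].
#' @param ibi0 baseline inter-beat interval (s).
#' @param duration recording length (s), at least 180.
#' @param couplings a [coupling_params()] list.
#' @param rate sampling rate (Hz).
#' @param seed optional seed (set only when non-`NULL`, so cohort-level
#'   simulation can stream one RNG sequence).
#' @param patient_id identifier for the recording.
#' @return A list with `recording` (a [bp_recording()]) and `log` (a
#'   `data.frame`: `onset`, `sap`, `ibi`, `t_notch`, `t_peak`,
#'   `t_max_up`, all in seconds/mmHg; notch and peak times
#'   onset-referenced).
#' @export
simulate_recording <- function(params, ibi0, duration,
                               couplings = coupling_params(), rate = 200,
                               seed = NULL, patient_id = "sim") {
  stopifnot(duration >= 180)
  if (!is.null(seed)) set.seed(seed)
  cp <- couplings
  p <- params
  shape <- .beat_shape(p)
  sap0 <- p$dap + p$pp
  n_total <- as.integer(round(duration * rate))
  pressure <- numeric(n_total + as.integer(3 * rate))
  est <- as.integer(duration / 0.3) + 8L
  onset <- sapv <- ibiv <- tno <- tpk <- tup <- numeric(est)
  t_cur <- 0
  s_cur <- 1L
  m <- 0L
  ## AR(1) systolic-pressure fluctuation with ~2.5 s correlation time, so
  ## windowed correlation survives the sub-beat smear of the baroreflex
  ## delay.  The baseline is kept continuous across beat joints (the
  ## respiratory term is evaluated per sample and the AR term is ramped
  ## within each beat): a step at the joint would corrupt foot detection.
  ar_tau <- 2.5
  phi <- exp(-ibi0 / ar_tau)
  jit_sd <- cp$sap_jitter_sd * sqrt(1 - phi^2)
  jit_cur <- stats::rnorm(1, 0, cp$sap_jitter_sd)
  while (s_cur <= n_total) {
    m <- m + 1L
    jit_next <- phi * jit_cur + stats::rnorm(1, 0, jit_sd)
    o_n <- cp$resp_amp * sin(2 * pi * cp$resp_freq * t_cur) + jit_cur
    pfac <- exp(stats::rnorm(1, 0, cp$pp_cv))
    sfac <- exp(stats::rnorm(1, 0, cp$time_cv))
    pb <- p
    pb$pp <- p$pp * pfac
    pb$notch_depth <- p$notch_depth * pfac
    pb$dicrotic_wave_amp <- p$dicrotic_wave_amp * pfac
    pb$peak_cap <- p$peak_cap * pfac
    pb$dpdt <- p$dpdt * pfac / sfac
    pb$t_peak <- p$t_peak * sfac
    pb$t_max_up <- p$t_max_up * sfac
    pb$t_max_down <- p$t_max_down * sfac
    pb$lvet <- p$lvet * sfac
    sap_prov <- pb$dap + pb$pp + o_n   # onset-time baseline, for delay 0

    sap_del <- if (cp$brs_delay <= 0 || m == 1L) {
      if (cp$brs_delay <= 0) sap_prov else sap0
    } else {
      j <- findInterval(t_cur - cp$brs_delay, onset[seq_len(m - 1L)])
      if (j >= 1L) sapv[j] else sap0
    }
    ibi_n <- ibi0 + cp$brs_gain / 1000 * (sap_del - sap0) +
      stats::rnorm(1, 0, cp$ibi_jitter_sd)
    ibi_n <- min(max(ibi_n, pb$lvet + 0.07, 0.3), 2.0)

    s_next <- as.integer(round((t_cur + ibi_n) * rate)) + 1L
    if (s_next <= s_cur + 1L) s_next <- s_cur + 2L
    nsmp <- s_next - s_cur
    ibi_actual <- nsmp / rate
    t_smp <- t_cur + (seq_len(nsmp) - 1L) / rate
    baseline <- cp$resp_amp * sin(2 * pi * cp$resp_freq * t_smp) +
      jit_cur + (jit_next - jit_cur) * (seq_len(nsmp) - 1L) / nsmp
    beat <- render_beat(pb, ibi_actual, rate, shape = shape,
                        n_samples = nsmp) + baseline
    pressure[s_cur:(s_next - 1L)] <- beat
    sap_n <- pb$dap + pb$pp +
      cp$resp_amp * sin(2 * pi * cp$resp_freq * (t_cur + pb$t_peak)) +
      jit_cur + (jit_next - jit_cur) * pb$t_peak / ibi_actual
    onset[m] <- t_cur; sapv[m] <- sap_n; ibiv[m] <- ibi_actual
    tno[m] <- pb$lvet; tpk[m] <- pb$t_peak; tup[m] <- pb$t_max_up
    t_cur <- t_cur + ibi_actual
    s_cur <- s_next
    jit_cur <- jit_next
  }
  pressure <- pressure[seq_len(n_total)]
  if (cp$noise_sd > 0) {
    pressure <- pressure + stats::rnorm(n_total, 0, cp$noise_sd)
  }
  keep <- seq_len(m)
  list(
    recording = bp_recording(pressure, sample_rate = rate,
                             patient_id = patient_id),
    log = data.frame(onset = onset[keep], sap = sapv[keep],
                     ibi = ibiv[keep], t_notch = tno[keep],
                     t_peak = tpk[keep], t_max_up = tup[keep]))
}

## lognormal draw matched to a printed median and interquartile range
.ln_draw <- function(n, med, q1, q3) {
  sdlog <- log(q3 / q1) / (2 * stats::qnorm(0.75))
  stats::rlnorm(n, meanlog = log(med), sdlog = sdlog)
}

#' Cohort-level simulation parameters
#'
#' Per-group distributions (median and interquartile range, sampled
#' log-normally) for the beat-template parameters, heart period,
#' demographics, baroreflex gain, and recording duration, together with
#' the shared coupling settings.  Defaults reproduce the two study
#' groups: the stenosis group has delayed systolic landmarks, longer
#' ejection time, lower peak dP/dt, is older, lighter and shorter, has a
#' balanced sex ratio (versus a predominantly male control group), and
#' contributes longer recordings.
#'
#' @param n_aos,n_control group sizes (default 101 and 48).
#' @param couplings a [coupling_params()] list (the baroreflex gain is
#'   overridden per patient from the group distribution).
#' @param ... named overrides replacing whole group entries (`aos`,
#'   `control`) or top-level fields.
#' @return Object of class `"cohort_params"`.
#' @export
cohort_params <- function(n_aos = 101, n_control = 48,
                          couplings = coupling_params(), ...) {
  out <- list(
    n_aos = n_aos, n_control = n_control, rate = 200,
    couplings = couplings,
    lvet_frac_down = 0.73,  # t_max_down position between t_peak and lvet
    control = list(
      ibi   = c(0.88, 0.84, 0.95),
      dap   = c(76, 72, 87),
      pp    = c(80, 65, 88),
      t_peak = c(0.17, 0.15, 0.19),
      t_max_up = c(0.060, 0.053, 0.065),
      lvet  = c(0.325, 0.310, 0.345),
      dpdt  = c(1185, 881, 1509),
      notch_depth = c(40, 36, 44),
      brs_gain = c(5.1, 3.4, 8.0),
      age   = c(73, 68, 77),
      weight = c(83, 75, 92),
      height = c(176, 172, 179),
      female_frac = 7 / 48,
      duration = c(400, 250, 600)),
    aos = list(
      ibi   = c(0.87, 0.77, 0.97),
      dap   = c(75, 68, 81),
      pp    = c(84, 67, 94),
      t_peak = c(0.20, 0.18, 0.23),
      t_max_up = c(0.075, 0.065, 0.091),
      lvet  = c(0.345, 0.325, 0.365),
      dpdt  = c(858, 636, 1163),
      notch_depth = c(44, 40, 48),
      brs_gain = c(4.7, 3.0, 7.3),
      age   = c(78, 73, 83),
      weight = c(76, 70, 87),
      height = c(170, 164, 178),
      female_frac = 46 / 101,
      duration = c(600, 435, 600)))
  dots <- list(...)
  out[names(dots)] <- dots
  class(out) <- "cohort_params"
  out
}

# draw one patient's template + physiology from a group spec
.draw_patient <- function(g, lvet_frac_down, max_tries = 60) {
  d <- function(v) .ln_draw(1, v[1], v[2], v[3])
  for (i in seq_len(max_tries)) {
    t_peak <- d(g$t_peak); t_max_up <- d(g$t_max_up); lvet <- d(g$lvet)
    pp <- d(g$pp); dap <- d(g$dap); dpdt <- d(g$dpdt)
    nd <- d(g$notch_depth); ibi <- d(g$ibi)
    ok <- t_max_up < 0.55 * t_peak && t_peak + 0.08 < lvet &&
      nd > 6 && nd < pp - 8 &&
      dpdt * t_peak / (pp - 3) > 1.15 && dpdt * t_peak / (pp - 3) < 30 &&
      ibi > lvet + 0.15 &&
      ## physiological plausibility guards on the log-normal tails
      dap > 40 && pp > 30 && dap + pp < 285 && dpdt < 3200 && ibi < 1.7
    if (ok) break
  }
  if (!ok) stop("could not draw a feasible patient after ", max_tries,
                " attempts")
  tmpl <- beat_template(
    "control", dap = dap, pp = pp, t_peak = t_peak, t_max_up = t_max_up,
    t_max_down = t_peak + lvet_frac_down * (lvet - t_peak), lvet = lvet,
    notch_depth = nd, dpdt = dpdt)
  dur <- min(max(.ln_draw(1, g$duration[1], g$duration[2], g$duration[3]),
                 180), 600)
  list(template = tmpl, ibi0 = ibi, duration = dur,
       brs_gain = d(g$brs_gain),
       age = d(g$age), weight = d(g$weight), height = d(g$height),
       sex = if (stats::runif(1) < g$female_frac) "female" else "male")
}

#' Simulate a two-group cohort
#'
#' Draws per-patient morphology, physiology and demographics from the
#' group distributions of [cohort_params()], simulates every recording,
#' and (optionally) writes the cohort to disk in the package's waveform
#' and manifest formats.
#'
#' @param params a [cohort_params()].
#' @param seed integer seed controlling all randomness of the cohort.
#' @param out_dir optional output directory; when given, waveform CSVs, a
#'   `manifest.csv` and a `ground_truth.csv` are written there.
#' @param progress print one line per 25 recordings.
#' @return A list with `recordings` (list of [bp_recording()]),
#'   `meta` (manifest data.frame incl. `bsa`), `truth` (per-patient
#'   ground-truth parameter table) and `logs` (per-recording beat logs).
#' @export
simulate_cohort <- function(params = cohort_params(), seed = 1,
                            out_dir = NULL, progress = FALSE) {
  stopifnot(params$n_aos >= 1, params$n_control >= 1)
  set.seed(seed)
  n <- params$n_aos + params$n_control
  labels <- c(rep("AoS", params$n_aos), rep("noAoS", params$n_control))
  recordings <- vector("list", n)
  logs <- vector("list", n)
  meta <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    grp <- if (labels[i] == "AoS") params$aos else params$control
    pat <- .draw_patient(grp, params$lvet_frac_down)
    cp <- params$couplings
    cp$brs_gain <- pat$brs_gain
    pid <- sprintf("P%03d", i)
    sim <- simulate_recording(pat$template, pat$ibi0, pat$duration,
                              couplings = cp, rate = params$rate,
                              patient_id = pid)
    recordings[[i]] <- sim$recording
    logs[[i]] <- sim$log
    meta[[i]] <- data.frame(
      patient_id = pid, waveform_path = paste0(pid, ".csv"),
      age = pat$age, sex = pat$sex, height_cm = pat$height,
      weight_kg = pat$weight, label = labels[i])
    truth[[i]] <- data.frame(
      patient_id = pid, label = labels[i], ibi0 = pat$ibi0,
      duration = pat$duration, brs_gain = pat$brs_gain,
      brs_delay = cp$brs_delay,
      t_peak = pat$template$t_peak, t_max_up = pat$template$t_max_up,
      lvet = pat$template$lvet, dpdt = pat$template$dpdt,
      dap = pat$template$dap, pp = pat$template$pp)
    if (progress && i %% 25 == 0) message("simulated ", i, "/", n)
  }
  meta <- do.call(rbind, meta)
  meta$bsa <- bsa_du_bois(meta$height_cm, meta$weight_kg)
  truth <- do.call(rbind, truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_waveform(recordings[[i]],
                     file.path(out_dir, meta$waveform_path[i]))
    }
    write_cohort_manifest(meta, file.path(out_dir, "manifest.csv"))
    data.table::fwrite(truth, file.path(out_dir, "ground_truth.csv"),
                       eol = "\n")
  }
  list(recordings = recordings, meta = meta, truth = truth, logs = logs)
}

#' Stroke-volume calibration constant
#'
#' The pulse-contour stroke-volume surrogate is
#' `sv = k * integral over systole of (P - DAP) dt`.  The global constant
#' `k` is calibrated once so that the control-group reference beat
#' (template medians, 0.88 s cycle) yields 77 mL.
#'
#' @return `k` in mL per mmHg s.
#' @export
calibrate_sv_constant <- function() {
  if (!is.null(.pkg_cache$sv_k)) return(.pkg_cache$sv_k)
  p <- beat_template("control")
  rate <- 1000
  b <- render_beat(p, ibi = 0.88, rate = rate)
  tt <- (seq_along(b) - 1) / rate
  i <- tt <= p$lvet
  x <- tt[i]; y <- b[i] - p$dap
  a_sys <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  k <- p$true_sv / a_sys
  .pkg_cache$sv_k <- k
  k
}
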