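#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing of a pressure trace.  Output length
#' equals input length; the startup and tail transients are handled by
#' polynomial fits on the truncated edge windows (the standard
#' Savitzky-Golay edge treatment).
#'
#' @param x numeric vector or a [bp_recording()].
#' @param window odd filter length in samples (default 15, i.e. 75 ms at
#'   200 Hz).
#' @param order polynomial order (default 3).
#' @return Smoothed vector (or recording, matching the input type).
#' @export
#' @examples
#' smooth_pressure(sin(seq(0, 5, by = 0.01)) + rnorm(501, 0, 0.05))[1:5]
smooth_pressure <- function(x, window = 15L, order = 3L) {
  rec <- NULL
  if (inherits(x, "bp_recording")) {
    rec <- x
    x <- rec$pressure
  }
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2 == 0) stop("window must be odd")
  if (order < 1 || order >= window) stop("need window > order >= 1")
  if (window >= length(x)) stop("window must be shorter than the signal")
  out <- signal::sgolayfilt(x, p = order, n = window)
  if (is.null(rec)) return(out)
  rec$pressure <- out
  rec
}

# First derivative (mmHg/s) by centred differences; one-sided at the edges.
.d1_centred <- function(x, rate) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  d[1] <- (x[2] - x[1]) * rate
  d[n] <- (x[n] - x[n - 1]) * rate
  d
}

# Second derivative (mmHg/s^2) by a Savitzky-Golay differentiating filter;
# centred second differences are too noise-sensitive at 200 Hz for the
# curvature-based notch search.
.d2_sgolay <- function(x, rate, window = 21L, order = 3L) {
  window <- min(as.integer(window), length(x) - (1 - length(x) %% 2))
  if (window %% 2 == 0) window <- window - 1L
  if (window <= order + 1L) return(rep(0, length(x)))
  signal::sgolayfilt(x, p = order, n = window, m = 2, ts = 1 / rate)
}

# indices of strict interior local maxima
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(diff(sign(diff(x))) == -2) + 1L
}

#' Select the longest artefact-free segment
#'
#' An artefact is any sample outside `pressure_range` (default 20-300 mmHg)
#' or an adjacent-sample jump larger than `max_jump` (default 60 mmHg,
#' sized to catch cuff-recalibration steps).  The longest artefact-free run
#' is located and truncated to its first `max_len` seconds.
#'
#' @param rec a [bp_recording()].
#' @param max_len maximum segment length (s, default 600).
#' @param min_len admission minimum (s, default 180).
#' @param config optional [pipeline_config()] supplying the artefact
#'   thresholds.
#' @return A trimmed [bp_recording()] with `start_offset` advanced to the
#'   segment start.
#' @export
select_segment <- function(rec, max_len = 600, min_len = 180, config = NULL) {
  stopifnot(inherits(rec, "bp_recording"))
  pr <- if (is.null(config)) c(20, 300) else config$pressure_range
  mj <- if (is.null(config)) 60 else config$max_jump
  p <- rec$pressure
  bad <- p < pr[1] | p > pr[2]
  jump <- abs(diff(p)) > mj
  bad[which(jump)] <- TRUE
  bad[which(jump) + 1L] <- TRUE
  r <- rle(!bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  if (length(ok) == 0) {
    stop("no artefact-free data in recording ", rec$patient_id)
  }
  best <- ok[which.max(r$lengths[ok])]
  a <- starts[best]
  b <- min(ends[best], a + as.integer(max_len * rec$sample_rate) - 1L)
  if ((b - a + 1L) / rec$sample_rate < min_len) {
    stop(sprintf(
      "longest artefact-free window of %s is %.1f s; admission requires %g s",
      rec$patient_id, (b - a + 1L) / rec$sample_rate, min_len))
  }
  out <- rec
  out$pressure <- p[a:b]
  out$start_offset <- rec$start_offset + (a - 1L) / rec$sample_rate
  out
}

#' Segment a recording into beats
#'
#' Detects beat onsets at the pressure foot.  Steep-upstroke events are
#' first-derivative samples exceeding an adaptive threshold
#' (`upstroke_frac` times the 95th percentile of the derivative over a
#' rolling window), debounced by a refractory period; each event's onset is
#' the last local pressure minimum preceding it.  Beats shorter than 0.3 s
#' or longer than 2.0 s are marked invalid.
#'
#' @param rec a [bp_recording()]; the pressure should already be smoothed
#'   (see [smooth_pressure()]).  If `smoothed = FALSE` the recording is
#'   smoothed internally first.
#' @param config a [pipeline_config()].
#' @param smoothed whether `rec` already holds the smoothed pressure.
#' @return A `data.frame` with one row per beat: `onset_idx`, `end_idx`
#'   (index of the next onset), `onset_time`, `ibi` (s) and `valid`.
#' @export
detect_beats <- function(rec, config = pipeline_config(), smoothed = TRUE) {
  stopifnot(inherits(rec, "bp_recording"))
  rate <- rec$sample_rate
  if (recording_duration(rec) < config$min_duration_s) {
    stop(sprintf("recording %s is shorter than the %g s admission minimum",
                 rec$patient_id, config$min_duration_s))
  }
  p <- if (smoothed) rec$pressure else
    smooth_pressure(rec$pressure, config$sg_window, config$sg_order)
  n <- length(p)
  d1 <- .d1_centred(p, rate)

  block <- max(1L, as.integer(config$upstroke_roll_s * rate))
  nb <- ceiling(n / block)
  thr_block <- vapply(seq_len(nb), function(i) {
    seg <- d1[((i - 1L) * block + 1L):min(i * block, n)]
    config$upstroke_frac * stats::quantile(seg, 0.95, names = FALSE, type = 7)
  }, numeric(1))
  thr <- rep(thr_block, each = block, length.out = n)
  thr <- pmax(thr, 1e-8)

  above <- d1 > thr
  crossings <- which(above & !c(FALSE, above[-n]))
  if (length(crossings) == 0) {
    stop("insufficient data: no upstroke events detected in ",
         rec$patient_id)
  }
  refr <- as.integer(config$refractory_s * rate)
  events <- integer(length(crossings))
  k <- 0L
  last <- -refr
  for (cx in crossings) {
    if (cx - last >= refr) {
      k <- k + 1L
      events[k] <- cx
      last <- cx
    }
  }
  events <- events[seq_len(k)]

  ## foot localisation on an extra-smoothed copy: the diastolic valley is
  ## nearly flat, so residual noise would otherwise scatter the local
  ## minima over tens of milliseconds
  p_foot <- if (length(p) > 25) signal::sgolayfilt(p, p = 3, n = 25) else p
  lmin <- which(diff(sign(diff(p_foot))) == 2) + 1L
  pos <- findInterval(events - 1L, lmin)
  onset <- integer(length(events))
  for (i in seq_along(events)) {
    if (pos[i] >= 1L && events[i] - lmin[pos[i]] <= 0.5 * rate) {
      onset[i] <- lmin[pos[i]]
    } else {
      a <- max(1L, events[i] - as.integer(0.3 * rate))
      onset[i] <- a - 1L + which.min(p_foot[a:events[i]])
    }
    ## the diastolic valley is flat: centre the onset in the region that
    ## stays within 0.4 mmHg of the minimum (unbiased foot estimate)
    k <- onset[i]
    lim <- min(events[i], onset[i] + 30L, n)
    while (k + 1L <= lim && p_foot[k + 1L] <= p_foot[onset[i]] + 0.4) {
      k <- k + 1L
    }
    onset[i] <- (onset[i] + k) %/% 2L
  }
  onset <- sort(unique(onset))
  if (length(onset) < 2) {
    stop("insufficient data: fewer than two beat onsets in ", rec$patient_id)
  }
  ## low-amplitude event rejection: an "onset" whose following segment
  ## rises by less than 40% of the recording's median pulse amplitude is
  ## a secondary (e.g. dicrotic) event; dropping it merges the segment
  ## back into its beat
  if (length(onset) > 2) {
    amp <- vapply(seq_len(length(onset) - 1L), function(i) {
      max(p[onset[i]:(onset[i + 1L] - 1L)]) - p[onset[i]]
    }, numeric(1))
    med_amp <- stats::median(amp)
    low <- which(amp < 0.4 * med_amp & seq_along(amp) > 1L)
    if (length(low)) onset <- onset[-low]
  }
  ibi <- diff(onset) / rate
  beats <- data.frame(
    onset_idx = onset[-length(onset)],
    end_idx = onset[-1],
    onset_time = rec$start_offset + (onset[-length(onset)] - 1L) / rate,
    ibi = ibi,
    valid = ibi >= config$ibi_range[1] & ibi <= config$ibi_range[2] &
      ## exclude beats starting inside the smoothing startup transient
      onset[-length(onset)] > config$sg_window
  )
  if (sum(beats$valid) < config$min_beats) {
    stop(sprintf("insufficient data: %d valid beats in %s (need %d)",
                 sum(beats$valid), rec$patient_id, config$min_beats))
  }
  beats
}
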