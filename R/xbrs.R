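#' Resample beat-to-beat series to a uniform rate
#'
#' Step-interpolates the beat-to-beat systolic pressure and inter-beat
#' interval series onto a common uniform time base (default 1 Hz): each
#' resampled point carries the value of the most recent beat.  Gaps longer
#' than 3 s between beats are marked and later excluded from windowed
#' estimation.
#'
#' @param onset_times beat onset times (s).
#' @param sap per-beat systolic pressures (mmHg).
#' @param ibi per-beat inter-beat intervals (s).
#' @param rate resampling rate (Hz, default 1).
#' @param max_gap maximum tolerated beat gap (s, default 3).
#' @return A list with `time`, `sap`, `ibi` (uniform series; samples inside
#'   gaps are `NA`).
#' @export
beat_series_resample <- function(onset_times, sap, ibi, rate = 1,
                                 max_gap = 3) {
  stopifnot(length(onset_times) == length(sap),
            length(onset_times) == length(ibi))
  keep <- !is.na(sap) & !is.na(ibi)
  onset_times <- onset_times[keep]; sap <- sap[keep]; ibi <- ibi[keep]
  if (length(onset_times) < 2 ||
      diff(range(onset_times)) < 15) {
    stop("need at least 15 s of valid beats for resampling")
  }
  tt <- seq(onset_times[1], onset_times[length(onset_times)], by = 1 / rate)
  sap_u <- stats::approx(onset_times, sap, xout = tt, method = "constant",
                         rule = 2)$y
  ibi_u <- stats::approx(onset_times, ibi, xout = tt, method = "constant",
                         rule = 2)$y
  gaps <- which(diff(onset_times) > max_gap)
  for (g in gaps) {
    bad <- tt > onset_times[g] & tt < onset_times[g + 1]
    sap_u[bad] <- NA_real_
    ibi_u[bad] <- NA_real_
  }
  list(time = tt, sap = sap_u, ibi = ibi_u)
}

#' Windowed cross-correlation baroreflex sensitivity
#'
#' For every window start (1-s steps) the inter-beat-interval series is
#' shifted later than the systolic-pressure series by each candidate delay;
#' the delay maximising the (positive) correlation over the window is
#' selected, and when that correlation is two-sidedly significant at
#' `alpha` the window yields a gain (the regression slope of IBI on SAP,
#' ms/mmHg) and a delay `tau` (s).  Windows with non-positive best
#' correlation, insignificant correlation, zero SAP variance, or missing
#' samples are skipped.
#'
#' @param sap uniform systolic-pressure series (mmHg).
#' @param ibi uniform inter-beat-interval series (s).
#' @param rate series rate (Hz, default 1).
#' @param window window length (s, default 10).
#' @param delays candidate delays (s, default 0 to 5).
#' @param alpha two-sided significance level (default 0.01).
#' @return A `data.frame` with `window_start` (s), `gain` (ms/mmHg),
#'   `tau` (s), `correlation`.
#' @export
#' @examples
#' sap <- 120 + sin(seq_len(60))
#' ibi <- 0.8 + 0.005 * (sap - 120)
#' xbrs_windows(sap, ibi)
xbrs_windows <- function(sap, ibi, rate = 1, window = 10, delays = 0:5,
                         alpha = 0.01) {
  stopifnot(length(sap) == length(ibi))
  n <- length(sap)
  w <- as.integer(window * rate)
  dsmp <- as.integer(round(delays * rate))
  step <- max(1L, as.integer(rate))
  limit <- n - w + 1L - max(dsmp)
  if (limit < 1L) {
    return(data.frame(window_start = numeric(0), gain = numeric(0),
                      tau = numeric(0), correlation = numeric(0)))
  }
  starts <- seq(1L, limit, by = step)
  res <- vector("list", length(starts))
  for (j in seq_along(starts)) {
    s0 <- starts[j]
    x <- sap[s0:(s0 + w - 1L)]
    if (anyNA(x) || stats::sd(x) < 1e-12) next
    best_r <- -Inf; best_d <- NA_integer_; best_y <- NULL
    for (di in seq_along(dsmp)) {
      y <- ibi[(s0 + dsmp[di]):(s0 + dsmp[di] + w - 1L)]
      if (anyNA(y) || stats::sd(y) < 1e-12) next
      r <- stats::cor(x, y)
      if (r > best_r) {
        best_r <- r; best_d <- di; best_y <- y
      }
    }
    if (!is.finite(best_r) || best_r <= 0) next
    tstat <- best_r * sqrt((w - 2) / max(1 - best_r^2, 1e-15))
    pval <- 2 * stats::pt(-abs(tstat), df = w - 2)
    if (pval > alpha) next
    slope <- best_r * stats::sd(best_y) / stats::sd(x) * 1000  # ms/mmHg
    res[[j]] <- c((s0 - 1L) / rate, slope, dsmp[best_d] / rate, best_r)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) {
    return(data.frame(window_start = numeric(0), gain = numeric(0),
                      tau = numeric(0), correlation = numeric(0)))
  }
  m <- do.call(rbind, res)
  data.frame(window_start = m[, 1], gain = m[, 2], tau = m[, 3],
             correlation = m[, 4])
}

#' Summarise per-window baroreflex estimates
#'
#' Extracts the per-recording gain and tau series that enter the feature
#' summary as two of the 27 base features.
#'
#' @param estimates the window table from [xbrs_windows()].
#' @return A list with `gain` and `tau` series and their medians; both
#'   series empty when no window was accepted.
#' @export
summarize_xbrs <- function(estimates) {
  if (nrow(estimates) == 0) {
    return(list(gain = numeric(0), tau = numeric(0),
                gain_median = NA_real_, tau_median = NA_real_))
  }
  list(gain = estimates$gain, tau = estimates$tau,
       gain_median = stats::median(estimates$gain),
       tau_median = stats::median(estimates$tau))
}
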