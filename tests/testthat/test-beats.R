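# brute-force Savitzky-Golay oracle: explicit least squares per window
sg_oracle <- function(x, window, order) {
  half <- (window - 1) / 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    tt <- (lo:hi) - i
    fit <- stats::lm.fit(outer(tt, 0:order, "^"), x[lo:hi])
    out[i] <- fit$coefficients[1]
  }
  out
}

test_that("smoothing reproduces low-degree polynomials and reduces noise", {
  t <- seq(0, 1, length.out = 400)
  poly3 <- 2 + 3 * t - t^2 + 0.5 * t^3
  sm <- smooth_pressure(poly3, window = 15, order = 3)
  interior <- 8:392
  expect_lt(max(abs(sm[interior] - poly3[interior])), 1e-9)

  set.seed(1)
  noise <- rnorm(4000, sd = 1)
  expect_lt(sd(smooth_pressure(noise, 15, 3)), sd(noise))
})

test_that("smoothing matches the explicit least-squares oracle on a step", {
  x <- c(rep(0, 60), rep(10, 60))
  sm <- smooth_pressure(x, window = 15, order = 3)
  expect_equal(sm, sg_oracle(x, 15, 3), tolerance = 1e-8)
  expect_lte(max(sm), max(x) * 1.2)
})

test_that("smoothing validates its window", {
  expect_error(smooth_pressure(1:100, window = 14), "odd")
  expect_error(smooth_pressure(1:10, window = 15), "shorter")
  expect_error(smooth_pressure(1:100, window = 3, order = 3), "order")
})

test_that("beat detection recovers the generated beats", {
  sim <- cached_recording("control", duration = 600, seed = 21)
  beats <- detect_beats(smooth_pressure(sim$recording))
  nb <- sum(beats$valid)
  ## 600 s at a 0.88 s interval: about 682 beats
  expect_gt(nb, 600 / 0.88 - 4)
  expect_lt(nb, 600 / 0.88 + 4)
  expect_equal(nb, nrow(sim$log), tolerance = 0.005)

  ## onsets within 10 ms of ground truth (median absolute error)
  err <- vapply(beats$onset_time[beats$valid], function(o) {
    min(abs(sim$log$onset - o))
  }, numeric(1))
  expect_lte(median(err), 0.010)

  ## IBI median within ground truth +- 10 ms; IBIs fit in the segment
  expect_lt(abs(median(beats$ibi[beats$valid]) - median(sim$log$ibi)), 0.010)
  expect_lte(sum(beats$ibi[beats$valid]),
             recording_duration(sim$recording))
})

test_that("beat detection is deterministic and rejects flat signals", {
  sim <- cached_recording("control", duration = 300, seed = 11)
  sm <- smooth_pressure(sim$recording)
  expect_identical(detect_beats(sm), detect_beats(sm))
  flat <- bp_recording(rep(100, 200 * 200), patient_id = "flat")
  expect_error(detect_beats(flat), "insufficient|upstroke")
})

test_that("segment selection finds the longest artefact-free window", {
  sim <- cached_recording("control", duration = 600, seed = 21)
  rec <- sim$recording
  expect_equal(recording_duration(select_segment(rec)), 600)

  ## inject a 5 s artefact burst at t = 500: the 500 s prefix wins
  bad <- rec
  idx <- (500 * 200):(505 * 200)
  bad$pressure[idx] <- 400
  seg <- select_segment(bad)
  expect_equal(seg$start_offset, rec$start_offset)
  expect_equal(recording_duration(seg), 500, tolerance = 0.01)

  ## brute-force longest clean window agrees
  art <- bad$pressure < 20 | bad$pressure > 300
  art[which(abs(diff(bad$pressure)) > 60)] <- TRUE
  art[which(abs(diff(bad$pressure)) > 60) + 1L] <- TRUE
  runs <- rle(!art)
  expect_equal(length(seg$pressure),
               min(max(runs$lengths[runs$values]), 600 * 200))

  allbad <- bp_recording(rep(400, 40000), patient_id = "ab")
  expect_error(select_segment(allbad), "artefact-free")
})

test_that("recordings longer than the cap are truncated to their start", {
  sim <- cached_recording("control", duration = 300, seed = 11)
  seg <- select_segment(sim$recording, max_len = 200, min_len = 60)
  expect_equal(length(seg$pressure), 200 * 200)
  expect_equal(seg$pressure, sim$recording$pressure[1:(200 * 200)])
})
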