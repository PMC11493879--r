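test_that("a rendered median beat hits its construction targets", {
  p <- beat_template("control")
  b <- render_beat(p, ibi = 0.88, rate = 200)
  expect_length(b, 176)
  expect_lt(abs(max(b) - (p$dap + p$pp)), 0.5)
  expect_equal(b[1], p$dap, tolerance = 0.01)
  expect_true(all(b >= p$dap - 0.5))
})

test_that("template validation rejects infeasible parameters", {
  expect_error(beat_template("control", t_max_up = 0.2), "timing")
  expect_error(beat_template("control", dpdt = 100), "infeasibl")
  expect_error(beat_template("control", notch_depth = 100), "below pp")
  expect_error(render_beat(beat_template("control"), ibi = 0.3), "lvet")
})

test_that("noise-free landmark recovery holds across the parameter grid", {
  set.seed(31)
  for (i in 1:40) {
    tm <- random_template()
    b <- smooth_pressure(render_beat(tm, ibi = 0.95))
    lm <- extract_landmarks(b)
    tol <- 1 / 200 + 0.005   # one sample period plus 5 ms
    expect_lt(abs(lm$t_sap - tm$t_peak), tol)
    expect_lt(abs(lm$t_max_up - tm$t_max_up), tol)
    expect_lt(abs(lm$t_notch - tm$lvet), tol + 0.002)
  }
})

test_that("increasing the generated upstroke time shifts the extracted one", {
  extract_up <- function(t_up) {
    tm <- beat_template("control", t_max_up = t_up)
    median(vapply(1:20, function(i) {
      extract_landmarks(
        smooth_pressure(render_beat(tm, 0.88) + rnorm(176, 0, 0.5)))$t_max_up
    }, numeric(1)))
  }
  set.seed(8)
  ups <- vapply(c(0.050, 0.065, 0.080), extract_up, numeric(1))
  expect_true(all(diff(ups) > 0))
})

test_that("simulation is reproducible and honours zero-noise settings", {
  tm <- beat_template("control")
  a <- simulate_recording(tm, 0.88, 180, seed = 4)
  b <- simulate_recording(tm, 0.88, 180, seed = 4)
  expect_identical(a$recording$pressure, b$recording$pressure)
  expect_identical(a$log, b$log)

  cp0 <- coupling_params(resp_amp = 0, sap_jitter_sd = 0, pp_cv = 0,
                         time_cv = 0, ibi_jitter_sd = 0, noise_sd = 0)
  s0 <- simulate_recording(tm, 0.88, 180, couplings = cp0, seed = 4)
  expect_true(all(s0$log$ibi == s0$log$ibi[1]))
  ## identical beats: per-beat feature variance collapses to zero
  ex <- extract_recording_features(s0$recording, config = pipeline_config())
  vf <- ex$features[ex$features$valid == TRUE, ]
  expect_lt(var(vf$sap), 1e-12)
  expect_lt(var(vf$sap_time), 1e-12)
  expect_lt(var(vf$lvet), 1e-12)
})

test_that("the baroreflex coupling is recoverable from the waveform", {
  cp <- coupling_params(brs_gain = 5, brs_delay = 0, noise_sd = 0)
  sim <- simulate_recording(beat_template("control"), 0.88, 300,
                            couplings = cp, seed = 3)
  ex <- extract_recording_features(sim$recording)
  expect_gt(nrow(ex$xbrs), 10)
  expect_lt(abs(median(ex$xbrs$gain) - 5) / 5, 0.2)
})

test_that("cohort simulation produces the configured group structure", {
  co <- simulate_cohort(cohort_params(n_aos = 2, n_control = 1,
                                      couplings = coupling_params()),
                        seed = 5)
  expect_length(co$recordings, 3)
  expect_equal(sum(co$meta$label == "AoS"), 2)
  expect_equal(co$meta$patient_id, co$truth$patient_id)
  expect_true(all(vapply(co$recordings, recording_duration,
                         numeric(1)) >= 180))
  ## same seed, same cohort
  co2 <- simulate_cohort(cohort_params(n_aos = 2, n_control = 1,
                                       couplings = coupling_params()),
                         seed = 5)
  expect_identical(co$recordings[[2]]$pressure,
                   co2$recordings[[2]]$pressure)
})

test_that("cohort files round-trip through the manifest formats", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(cohort_params(n_aos = 1, n_control = 1),
                        seed = 9, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  meta <- read_cohort_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(meta), 2)
  rec <- read_waveform(meta$waveform_path[1],
                       patient_id = meta$patient_id[1])
  expect_equal(rec$pressure, round(co$recordings[[1]]$pressure, 6))
})
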