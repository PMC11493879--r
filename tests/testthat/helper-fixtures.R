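# Shared fixtures. Heavy cohort/pipeline runs are memoised per seed so that
# calibration checks and the end-to-end tests reuse the same computation.

.fixture_env <- new.env(parent = emptyenv())

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# full default-size cohort -> features -> model, cached per seed
cached_pipeline <- function(seed) {
  key <- paste0("pipe", seed)
  if (is.null(.fixture_env[[key]])) {
    co <- simulate_cohort(cohort_params(), seed = seed)
    summ <- cohort_features(co$recordings, co$meta)
    fit <- quiet(train_detection_model(summ, seed = seed))
    .fixture_env[[key]] <- list(cohort = co, summaries = summ, fit = fit)
  }
  .fixture_env[[key]]
}

# a clean 200 Hz test recording with ground truth, cached
cached_recording <- function(group = "control", duration = 300, seed = 11) {
  key <- paste0("rec", group, duration, seed)
  if (is.null(.fixture_env[[key]])) {
    sim <- simulate_recording(beat_template(group), ibi0 = 0.88,
                              duration = duration, seed = seed,
                              patient_id = paste0("fix_", group))
    .fixture_env[[key]] <- sim
  }
  .fixture_env[[key]]
}

# write a two-column waveform CSV from a time/pressure pair
write_waveform_csv <- function(path, time_s, pressure) {
  writeLines(c("time_s,pressure_mmHg",
               paste(format(time_s, scientific = FALSE, trim = TRUE),
                     pressure, sep = ",")), path)
  path
}

# random feasible beat template drawn from a wide physiological grid
random_template <- function() {
  repeat {
    t_peak <- runif(1, 0.15, 0.23)
    t_max_up <- runif(1, 0.05, min(0.095, 0.5 * t_peak))
    lvet <- runif(1, t_peak + 0.10, 0.37)
    pp <- runif(1, 60, 100)
    dpdt <- runif(1, 700, 1600)
    if (dpdt * t_peak / (pp - 3) <= 1.15) next
    return(beat_template("control",
      dap = runif(1, 65, 90), pp = pp, t_peak = t_peak,
      t_max_up = t_max_up, lvet = lvet,
      t_max_down = t_peak + 0.73 * (lvet - t_peak),
      notch_depth = runif(1, 30, min(55, pp - 9)), dpdt = dpdt))
  }
}
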