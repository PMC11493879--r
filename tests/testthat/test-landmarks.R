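test_that("the dicrotic notch is located at the ejection end", {
  p <- beat_template("aos")  # lvet 0.345
  b <- smooth_pressure(render_beat(p, ibi = 0.9))
  t_sap <- (which.max(b) - 1) / 200
  no <- locate_dicrotic_notch(b, t_sap)
  expect_gte(no$t_notch, 0.335)
  expect_lte(no$t_notch, 0.355)
  expect_gt(no$p_notch, p$dap)
  expect_lt(no$p_notch, p$dap + p$pp)

  ## shift invariance: +10 mmHg changes nothing in the timing
  no2 <- locate_dicrotic_notch(b + 10, t_sap)
  expect_equal(no2$t_notch, no$t_notch)
})

test_that("a beat without a dicrotic wave raises notch-not-found", {
  tt <- seq(0, 0.9, by = 1 / 200)
  mono <- 120 * exp(-tt / 0.4) + 40   # monotone decay, no shoulder
  expect_error(locate_dicrotic_notch(mono, t_sap = 0),
               class = "notch_not_found")
  short <- smooth_pressure(render_beat(beat_template("control"), 0.9))[1:80]
  expect_error(locate_dicrotic_notch(short, t_sap = 0.17),
               class = "notch_not_found")
})

test_that("landmarks of a rendered median beat match their parameters", {
  p <- beat_template("control")
  b <- smooth_pressure(render_beat(p, ibi = 0.88))
  lm <- extract_landmarks(b)
  expect_lt(abs(lm$t_sap - p$t_peak), 0.011)
  expect_lt(abs(lm$t_max_up - p$t_max_up), 0.0075)
  expect_lt(abs(lm$t_notch - p$lvet), 0.011)
  expect_lt(abs(lm$sap - (p$dap + p$pp)), 0.5)
  ## the onset sample sits in the filter edge fit, so DAP is looser
  expect_lt(abs(lm$dap - p$dap), 1.0)
  expect_gt(lm$max_up_slope, 0)
  expect_lt(lm$max_down_slope, 0)
  expect_lt(lm$t_max_up, lm$t_sap)
  expect_lt(lm$t_sap, lm$t_max_down)
  expect_lt(lm$t_max_down, lm$t_notch)
})

test_that("flat beats are invalid", {
  expect_error(extract_landmarks(rep(100, 200)), class = "invalid_beat")
})

test_that("the half-sine toy systole has the closed-form peak and slope", {
  ## P = 80 + 40 sin(pi t / 0.3) on [0, 0.3]: peak 120 at 0.15 s,
  ## steepest slope 40 pi / 0.3 at t -> 0+
  tt <- seq(0, 0.3, by = 1 / 2000)
  p <- 80 + 40 * sin(pi * tt / 0.3)
  expect_equal(max(p), 120)
  expect_equal(tt[which.max(p)], 0.15)
  d1 <- aoswave:::.d1_centred(p, 2000)
  expect_equal(max(d1), 40 * pi / 0.3, tolerance = 0.01)
  expect_lte(tt[which.max(d1)], 0.002)
})

test_that("per-beat features satisfy their algebraic identities", {
  p <- beat_template("control")
  b <- smooth_pressure(render_beat(p, ibi = 0.88))
  lm <- extract_landmarks(b)
  f <- compute_beat_features(lm, b, meta = list(bsa = 2.0))
  expect_equal(f[["pp"]], f[["sap"]] - f[["dap"]])
  expect_equal(f[["auc_sap_pct"]] + f[["auc_dap_pct"]], 100,
               tolerance = 1e-9)
  expect_equal(f[["hr"]], 60 / f[["ibi"]])
  expect_equal(f[["sw"]], f[["sv"]] * f[["map"]])
  expect_equal(f[["svr"]], 80 * f[["map"]] / f[["co"]])
  expect_equal(f[["svi"]], f[["sv"]] / 2.0)
  expect_equal(f[["svri"]], f[["svr"]] * 2.0)
  expect_equal(f[["lvet"]], f[["notch_time"]])
})

test_that("svr magnitude follows 80 * MAP / CO", {
  expect_equal(80 * 105 / 5.3, 1584.9, tolerance = 0.001)
})

test_that("a rectangular beat with a centred notch splits its area 50/50", {
  ibi <- 0.8
  b <- rep(100, ibi * 200 + 1)
  lm <- structure(list(
    sap = 100, t_sap = 0.1, dap = 100, t_notch = ibi / 2, p_notch = 100,
    t_max_up = 0.05, p_max_up = 100, max_up_slope = 1,
    t_max_down = 0.2, p_max_down = 100, max_down_slope = -1,
    duration = ibi), class = "beat_landmarks")
  f <- compute_beat_features(lm, b, ibi = ibi)
  expect_equal(f[["auc_sap_pct"]], 50)
  expect_equal(f[["map"]], 100)
})

test_that("integral features match a 10x-oversampled Riemann oracle", {
  set.seed(99)
  worst <- 0
  for (i in 1:100) {
    tm <- random_template()
    ibi <- runif(1, tm$lvet + 0.3, 1.1)
    n200 <- ceiling(ibi * 200)
    b <- render_beat(tm, ibi, rate = 200, n_samples = n200)
    lm <- tryCatch(extract_landmarks(b), error = function(e) NULL)
    if (is.null(lm)) next
    f <- compute_beat_features(lm, b, meta = list(bsa = 1.9))

    ## Riemann oracle on the same sampled beat, linearly oversampled 10x
    tt <- (seq_len(n200) - 1) / 200
    tf <- seq(0, max(tt), by = 1 / 2000)
    bf <- approx(tt, b, xout = tf)$y
    h <- 1 / 2000
    tot <- sum(bf[tf < max(tt)]) * h
    asys <- sum(bf[tf < lm$t_notch]) * h
    dur <- max(tt)
    oracle <- c(
      map = tot / dur,
      auc_sap_pct = 100 * asys / tot,
      auc_notch_pct = 100 * sum(pmax(bf[tf < max(tt)] - lm$p_notch, 0)) *
        h / tot,
      sv = pipeline_config()$sv_k * (asys - lm$dap * lm$t_notch))
    for (nm in names(oracle)) {
      relerr <- abs(f[[nm]] - oracle[[nm]]) / abs(oracle[[nm]])
      worst <- max(worst, relerr)
    }
  }
  expect_lt(worst, 0.005)
})

test_that("dpdt equals the brute-force maximum finite-difference slope", {
  set.seed(5)
  p <- beat_template("control")
  b <- smooth_pressure(render_beat(p, ibi = 0.88) + rnorm(176, 0, 1))
  lm <- extract_landmarks(b)
  n <- length(b)
  brute <- -Inf
  for (i in 2:(n - 1)) {
    brute <- max(brute, (b[i + 1] - b[i - 1]) * 200 / 2)
  }
  expect_identical(lm$max_up_slope, brute)
})
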