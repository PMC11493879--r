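test_that("stratified split reproduces the cohort arithmetic", {
  y <- rep(c("AoS", "noAoS"), c(101, 48))
  sp <- stratified_split(y, 0.75, seed = 3)
  expect_length(sp$test, 38)   # ceiling(0.25 * 149)
  tr <- table(y[sp$train])
  expect_equal(unname(tr[["AoS"]]), 75)
  expect_equal(unname(tr[["noAoS"]]), 36)
  expect_setequal(c(sp$train, sp$test), seq_along(y))

  ## determinism
  expect_identical(sp, stratified_split(y, 0.75, seed = 3))
  expect_false(identical(sp$train,
                         stratified_split(y, 0.75, seed = 4)$train))

  ## tiny balanced cohort: 3 train / 1 test
  sp4 <- stratified_split(c("a", "a", "b", "b"), 0.75, seed = 1)
  expect_length(sp4$train, 3)
  expect_length(sp4$test, 1)

  expect_error(stratified_split(rep("a", 5)), "two classes")
})

test_that("SMOTE balances the minority class on neighbour segments", {
  set.seed(20)
  x <- rbind(matrix(rnorm(75 * 4, 5), ncol = 4),
             matrix(rnorm(36 * 4, 0), ncol = 4))
  y <- rep(c("AoS", "noAoS"), c(75, 36))
  out <- smote_oversample(x, y, k = 5, seed = 2)
  expect_equal(sum(out$y == "noAoS"), 75)
  expect_equal(sum(out$y == "AoS"), 75)
  expect_equal(sum(out$synthetic), 39)
  ## originals retained verbatim
  expect_equal(unname(out$x[1:111, ]), unname(x))

  ## synthetic coordinates are convex combinations of minority points
  minx <- x[y == "noAoS", ]
  syn <- out$x[out$synthetic, ]
  expect_true(all(syn >= min(minx) - 1e-12 & syn <= max(minx) + 1e-12))

  ## two-point minority: all synthetics on the connecting segment
  x2 <- rbind(matrix(rnorm(20 * 2), ncol = 2),
              matrix(c(0, 0, 1, 2), ncol = 2, byrow = TRUE))
  y2 <- rep(c("maj", "min"), c(20, 2))
  expect_warning(o2 <- smote_oversample(x2, y2, k = 5, seed = 3),
                 "k reduced")
  syn2 <- o2$x[o2$synthetic, ]
  lam <- syn2[, 1] / 1
  expect_equal(syn2[, 2], 2 * lam, tolerance = 1e-12)
  expect_true(all(lam >= -1e-12 & lam <= 1 + 1e-12))

  ## determinism
  expect_identical(out, smote_oversample(x, y, k = 5, seed = 2))
})

test_that("min-max normalisation follows the fitted training transform", {
  x <- cbind(a = c(2, 4, 6), b = c(1, 1, 2))
  norm <- fit_normalizer(x)
  expect_equal(unname(apply_normalizer(norm, x)[, 1]), c(0, 0.5, 1))
  ## test data may leave [0, 1]
  expect_equal(unname(apply_normalizer(norm, cbind(8, 2))[1, 1]), 1.5)
  ## inverse round-trip
  z <- apply_normalizer(norm, x)
  expect_equal(unname(apply_normalizer(norm, z, inverse = TRUE)),
               unname(x), tolerance = 1e-12)
  ## constant columns map to 0 with a warning
  expect_warning(ncst <- fit_normalizer(cbind(c(1, 1, 1))), "constant")
  expect_true(all(apply_normalizer(ncst, cbind(c(1, 1, 1))) == 0))
})

test_that("AUROC follows the Mann-Whitney formulation with tie handling", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "single-class")

  ## trapezoidal ROC integration oracle (exact equivalence)
  set.seed(21)
  for (i in 1:20) {
    sc <- round(runif(40), 2)   # force ties
    y <- runif(40) < 0.4
    if (all(y) || !any(y)) next
    th <- sort(unique(c(-Inf, sc, Inf)), decreasing = TRUE)
    fpr <- sapply(th, function(t0) sum(sc >= t0 & !y) / sum(!y))
    tpr <- sapply(th, function(t0) sum(sc >= t0 & y) / sum(y))
    trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    expect_equal(auroc(sc, y), trap, tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  sc <- runif(60); y <- runif(60) < 0.5
  ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(sc, y), ref, tolerance = 1e-12)
})

test_that("evaluation reproduces diagnostic metrics from counts", {
  ## counts: 21 true/5 false of 26 positives; 8 true/4 false of 12 negatives
  m <- confusion_metrics(tp = 21, fp = 4, tn = 8, fn = 5)
  expect_equal(unname(round(m, 2)), c(0.81, 0.67, 0.76, 0.84, 0.62))

  ## a score vector realising those counts at threshold 0.5
  y <- c(rep(TRUE, 26), rep(FALSE, 12))
  sc <- c(seq(0.55, 0.95, length.out = 21), rep(0.4, 5),
          rep(0.6, 4), seq(0.05, 0.45, length.out = 8))
  rep_ <- evaluate_classifier(sc, y, threshold = 0.5)
  expect_equal(c(rep_$tp, rep_$fp, rep_$tn, rep_$fn), c(21, 4, 8, 5))
  expect_equal(unname(rep_$metrics_2dp),
               c(0.81, 0.67, 0.76, 0.84, 0.62))
  ## metrics recompute from the emitted counts exactly
  expect_equal(rep_$metrics,
               confusion_metrics(rep_$tp, rep_$fp, rep_$tn, rep_$fn))

  perfect <- evaluate_classifier(c(0.9, 0.8, 0.1), c(TRUE, TRUE, FALSE))
  expect_equal(perfect$auroc, 1)
  expect_equal(unname(perfect$metrics), rep(1, 5))
  expect_error(evaluate_classifier(1:3 / 3, c(TRUE, TRUE, TRUE)),
               "single-class")
})

test_that("grid search optimises cross-validated AUROC", {
  set.seed(23)
  n <- 48
  x <- cbind(x1 = c(rnorm(n / 2, 3), rnorm(n / 2, -3)),
             x2 = rnorm(n))
  y <- factor(rep(c("AoS", "noAoS"), each = n / 2),
              levels = c("noAoS", "AoS"))
  fit <- grid_search_train(x, y, seed = 1, families = "logistic")
  lr <- fit$cv_report[fit$cv_report$family == "logistic", ]
  expect_true(any(lr$mean_auroc == 1))
  expect_true(any(grepl("C=10$", lr$params)))   # the reference optimum
  expect_equal(fit$family, "logistic")

  ## permuted labels: chance-level CV performance
  set.seed(24)
  yp <- sample(y)
  fitp <- grid_search_train(x, yp, seed = 1, families = "logistic")
  expect_lt(max(fitp$cv_report$mean_auroc), 0.75)
  expect_gt(max(fitp$cv_report$mean_auroc), 0.3)

  expect_error(grid_search_train(x[1:6, ], y[c(1:3, 25:27)], cv_folds = 4),
               "fewer members")
})

test_that("all five classifier families fit and score", {
  set.seed(25)
  n <- 40
  x <- cbind(a = c(rnorm(n / 2, 2), rnorm(n / 2, -2)), b = rnorm(n))
  y <- factor(rep(c("noAoS", "AoS"), each = n / 2),
              levels = c("noAoS", "AoS"))
  fit <- grid_search_train(x, y, grid = list(
    logistic = data.frame(C = 1), knn = data.frame(k = 3),
    tree = data.frame(maxdepth = 3),
    svm = data.frame(C = 1, kernel = "linear"),
    rf = data.frame(ntree = 50)), seed = 2)
  expect_s3_class(fit, "aos_model")
  expect_equal(nrow(fit$cv_report), 5)
  expect_true(all(fit$cv_report$mean_auroc >= 0.5))
  sc <- predict(fit, x)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_gt(auroc(sc, y), 0.9)
})

test_that("the leakage-conservative order is available alongside the default", {
  set.seed(30)
  mk <- function(id, lab, mu) {
    v <- stats::setNames(rnorm(135, mu), feature_column_names())
    feature_summary(v, patient_id = id, age = 70, label = lab,
                    age_adjusted = TRUE)
  }
  summ <- c(lapply(1:24, function(i) mk(paste0("a", i), "AoS", 1)),
            lapply(1:12, function(i) mk(paste0("n", i), "noAoS", -1)))
  fit <- quiet(train_detection_model(
    summ, seed = 2, families = "logistic", paranoid = TRUE))
  expect_s3_class(fit$report, "evaluation_report")
  expect_s3_class(fit$paranoid$report, "evaluation_report")
  ## both orders see the same split and a well-separated problem
  expect_gt(fit$report$auroc, 0.9)
  expect_gt(fit$paranoid$report$auroc, 0.9)
})
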