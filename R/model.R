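#' Stratified train/test split
#'
#' The test set holds `ceiling((1 - train_fraction) * n)` patients; the
#' per-class training counts are allocated proportionally to the class
#' frequencies by largest-remainder rounding, and the assignment within
#' each class is random under the seed.
#'
#' @param y factor (or character) of class labels.
#' @param train_fraction training fraction (default 0.75).
#' @param seed integer seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
#' @examples
#' y <- rep(c("AoS", "noAoS"), c(101, 48))
#' sp <- stratified_split(y, seed = 1)
#' table(y[sp$train])
stratified_split <- function(y, train_fraction = 0.75, seed = 1) {
  y <- as.factor(y)
  n <- length(y)
  if (nlevels(droplevels(y)) < 2) stop("need two classes to split")
  n_test <- ceiling((1 - train_fraction) * n)
  n_train <- n - n_test
  counts <- table(y)
  exact <- as.numeric(counts) / n * n_train
  base <- floor(exact)
  rem <- exact - base
  short <- n_train - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  names(base) <- names(counts)
  set.seed(seed)
  train <- integer(0)
  for (cl in names(counts)) {
    idx <- which(y == cl)
    take <- sample(idx, base[cl])
    train <- c(train, take)
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' SMOTE oversampling
#'
#' Balances a two-class training set by synthesising minority-class rows:
#' each synthetic row is `x_i + runif(1) * (x_nn - x_i)` for a random
#' minority row `x_i` and one of its `k` nearest minority neighbours
#' (Euclidean distance).  Originals are retained; the minority count is
#' raised to the majority count.
#'
#' @param x numeric feature matrix.
#' @param y factor/character labels (two classes).
#' @param k number of nearest neighbours (default 5); reduced with a
#'   warning when the minority class has `k` or fewer rows.
#' @param seed integer seed.
#' @return A list with the balanced `x`, `y`, and `synthetic` (logical
#'   flag per returned row).
#' @export
smote_oversample <- function(x, y, k = 5, seed = 1) {
  x <- as.matrix(x)
  y <- as.factor(y)
  counts <- table(droplevels(y))
  if (length(counts) != 2) stop("smote_oversample needs exactly two classes")
  minority <- names(counts)[which.min(counts)]
  n_min <- min(counts); n_maj <- max(counts)
  n_syn <- n_maj - n_min
  if (n_syn == 0) {
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
  }
  if (n_min <= k) {
    k <- n_min - 1L
    warning("minority class has too few rows; k reduced to ", k)
  }
  if (k < 1) stop("minority class too small for SMOTE")
  xm <- x[y == minority, , drop = FALSE]
  dm <- as.matrix(stats::dist(xm))
  diag(dm) <- Inf
  nn <- t(matrix(apply(dm, 1, function(r) order(r)[seq_len(k)]), nrow = k))
  set.seed(seed)
  base_i <- sample.int(n_min, n_syn, replace = TRUE)
  nn_j <- nn[cbind(base_i, sample.int(k, n_syn, replace = TRUE))]
  lam <- stats::runif(n_syn)
  syn <- xm[base_i, , drop = FALSE] +
    lam * (xm[nn_j, , drop = FALSE] - xm[base_i, , drop = FALSE])
  rownames(syn) <- sprintf("syn%03d", seq_len(n_syn))
  out_x <- rbind(x, syn)
  out_y <- factor(c(as.character(y), rep(minority, n_syn)),
                  levels = levels(y))
  list(x = out_x, y = out_y,
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_syn)))
}

#' Fit a column-wise min-max normalizer
#'
#' Learns the affine map sending each training column's minimum to 0 and
#' maximum to 1.  Constant columns are mapped to 0 with a warning.  The
#' same fitted transform is applied to test data, whose values may fall
#' outside `[0, 1]`.
#'
#' @param x training matrix.
#' @return Object of class `"minmax_normalizer"`.
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  const <- hi - lo <= 0
  if (any(const)) {
    warning(sum(const), " constant column(s) mapped to 0")
  }
  structure(list(min = lo, range = ifelse(const, 1, hi - lo),
                 constant = const),
            class = "minmax_normalizer")
}

#' Apply (or invert) a fitted min-max transform
#' @param norm a `"minmax_normalizer"`.
#' @param x matrix to transform.
#' @param inverse map from the unit scale back to the original scale.
#' @return Transformed matrix.
#' @export
apply_normalizer <- function(norm, x, inverse = FALSE) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(norm$min))
  if (inverse) {
    out <- sweep(sweep(x, 2, norm$range, "*"), 2, norm$min, "+")
  } else {
    out <- sweep(sweep(x, 2, norm$min, "-"), 2, norm$range, "/")
    out[, norm$constant] <- 0
  }
  out
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' `P(score_pos > score_neg) + 0.5 P(score_pos = score_neg)` over all
#' positive/negative pairs, computed from midranks.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical/factor; the positive class is `TRUE`, or the
#'   second factor level.
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE))
auroc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("AUROC undefined: single-class labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Default hyperparameter grids
#'
#' Modest documented grids for the five classifier families: logistic
#' regression (inverse regularisation `C`), k-nearest neighbours (`k`),
#' decision tree (`maxdepth`), support vector machine (`C` x kernel) and
#' random forest (`ntree`).
#'
#' @return Named list of data.frames, one per family, in tie-break order.
#' @export
default_model_grid <- function() {
  list(
    logistic = data.frame(C = c(0.01, 0.1, 1, 10, 100)),
    knn = data.frame(k = c(3, 5, 7, 11)),
    tree = data.frame(maxdepth = c(2, 3, 5, 30)),
    svm = expand.grid(C = c(0.1, 1, 10), kernel = c("linear", "radial"),
                      stringsAsFactors = FALSE),
    rf = data.frame(ntree = c(100, 300)))
}

## -- family fit/predict backends -------------------------------------------
## scores are always P(positive class); positive = second factor level

.fit_one <- function(family, par, x, y, seed) {
  set.seed(seed)
  pos <- levels(y)[2]
  switch(family,
    logistic = {
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                            lambda = 1 / (par$C * nrow(x)),
                            maxit = 500000L, standardize = FALSE)
      list(fit = fit, predict = function(model, newx) {
        as.numeric(predict(model$fit, as.matrix(newx), type = "response"))
      })
    },
    knn = {
      list(fit = list(x = x, y = y, k = par$k),
           predict = function(model, newx) {
             pr <- class::knn(model$fit$x, as.matrix(newx), model$fit$y,
                              k = model$fit$k, prob = TRUE)
             p <- attr(pr, "prob")
             ifelse(pr == pos, p, 1 - p)
           })
    },
    tree = {
      df <- data.frame(y = y, x)
      fit <- rpart::rpart(y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = par$maxdepth, cp = 0.001,
                            xval = 0))
      list(fit = fit, predict = function(model, newx) {
        predict(model$fit, data.frame(as.matrix(newx)))[, pos]
      })
    },
    svm = {
      fit <- e1071::svm(x, y, kernel = par$kernel, cost = par$C,
                        probability = TRUE, scale = FALSE)
      list(fit = fit, predict = function(model, newx) {
        pr <- predict(model$fit, as.matrix(newx), probability = TRUE)
        attr(pr, "probabilities")[, pos]
      })
    },
    rf = {
      fit <- randomForest::randomForest(x, y, ntree = par$ntree)
      list(fit = fit, predict = function(model, newx) {
        predict(model$fit, as.matrix(newx), type = "prob")[, pos]
      })
    },
    stop("unknown classifier family: ", family))
}

# stratified fold assignment
.cv_folds <- function(y, nfold, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(nfold), length(idx))
  }
  fold
}

#' Grid-searched classifier training
#'
#' Evaluates every (family, hyperparameter) candidate by stratified
#' 4-fold cross-validated mean AUROC on the balanced training set, then
#' refits the best candidate on the full training set.  Ties are broken
#' by family order (logistic regression, k-nearest neighbours, decision
#' tree, support vector machine, random forest) and then by grid order
#' (simpler settings first).
#'
#' @param x training matrix (already oversampled and normalized).
#' @param y training labels (factor; positive class second level).
#' @param grid candidate grids ([default_model_grid()]).
#' @param cv_folds number of folds (default 4).
#' @param seed integer seed (controls fold assignment and stochastic
#'   fits).
#' @param families optional subset of family names to search.
#' @return Object of class `"aos_model"`: the refitted best classifier
#'   plus a `cv_report` data.frame (mean and SD of the per-fold AUROC for
#'   every candidate).
#' @export
grid_search_train <- function(x, y, grid = default_model_grid(),
                              cv_folds = 4, seed = 1, families = NULL) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2)
  if (min(table(y)) < cv_folds) {
    stop("a class has fewer members than cv_folds")
  }
  if (!is.null(families)) grid <- grid[families]
  fold <- .cv_folds(y, cv_folds, seed)
  for (f in seq_len(cv_folds)) {
    if (nlevels(droplevels(y[fold == f])) < 2) {
      stop("degenerate fold ", f, ": single class")
    }
  }
  report <- list()
  for (family in names(grid)) {
    g <- grid[[family]]
    for (i in seq_len(nrow(g))) {
      par <- as.list(g[i, , drop = FALSE])
      aucs <- vapply(seq_len(cv_folds), function(f) {
        tr <- fold != f
        m <- .fit_one(family, par, x[tr, , drop = FALSE], y[tr],
                      seed = seed + f)
        auroc(m$predict(m, x[!tr, , drop = FALSE]), y[!tr])
      }, numeric(1))
      report[[length(report) + 1L]] <- data.frame(
        family = family, params = paste(names(par), unlist(par),
                                        sep = "=", collapse = ","),
        mean_auroc = mean(aucs), sd_auroc = stats::sd(aucs))
    }
  }
  report <- do.call(rbind, report)
  best_i <- which.max(report$mean_auroc)  # which.max: earliest on ties
  best_family <- report$family[best_i]
  grid_row <- sum(report$family[seq_len(best_i)] == best_family)
  best_par <- as.list(grid[[best_family]][grid_row, , drop = FALSE])
  final <- .fit_one(best_family, best_par, x, y, seed = seed)
  structure(list(family = best_family, params = best_par,
                 model = final, levels = levels(y),
                 feature_names = colnames(x), cv_report = report,
                 seed = seed),
            class = "aos_model")
}

#' @export
print.aos_model <- function(x, ...) {
  cat(sprintf("<aos_model> %s (%s); CV AUROC %.3f (SD %.3f)\n",
              x$family,
              paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", "),
              max(x$cv_report$mean_auroc),
              x$cv_report$sd_auroc[which.max(x$cv_report$mean_auroc)]))
  invisible(x)
}

#' Predict class probabilities from a fitted detection model
#' @param object an `"aos_model"`.
#' @param newdata feature matrix on the model's normalized scale.
#' @param ... unused.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict.aos_model <- function(object, newdata, ...) {
  object$model$predict(object$model, newdata)
}

#' Evaluate a classifier on a test set
#'
#' Computes the Mann-Whitney AUROC of the probability scores plus the
#' confusion matrix and derived diagnostic metrics at the given
#' probability threshold.
#'
#' @param scores positive-class probabilities, or an `"aos_model"` (then
#'   `x` must be supplied).
#' @param y true labels (factor; positive class second level, or
#'   logical).
#' @param threshold decision threshold (default 0.5).
#' @param x test matrix when `scores` is a model.
#' @return An `"evaluation_report"`: counts `tp, fp, tn, fn`, proportions
#'   `sensitivity, specificity, accuracy, ppv, npv` (plus 2-decimal
#'   rounded versions), `auroc`, and the ROC curve points.
#' @export
#' @examples
#' evaluate_classifier(c(0.9, 0.6, 0.4, 0.2), c(TRUE, TRUE, FALSE, FALSE))
evaluate_classifier <- function(scores, y, threshold = 0.5, x = NULL) {
  if (inherits(scores, "aos_model")) {
    stopifnot(!is.null(x))
    scores <- predict(scores, x)
  }
  if (is.factor(y)) y <- y == levels(y)[2]
  y <- as.logical(y)
  if (all(y) || !any(y)) stop("AUROC undefined: single-class test set")
  au <- auroc(scores, y)
  pred <- scores >= threshold
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)
  mets <- c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
            accuracy = (tp + tn) / length(y),
            ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
            npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
  th <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  roc <- t(vapply(th, function(t0) {
    c(fpr = sum(scores >= t0 & !y) / sum(!y),
      tpr = sum(scores >= t0 & y) / sum(y))
  }, c(fpr = 0, tpr = 0)))
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 metrics = mets, metrics_2dp = round(mets, 2),
                 auroc = au, threshold = threshold,
                 roc = as.data.frame(roc)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    paste0("<evaluation_report> AUROC %.3f | tp %d fp %d tn %d fn %d | ",
           "sens %.2f spec %.2f acc %.2f ppv %.2f npv %.2f\n"),
    x$auroc, x$tp, x$fp, x$tn, x$fn,
    x$metrics_2dp["sensitivity"], x$metrics_2dp["specificity"],
    x$metrics_2dp["accuracy"], x$metrics_2dp["ppv"], x$metrics_2dp["npv"]))
  invisible(x)
}

#' Diagnostic metrics from confusion-matrix counts
#'
#' @param tp,fp,tn,fn confusion-matrix counts (positive = disease).
#' @return Named vector: sensitivity, specificity, accuracy, ppv, npv.
#' @export
#' @examples
#' round(confusion_metrics(tp = 21, fp = 4, tn = 8, fn = 5), 2)
confusion_metrics <- function(tp, fp, tn, fn) {
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    ppv = tp / (tp + fp), npv = tn / (tn + fn))
}
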