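# Two feature-selection arms over the curated matrix: random-forest
# variable importances (mean decrease accuracy and Gini decrease) cut by
# the boxplot-notch rule, and L1-penalised logistic regression with the
# penalty tuned by cross-validated deviance. Plus the classification
# losses (Gini impurity, binomial deviance, misclassification) and
# held-out evaluation metrics.

#' Gini impurity of a class distribution
#'
#' `sum(p * (1 - p))`; for a binary node it is maximal (0.5) at a 50/50
#' split and 0 at a pure node.
#'
#' @param class_probabilities Nonnegative probabilities summing to 1.
#' @return The impurity.
#' @export
gini_impurity <- function(class_probabilities) {
  p <- class_probabilities
  if (any(p < 0)) stop("class probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-8) stop("class probabilities must sum to 1 (within 1e-8)")
  sum(p * (1 - p))
}

#' Binomial deviance of predicted probabilities
#'
#' `-2 * sum(y * log(p) + (1 - y) * log(1 - p))`, with probabilities
#' clipped to `[1e-12, 1 - 1e-12]`.
#'
#' @param y Binary outcome vector.
#' @param p_hat Predicted probabilities, same length.
#' @return Nonnegative deviance.
#' @export
binomial_deviance <- function(y, p_hat) {
  if (length(y) != length(p_hat)) stop("length mismatch between y and p_hat")
  eps <- 1e-12
  p <- pmin(pmax(p_hat, eps), 1 - eps)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Misclassification error
#'
#' Overall fraction of mismatching labels.
#'
#' @param y Binary outcome vector (non-empty).
#' @param predicted_class Binary predictions, same length.
#' @return Fraction in `[0, 1]`.
#' @export
misclassification_error <- function(y, predicted_class) {
  if (length(y) == 0) stop("empty input")
  if (length(y) != length(predicted_class)) stop("length mismatch")
  mean(y != predicted_class)
}

#' Train/test split plan
#'
#' @param train_fraction Fraction of records used for fitting (default
#'   0.7, testing on the remaining 30 percent).
#' @param cv_folds Folds for the lasso cross-validation (default 10).
#' @param seed Seed governing the split and fold assignment.
#' @return A `split_plan` list.
#' @export
split_plan <- function(train_fraction = 0.7, cv_folds = 10, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, cv_folds >= 2)
  structure(list(train_fraction = train_fraction, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)), class = "split_plan")
}

#' Seeded train/test record split
#'
#' @param n Number of records.
#' @param plan A [split_plan()].
#' @return List with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(n, plan = split_plan()) {
  set.seed(plan$seed)
  train <- sort(sample.int(n, floor(n * plan$train_fraction)))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Random-forest variable importances
#'
#' Grows two forests with identical settings: one reporting permutation
#' importance (mean decrease accuracy, MDA: the average over trees of
#' the rise in out-of-bag misclassification error after permuting the
#' variable's values) and one reporting total Gini impurity decrease.
#'
#' @param x Predictor matrix or data frame (binary/numeric columns).
#' @param y Binary outcome (two classes required).
#' @param num_trees Trees per forest (default 500).
#' @param mtry Candidate variables per split (default `floor(sqrt(p))`).
#' @param seed Seed; forests are grown single-threaded so the result is
#'   reproducible.
#' @return An `importance_table` data frame: variable, mda, gini_decrease.
#' @export
rf_importances <- function(x, y, num_trees = 500, mtry = NULL, seed = 1L) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2) stop("outcome has a single class; importances undefined")
  yf <- factor(y, levels = sort(unique(y)))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  f_mda <- ranger::ranger(x = x, y = yf, num.trees = num_trees, mtry = mtry,
                          importance = "permutation", seed = seed, num.threads = 1,
                          verbose = FALSE)
  f_gini <- ranger::ranger(x = x, y = yf, num.trees = num_trees, mtry = mtry,
                           importance = "impurity", seed = seed, num.threads = 1,
                           verbose = FALSE)
  out <- data.frame(variable = colnames(x),
                    mda = unname(f_mda$variable.importance[colnames(x)]),
                    gini_decrease = unname(f_gini$variable.importance[colnames(x)]),
                    stringsAsFactors = FALSE)
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Boxplot-notch selection threshold over importances
#'
#' Selects the variables whose importance exceeds
#' `median + 1.58 * IQR / sqrt(n)` -- the upper bound of the boxplot
#' notch, an approximate 95 percent confidence bound for the median --
#' where `n` is the number of values. The rule is scale-equivariant.
#'
#' @param importances Named numeric vector (>= 5 values).
#' @return List with `selected` (names above the threshold), `threshold`,
#'   `median` and `iqr`.
#' @export
boxplot_select <- function(importances) {
  if (length(importances) < 5) stop("need at least 5 importance values")
  if (is.null(names(importances))) names(importances) <- as.character(seq_along(importances))
  med <- median(importances)
  iqr <- IQR(importances)
  thr <- med + 1.58 * iqr / sqrt(length(importances))
  list(selected = names(importances)[importances > thr],
       threshold = thr, median = med, iqr = iqr)
}

#' Random-forest selection from an importance table
#'
#' Applies [boxplot_select()] to the MDA and the Gini-decrease
#' distributions and combines the two sets.
#'
#' @param importances An `importance_table` from [rf_importances()].
#' @param rule `"union"` (default: selected if above threshold on either
#'   measure) or `"intersection"`.
#' @return List with `method = "RF"`, `selected`, and per-measure
#'   thresholds.
#' @export
rf_select <- function(importances, rule = c("union", "intersection")) {
  rule <- match.arg(rule)
  mda <- boxplot_select(setNames(importances$mda, importances$variable))
  gin <- boxplot_select(setNames(importances$gini_decrease, importances$variable))
  sel <- if (rule == "union") union(mda$selected, gin$selected)
         else intersect(mda$selected, gin$selected)
  list(method = "RF", selected = intersect(importances$variable, sel),
       rule = rule, thresholds = list(mda = mda, gini = gin))
}

#' Lasso (L1-penalised logistic) selection
#'
#' Fits the regularisation path and picks the penalty minimising the
#' mean cross-validated deviance; selected variables are those with a
#' nonzero coefficient at that penalty. The intercept is never
#' penalised. A `family = "gaussian"` flag fits the squared-error form
#' of the objective instead of the logistic likelihood.
#'
#' @param x Predictor matrix.
#' @param y Binary outcome.
#' @param cv_folds Cross-validation folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param lambda Optional fixed penalty; if supplied, cross-validation is
#'   skipped and coefficients are computed exactly at this value
#'   (`lambda = 0` reproduces the unpenalised fit).
#' @param family `"binomial"` (default) or `"gaussian"`.
#' @return List with `method = "LASSO"`, `selected`, `lambda`, `beta`
#'   (named coefficient vector incl. intercept) and the underlying fit.
#' @export
lasso_select <- function(x, y, cv_folds = 10, seed = 1L, lambda = NULL,
                         family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  x <- as.matrix(x)
  if (family == "binomial" && length(unique(y)) < 2)
    stop("outcome has a single class")
  if (is.null(lambda)) {
    set.seed(seed)
    foldid <- sample(rep(seq_len(cv_folds), length.out = nrow(x)))
    cvfit <- glmnet::cv.glmnet(x, y, family = family, foldid = foldid,
                               type.measure = "deviance")
    if (!any(is.finite(cvfit$cvm))) stop("no penalty with finite cross-validated loss")
    lambda <- cvfit$lambda.min
    beta <- coef(cvfit, s = "lambda.min")
    fit <- cvfit
  } else {
    fit <- glmnet::glmnet(x, y, family = family, thresh = 1e-10)
    beta <- coef(fit, s = lambda, exact = TRUE, x = x, y = y,
                 family = family, thresh = 1e-10)
  }
  b <- as.numeric(beta)
  names(b) <- rownames(beta)
  nz <- names(b)[b != 0]
  list(method = "LASSO", selected = setdiff(nz, "(Intercept)"),
       lambda = lambda, beta = b, fit = fit, family = family)
}

#' Held-out classification metrics
#'
#' Accuracy, precision and recall at probability threshold 0.5
#' (predicted positive iff probability strictly exceeds the threshold),
#' and ROC AUC by the midrank statistic over predicted probabilities.
#'
#' @param prob Predicted probabilities on the test records.
#' @param y Observed binary outcomes.
#' @param threshold Class threshold (default 0.5).
#' @return Named list: accuracy, precision, recall, roc_auc. With a
#'   one-class test set `roc_auc` is `NA` with a warning; precision is
#'   `NA` when nothing is predicted positive.
#' @export
evaluate_classifier <- function(prob, y, threshold = 0.5) {
  if (length(prob) != length(y)) stop("length mismatch")
  if (length(y) == 0) stop("empty test set")
  pred <- as.integer(prob > threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- if (n1 == 0 || n0 == 0) {
    warning("one-class test set: ROC AUC undefined")
    NA_real_
  } else {
    r <- rank(prob)  # midranks: ties handled symmetrically
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(accuracy = mean(pred == y),
       precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       recall = if (n1 == 0) NA_real_ else tp / n1,
       roc_auc = auc)
}

#' Run both selection arms on a curated matrix
#'
#' Splits the records per the plan, runs the requested arms on the
#' training fraction and evaluates each arm's classifier on the held-out
#' records (the random-forest arm is evaluated with a probability
#' forest grown on the same training data and seed; the lasso arm with
#' the penalised fit at the chosen penalty).
#'
#' @param curated A `curated_matrix` from [apply_curation()].
#' @param plan A [split_plan()].
#' @param methods Any of `"rf"`, `"lasso"`.
#' @param num_trees Trees per forest for the RF arm.
#' @param rf_rule Combination rule for [rf_select()].
#' @return Named list of `selection_result` objects, each carrying
#'   `method`, `selected`, `metrics`, and the arm's threshold or lambda.
#' @export
run_selection <- function(curated, plan = split_plan(),
                          methods = c("rf", "lasso"), num_trees = 500,
                          rf_rule = "union") {
  stopifnot(inherits(curated, "curated_matrix"))
  methods <- match.arg(methods, c("rf", "lasso"), several.ok = TRUE)
  idx <- train_test_split(nrow(curated$x), plan)
  xtr <- curated$x[idx$train, , drop = FALSE]; ytr <- curated$y[idx$train]
  xte <- curated$x[idx$test, , drop = FALSE];  yte <- curated$y[idx$test]
  out <- list()
  if ("rf" %in% methods) {
    imp <- rf_importances(xtr, ytr, num_trees = num_trees, seed = plan$seed)
    sel <- rf_select(imp, rule = rf_rule)
    pf <- ranger::ranger(x = xtr, y = factor(ytr, levels = c(0, 1)),
                         num.trees = num_trees, probability = TRUE,
                         seed = plan$seed, num.threads = 1, verbose = FALSE)
    prob <- predict(pf, data = xte, num.threads = 1)$predictions[, "1"]
    out$rf <- structure(list(method = "RF", selected = sel$selected,
                             metrics = evaluate_classifier(prob, yte),
                             thresholds = sel$thresholds, rule = sel$rule,
                             importances = imp), class = "selection_result")
  }
  if ("lasso" %in% methods) {
    ls <- lasso_select(xtr, ytr, cv_folds = plan$cv_folds, seed = plan$seed)
    prob <- as.numeric(predict(ls$fit, newx = xte, s = ls$lambda, type = "response"))
    out$lasso <- structure(list(method = "LASSO", selected = ls$selected,
                                metrics = evaluate_classifier(prob, yte),
                                lambda = ls$lambda, beta = ls$beta),
                           class = "selection_result")
  }
  out
}

#' @export
print.selection_result <- function(x, ...) {
  cat(x$method, "selection:", length(x$selected), "variables\n")
  m <- x$metrics
  if (!is.null(m))
    cat(sprintf("  accuracy=%.3f precision=%.3f recall=%.3f auc=%.3f\n",
                m$accuracy, m$precision, m$recall, m$roc_auc))
  invisible(x)
}
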