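test_that("gini impurity matches hand evaluation and rejects bad input", {
  expect_equal(gini_impurity(c(0.5, 0.5)), 0.5)
  expect_equal(gini_impurity(c(1, 0)), 0)
  expect_equal(gini_impurity(c(0.9, 0.1)), 0.18)
  expect_error(gini_impurity(c(0.5, 0.4)), "sum to 1")
  expect_error(gini_impurity(c(1.2, -0.2)), "nonnegative")
})

test_that("binomial deviance matches hand evaluation", {
  expect_lt(binomial_deviance(c(1, 0), c(1 - 1e-12, 1e-12)), 1e-9)
  expect_equal(binomial_deviance(c(1, 0), c(0.5, 0.5)), -2 * 2 * log(0.5))
  expect_equal(binomial_deviance(1, 0.25), -2 * log(0.25))
  expect_equal(binomial_deviance(c(1, 0), c(0.5, 0.5)), 2.772589, tolerance = 1e-6)
  expect_error(binomial_deviance(c(1, 0), 0.5), "length")
})

test_that("misclassification error counts mismatches", {
  expect_equal(misclassification_error(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(misclassification_error(c(1, 0), c(0, 1)), 1)
  expect_equal(misclassification_error(c(1, 1, 0, 0), c(1, 0, 0, 0)), 0.25)
  expect_error(misclassification_error(integer(), integer()), "empty")
})

test_that("boxplot-notch threshold selects only clear outliers", {
  vals <- setNames(c(0.9, 0.95, 1.0, 1.05, 1.1, 5.0), paste0("v", 1:6))
  # hand oracle: median 1.025, IQR (type-7 quartiles) 0.125,
  # threshold 1.025 + 1.58 * 0.125 / sqrt(6) = 1.105625
  res <- boxplot_select(vals)
  expect_equal(res$threshold, 1.025 + 1.58 * 0.125 / sqrt(6))
  expect_equal(res$selected, "v6")
})

test_that("degenerate importance distributions select nothing", {
  res <- boxplot_select(setNames(rep(2, 8), paste0("v", 1:8)))
  expect_length(res$selected, 0)
  expect_error(boxplot_select(c(a = 1, b = 2)), "at least 5")
})

test_that("boxplot selection is scale-equivariant", {
  set.seed(5)
  vals <- setNames(rexp(40), paste0("v", 1:40))
  base <- boxplot_select(vals)$selected
  for (c in c(0.01, 3, 1e4))
    expect_equal(boxplot_select(vals * c)$selected, base)
})

test_that("RF importances rank a planted predictor first and are seed-stable", {
  set.seed(42)
  n <- 3000
  x <- matrix(rbinom(n * 31, 1, 0.3), n, 31,
              dimnames = list(NULL, c("planted", paste0("noise", 1:30))))
  x[, "noise1"] <- x[, "noise2"]  # duplicated noise pair
  y <- rbinom(n, 1, plogis(-1 + 2 * x[, "planted"]))
  imp <- rf_importances(x, y, num_trees = 300, seed = 7)
  expect_equal(imp$variable[which.max(imp$mda)], "planted")
  expect_equal(imp$variable[which.max(imp$gini_decrease)], "planted")
  dup_mda <- imp$mda[imp$variable %in% c("noise1", "noise2")]
  expect_true(all(dup_mda < max(imp$mda)))
  imp2 <- rf_importances(x, y, num_trees = 300, seed = 7)
  expect_identical(imp, imp2)
  expect_error(rf_importances(x, rep(1, n)), "single class")
})

test_that("permuted outcome keeps MDA inside the null band", {
  set.seed(11)
  n <- 1500
  x <- matrix(rbinom(n * 20, 1, 0.3), n, 20,
              dimnames = list(NULL, paste0("v", 1:20)))
  y <- rbinom(n, 1, plogis(-1 + 2 * x[, 1]))
  yperm <- sample(y)
  imp <- rf_importances(x, yperm, num_trees = 300, seed = 3)
  # sign-symmetric null band from the permuted importances themselves
  band <- quantile(c(imp$mda, -imp$mda), 0.99)
  expect_true(all(imp$mda <= band + 1e-12))
  imp_sig <- rf_importances(x, y, num_trees = 300, seed = 3)
  expect_gt(imp_sig$mda[1], band)
})

test_that("lasso endpoints: lambda_max empties the model, lambda=0 matches glm", {
  set.seed(2)
  n <- 1000; p <- 6
  x <- matrix(rbinom(n * p, 1, 0.3), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  y <- rbinom(n, 1, plogis(-0.5 + x[, 1] - 0.8 * x[, 2]))
  big <- lasso_select(x, y, lambda = 10)
  expect_length(big$selected, 0)
  free <- lasso_select(x, y, lambda = 0)
  ref <- glm(y ~ x, family = binomial())  # independent unpenalised fitter
  expect_equal(unname(free$beta), unname(coef(ref)), tolerance = 1e-4)
  expect_setequal(free$selected, paste0("v", 1:p))
})

test_that("cross-validated lasso recovers planted predictors", {
  set.seed(91)
  n <- 2500
  x <- matrix(rbinom(n * 40, 1, 0.3), n, 40,
              dimnames = list(NULL, c(paste0("pred", 1:5), paste0("noise", 1:35))))
  y <- rbinom(n, 1, plogis(-1 + x[, 1] + x[, 2] - x[, 3] + x[, 4] - x[, 5]))
  sel <- lasso_select(x, y, seed = 1)
  expect_true(all(paste0("pred", 1:5) %in% sel$selected))
  expect_gt(sel$lambda, 0)
})

test_that("classifier metrics follow their standard definitions", {
  perfect <- evaluate_classifier(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "roc_auc")]),
               c(accuracy = 1, precision = 1, recall = 1, roc_auc = 1))
  # all probabilities at the threshold tie-break to class 0
  flat <- evaluate_classifier(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(flat$recall, 0)
  expect_true(is.na(flat$precision))
  auc <- evaluate_classifier(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))$roc_auc
  expect_equal(auc, 0.75)  # 3 of 4 positive-negative pairs concordant
  expect_warning(one <- evaluate_classifier(c(0.2, 0.8), c(1, 1)), "one-class")
  expect_true(is.na(one$roc_auc))
})

test_that("run_selection evaluates both arms on held-out records", {
  spec <- small_block_spec(seed = 77, n = 900, n_noise = 10)
  cm <- apply_curation(generate_cohort(spec)$table, curation_config())
  res <- run_selection(cm, split_plan(seed = 5), num_trees = 150)
  expect_named(res, c("rf", "lasso"))
  for (arm in res) {
    expect_true(all(arm$selected %in% colnames(cm$x)))
    m <- arm$metrics
    expect_true(all(unlist(m[c("accuracy", "recall", "roc_auc")]) >= 0 &
                      unlist(m[c("accuracy", "recall", "roc_auc")]) <= 1))
  }
})
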