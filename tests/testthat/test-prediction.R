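test_that("progression labels follow the KL transition definition", {
  expect_identical(as.character(progression_label(0, 2)), "1")
  expect_identical(as.character(progression_label(1, 1)), "0")
  expect_identical(as.character(progression_label(3, 4)), "excluded")
  expect_identical(as.character(progression_label(1, NA)), "excluded")
  expect_identical(
    as.character(progression_label(c(0, 1, 2, 1), c(3, 0, 4, NA))),
    c("1", "0", "excluded", "excluded"))
  expect_error(progression_label(5, 2), "invalid KL grade")
  expect_error(progression_label(1, 7), "invalid KL grade")
})

test_that("a separable cohort is fit to near-perfect training F1", {
  co <- make_cohort(300, signal_strength = 1, seed = 2)
  grid <- data.frame(max_depth = 6, alpha = 1, lambda = 1)
  fit <- fit_model(co, "severity", grid = grid, seed = 3)
  prob <- predict_prob(fit, co)
  pred <- fit$classes[max.col(prob, ties.method = "first")]
  expect_gte(kneejsw:::macro_f1(co$kl_baseline, pred, fit$classes), 0.95)
})

test_that("a one-point grid is returned as-is", {
  co <- make_cohort(120, signal_strength = 1, seed = 4)
  grid <- data.frame(max_depth = 4, alpha = 0.5, lambda = 2)
  fit <- fit_model(co, "severity", grid = grid, seed = 5)
  expect_equal(fit$hyperparams$max_depth, 4)
  expect_equal(fit$hyperparams$alpha, 0.5)
  expect_equal(fit$hyperparams$lambda, 2)
})

test_that("model fitting and bootstrap evaluation are seed-deterministic", {
  co <- make_cohort(150, signal_strength = 0.8, seed = 6)
  grid <- data.frame(max_depth = c(4, 8), alpha = 1, lambda = 1)
  f1 <- fit_model(co, "severity", grid = grid, seed = 7)
  f2 <- fit_model(co, "severity", grid = grid, seed = 7)
  expect_identical(f1$hyperparams, f2$hyperparams)
  expect_identical(f1$cv_results, f2$cv_results)
  expect_identical(predict_prob(f1, co), predict_prob(f2, co))
  r1 <- evaluate_bootstrap(f1, co, n_boot = 20, seed = 8)
  r2 <- evaluate_bootstrap(f2, co, n_boot = 20, seed = 8)
  expect_identical(r1$auc_samples, r2$auc_samples)
  expect_identical(r1$macro_f1_mean, r2$macro_f1_mean)
})

test_that("single-class training labels are rejected", {
  co <- make_cohort(80, signal_strength = 1, seed = 9)
  co$kl_baseline <- 2L
  expect_error(fit_model(co, "severity"), "2 classes")
})

test_that("a perfect classifier bootstraps to AUC 1 with zero CI width", {
  co <- make_cohort(200, signal_strength = 1, seed = 10)
  # evaluated on its own training records the boosted trees separate the
  # cohort exactly, so every bootstrap resample scores AUC 1
  grid <- data.frame(max_depth = 6, alpha = 0, lambda = 1)
  fit <- fit_model(co, "severity", grid = grid, seed = 11)
  rep_train <- evaluate_bootstrap(fit, co, n_boot = 25, seed = 12)
  expect_gte(rep_train$auc_mean, 0.99)
  expect_lte(rep_train$auc_ci95, 0.02)
})

test_that("label-independent features bootstrap to chance AUC", {
  co <- make_cohort(1250, signal_strength = 0, seed = 13)
  sp <- split_records(co, "severity", prop = 0.8, seed = 14)
  grid <- data.frame(max_depth = 6, alpha = 1, lambda = 1)
  fit <- fit_model(sp$train, "severity", grid = grid, seed = 15)
  rep <- evaluate_bootstrap(fit, sp$test, n_boot = 50, seed = 16)
  expect_gte(rep$n_test, 200)
  expect_lt(abs(rep$auc_mean - 0.5), 0.07)
})

test_that("AUC monotonically improves with cohort signal strength", {
  aucs <- vapply(c(0, 0.5, 1), function(s) {
    co <- make_cohort(500, signal_strength = s, seed = 17)
    sp <- split_records(co, "severity", prop = 0.8, seed = 18)
    grid <- data.frame(max_depth = 6, alpha = 1, lambda = 1)
    fit <- fit_model(sp$train, "severity", grid = grid, seed = 19)
    evaluate_bootstrap(fit, sp$test, n_boot = 20, seed = 20)$auc_mean
  }, 0.0)
  expect_gte(aucs[2], aucs[1] - 0.05)
  expect_gte(aucs[3], aucs[2] - 0.05)
  expect_gt(aucs[3], aucs[1])
})

test_that("AUC comparison is a Welch t-test with degenerate conventions", {
  mk_rep <- function(samples)
    structure(list(auc_samples = samples), class = "kj_prediction_report")
  set.seed(21)
  x <- rnorm(100, 0.6, 0.01)
  expect_equal(compare_auc(mk_rep(x), mk_rep(x)), 1.0)
  a <- rnorm(100, 0.55, 0.001); b <- rnorm(100, 0.75, 0.001)
  expect_lt(compare_auc(mk_rep(a), mk_rep(b)), 1e-10)
  expect_equal(compare_auc(mk_rep(rep(0.7, 10)), mk_rep(rep(0.7, 10))), 1.0)
  expect_equal(compare_auc(mk_rep(rep(0.6, 10)), mk_rep(rep(0.7, 10))), 0)
  expect_error(compare_auc(mk_rep(NULL), mk_rep(x)), "auc_samples")
})

test_that("train/test splits keep subjects together", {
  co <- make_cohort(300, signal_strength = 0.5, seed = 22)
  sp <- split_records(co, "severity", prop = 0.8, seed = 23)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  frac <- nrow(sp$test) / (nrow(sp$train) + nrow(sp$test))
  expect_gt(frac, 0.12); expect_lt(frac, 0.30)
})

test_that("dyadic feature subsets select the nested site columns", {
  co <- make_cohort(60, seed = 24)
  expect_identical(jsw_feature_cols(co, "min"), "min_jsw")
  c16 <- jsw_feature_cols(co, 16L)
  expect_length(c16, 16L)
  sites <- attr(co, "sites")
  expect_equal(sites[as.integer(sub("w_", "", c16))],
               sample_sites(sampling_grid(16L)), tolerance = 1e-12)
  expect_identical(jsw_feature_cols(co, 64L), paste0("w_", 1:64))
  expect_error(jsw_feature_cols(co, 12L), "8, 16, 32, 64")
})
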