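#' 48-month progression label
#'
#' Progression is defined as the transition from an unaffected knee
#' (KL grade 0 or 1 at baseline) to a confirmed case (grade 2-4) within
#' 48 months. Knees already confirmed at baseline are excluded, as are
#' knees whose follow-up grade is missing (dropouts).
#'
#' @param kl_baseline,kl_48mo integer KL grades 0-4; `kl_48mo` may be
#'   `NA` (missing follow-up). Vectorized.
#' @return Factor with levels `"0"`, `"1"`, `"excluded"`.
#' @export
progression_label <- function(kl_baseline, kl_48mo) {
  chk <- function(g, nm, na_ok) {
    bad <- if (na_ok) !is.na(g) & !(g %in% 0:4) else !(g %in% 0:4)
    if (any(bad)) stop("invalid KL grade in ", nm)
  }
  chk(kl_baseline, "kl_baseline", na_ok = FALSE)
  chk(kl_48mo, "kl_48mo", na_ok = TRUE)
  out <- rep("excluded", length(kl_baseline))
  unaffected <- kl_baseline %in% 0:1
  out[unaffected & !is.na(kl_48mo) & kl_48mo %in% 2:4] <- "1"
  out[unaffected & !is.na(kl_48mo) & kl_48mo %in% 0:1] <- "0"
  factor(out, levels = c("0", "1", "excluded"))
}

feature_matrix <- function(records, feature_cols = NULL) {
  if (is.null(feature_cols))
    feature_cols <- grep("^(w_[0-9]+|min_jsw)$", names(records), value = TRUE)
  if (length(feature_cols) == 0L) stop("no JSW feature columns found")
  x <- as.matrix(records[, feature_cols, drop = FALSE])
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("features must be finite")
  x
}

task_labels <- function(records, task) {
  if (task == "severity") {
    y <- as.integer(records$kl_baseline)
    if (any(!(y %in% 0:4))) stop("invalid KL grade in kl_baseline")
    list(y = y, keep = rep(TRUE, nrow(records)), classes = sort(unique(y)))
  } else {
    lab <- progression_label(records$kl_baseline, records$kl_48mo)
    keep <- lab != "excluded"
    y <- as.integer(as.character(lab[keep]))
    list(y = y, keep = keep, classes = sort(unique(y)))
  }
}

#' Default hyperparameter grids
#'
#' Small grid-search spaces for the gradient-boosted models. Both grids
#' include the optimum reported for full-cohort tuning (severity:
#' depth 30, alpha 1, lambda 1; progression: depth 25, alpha 0.5,
#' lambda 1) next to a shallow alternative.
#'
#' @param task `"severity"` or `"progression"`.
#' @return Data frame with columns `max_depth`, `alpha`, `lambda`.
#' @export
default_grid <- function(task = c("severity", "progression")) {
  task <- match.arg(task)
  if (task == "severity")
    expand.grid(max_depth = c(6, 30), alpha = c(0, 1), lambda = 1)
  else
    expand.grid(max_depth = c(6, 25), alpha = c(0.5, 1), lambda = 1)
}

macro_f1 <- function(truth, pred, classes) {
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) return(NA_real_)  # class absent everywhere
    2 * tp / (2 * tp + fp + fn)
  }, 0.0)
  mean(f1, na.rm = TRUE)
}

# Macro one-vs-rest AUC; binary input reduces to the standard AUC of the
# positive-class score.
macro_auc <- function(truth, prob, classes) {
  if (length(classes) == 2L) {
    return(as.numeric(pROC::auc(
      response = factor(truth == classes[2], c(FALSE, TRUE)),
      predictor = prob[, 2L], quiet = TRUE, direction = "<")))
  }
  aucs <- vapply(seq_along(classes), function(i) {
    resp <- truth == classes[i]
    if (all(resp) || !any(resp)) return(NA_real_)
    as.numeric(pROC::auc(response = factor(resp, c(FALSE, TRUE)),
                         predictor = prob[, i], quiet = TRUE,
                         direction = "<"))
  }, 0.0)
  mean(aucs, na.rm = TRUE)
}

xgb_fit <- function(x, y01, n_class, hp, seed, nrounds = 60) {
  params <- list(max_depth = hp$max_depth, alpha = hp$alpha,
                 lambda = hp$lambda, eta = 0.3, nthread = 1,
                 seed = seed %% .Machine$integer.max)
  if (n_class > 2L) {
    params$objective <- "multi:softprob"
    params$num_class <- n_class
    params$eval_metric <- "mlogloss"
  } else {
    params$objective <- "binary:logistic"
    params$eval_metric <- "logloss"
  }
  dtrain <- xgboost::xgb.DMatrix(x, label = y01)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = nrounds, verbose = 0)
}

xgb_prob <- function(booster, x, n_class) {
  p <- predict(booster, xgboost::xgb.DMatrix(x))
  if (n_class > 2L) {
    if (!is.matrix(p)) p <- matrix(p, ncol = n_class, byrow = TRUE)
    p
  } else cbind(1 - p, p)
}

#' Fit a gradient-boosted JSW classifier with grid-searched tuning
#'
#' Trains an XGBoost tree classifier on JSW features for either 5-class
#' KL severity classification or binary 48-month progression prediction.
#' Hyperparameters (`max_depth`, `alpha`, `lambda`) are selected by
#' grid search with stratified k-fold cross-validation, scored by mean
#' CV macro F1; ties keep the first grid row. The winning setting is
#' refit on all rows. Fully seeded and single-threaded, so repeated
#' calls are reproducible.
#'
#' @param records data frame with feature columns (`w_1...` and/or
#'   `min_jsw`), `kl_baseline` and (for progression) `kl_48mo`.
#' @param task `"severity"` or `"progression"`.
#' @param grid data frame of candidate hyperparameters; defaults to
#'   [default_grid()].
#' @param cv_folds number of CV folds.
#' @param seed integer seed.
#' @param feature_cols optional explicit feature column names.
#' @return An object of class `kj_model`: list with `booster`, `task`,
#'   `classes`, `hyperparams`, `cv_results`, `feature_cols`.
#' @export
fit_model <- function(records, task = c("severity", "progression"),
                      grid = NULL, cv_folds = 5L, seed = 1L,
                      feature_cols = NULL) {
  task <- match.arg(task)
  if (is.null(grid)) grid <- default_grid(task)
  x <- feature_matrix(records, feature_cols)
  lab <- task_labels(records, task)
  x <- x[lab$keep, , drop = FALSE]
  y <- lab$y
  classes <- lab$classes
  if (length(classes) < 2L)
    stop("need at least 2 classes in the training labels")
  y01 <- match(y, classes) - 1L
  n_class <- length(classes)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  folds <- make_stratified_folds(y, cv_folds)
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    f1s <- vapply(seq_len(cv_folds), function(k) {
      tr <- folds != k
      if (length(unique(y01[tr])) < n_class) return(NA_real_)
      fit <- xgb_fit(x[tr, , drop = FALSE], y01[tr], n_class,
                     grid[g, ], seed)
      prob <- xgb_prob(fit, x[!tr, , drop = FALSE], n_class)
      pred <- classes[max.col(prob, ties.method = "first")]
      macro_f1(y[!tr], pred, classes)
    }, 0.0)
    scores[g] <- mean(f1s, na.rm = TRUE)
  }
  best <- which.max(scores)  # first maximum on ties
  booster <- xgb_fit(x, y01, n_class, grid[best, ], seed)
  structure(list(booster = booster, task = task, classes = classes,
                 hyperparams = as.list(grid[best, ]),
                 cv_results = cbind(grid, cv_macro_f1 = scores),
                 feature_cols = colnames(x)),
            class = "kj_model")
}

make_stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' @export
print.kj_model <- function(x, ...) {
  cat(sprintf("<kj_model> task=%s, classes={%s}\n", x$task,
              paste(x$classes, collapse = ",")))
  cat(sprintf("  chosen: max_depth=%g alpha=%g lambda=%g\n",
              x$hyperparams$max_depth, x$hyperparams$alpha,
              x$hyperparams$lambda))
  invisible(x)
}

#' Predicted class probabilities from a fitted model
#'
#' @param model a [fit_model()] result.
#' @param records data frame with the model's feature columns.
#' @return Matrix of class probabilities, columns ordered as
#'   `model$classes`.
#' @export
predict_prob <- function(model, records) {
  x <- feature_matrix(records, model$feature_cols)
  xgb_prob(model$booster, x, length(model$classes))
}

#' Bootstrap evaluation of a fitted classifier
#'
#' Resamples the test set with replacement `n_boot` times (resamples
#' missing a class are redrawn, at most 1000 attempts each) and computes
#' macro F1 and AUC (macro one-vs-rest for multiclass, standard for
#' binary) on each resample. Reports the bootstrap means and 95% CI
#' half-widths (`1.96 * SD` of the bootstrap samples).
#'
#' @param model a [fit_model()] result.
#' @param test_records held-out records.
#' @param n_boot number of bootstrap iterations.
#' @param seed integer seed.
#' @return An object of class `kj_prediction_report` with fields `task`,
#'   `macro_f1_mean`, `macro_f1_ci95`, `auc_mean`, `auc_ci95`,
#'   `n_bootstrap`, `n_test`, `f1_samples`, `auc_samples`, `hyperparams`.
#' @export
evaluate_bootstrap <- function(model, test_records, n_boot = 100L,
                               seed = 1L) {
  lab <- task_labels(test_records, model$task)
  recs <- test_records[lab$keep, , drop = FALSE]
  y <- lab$y
  if (nrow(recs) == 0L) stop("empty test set after exclusions")
  if (!all(model$classes %in% y))
    stop("test set must contain every training class")
  prob <- predict_prob(model, recs)
  pred <- model$classes[max.col(prob, ties.method = "first")]

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- length(y)
  f1s <- aucs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    for (attempt in seq_len(1000L)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (all(model$classes %in% y[idx])) break
      if (attempt == 1000L)
        stop("a class was never drawn in 1000 bootstrap attempts")
    }
    f1s[b] <- macro_f1(y[idx], pred[idx], model$classes)
    aucs[b] <- macro_auc(y[idx], prob[idx, , drop = FALSE], model$classes)
  }
  structure(list(task = model$task,
                 macro_f1_mean = mean(f1s),
                 macro_f1_ci95 = 1.96 * sd(f1s),
                 auc_mean = mean(aucs),
                 auc_ci95 = 1.96 * sd(aucs),
                 n_bootstrap = n_boot, n_test = n,
                 f1_samples = f1s, auc_samples = aucs,
                 hyperparams = model$hyperparams),
            class = "kj_prediction_report")
}

#' @export
print.kj_prediction_report <- function(x, ...) {
  cat(sprintf("<kj_prediction_report> task=%s, n_test=%d, %d bootstraps\n",
              x$task, x$n_test, x$n_bootstrap))
  cat(sprintf("  macro F1 = %.3f (+/- %.3f), AUC = %.3f (+/- %.3f)\n",
              x$macro_f1_mean, x$macro_f1_ci95, x$auc_mean, x$auc_ci95))
  invisible(x)
}

#' Compare the AUC of two bootstrap reports
#'
#' Welch unpaired two-sided t-test on the bootstrap AUC sample vectors.
#' When both vectors are constant the p-value is 1 if the means are
#' equal and 0 otherwise (degenerate convention).
#'
#' @param report_a,report_b [evaluate_bootstrap()] results.
#' @return Two-sided p-value.
#' @export
compare_auc <- function(report_a, report_b) {
  xa <- report_a$auc_samples; xb <- report_b$auc_samples
  if (is.null(xa) || is.null(xb)) stop("reports must carry auc_samples")
  if (length(xa) != length(xb)) stop("sample vectors differ in length")
  if (sd(xa) == 0 && sd(xb) == 0)
    return(if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0)
  t.test(xa, xb, var.equal = FALSE)$p.value
}

#' Stratified grouped train/test split
#'
#' Splits records 8:2 (by default) at the subject level, so both knees
#' of a subject land on the same side (bilateral knees are correlated),
#' approximately stratified by the subject's maximum task label.
#'
#' @param records data frame with `subject_id` and label columns.
#' @param task `"severity"` or `"progression"`.
#' @param prop training proportion.
#' @param seed integer seed.
#' @return List with data frames `train` and `test`.
#' @export
split_records <- function(records, task = c("severity", "progression"),
                          prop = 0.8, seed = 1L) {
  task <- match.arg(task)
  lab <- task_labels(records, task)
  recs <- records[lab$keep, , drop = FALSE]
  y <- lab$y
  sid <- if ("subject_id" %in% names(recs)) recs$subject_id
         else recs$knee_id
  subj_lab <- vapply(split(y, sid), max, 0)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  test_subj <- character(0)
  for (cl in unique(subj_lab)) {
    s <- sample(names(subj_lab)[subj_lab == cl])
    n_test <- max(1L, round((1 - prop) * length(s)))
    test_subj <- c(test_subj, s[seq_len(n_test)])
  }
  is_test <- sid %in% test_subj
  list(train = recs[!is_test, , drop = FALSE],
       test = recs[is_test, , drop = FALSE])
}

#' Subset dyadic JSW features from a 64-point cohort
#'
#' Selects the `n_points`-point feature subset of a 64-point profile
#' table (grids nest dyadically), or the single `min_jsw` column.
#'
#' @param records cohort data frame from [make_cohort()] (or any table
#'   with `w_1..w_64` at the canonical 64-point sites).
#' @param n_points 8, 16, 32, 64, or `"min"`.
#' @return The feature column names to pass to [fit_model()].
#' @export
jsw_feature_cols <- function(records, n_points = 16L) {
  if (identical(n_points, "min")) {
    if (!"min_jsw" %in% names(records)) stop("no min_jsw column")
    return("min_jsw")
  }
  n_points <- as.integer(n_points)
  if (!n_points %in% c(8L, 16L, 32L, 64L))
    stop("n_points must be 8, 16, 32, 64 or \"min\"")
  sites64 <- sample_sites(sampling_grid(64L))
  sites_n <- sample_sites(sampling_grid(n_points))
  idx <- vapply(sites_n, function(s) which.min(abs(sites64 - s)), 0L)
  if (max(abs(sites64[idx] - sites_n)) > 1e-9)
    stop("requested grid does not nest in the 64-point grid")
  cols <- paste0("w_", idx)
  if (!all(cols %in% names(records))) stop("missing feature columns")
  cols
}
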