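#' AdaBoost.R2 regression over depth-limited trees
#'
#' Boosted-tree regressor following the AdaBoost.R2 scheme with linear
#' loss: at each round a depth-limited regression tree (`rpart`, squared
#' error splits) is fit with the current case weights, per-case losses are
#' the absolute residuals scaled by their maximum, the weighted average
#' loss sets the stage weight `log(1/beta)` with
#' `beta = loss/(1 - loss)`, and case weights are multiplied by
#' `beta^(1 - loss_i)`. Boosting stops early when a round fits perfectly
#' or its weighted loss reaches 0.5. Case weights enter the tree fit
#' directly (deterministic weighted fitting rather than weighted
#' resampling), so training is reproducible without a random stream.
#'
#' @param x data.frame or matrix of predictors.
#' @param y numeric response.
#' @param n_estimators maximum number of boosting rounds.
#' @param max_depth maximum tree depth.
#' @return An object of class `adaboost_r2` with `trees`, `stage_weights`.
#' @seealso [predict.adaboost_r2()]
#' @export
adaboost_r2 <- function(x, y, n_estimators = 50L, max_depth = 5L) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y), n_estimators >= 1L, max_depth >= 1L)
  n <- nrow(x)
  dat <- cbind(x, .y = y)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, xval = 0,
                               minsplit = 2, minbucket = 1)
  w <- rep(1 / n, n)
  trees <- list(); stage <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "anova",
                        control = ctrl)
    pred <- stats::predict(fit, dat)
    err <- abs(y - pred)
    D <- max(err)
    if (D <= 0) {                       # perfect fit: keep it, stop boosting
      trees[[length(trees) + 1L]] <- fit
      stage <- c(stage, log(1 / 1e-10))
      break
    }
    L <- err / D                        # linear loss in [0, 1]
    eps <- sum(w * L)
    if (eps >= 0.5) {
      if (!length(trees)) { trees[[1L]] <- fit; stage <- 0 }
      break
    }
    beta <- eps / (1 - eps)
    trees[[length(trees) + 1L]] <- fit
    stage <- c(stage, log(1 / max(beta, 1e-12)))
    w <- w * beta^(1 - L)
    w <- w / sum(w)
  }
  structure(list(trees = trees, stage_weights = stage,
                 feature_names = names(x)),
            class = "adaboost_r2")
}

#' Predict from an AdaBoost.R2 model
#'
#' Predictions are the weighted median of the stage predictions, weighted
#' by the stage weights `log(1/beta)` (the AdaBoost.R2 aggregation rule).
#'
#' @param object an [adaboost_r2()] fit.
#' @param newdata data.frame of predictors.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.adaboost_r2 <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  P <- vapply(object$trees, function(tr) stats::predict(tr, newdata),
              numeric(nrow(newdata)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  w <- object$stage_weights
  if (length(w) == 1L) return(as.numeric(P))
  apply(P, 1L, weighted_median, w = w)
}

# weighted median: smallest value whose cumulative weight reaches half
weighted_median <- function(v, w) {
  o <- order(v)
  cw <- cumsum(w[o])
  v[o][which(cw >= 0.5 * sum(w))[1L]]
}

#' Model specification for the pressure regressors
#'
#' @param n_estimators boosting rounds.
#' @param max_depth tree depth.
#' @param shuffle_seed seed controlling the pre-split shuffling of samples.
#' @return A list of class `bp_model_spec`.
#' @export
bp_model_spec <- function(n_estimators = 50L, max_depth = 5L,
                          shuffle_seed = 0L) {
  stopifnot(n_estimators >= 1L, max_depth >= 1L)
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 shuffle_seed = as.integer(shuffle_seed)),
            class = "bp_model_spec")
}

#' K-fold out-of-fold SBP/DBP predictions
#'
#' Shuffles the smoothed samples (seeded), splits them into K folds, and
#' for each fold trains separate AdaBoost.R2 models for systolic and
#' diastolic pressure on the remaining folds. Every sample receives
#' exactly one out-of-fold prediction.
#'
#' @param samples data.frame of smoothed windows: feature columns plus
#'   `sbp` and `dbp` (from [smooth_windows()]).
#' @param spec a [bp_model_spec()].
#' @param K number of folds.
#' @param feature_cols character vector of predictor columns; defaults to
#'   the 15 canonical features present in `samples`.
#' @return `samples` with added columns `sbp_pred`, `dbp_pred`, `fold`.
#' @export
fit_predict_kfold <- function(samples, spec = bp_model_spec(), K = 5L,
                              feature_cols = NULL) {
  stopifnot(is.data.frame(samples), all(c("sbp", "dbp") %in% names(samples)))
  if (is.null(feature_cols))
    feature_cols <- intersect(bioz_feature_names(), names(samples))
  stopifnot(length(feature_cols) >= 1L)
  n <- nrow(samples)
  if (n < K) stop("fewer samples than folds")
  set.seed(spec$shuffle_seed)
  perm <- sample.int(n)
  fold <- integer(n)
  fold[perm] <- rep_len(seq_len(K), n)
  sbp_pred <- numeric(n); dbp_pred <- numeric(n)
  for (k in seq_len(K)) {
    tr <- fold != k; te <- !tr
    m_s <- adaboost_r2(samples[tr, feature_cols, drop = FALSE],
                       samples$sbp[tr], spec$n_estimators, spec$max_depth)
    m_d <- adaboost_r2(samples[tr, feature_cols, drop = FALSE],
                       samples$dbp[tr], spec$n_estimators, spec$max_depth)
    sbp_pred[te] <- predict(m_s, samples[te, feature_cols, drop = FALSE])
    dbp_pred[te] <- predict(m_d, samples[te, feature_cols, drop = FALSE])
  }
  out <- samples
  out$sbp_pred <- sbp_pred
  out$dbp_pred <- dbp_pred
  out$fold <- fold
  out
}

#' Error statistics of a prediction series
#'
#' @param pred,ref numeric vectors of predicted and reference pressures.
#' @return A list: `mean_error`, `sd_error`, `rmse` (mmHg), `pearson_r`,
#'   `n`, plus the cumulative fractions of absolute errors within
#'   5/10/15 mmHg and the AAMI/BHS grades of [grade_bp_errors()].
#' @export
bp_error_stats <- function(pred, ref) {
  stopifnot(length(pred) == length(ref), length(pred) >= 1L)
  e <- pred - ref
  g <- grade_bp_errors(e)
  list(mean_error = mean(e), sd_error = stats::sd(e),
       rmse = sqrt(mean(e^2)),
       pearson_r = if (length(e) > 2L &&
                       stats::sd(pred) > 0 && stats::sd(ref) > 0)
         stats::cor(pred, ref) else NA_real_,
       n = length(e),
       frac_within_5 = g$fractions[1L], frac_within_10 = g$fractions[2L],
       frac_within_15 = g$fractions[3L],
       aami_pass = g$aami_pass, bhs_grade = g$bhs_grade)
}

#' AAMI pass/fail and BHS grade of an error series
#'
#' AAMI: a device passes when the absolute mean error is at most 5 mmHg
#' and the standard deviation of the errors is at most 8 mmHg. BHS: grades
#' are assigned from the cumulative fractions of absolute errors within
#' 5, 10 and 15 mmHg — grade A requires at least 60/85/95%, grade B
#' 50/75/90%, grade C 40/65/85%; anything less fails.
#'
#' @param errors numeric vector of prediction errors (mmHg), non-empty.
#' @return A list: `aami_pass` (logical), `bhs_grade` (`"A"`, `"B"`,
#'   `"C"` or `"fail"`), `fractions` (within 5/10/15 mmHg, in percent),
#'   `mean_error`, `sd_error`.
#' @export
grade_bp_errors <- function(errors) {
  stopifnot(is.numeric(errors), length(errors) >= 1L)
  me <- mean(errors)
  sde <- if (length(errors) > 1L) stats::sd(errors) else 0
  fr <- 100 * c(mean(abs(errors) <= 5), mean(abs(errors) <= 10),
                mean(abs(errors) <= 15))
  grade <- if (fr[1] >= 60 && fr[2] >= 85 && fr[3] >= 95) "A"
    else if (fr[1] >= 50 && fr[2] >= 75 && fr[3] >= 90) "B"
    else if (fr[1] >= 40 && fr[2] >= 65 && fr[3] >= 85) "C"
    else "fail"
  list(aami_pass = abs(me) <= 5 && sde <= 8,
       bhs_grade = grade,
       fractions = fr, mean_error = me, sd_error = sde)
}

#' Calibration specification for cross-subject evaluation
#'
#' @param mode `"none"` or `"single_value_offset"`: one reference reading
#'   of the held-out subject supplies an additive offset applied to all of
#'   that subject's predictions.
#' @param calibration_beat which sample supplies the offset: `"first"`
#'   (default, the clinically realistic enrolment reading) or `"last"`.
#' @return A list of class `bp_calibration_spec`.
#' @export
bp_calibration_spec <- function(mode = c("single_value_offset", "none"),
                                calibration_beat = c("first", "last")) {
  structure(list(mode = match.arg(mode),
                 calibration_beat = match.arg(calibration_beat)),
            class = "bp_calibration_spec")
}

#' Leave-one-subject-out evaluation with single-value calibration
#'
#' For each held-out subject, trains SBP/DBP models on all remaining
#' subjects' smoothed samples, predicts the held-out subject, and (when
#' calibration is enabled) shifts all predictions by the offset
#' `reference - prediction` observed at the designated calibration sample;
#' that sample is excluded from the error metrics.
#'
#' @param subjects named list of data.frames, one per subject, each with
#'   feature columns plus `sbp` and `dbp`.
#' @param spec a [bp_model_spec()].
#' @param calib a [bp_calibration_spec()].
#' @param feature_cols predictor columns (default: canonical 15).
#' @return A list with `per_subject` (named list of per-subject reports,
#'   each containing `sbp` and `dbp` [bp_error_stats()] plus predictions)
#'   and `pooled` (stats over concatenated errors of all subjects).
#' @export
loso_evaluate <- function(subjects, spec = bp_model_spec(),
                          calib = bp_calibration_spec(),
                          feature_cols = NULL) {
  stopifnot(is.list(subjects), length(subjects) >= 2L)
  if (is.null(names(subjects)))
    names(subjects) <- paste0("S", seq_along(subjects))
  if (is.null(feature_cols))
    feature_cols <- intersect(bioz_feature_names(), names(subjects[[1L]]))
  reports <- list()
  pooled <- list(sbp_pred = numeric(0), sbp_ref = numeric(0),
                 dbp_pred = numeric(0), dbp_ref = numeric(0))
  for (s in names(subjects)) {
    train <- do.call(rbind, subjects[setdiff(names(subjects), s)])
    test <- subjects[[s]]
    m_s <- adaboost_r2(train[, feature_cols, drop = FALSE], train$sbp,
                       spec$n_estimators, spec$max_depth)
    m_d <- adaboost_r2(train[, feature_cols, drop = FALSE], train$dbp,
                       spec$n_estimators, spec$max_depth)
    ps <- predict(m_s, test[, feature_cols, drop = FALSE])
    pd <- predict(m_d, test[, feature_cols, drop = FALSE])
    keep <- rep(TRUE, nrow(test))
    if (calib$mode == "single_value_offset") {
      ci <- if (calib$calibration_beat == "first") 1L else nrow(test)
      ps <- ps + (test$sbp[ci] - ps[ci])
      pd <- pd + (test$dbp[ci] - pd[ci])
      keep[ci] <- FALSE
    }
    reports[[s]] <- list(
      sbp = bp_error_stats(ps[keep], test$sbp[keep]),
      dbp = bp_error_stats(pd[keep], test$dbp[keep]),
      sbp_pred = ps, dbp_pred = pd, kept = keep)
    pooled$sbp_pred <- c(pooled$sbp_pred, ps[keep])
    pooled$sbp_ref <- c(pooled$sbp_ref, test$sbp[keep])
    pooled$dbp_pred <- c(pooled$dbp_pred, pd[keep])
    pooled$dbp_ref <- c(pooled$dbp_ref, test$dbp[keep])
  }
  list(per_subject = reports,
       pooled = list(sbp = bp_error_stats(pooled$sbp_pred, pooled$sbp_ref),
                     dbp = bp_error_stats(pooled$dbp_pred, pooled$dbp_ref)))
}
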