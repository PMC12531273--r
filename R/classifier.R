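# Elastic-net penalized logistic regression over the binary database flags:
# nested cross-validation with 1-SE lambda selection on AUC, Platt
# recalibration on held-out scores, Brier scoring, threshold sweeps and
# calibration diagnostics. Penalized fitting and the inner-loop lambda path
# are delegated to glmnet; everything around it (fold orchestration,
# calibration, sweeps) is implemented here.

#' Classifier configuration
#'
#' @param l1_mix elastic-net mixing fraction in \[0,1\] (1 = lasso,
#'   0 = ridge); default 0.5, an even L1/L2 blend.
#' @param inner_folds,outer_folds cross-validation folds (default 10 each).
#' @param outer_repeats outer-loop repeats; default 5 (desk scale; raise to
#'   100 for a full internal validation run — the estimator is identical,
#'   only the Monte Carlo error on the outer AUROC spread changes).
#' @param seed RNG seed.
#' @param demographic_exclusion_patterns column-name patterns stripped from
#'   the feature set before fitting; the model is deliberately restricted to
#'   database flags.
#' @return list of class `model_config`.
#' @export
model_config <- function(l1_mix = 0.5, inner_folds = 10, outer_folds = 10,
                         outer_repeats = 5, seed = 1L,
                         demographic_exclusion_patterns =
                           c("age", "sex", "ethnic", "imd", "year")) {
  if (l1_mix < 0 || l1_mix > 1) stop_config("l1_mix must lie in [0, 1]")
  if (inner_folds < 2 || outer_folds < 2) stop_config("folds must be >= 2")
  structure(list(l1_mix = l1_mix, inner_folds = inner_folds,
                 outer_folds = outer_folds, outer_repeats = outer_repeats,
                 seed = as.integer(seed),
                 demographic_exclusion_patterns = demographic_exclusion_patterns),
            class = "model_config")
}

#' Prepare the model feature matrix
#'
#' Drops the patient-id column, removes demographic columns by pattern
#' match, and z-scores the remainder. Standardization statistics default to
#' the supplied data but can (and during cross-validation must) be learned
#' on the training fold only and passed in for the held-out fold.
#'
#' @param features data.frame of candidate features (e.g. the membership
#'   table, optionally joined to demographics).
#' @param config a [model_config()] (source of the exclusion patterns).
#' @param center,scale optional named statistics from a training fold.
#' @return list: `x` (numeric matrix), `center`, `scale` (named vectors).
#'   Zero-variance columns are kept with scale 1 and a warning; the penalty
#'   then zeroes their weight.
#' @export
prepare_features <- function(features, config = model_config(),
                             center = NULL, scale = NULL) {
  df <- as.data.frame(features)
  df <- df[setdiff(names(df), c("patient_id", "id"))]
  pat <- paste(config$demographic_exclusion_patterns, collapse = "|")
  keep <- !grepl(pat, names(df), ignore.case = TRUE)
  df <- df[keep]
  if (ncol(df) == 0) stop_config("no feature columns left after exclusion")
  x <- as.matrix(df)
  storage.mode(x) <- "numeric"
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, sd)
    if (any(scale == 0)) {
      warning("zero-variance feature(s) kept unscaled: ",
              paste(colnames(x)[scale == 0], collapse = ", "))
      scale[scale == 0] <- 1
    }
  }
  x <- sweep(sweep(x, 2, center[colnames(x)]), 2, scale[colnames(x)], "/")
  list(x = x, center = center, scale = scale)
}

#' Fit a penalized logistic regression at a given lambda
#'
#' Thin wrapper over [glmnet::glmnet()] with the configured elastic-net mix.
#'
#' @param x numeric feature matrix (already standardized; internal
#'   re-standardization is off).
#' @param y binary labels.
#' @param lambda penalty strength at which coefficients are extracted.
#' @param config a [model_config()].
#' @return list of class `enet_fit`: `coefficients` (named, excluding
#'   intercept), `intercept`, `odds_ratios` (`exp(coefficients)`), `lambda`,
#'   and the underlying glmnet object.
#' @export
fit_elastic_net <- function(x, y, lambda, config = model_config()) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("cannot fit: labels contain a single class")
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = config$l1_mix,
                        standardize = FALSE)
  if (lambda < min(fit$lambda) || lambda > max(fit$lambda)) {
    # refit with the requested lambda on the path so no extrapolation occurs
    lams <- sort(unique(c(fit$lambda, lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = config$l1_mix,
                          standardize = FALSE, lambda = lams)
  }
  cf <- as.matrix(coef(fit, s = lambda))[, 1]
  coefs <- cf[-1]
  structure(list(coefficients = coefs, intercept = unname(cf[1]),
                 odds_ratios = exp(coefs), lambda = lambda, glmnet_fit = fit),
            class = "enet_fit")
}

#' Predict probabilities from an elastic-net fit
#'
#' @param object an `enet_fit`.
#' @param newx standardized feature matrix.
#' @param ... unused.
#' @return vector of predicted probabilities.
#' @export
predict.enet_fit <- function(object, newx, ...) {
  eta <- drop(newx %*% object$coefficients) + object$intercept
  plogis(eta)
}

# stratified fold assignment so every fold sees both classes
stratified_folds <- function(y, k) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  foldid
}

#' Nested cross-validation for the elastic-net classifier
#'
#' Inner loop: [glmnet::cv.glmnet()] on each outer-training fold, selecting
#' lambda by the one-standard-error rule on cross-validated AUC (the most
#' regularized model within 1 SE of the best). Outer loop: repeated
#' stratified k-fold, reporting the distribution of held-out AUROC. All
#' standardization and selection happen inside the training folds; the final
#' model is refit on all data at the 1-SE lambda of a full-data inner CV.
#'
#' @param features feature data.frame (see [prepare_features()]).
#' @param labels binary labels aligned to `features` rows.
#' @param config a [model_config()].
#' @return list of class `nested_cv`: `outer_auc` (vector over folds x
#'   repeats), `auc_mean`, `auc_sd`, `lambda_1se`, `lambda_min`, `model`
#'   (final `enet_fit`), `report` (coefficient/odds-ratio table),
#'   `oof_scores` (first-repeat out-of-fold probabilities, for calibration),
#'   `center`/`scale` (full-data standardization), `config`.
#' @export
nested_cv <- function(features, labels, config = model_config()) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("labels contain a single class")
  outer_auc <- numeric(0)
  oof <- rep(NA_real_, length(y))
  withr::with_seed(config$seed, {
    for (rep_i in seq_len(config$outer_repeats)) {
      foldid <- stratified_folds(y, config$outer_folds)
      for (k in seq_len(config$outer_folds)) {
        tr <- foldid != k
        prep <- suppressWarnings(prepare_features(features[tr, , drop = FALSE],
                                                  config))
        inner_id <- stratified_folds(y[tr], config$inner_folds)
        cvfit <- glmnet::cv.glmnet(prep$x, y[tr], family = "binomial",
                                   alpha = config$l1_mix,
                                   type.measure = "auc",
                                   foldid = inner_id, standardize = FALSE)
        fit <- fit_elastic_net(prep$x, y[tr], cvfit$lambda.1se, config)
        te_prep <- suppressWarnings(
          prepare_features(features[!tr, , drop = FALSE], config,
                           center = prep$center, scale = prep$scale))
        p <- predict(fit, te_prep$x)
        if (length(unique(y[!tr])) == 2) {
          outer_auc <- c(outer_auc, auc_value(y[!tr], p))
        }
        if (rep_i == 1) oof[!tr] <- p
      }
    }
    prep_all <- suppressWarnings(prepare_features(features, config))
    inner_id <- stratified_folds(y, config$inner_folds)
    cv_all <- glmnet::cv.glmnet(prep_all$x, y, family = "binomial",
                                alpha = config$l1_mix, type.measure = "auc",
                                foldid = inner_id, standardize = FALSE)
    final <- fit_elastic_net(prep_all$x, y, cv_all$lambda.1se, config)
  })
  report <- data.frame(
    feature = c("(Intercept)", names(final$coefficients)),
    coefficient = c(final$intercept, unname(final$coefficients)),
    odds_ratio = c(NA, unname(exp(final$coefficients))),
    stringsAsFactors = FALSE)
  structure(list(outer_auc = outer_auc, auc_mean = mean(outer_auc),
                 auc_sd = sd(outer_auc),
                 lambda_1se = cv_all$lambda.1se, lambda_min = cv_all$lambda.min,
                 model = final, report = report, oof_scores = oof,
                 center = prep_all$center, scale = prep_all$scale,
                 config = config),
            class = "nested_cv")
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf("Nested CV elastic-net (alpha = %.2f): outer AUROC %.3f (sd %.3f, %d folds)\n",
              x$config$l1_mix, x$auc_mean, x$auc_sd, length(x$outer_auc)))
  cat(sprintf("lambda (1-SE rule): %.5f  [lambda at best AUC: %.5f]\n",
              x$lambda_1se, x$lambda_min))
  print(x$report, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Predict cohort probabilities from a nested-CV model
#'
#' Applies the full-data standardization and the final fit to new rows.
#'
#' @param object a `nested_cv` result.
#' @param features feature data.frame for the target population.
#' @param calibrator optional [platt_calibrate()] output applied to the raw
#'   probabilities.
#' @param ... unused.
#' @return vector of probabilities.
#' @export
predict.nested_cv <- function(object, features, calibrator = NULL, ...) {
  prep <- suppressWarnings(prepare_features(features, object$config,
                                            center = object$center,
                                            scale = object$scale))
  p <- predict(object$model, prep$x)
  if (!is.null(calibrator)) p <- predict(calibrator, p)
  p
}

#' Platt scaling calibrator
#'
#' Fits a two-parameter logistic map `sigma(a + b * score)` to held-out
#' (score, label) pairs. Must be fitted on scores the model did not train
#' on, e.g. the out-of-fold scores from [nested_cv()].
#'
#' @param raw_scores held-out classifier scores/probabilities.
#' @param labels binary outcomes.
#' @return object of class `platt_calibrator` with `a`, `b` (identity map
#'   with a warning when the calibration set is single-class).
#' @export
platt_calibrate <- function(raw_scores, labels) {
  keep <- is.finite(raw_scores) & !is.na(labels)
  s <- raw_scores[keep]; y <- as.integer(labels[keep])
  if (length(unique(y)) < 2) {
    warning("single-class calibration set; returning identity map")
    return(structure(list(a = 0, b = 1, identity = TRUE),
                     class = "platt_calibrator"))
  }
  fit <- suppressWarnings(glm(y ~ s, family = binomial()))
  structure(list(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
                 identity = FALSE), class = "platt_calibrator")
}

#' @export
predict.platt_calibrator <- function(object, scores, ...) {
  if (object$identity) return(scores)
  plogis(object$a + object$b * scores)
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; lower is better.
#'
#' @param probabilities predicted probabilities.
#' @param labels binary outcomes.
#' @return a single number in \[0, 1\].
#' @export
brier_score <- function(probabilities, labels) {
  mean((probabilities - as.integer(labels))^2)
}

#' Threshold sweep over model probabilities
#'
#' For each threshold: precision, recall and accuracy on the labeled
#' validation set (with percentile-bootstrap CIs over patient resamples),
#' the count of the target population above the threshold, and the
#' precision-discounted expected true-positive total
#' `round(predicted_total * precision)`. Population totals are rescaled
#' within each bootstrap replicate by the resampled above-threshold rate so
#' the paired interval reflects both sources of uncertainty.
#'
#' @param probabilities probabilities on the labeled validation set.
#' @param labels binary labels for that set.
#' @param population_probabilities probabilities for the full target
#'   population.
#' @param thresholds vector of thresholds in (0, 1\].
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return data.frame, one row per threshold: metrics with `_lower`/`_upper`
#'   bounds, `predicted_total` and `actual_predicted_total` with bounds.
#' @export
threshold_sweep <- function(probabilities, labels, population_probabilities,
                            thresholds = c(0.25, 0.31, 0.38, 0.44, 0.5,
                                           0.56, 0.62, 0.69, 0.75),
                            n_boot = 1000, seed = 1L) {
  if (length(thresholds) == 0) stop_config("thresholds must be non-empty")
  y <- as.integer(labels)
  n <- length(y)
  rows <- lapply(thresholds, function(th) {
    pred <- as.integer(probabilities >= th)
    pt <- sum(population_probabilities >= th)
    met <- suppressWarnings(classification_metrics(confusion_counts(pred, y)))
    rate <- mean(pred)
    apt <- as.integer(round_half_away(pt * met[["precision"]]))
    boot <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        mb <- suppressWarnings(
          classification_metrics(confusion_counts(pred[idx], y[idx])))
        rate_b <- mean(pred[idx])
        pt_b <- if (rate > 0) pt * rate_b / rate else pt
        c(precision = mb[["precision"]], recall = mb[["recall"]],
          accuracy = mb[["accuracy"]], predicted_total = pt_b,
          actual_predicted_total = pt_b * mb[["precision"]])
      }, numeric(5))
    })
    qs <- apply(boot, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
    data.frame(
      threshold = th,
      precision = met[["precision"]], precision_lower = qs[1, 1],
      precision_upper = qs[2, 1],
      recall = met[["recall"]], recall_lower = qs[1, 2], recall_upper = qs[2, 2],
      accuracy = met[["accuracy"]], accuracy_lower = qs[1, 3],
      accuracy_upper = qs[2, 3],
      predicted_total = pt,
      predicted_total_lower = round_half_away(qs[1, 4]),
      predicted_total_upper = round_half_away(qs[2, 4]),
      actual_predicted_total = apt,
      actual_predicted_total_lower = round_half_away(qs[1, 5]),
      actual_predicted_total_upper = round_half_away(qs[2, 5]))
  })
  do.call(rbind, rows)
}

#' Select an operating threshold
#'
#' Deterministic scan over candidate thresholds (the sorted unique
#' probabilities unless supplied); ties resolve to the lowest threshold.
#'
#' @param probabilities held-out probabilities.
#' @param labels binary labels.
#' @param criterion `"max_f1"` (maximize F1), `"youden"` (maximize
#'   sensitivity + specificity - 1) or `"fixed"`.
#' @param fixed_value the threshold returned under `criterion = "fixed"`.
#' @param candidates optional candidate thresholds.
#' @return a single threshold.
#' @export
select_threshold <- function(probabilities, labels,
                             criterion = c("max_f1", "youden", "fixed"),
                             fixed_value = NULL, candidates = NULL) {
  criterion <- match.arg(criterion)
  if (criterion == "fixed") {
    if (is.null(fixed_value)) stop_config("criterion 'fixed' needs fixed_value")
    return(fixed_value)
  }
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("threshold selection needs both classes")
  cand <- sort(unique(candidates %||% probabilities))
  score <- vapply(cand, function(th) {
    m <- suppressWarnings(classification_metrics(
      confusion_counts(as.integer(probabilities >= th), y)))
    switch(criterion,
           max_f1 = m[["f1"]],
           youden = m[["recall"]] + m[["specificity"]] - 1)
  }, numeric(1))
  cand[which.max(score)]  # which.max returns the first (lowest) maximizer
}

#' Calibration report
#'
#' Three standard views of calibration: (1) a binned curve of mean predicted
#' probability vs observed outcome proportion; (2) a locally weighted
#' (loess) smooth of outcome against predicted probability; (3) logistic
#' recalibration — a logistic regression of outcomes on the logit of the
#' predicted probabilities, whose slope/intercept are (1, 0) for a perfectly
#' calibrated model.
#'
#' @param probabilities predicted probabilities.
#' @param labels binary outcomes.
#' @param n_bins number of equal-width bins (default 10).
#' @return list of class `calibration_report`: `binned` (data.frame with
#'   `bin`, `n`, `mean_predicted`, `observed`), `smoothed` (data.frame
#'   `predicted`, `observed_smooth`), `slope`, `intercept`,
#'   `dropped_bins`.
#' @export
calibration_report <- function(probabilities, labels, n_bins = 10) {
  if (n_bins < 2) stop_config("n_bins must be >= 2")
  y <- as.integer(labels)
  p <- pmin(pmax(probabilities, 1e-10), 1 - 1e-10)
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(probabilities, edges, include.lowest = TRUE, labels = FALSE)
  binned <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    idx <- which(bin == b)
    if (length(idx) == 0) return(NULL)
    data.frame(bin = b, n = length(idx), mean_predicted = mean(p[idx]),
               observed = mean(y[idx]))
  }))
  dropped <- setdiff(seq_len(n_bins), binned$bin)
  lo <- suppressWarnings(loess(y ~ p, span = 0.75,
                               degree = if (length(y) > 50) 2 else 1))
  grid <- seq(min(p), max(p), length.out = 101)
  smoothed <- data.frame(predicted = grid,
                         observed_smooth = pmin(1, pmax(0, predict(lo, grid))))
  recal <- suppressWarnings(glm(y ~ qlogis(p), family = binomial()))
  structure(list(binned = binned, smoothed = smoothed,
                 slope = unname(coef(recal)[2]),
                 intercept = unname(coef(recal)[1]),
                 dropped_bins = dropped,
                 brier = brier_score(probabilities, y)),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Calibration: slope %.3f, intercept %.3f, Brier %.4f\n",
              x$slope, x$intercept, x$brier))
  if (length(x$dropped_bins)) {
    cat("empty bins dropped:", paste(x$dropped_bins, collapse = ", "), "\n")
  }
  print(x$binned, row.names = FALSE, digits = 3)
  invisible(x)
}
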