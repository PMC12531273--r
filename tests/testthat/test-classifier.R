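test_that("feature preparation excludes demographics and standardizes", {
  df <- data.frame(patient_id = 1:50, dbA = rbinom(50, 1, 0.5),
                   dbB = rbinom(50, 1, 0.3), age = rnorm(50, 50),
                   sex_female = rbinom(50, 1, 0.6),
                   imd_decile = sample(1:10, 50, TRUE))
  prep <- prepare_features(df)
  expect_equal(colnames(prep$x), c("dbA", "dbB"))
  expect_lt(max(abs(colMeans(prep$x))), 1e-9)
  expect_equal(unname(apply(prep$x, 2, sd)), c(1, 1))
  # training-fold statistics applied to held-out data
  prep2 <- prepare_features(df, center = prep$center, scale = prep$scale)
  expect_equal(prep2$x, prep$x)
  # constant columns survive with a warning and no division by zero
  df$dbC <- 1
  expect_warning(p3 <- prepare_features(df), "zero-variance")
  expect_true(all(is.finite(p3$x)))
})

test_that("full shrinkage collapses to the base-rate model", {
  inst <- logistic_instance(400, betas = c(1.5, -1, 0.5), seed = 1)
  prep <- prepare_features(inst$x)
  fit <- fit_elastic_net(prep$x, inst$y, lambda = 1e3)
  expect_true(all(abs(fit$coefficients) < 1e-6))
  expect_lt(abs(fit$intercept - qlogis(mean(inst$y))), 0.02)
  expect_equal(unname(fit$odds_ratios), rep(1, 3))
})

test_that("a vanishing penalty recovers the unpenalized fit", {
  inst <- logistic_instance(500, betas = c(1.2, -0.8, 0), seed = 2)
  prep <- prepare_features(inst$x)
  fit <- fit_elastic_net(prep$x, inst$y, lambda = 1e-6)
  ml <- glm(inst$y ~ prep$x, family = binomial())
  expect_lt(max(abs(fit$coefficients - coef(ml)[-1])), 0.05)
  expect_lt(abs(fit$intercept - coef(ml)[1]), 0.05)
  expect_error(fit_elastic_net(prep$x, rep(1, 500), 0.1), "single class")
})

test_that("odds ratios are exp(coefficient) for every reported feature", {
  inst <- logistic_instance(300, betas = c(1, -0.5, 0.3, 0), seed = 3)
  prep <- prepare_features(inst$x)
  fit <- fit_elastic_net(prep$x, inst$y, lambda = 0.05)
  expect_equal(fit$odds_ratios, exp(fit$coefficients))
})

test_that("nested CV separates separable data and respects the 1-SE rule", {
  withr::with_seed(4, {
    y <- rbinom(400, 1, 0.5)
    x <- data.frame(sig = y + rnorm(400, sd = 0.05),
                    noise = rnorm(400))
  })
  cv <- nested_cv(x, y, model_config(outer_repeats = 1, seed = 5))
  expect_gt(min(cv$outer_auc), 0.99)
  expect_gte(cv$lambda_1se, cv$lambda_min)
  expect_equal(length(cv$outer_auc), 10)
  # report carries exp-consistent odds ratios
  nz <- cv$report[-1, ]
  expect_equal(nz$odds_ratio, exp(nz$coefficient))
  # out-of-fold scores exist for every patient
  expect_false(anyNA(cv$oof_scores))
  # full-data predictions discriminate
  expect_gt(cohortcapture:::auc_value(y, predict(cv, x)), 0.99)
})

test_that("Platt scaling behaves at the fixed points", {
  # perfectly calibrated input: fitted map close to identity on probabilities
  withr::with_seed(6, {
    p <- runif(4000, 0.05, 0.95)
    y <- rbinom(4000, 1, p)
  })
  cal <- platt_calibrate(p, y)
  grid <- seq(0.1, 0.9, by = 0.1)
  expect_lt(max(abs(predict(cal, grid) - plogis(cal$a + cal$b * grid))), 1e-12)
  expect_lt(mean(abs(predict(cal, grid) - grid)), 0.05)
  expect_warning(id <- platt_calibrate(c(0.2, 0.8), c(1, 1)), "single-class")
  expect_equal(predict(id, c(0.3, 0.7)), c(0.3, 0.7))
})

test_that("Brier score has its closed-form values", {
  expect_equal(brier_score(rep(0.5, 10), rep(c(0, 1), 5)), 0.25)
  expect_equal(brier_score(c(1, 0), c(1, 0)), 0)
  expect_equal(brier_score(c(1, 0), c(0, 1)), 1)
})

test_that("threshold sweep rows satisfy their internal identities", {
  withr::with_seed(7, {
    p_lab <- runif(200)
    y <- rbinom(200, 1, p_lab)
    p_pop <- runif(3000)
  })
  sw <- threshold_sweep(p_lab, y, p_pop,
                        thresholds = c(0.2, 0.5, 0.8, 0.999),
                        n_boot = 100, seed = 8)
  expect_true(all(diff(sw$predicted_total) <= 0))
  expect_true(all(sw$actual_predicted_total <= sw$predicted_total))
  expect_equal(sw$actual_predicted_total,
               as.integer(round_half_away(sw$predicted_total * sw$precision)))
  expect_true(all(sw$precision_lower <= sw$precision + 1e-9 &
                  sw$precision <= sw$precision_upper + 1e-9))
  expect_equal(sw$predicted_total[4], sum(p_pop >= 0.999))
  expect_config_error(threshold_sweep(p_lab, y, p_pop,
                                      thresholds = numeric(0)))
  # deterministic under a fixed seed
  sw2 <- threshold_sweep(p_lab, y, p_pop,
                         thresholds = c(0.2, 0.5, 0.8, 0.999),
                         n_boot = 100, seed = 8)
  expect_identical(sw, sw2)
})

test_that("threshold selection scans deterministically with lowest-tie rule", {
  probs <- c(rep(0.1, 5), rep(0.9, 5))
  labs <- c(rep(0, 5), rep(1, 5))
  expect_equal(select_threshold(probs, labs, "max_f1"), 0.9)
  expect_equal(select_threshold(probs, labs, "youden"), 0.9)
  expect_equal(select_threshold(probs, labs, "fixed", fixed_value = 0.496),
               0.496)
  expect_error(select_threshold(probs, rep(1, 10), "max_f1"), "both classes")
  expect_config_error(select_threshold(probs, labs, "fixed"))
})

test_that("calibration report recognizes calibrated and shifted scores", {
  withr::with_seed(9, {
    p <- runif(10000)
    y <- rbinom(10000, 1, p)
  })
  rep_ok <- calibration_report(p, y, n_bins = 10)
  expect_lt(abs(rep_ok$slope - 1), 0.1)
  expect_lt(abs(rep_ok$intercept), 0.1)
  expect_equal(nrow(rep_ok$binned), 10)
  expect_equal(sum(rep_ok$binned$n), 10000)
  # every populated bin sits near the diagonal
  expect_lt(max(abs(rep_ok$binned$observed - rep_ok$binned$mean_predicted)),
            0.05)
  # a +0.2 shift shows observed < predicted in every populated bin
  shifted <- pmin(p + 0.2, 0.999)
  rep_sh <- calibration_report(shifted, y, n_bins = 10)
  expect_true(all(rep_sh$binned$observed < rep_sh$binned$mean_predicted))
  expect_true(all(rep_sh$dropped_bins %in% 1:2))
  expect_config_error(calibration_report(p, y, n_bins = 1))
})
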