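# Model fits in this file use reduced basis dimension and sample sizes to
# keep the suite fast; the statistical properties checked do not depend on
# the exact sizes.

test_that("infinite smoothing with no correlation collapses to ordinary least squares", {
  df <- sim_model_data(1, n_horses = 6, per_horse = 20)
  fit <- fit_association_model(df, lambda = Inf, phi = 0, gamma_horse = 0)
  ols <- stats::lm(total_score ~ I(timing == "before_gait") + tas, data = df)
  expect_equal(unname(fit$beta), unname(stats::coef(ols)), tolerance = 1e-6)
  expect_equal(fit$edf_smooth, 1, tolerance = 1e-8)
  expect_equal(fit$fitted, unname(stats::fitted(ols)), tolerance = 1e-6)
})

test_that("with fixed variance parameters the fit equals closed-form GLS", {
  df <- sim_model_data(2, n_horses = 4, per_horse = 15, phi = 0.4,
                       sigma_horse = 1)
  phi <- 0.4; g_h <- 0.8
  fit <- fit_association_model(df, lambda = Inf, phi = phi, gamma_horse = g_h)
  # independent GLS on the blockwise-transformed design
  dfo <- equipain:::normalize_model_data(df)
  X <- cbind(1, as.numeric(dfo$timing == "before_gait"), dfo$tas)
  y <- dfo$score
  V <- matrix(0, nrow(X), nrow(X))
  for (idx in split(seq_len(nrow(X)), dfo$horse)) {
    ni <- length(idx)
    V[idx, idx] <- phi^abs(outer(1:ni, 1:ni, "-")) + g_h
  }
  beta_gls <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y))
  expect_equal(unname(fit$beta), as.numeric(beta_gls), tolerance = 1e-6)
})

test_that("linear truth is recovered: slope, effective degrees of freedom, phi", {
  res <- vapply(1:7, function(s) {
    df <- sim_model_data(s, n_horses = 8, per_horse = 50)
    fit <- fit_association_model(df)
    slope <- unname(stats::coef(stats::lm(fit$fitted ~ df$tas))[2])
    c(slope = slope, edf = fit$edf_smooth, phi = fit$phi)
  }, numeric(3))
  expect_lt(abs(median(res["slope", ]) - 0.1), 0.02)
  expect_lte(median(res["edf", ]), 1.5)
  expect_lt(abs(median(res["phi", ])), 0.1) # truth: no autocorrelation
})

test_that("autocorrelation and horse variance are recovered from structured data", {
  # 16 horses x 25 rows: the horse variance needs enough realized intercepts;
  # medians over 50 replicates keep the check stable against single-seed noise
  res <- vapply(1:50, function(s) {
    df <- sim_model_data(100 + s, n_horses = 16, per_horse = 25, phi = 0.5,
                         sigma_horse = 1.5, sigma = 1)
    fit <- fit_association_model(df, k = 8)
    c(phi = fit$phi, s2h = fit$sigma2_horse)
  }, numeric(2))
  expect_lt(abs(median(res["phi", ]) - 0.5), 0.1)
  expect_lt(abs(median(res["s2h", ]) - 1.5^2) / 1.5^2, 0.20)
})

test_that("a strongly cubic relationship is detected as nonlinear", {
  df <- sim_model_data(5, n_horses = 8, per_horse = 40,
                       f = function(t) 1 + 5 * ((t - 30) / 30)^3, sigma = 0.5)
  fit <- fit_association_model(df)
  expect_gte(fit$edf_smooth, 2.5)
  expect_lt(fit$p_association, 1e-4)
})

test_that("timing effect is estimated with a valid Wald test", {
  df <- sim_model_data(6, n_horses = 8, per_horse = 40, beta_before = 2,
                       sigma = 1)
  fit <- fit_association_model(df)
  expect_gt(fit$beta["before_gait"], 1)
  expect_lt(fit$p_timing, 0.01)
})

test_that("predictions reproduce fitted values and the constant-model mean", {
  df <- sim_model_data(7, n_horses = 6, per_horse = 20)
  fit <- fit_association_model(df, k = 8)
  pred <- predict_scores(fit, fit$data, type = "conditional")
  expect_equal(pred, fit$fitted_conditional, tolerance = 1e-8)
  # population predictions on training rows equal the population fit
  expect_equal(predict_scores(fit, fit$data), fit$fitted, tolerance = 1e-8)
  # flat truth + infinite smoothing: predictions equal the adjusted mean
  df0 <- sim_model_data(8, n_horses = 6, per_horse = 20,
                        f = function(t) 3 + 0 * t)
  fit0 <- fit_association_model(df0, lambda = Inf, phi = 0, gamma_horse = 0)
  newd <- data.frame(tas = c(5, 25, 45), timing = "after_gait")
  p0 <- predict_scores(fit0, newd)
  expect_equal(diff(range(p0)), 0, tolerance = abs(fit0$beta["tas"]) * 40 + 1e-8)
  # extrapolation warns and is linear in the smooth
  expect_warning(predict_scores(fit, data.frame(tas = 100)), "extrapolated")
})

test_that("monotone fits give monotone predictions over a grid", {
  df <- sim_model_data(9, n_horses = 8, per_horse = 40, sigma = 0.3)
  fit <- fit_association_model(df)
  grid <- data.frame(tas = seq(2, 58, length.out = 50), timing = "after_gait")
  expect_true(all(diff(predict_scores(fit, grid)) > -1e-6))
})

test_that("partial effect curves are centered, banded, and tighten with n", {
  df <- sim_model_data(10, n_horses = 8, per_horse = 25)
  fit <- fit_association_model(df)
  pe <- partial_effect_curve(fit)
  expect_true(all(pe$lo <= pe$estimate & pe$estimate <= pe$hi))
  # centering: mean of the smooth over training covariate values ~ 0
  pe_train <- partial_effect_curve(fit, grid = fit$data$tas)
  expect_equal(mean(pe_train$estimate), 0, tolerance = 1e-8)
  # linear truth: a straight line fits inside the band
  line <- stats::lm(estimate ~ tas, data = pe)
  expect_true(all(stats::fitted(line) >= pe$lo - 1e-6 &
                    stats::fitted(line) <= pe$hi + 1e-6))
  # band area shrinks when n doubles under the same generator
  df2 <- sim_model_data(10, n_horses = 8, per_horse = 50)
  fit2 <- fit_association_model(df2)
  g <- seq(5, 55, length.out = 40)
  w1 <- mean(partial_effect_curve(fit, g)$hi - partial_effect_curve(fit, g)$lo)
  w2 <- mean(partial_effect_curve(fit2, g)$hi - partial_effect_curve(fit2, g)$lo)
  expect_lt(w2, w1)
})

test_that("fitting preconditions are enforced", {
  df <- sim_model_data(11, n_horses = 2, per_horse = 8)
  expect_error(fit_association_model(df), class = "equipain_insufficient_data")
  one_horse <- sim_model_data(12, n_horses = 1, per_horse = 30)
  expect_error(fit_association_model(one_horse),
               class = "equipain_insufficient_data")
})
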