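# Independent oracles and small data builders used across the suite.

# Brute-force ICC(2,A1) through stats::aov mean squares (independent of the
# package's hand-rolled ANOVA decomposition).
icc_oracle <- function(m) {
  df <- data.frame(y = as.vector(m),
                   subject = factor(as.vector(row(m))),
                   rater = factor(as.vector(col(m))))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Brute-force AUC: proportion of (pain, no-pain) pairs ranked correctly,
# ties counted one half.
auc_oracle <- function(pred, status) {
  pos <- pred[as.logical(status)]; neg <- pred[!as.logical(status)]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Trapezoid integration of an ROC curve's operating points.
auc_trapezoid <- function(points) {
  x <- 1 - points$specificity; y <- points$sensitivity
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Independent de Boor recursion for B-spline evaluation.
deboor_one <- function(t, j, k, x) {
  if (k == 1) return(as.numeric(x >= t[j] && x < t[j + 1]))
  w1 <- if (t[j + k - 1] > t[j]) (x - t[j]) / (t[j + k - 1] - t[j]) else 0
  w2 <- if (t[j + k] > t[j + 1]) (t[j + k] - x) / (t[j + k] - t[j + 1]) else 0
  w1 * deboor_one(t, j, k - 1, x) + w2 * deboor_one(t, j + 1, k - 1, x)
}
deboor_basis <- function(knots, x, ord = 4) {
  nb <- length(knots) - ord
  out <- matrix(0, length(x), nb)
  for (j in seq_len(nb))
    out[, j] <- vapply(x, function(xx) deboor_one(knots, j, ord, xx), numeric(1))
  out
}

# Longitudinal score data with known structure: score = f(tas) +
# beta_before * [before] + horse effect + AR(1) Gaussian noise.
sim_model_data <- function(seed, n_horses = 8, per_horse = 50,
                           f = function(t) 2 + 0.1 * t,
                           beta_before = 0, sigma_horse = 0, phi = 0,
                           sigma = 1, tas_max = 60) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_horses), function(h) {
    tas <- stats::runif(per_horse, 0, tas_max)
    e <- if (phi != 0) {
      as.numeric(stats::arima.sim(list(ar = phi), per_horse,
                                  sd = sigma * sqrt(1 - phi^2)))
    } else stats::rnorm(per_horse, 0, sigma)
    before <- sample(c("before_gait", "after_gait"), per_horse, TRUE)
    data.frame(horse = sprintf("h%02d", h),
               prop_time = sort(stats::runif(per_horse, 0, 100)),
               tas = tas, timing = before,
               total_score = f(tas) + beta_before * (before == "before_gait") +
                 stats::rnorm(1, 0, sigma_horse) + e)
  }))
}
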