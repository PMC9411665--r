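## Semiparametric mixed model of total pain score versus movement asymmetry:
##
##   score_ij = beta0 + f(TAS_ij) + beta1 * 1[before gait analysis]
##              + b_i + eps_ij,   b_i ~ N(0, sigma2_horse),
##   eps_i ~ N(0, sigma2 * R(phi)),  R = AR(1) over the horse's
##   observation order (occasions sorted by proportional time).
##
## The smooth f is a penalized cubic B-spline in its mixed-model
## representation: the penalty null space (linear in TAS) is a fixed effect,
## the wiggly component enters as i.i.d. random coefficients with variance
## sigma2 / lambda. Variance ratios (gamma_horse, gamma_smooth = 1/lambda)
## and phi are estimated by numerically maximized profiled REML (ML for the
## likelihood-ratio association test), blockwise over horses.

normalize_model_data <- function(data) {
  pick <- function(cands) {
    hit <- cands[cands %in% names(data)]
    if (!length(hit))
      ep_validation_error("model data lacks a column named one of: %s",
                          paste(cands, collapse = ", "))
    data[[hit[1]]]
  }
  df <- data.frame(
    horse = as.character(pick(c("horse", "horse_id"))),
    prop_time = as.numeric(pick(c("prop_time", "prop_time_pct"))),
    tas = as.numeric(pick(c("tas", "tas_mm"))),
    timing = as.character(pick("timing")),
    score = as.numeric(pick(c("total_score", "score"))),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$tas) || anyNA(df$score))
    ep_validation_error("model data contains missing TAS or score values")
  timing_rank <- ifelse(df$timing == "before_gait", 0L, 1L)
  df[order(df$horse, df$prop_time, timing_rank), , drop = FALSE]
}

# Profiled Gaussian (restricted) likelihood criterion, blockwise by horse.
# Returns -2 * profiled log-likelihood up to an additive constant, plus the
# ingredients needed at the optimum.
gaussian_crit <- function(y, X, Zs, horse_idx, g_h, g_s, phi, reml = TRUE,
                          details = FALSE) {
  n <- length(y); p <- ncol(X)
  logdet <- 0
  XtVX <- matrix(0, p, p); XtVy <- numeric(p); ytVy <- 0
  blocks <- vector("list", length(horse_idx))
  for (bi in seq_along(horse_idx)) {
    idx <- horse_idx[[bi]]
    ni <- length(idx)
    Vi <- phi^abs(outer(seq_len(ni), seq_len(ni), "-"))
    if (g_h > 0) Vi <- Vi + g_h
    if (g_s > 0 && !is.null(Zs)) {
      Zi <- Zs[idx, , drop = FALSE]
      Vi <- Vi + g_s * tcrossprod(Zi)
    }
    ch <- tryCatch(chol(Vi), error = function(e) NULL)
    if (is.null(ch)) return(list(crit = 1e10))
    logdet <- logdet + 2 * sum(log(diag(ch)))
    Xi <- X[idx, , drop = FALSE]; yi <- y[idx]
    sx <- backsolve(ch, Xi, transpose = TRUE)
    sy <- backsolve(ch, yi, transpose = TRUE)
    XtVX <- XtVX + crossprod(sx)
    XtVy <- XtVy + crossprod(sx, sy)[, 1]
    ytVy <- ytVy + sum(sy^2)
    if (details) blocks[[bi]] <- ch
  }
  beta <- tryCatch(solve(XtVX, XtVy), error = function(e) NULL)
  if (is.null(beta)) return(list(crit = 1e10))
  quad <- ytVy - sum(beta * XtVy)
  if (!is.finite(quad) || quad <= 0) return(list(crit = 1e10))
  crit <- if (reml) {
    logdet + determinant(XtVX, logarithm = TRUE)$modulus +
      (n - p) * log(quad)
  } else {
    logdet + n * log(quad)
  }
  out <- list(crit = as.numeric(crit), beta = beta, quad = quad,
              logdet = logdet, XtVX = XtVX)
  if (details) out$chol_blocks <- blocks
  out
}

# Exact ML log-likelihood at the profiled optimum.
ml_loglik <- function(fitres, n) {
  s2 <- fitres$quad / n
  -0.5 * (fitres$logdet + n * log(2 * pi * s2) + n)
}

fit_variance_params <- function(y, X, Zs, horse_idx, fix = list(),
                                reml = TRUE) {
  free <- c(g_h = is.null(fix$g_h), g_s = is.null(fix$g_s) && !is.null(Zs),
            phi = is.null(fix$phi))
  par_index <- cumsum(free)
  unpack <- function(par) {
    list(
      g_h = if (free["g_h"]) exp(par[par_index["g_h"]]) else fix$g_h %||% 0,
      g_s = if (free["g_s"]) exp(par[par_index["g_s"]]) else fix$g_s %||% 0,
      phi = if (free["phi"]) tanh(par[par_index["phi"]]) else fix$phi %||% 0
    )
  }
  obj <- function(par) {
    v <- unpack(par)
    gaussian_crit(y, X, Zs, horse_idx, v$g_h, v$g_s, v$phi, reml = reml)$crit
  }
  n_free <- sum(free)
  if (n_free == 0) {
    v <- unpack(numeric(0))
  } else {
    starts <- list(rep(0, n_free), rep(-2, n_free), c(1, rep(-1, n_free - 1)))
    method <- if (n_free == 1) "BFGS" else "Nelder-Mead"
    best <- NULL
    for (st in starts) {
      op <- stats::optim(st, obj, method = method,
                         control = list(maxit = 500, reltol = 1e-10))
      if (is.null(best) || op$value < best$value) best <- op
    }
    if (!is.finite(best$value) || best$value >= 1e10)
      ep_stop("equipain_convergence_error",
              "variance-parameter optimization failed (criterion %.3g; par %s)",
              best$value, paste(round(best$par, 3), collapse = ", "))
    v <- unpack(best$par)
  }
  if (abs(v$phi) > 0.98) {
    warning("AR(1) parameter on the boundary; refitting with phi clamped to +/-0.95")
    fix$phi <- sign(v$phi) * 0.95
    return(fit_variance_params(y, X, Zs, horse_idx, fix = fix, reml = reml))
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the pain-score versus asymmetry mixed model
#'
#' Fits `score = b0 + f(tas) + b1 * [before gait] + b_horse + eps` with a
#' penalized cubic B-spline smooth `f`, a horse random intercept and AR(1)
#' within-horse residual correlation (observations ordered by proportional
#' time). Smoothing parameter and variance components are estimated by
#' profiled REML; the association test compares full and smooth-dropped
#' models by maximum likelihood, referred to a chi-square with the smooth's
#' effective degrees of freedom.
#'
#' @param data Data.frame with columns `horse`/`horse_id`,
#'   `prop_time`/`prop_time_pct`, `tas`/`tas_mm`, `timing`
#'   (`before_gait`/`after_gait`) and `total_score`/`score`; one observer and
#'   one scale at a time.
#' @param k Spline basis dimension (default 10).
#' @param lambda Smoothing parameter; `NULL` (default) estimates it by REML,
#'   a finite value fixes it, `Inf` removes all wiggliness so the smooth
#'   collapses to a straight line.
#' @param phi AR(1) parameter; `NULL` to estimate, a value in (-1, 1) to fix.
#' @param gamma_horse Horse random-intercept variance expressed as a ratio to
#'   the residual variance; `NULL` to estimate, `0` to drop the random effect.
#' @param min_rows,min_horses Fitting preconditions (defaults 20 and 2).
#' @return An `ep_gamm` object; see Details. Key elements: `beta`
#'   (intercept, timing, linear TAS), `theta` (all coefficients), `edf_smooth`,
#'   `edf_total`, `lambda`, `phi`, `sigma2_horse`, `sigma2_resid`, `r2_adj`,
#'   `p_association`, `p_timing`, `fitted` (population), `fitted_conditional`,
#'   `loglik_reml`.
#' @export
fit_association_model <- function(data, k = 10, lambda = NULL, phi = NULL,
                                  gamma_horse = NULL, min_rows = 20,
                                  min_horses = 2) {
  df <- normalize_model_data(data)
  n <- nrow(df)
  if (n < min_rows)
    ep_insufficient_data("only %d rows; >= %d required", n, min_rows)
  if (length(unique(df$horse)) < min_horses)
    ep_insufficient_data("fewer than %d horses", min_horses)
  y <- df$score
  before <- as.numeric(df$timing == "before_gait")
  X <- cbind(intercept = 1, before = before, tas = df$tas)
  basis <- build_penalized_basis(df$tas, k = k)
  eg <- eigen(basis$penalty, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-9
  Zs <- basis$design_raw %*% eg$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[pos]), sum(pos))
  horse_idx <- split(seq_len(n), df$horse)

  fix <- list()
  if (!is.null(gamma_horse)) fix$g_h <- gamma_horse
  if (!is.null(lambda)) fix$g_s <- if (is.infinite(lambda)) 0 else 1 / lambda
  if (!is.null(phi)) fix$phi <- phi
  v <- fit_variance_params(y, X, Zs, horse_idx, fix = fix, reml = TRUE)
  res <- gaussian_crit(y, X, Zs, horse_idx, v$g_h, v$g_s, v$phi, reml = TRUE)
  p <- ncol(X)
  sigma2 <- res$quad / (n - p)

  # penalized GLS form: smooth coefficients as penalized "fixed" effects,
  # horse effect + AR(1) in the error covariance
  use_smooth <- v$g_s > 1e-8 # an effectively infinite lambda: smooth is a line
  penalized_gls <- function(use_smooth) {
    C <- if (use_smooth) cbind(X, Zs) else X
    q <- ncol(C)
    P <- diag(c(rep(0, p), rep(if (use_smooth) 1 / v$g_s else 0, q - p)), q)
    A <- matrix(0, q, q); Cty <- numeric(q)
    for (idx in horse_idx) {
      ni <- length(idx)
      S0 <- v$phi^abs(outer(seq_len(ni), seq_len(ni), "-")) + v$g_h
      ch <- chol(S0)
      sc <- backsolve(ch, C[idx, , drop = FALSE], transpose = TRUE)
      sy <- backsolve(ch, y[idx], transpose = TRUE)
      A <- A + crossprod(sc)
      Cty <- Cty + crossprod(sc, sy)[, 1]
    }
    Ainv_pen <- tryCatch(chol2inv(chol(A + P)), error = function(e) NULL)
    if (is.null(Ainv_pen)) return(NULL)
    list(C = C, q = q, A = A, Cty = Cty, Ainv_pen = Ainv_pen)
  }
  gls <- penalized_gls(use_smooth)
  if (is.null(gls) && use_smooth) { # near-singular penalty: fall back to line
    use_smooth <- FALSE
    gls <- penalized_gls(FALSE)
  }
  if (is.null(gls))
    ep_stop("equipain_convergence_error", "penalized GLS system is singular")
  C <- gls$C; q <- gls$q; A <- gls$A; Cty <- gls$Cty; Ainv_pen <- gls$Ainv_pen
  theta <- Ainv_pen %*% Cty
  Fmat <- Ainv_pen %*% A
  edf <- diag(Fmat)
  edf_total <- sum(edf)
  edf_smooth <- edf[3] + if (use_smooth) sum(edf[(p + 1):q]) else 0
  Vtheta <- sigma2 * Ainv_pen

  fitted_pop <- as.numeric(C %*% theta)
  # horse BLUPs given the population fit
  b_h <- vapply(horse_idx, function(idx) {
    ni <- length(idx)
    S0 <- v$phi^abs(outer(seq_len(ni), seq_len(ni), "-")) + v$g_h
    v$g_h * sum(solve(S0, y[idx] - fitted_pop[idx]))
  }, numeric(1))
  fitted_cond <- fitted_pop + b_h[match(df$horse, names(horse_idx))]

  rss <- sum((y - fitted_pop)^2)
  tss <- sum((y - mean(y))^2)
  r2_adj <- 1 - (rss / (n - edf_total)) / (tss / (n - 1))

  # association test: ML likelihood ratio, full vs. smooth-dropped
  fix_ml <- fix; fix_ml$g_s <- NULL
  if (!is.null(lambda)) fix_ml$g_s <- if (is.infinite(lambda)) 0 else 1 / lambda
  v1 <- fit_variance_params(y, X, Zs, horse_idx, fix = fix_ml, reml = FALSE)
  l1 <- ml_loglik(gaussian_crit(y, X, Zs, horse_idx, v1$g_h, v1$g_s, v1$phi,
                                reml = FALSE), n)
  X0 <- X[, 1:2, drop = FALSE]
  fix0 <- fix; fix0$g_s <- 0
  v0 <- fit_variance_params(y, X0, NULL, horse_idx, fix = fix0, reml = FALSE)
  l0 <- ml_loglik(gaussian_crit(y, X0, NULL, horse_idx, v0$g_h, 0, v0$phi,
                                reml = FALSE), n)
  lrt <- max(0, 2 * (l1 - l0))
  p_association <- stats::pchisq(lrt, df = max(edf_smooth, 1), lower.tail = FALSE)
  z_timing <- theta[2] / sqrt(Vtheta[2, 2])
  p_timing <- 2 * stats::pnorm(-abs(z_timing))

  loglik_reml <- -0.5 * (res$crit + (n - p) * (1 + log(2 * pi / (n - p))))

  structure(list(
    beta = stats::setNames(as.numeric(theta[1:p]),
                           c("intercept", "before_gait", "tas")),
    theta = as.numeric(theta), use_smooth = use_smooth,
    basis = basis, eigen_pos = pos, eigen_vectors = eg$vectors,
    eigen_values = eg$values,
    lambda = if (use_smooth) 1 / v$g_s else Inf,
    phi = v$phi, gamma_horse = v$g_h,
    sigma2_resid = sigma2, sigma2_horse = sigma2 * v$g_h,
    edf = edf, edf_smooth = as.numeric(edf_smooth),
    edf_total = as.numeric(edf_total),
    r2_adj = r2_adj, p_association = as.numeric(p_association),
    p_timing = as.numeric(p_timing), lrt = lrt,
    fitted = fitted_pop, fitted_conditional = fitted_cond,
    ranef_horse = b_h, Vtheta = Vtheta,
    loglik_reml = as.numeric(loglik_reml),
    data = df, n = n, k = k
  ), class = "ep_gamm")
}

# Design row(s) for the full coefficient vector at new covariate values.
model_design <- function(fit, tas, before) {
  B <- basis_eval(fit$basis, tas)
  X <- cbind(1, before, tas)
  if (!fit$use_smooth) return(X)
  pos <- fit$eigen_pos
  Zs <- B %*% fit$eigen_vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(fit$eigen_values[pos]), sum(pos))
  cbind(X, Zs)
}

#' Predict total pain scores from a fitted model
#'
#' @param fit An `ep_gamm`.
#' @param newdata Data.frame with `tas` (or `tas_mm`) and optionally `timing`
#'   and `horse`; missing timing predicts the after-gait state.
#' @param type `"population"` (random effect at zero, default) or
#'   `"conditional"` (adds the horse BLUP for known horses).
#' @return Numeric vector of predicted totals.
#' @export
predict_scores <- function(fit, newdata, type = c("population", "conditional")) {
  type <- match.arg(type)
  tas <- as.numeric(newdata[[intersect(c("tas", "tas_mm"), names(newdata))[1]]])
  if (anyNA(tas)) ep_validation_error("newdata contains missing TAS")
  rng <- fit$basis$x_range
  if (any(tas < rng[1] | tas > rng[2]))
    warning("TAS outside the training range; smooth extrapolated linearly")
  before <- if ("timing" %in% names(newdata))
    as.numeric(newdata$timing == "before_gait") else rep(0, length(tas))
  pred <- as.numeric(model_design(fit, tas, before) %*% fit$theta)
  if (type == "conditional" && "horse" %in% names(newdata)) {
    b <- fit$ranef_horse[match(as.character(newdata$horse),
                               names(fit$ranef_horse))]
    b[is.na(b)] <- 0
    pred <- pred + b
  }
  pred
}

#' Partial effect of movement asymmetry on pain score
#'
#' Centered estimate of the smooth f(TAS) on a grid, with a pointwise 95%
#' band from the coefficient covariance. The curve is centered to mean zero
#' over the training TAS values, matching the usual partial-effect display.
#'
#' @param fit An `ep_gamm`.
#' @param grid TAS values (default: 100 points over the training range).
#' @param level Band level (default 0.95).
#' @return Data.frame `tas, estimate, lo, hi`.
#' @export
partial_effect_curve <- function(fit, grid = NULL, level = 0.95) {
  rng <- fit$basis$x_range
  if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = 100)
  smooth_cols <- function(tas) {
    M <- model_design(fit, tas, before = rep(0, length(tas)))
    M[, 1:2] <- 0 # intercept and timing are not part of the smooth
    M
  }
  Ctr <- smooth_cols(fit$data$tas)
  cbar <- colMeans(Ctr)
  Cg <- sweep(smooth_cols(grid), 2, cbar)
  est <- as.numeric(Cg %*% fit$theta)
  se <- sqrt(pmax(0, rowSums((Cg %*% fit$Vtheta) * Cg)))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(tas = grid, estimate = est, lo = est - zq * se,
             hi = est + zq * se)
}

#' @export
print.ep_gamm <- function(x, ...) {
  cat(sprintf("Penalized-spline mixed model (n = %d, %d horses)\n",
              x$n, length(x$ranef_horse)))
  cat(sprintf("  edf(smooth) = %.2f  lambda = %.3g  phi = %.3f\n",
              x$edf_smooth, x$lambda, x$phi))
  cat(sprintf("  sigma2_horse = %.3f  sigma2_resid = %.3f\n",
              x$sigma2_horse, x$sigma2_resid))
  cat(sprintf("  R2_adj = %.3f  p(association) = %.3g  p(timing) = %.3g\n",
              x$r2_adj, x$p_association, x$p_timing))
  invisible(x)
}
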