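## Inter-observer agreement: two-way random-effects, absolute-agreement,
## single-rater intraclass correlation ICC(2,A1), with the McGraw-Wong
## F-based 95% confidence interval, and categorization of the estimate.

#' Build a subjects x raters ratings matrix
#'
#' Pivots long-format assessments for one scale into a matrix with one row
#' per assessment event (horse x occasion x timing) and one column per rater.
#' Because the third observer rotated between observers 3-5, the default
#' pools them into a single third rater column (`rater3`), mirroring the
#' study design; `pool_third = FALSE` keeps observers as separate columns.
#'
#' @param assessments Long data.frame (`horse, occasion, observer, scale,
#'   timing, total_score`).
#' @param scale Scale name to extract.
#' @param pool_third Pool observers 3-5 into one column?
#' @return Numeric matrix (missing entries `NA`) with attribute `scale`.
#' @export
ratings_matrix <- function(assessments, scale, pool_third = TRUE) {
  a <- assessments[assessments$scale == scale, , drop = FALSE]
  if (!nrow(a)) ep_insufficient_data("no assessments for scale '%s'", scale)
  a$subject <- paste(a$horse, a$occasion, a$timing, sep = "|")
  a$rater <- if (pool_third) {
    ifelse(a$observer %in% c(1, 2), paste0("rater", a$observer), "rater3")
  } else paste0("rater", a$observer)
  m <- tapply(a$total_score, list(a$subject, a$rater), function(x) x[1])
  m <- m[order(rownames(m)), , drop = FALSE]
  attr(m, "scale") <- scale
  m
}

#' Absolute-agreement single-rater ICC, ICC(2,A1)
#'
#' Two-way random-effects decomposition over complete cases: with mean
#' squares for rows/subjects (MSR), columns/raters (MSC) and error (MSE),
#'
#'   ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)).
#'
#' The 95% CI uses the McGraw-Wong F-distribution method with
#' Satterthwaite degrees of freedom.
#'
#' @param m Subjects x raters matrix (missing values allowed; rows with any
#'   `NA` are dropped, i.e. complete-case analysis).
#' @param conf_level Confidence level (default 0.95).
#' @return An `ep_icc` list: `estimate, ci_low, ci_high, msr, msc, mse,
#'   n_subjects, k_raters, label`.
#' @export
icc_agreement <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 5) ep_insufficient_data("only %d complete cases; >= 5 required", n)
  if (k < 2) ep_insufficient_data("need >= 2 raters with data")
  grand <- mean(m)
  if (stats::var(as.vector(m)) == 0)
    ep_degenerate_error("zero total variance in ratings")
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    ci <- c(1, 1) # perfect agreement
  } else {
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(max(-1, lo), min(1, hi))
  }
  structure(list(estimate = est, ci_low = ci[1], ci_high = ci[2],
                 msr = msr, msc = msc, mse = mse,
                 n_subjects = n, k_raters = k,
                 label = classify_reliability(est)),
            class = "ep_icc")
}

#' Categorize a reliability coefficient
#'
#' Default bands follow the conventional system for ICC interpretation:
#' below 0.5 poor, 0.5 to <0.75 moderate, 0.75 to <0.9 good, >= 0.9
#' excellent.
#'
#' @param estimate ICC estimate (<= 1).
#' @param thresholds Increasing cut points (length 3).
#' @return One of "poor", "moderate", "good", "excellent".
#' @examples
#' classify_reliability(0.753)  # "good"
#' classify_reliability(0.432)  # "poor"
#' @export
classify_reliability <- function(estimate, thresholds = c(0.5, 0.75, 0.9)) {
  if (any(estimate > 1)) ep_validation_error("ICC estimate cannot exceed 1")
  cut_labels <- c("poor", "moderate", "good", "excellent")
  idx <- findInterval(estimate, thresholds) + 1L
  cut_labels[idx]
}

#' Per-scale inter-observer ICC table
#'
#' @param assessments Long assessment table.
#' @param scales Scale names (default: those present).
#' @param pool_third Passed to [ratings_matrix()].
#' @return Data.frame `scale, icc, ci_low, ci_high, label, n, k`.
#' @export
icc_by_scale <- function(assessments, scales = NULL, pool_third = TRUE) {
  if (is.null(scales)) scales <- unique(as.character(assessments$scale))
  rows <- lapply(scales, function(sc) {
    r <- icc_agreement(ratings_matrix(assessments, sc, pool_third))
    data.frame(scale = sc, icc = r$estimate, ci_low = r$ci_low,
               ci_high = r$ci_high, label = r$label,
               n = r$n_subjects, k = r$k_raters, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
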