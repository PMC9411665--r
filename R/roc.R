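## Diagnostic accuracy: empirical ROC curves of model-predicted pain scores
## against the TAS-defined pain status, AUC with a DeLong 95% CI, and
## categorization of the AUC.

#' Empirical ROC curve and AUC
#'
#' Operating points over all distinct prediction thresholds; AUC by the
#' trapezoid rule, which equals the Mann-Whitney probability that a random
#' "pain" observation is ranked above a random "no pain" observation, ties
#' counted 1/2.
#'
#' @param predictions Numeric predicted values (higher = more likely pain).
#' @param pain_status Logical (or 0/1) true status; both classes required.
#' @return An `ep_roc` with `points` (threshold, sensitivity, specificity),
#'   `auc`, `n_pos`, `n_neg`, and (after [auc_ci()]) `ci_low`, `ci_high`,
#'   `label`.
#' @examples
#' compute_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc  # 1
#' @export
compute_roc <- function(predictions, pain_status) {
  status <- as.logical(pain_status)
  if (length(predictions) != length(status) || anyNA(predictions) || anyNA(status))
    ep_validation_error("predictions and pain_status must be equal-length, complete")
  n_pos <- sum(status); n_neg <- sum(!status)
  if (n_pos == 0 || n_neg == 0)
    ep_stop("equipain_undefined_roc",
            "ROC undefined: only one class present (%d pain, %d no-pain)",
            n_pos, n_neg)
  thr <- c(Inf, sort(unique(predictions), decreasing = TRUE))
  sens <- vapply(thr, function(th) mean(predictions[status] >= th), numeric(1))
  spec <- vapply(thr, function(th) mean(predictions[!status] < th), numeric(1))
  r <- rank(predictions) # midranks: ties counted 1/2
  auc <- (sum(r[status]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(points = data.frame(threshold = thr, sensitivity = sens,
                                     specificity = spec),
                 auc = auc, n_pos = n_pos, n_neg = n_neg,
                 ci_low = NA_real_, ci_high = NA_real_,
                 label = classify_auc(auc)),
            class = "ep_roc")
}

#' DeLong confidence interval for the AUC
#'
#' Normal-approximation interval using the DeLong placement-variance
#' estimate, clipped to [0, 1]. With degenerate variance (e.g. perfect
#' separation) the interval collapses to the point estimate, with a warning.
#'
#' @param roc An `ep_roc` from [compute_roc()].
#' @param predictions,pain_status The data the curve was computed from.
#' @param conf_level Confidence level (default 0.95).
#' @return The `ep_roc` with `ci_low`/`ci_high` filled in.
#' @export
auc_ci <- function(roc, predictions, pain_status, conf_level = 0.95) {
  status <- as.logical(pain_status)
  pos <- predictions[status]; neg <- predictions[!status]
  m <- length(pos); n <- length(neg)
  if (m < 2 || n < 2)
    ep_insufficient_data("DeLong CI needs >= 2 observations in each class")
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  V10 <- vapply(pos, function(x) mean(psi(x, neg)), numeric(1))
  V01 <- vapply(neg, function(y) mean(psi(pos, y)), numeric(1))
  var_auc <- stats::var(V10) / m + stats::var(V01) / n
  if (var_auc <= 0) {
    warning("degenerate DeLong variance; CI collapses to the point estimate")
    roc$ci_low <- roc$auc; roc$ci_high <- roc$auc
    return(roc)
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  roc$ci_low <- max(0, roc$auc - zq * sqrt(var_auc))
  roc$ci_high <- min(1, roc$auc + zq * sqrt(var_auc))
  roc
}

#' Categorize diagnostic accuracy from the AUC
#'
#' Default bands: AUC <= 0.5 no discrimination (pain cannot be distinguished
#' from no pain); (0.5, 0.7) poor; [0.7, 0.8) good (the conventional
#' "acceptable" band; a lower bound above 0.72 is commonly read as good
#' accuracy); [0.8, 0.9) excellent; >= 0.9 outstanding. Bands and labels are
#' configurable.
#'
#' @param auc AUC value(s) in [0, 1].
#' @param thresholds Increasing cut points (default `c(0.5, 0.7, 0.8, 0.9)`).
#' @param labels Band labels, length `length(thresholds) + 1`.
#' @return Character label(s).
#' @examples
#' classify_auc(c(0.45, 0.75, 1.0))
#' @export
classify_auc <- function(auc,
                         thresholds = c(0.5, 0.7, 0.8, 0.9),
                         labels = c("no_discrimination", "poor", "good",
                                    "excellent", "outstanding")) {
  if (any(auc < 0 | auc > 1)) ep_validation_error("AUC must lie in [0, 1]")
  if (length(labels) != length(thresholds) + 1)
    ep_config_error("need one more label than thresholds")
  # first band is right-closed (AUC = 0.5 is still no discrimination);
  # the remaining cut points are left-closed ([0.7, 0.8) etc.)
  idx <- 1L + (auc > thresholds[1])
  for (th in thresholds[-1]) idx <- idx + (auc >= th)
  labels[idx]
}

#' @export
print.ep_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%s), %d pain / %d no-pain", x$auc, x$label,
              x$n_pos, x$n_neg))
  if (!is.na(x$ci_low)) cat(sprintf(", 95%% CI %.3f-%.3f", x$ci_low, x$ci_high))
  cat("\n")
  invisible(x)
}
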