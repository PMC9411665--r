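## Proportional-time normalization and pain-status categorization.
##
## Each horse's induction response runs on its own clock, so measurement
## series are aligned on a proportional time scale: baseline at 0%, the
## occasion of maximum TAS at 50%, the last measurement at 100%, with
## occasions in between interpolated linearly in clock time.

#' Assign proportional time to one horse's occasions
#'
#' Piecewise-linear map of clock time through the anchors
#' (baseline -> 0%, peak TAS -> 50%, last occasion -> 100%). Ties in the
#' maximum TAS resolve to the earliest occasion. If the peak falls on the
#' last occasion the 50% anchor is placed at the preceding occasion's clock
#' time and the mapping is flagged (`attr(, "degenerate_peak")`); a peak at
#' baseline is a degenerate-anchor error.
#'
#' @param occasions Data.frame for one horse with columns `clock_time_h` and
#'   `tas_mm` (>= 3 rows, unique clock times; the earliest row is the
#'   baseline).
#' @param pain_cutoff_mm TAS cut-off passed to [classify_pain_status()].
#' @return The input with `prop_time_pct` (in [0, 100], monotone in clock
#'   time) and `pain_status` columns added.
#' @export
assign_proportional_time <- function(occasions, pain_cutoff_mm = 10) {
  occ <- occasions[order(occasions$clock_time_h), , drop = FALSE]
  if (nrow(occ) < 3)
    ep_insufficient_data("need >= 3 occasions (incl. baseline), got %d", nrow(occ))
  if (anyDuplicated(occ$clock_time_h))
    ep_validation_error("occasion clock times must be unique")
  t <- occ$clock_time_h
  i_peak <- which.max(occ$tas_mm) # earliest occasion on ties
  degenerate <- FALSE
  if (i_peak == 1L)
    ep_degenerate_error("peak TAS at the baseline occasion; anchors degenerate")
  if (i_peak == nrow(occ)) {
    degenerate <- TRUE
    t50 <- t[nrow(occ) - 1L]
  } else {
    t50 <- t[i_peak]
  }
  anchors_t <- c(t[1], t50, t[length(t)])
  prop <- stats::approx(anchors_t, c(0, 50, 100), xout = t, ties = "ordered")$y
  occ$prop_time_pct <- prop
  occ$pain_status <- classify_pain_status(occ$tas_mm, pain_cutoff_mm)
  attr(occ, "degenerate_peak") <- degenerate
  if (degenerate)
    message(sprintf("horse %s: peak TAS on last occasion; 50%% anchor moved one segment back",
                    if (!is.null(occ$horse)) occ$horse[1] else "?"))
  occ
}

#' Classify pain status from TAS
#'
#' A TAS above the cut-off (default 10 mm, resembling a mild lameness grade)
#' categorizes the observation as "in pain"; TAS at or below it as free from
#' pain. The rule is strict: exactly 10 mm is no pain.
#'
#' @param tas TAS value(s) in mm, >= 0.
#' @param cutoff_mm Cut-off in mm (default 10).
#' @return Logical vector, `TRUE` = in pain.
#' @examples
#' classify_pain_status(c(0, 10, 10.5))  # FALSE FALSE TRUE
#' @export
classify_pain_status <- function(tas, cutoff_mm = 10) {
  if (any(tas < 0, na.rm = TRUE))
    ep_validation_error("TAS must be >= 0")
  tas > cutoff_mm
}

#' Apply proportional-time normalization to all horses
#'
#' @param occasions Occasion-level asymmetry table (`horse, occasion,
#'   clock_time_h, tas_mm, ...`).
#' @param pain_cutoff_mm TAS cut-off in mm.
#' @return The table with `prop_time_pct` and `pain_status` added.
#' @export
normalize_timeline <- function(occasions, pain_cutoff_mm = 10) {
  out <- lapply(split(occasions, occasions$horse), assign_proportional_time,
                pain_cutoff_mm = pain_cutoff_mm)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
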