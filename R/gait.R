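## Stride segmentation and vertical movement-asymmetry metrics.
##
## HDmin / PDmin: per stride, the difference between the head (pelvis)
## vertical minimum during the two stance phases; trial means with negative
## (left-side) means converted to positive right-side means. TAS: change in
## overall asymmetry versus the horse's baseline, |dHDmin|/2 + |dPDmin|.

# Dominant stride frequency from the periodogram of the (detrended) pelvis
# signal within the trot band. Errors if no clear periodicity.
estimate_stride_frequency <- function(x, fs, band = c(1.0, 2.5)) {
  x <- x - mean(x)
  n <- length(x)
  spec <- Mod(stats::fft(x))[seq_len(floor(n / 2))]^2
  freq <- (seq_len(floor(n / 2)) - 1) * fs / n
  in_band <- freq >= band[1] & freq <= band[2]
  if (!any(in_band))
    ep_segmentation_failure("trace too short to resolve the %.1f-%.1f Hz stride band",
                            band[1], band[2])
  # the trunk oscillates at twice the stride frequency; look for the dominant
  # spectral peak at either f or 2f within/above the band
  in_band2 <- freq >= 2 * band[1] & freq <= 2 * band[2]
  pow1 <- max(spec[in_band])
  pow2 <- if (any(in_band2)) max(spec[in_band2]) else 0
  nonzero <- freq > 0.2
  if (max(pow1, pow2) < 5 * stats::median(spec[nonzero]))
    ep_segmentation_failure("no dominant periodicity in the stride band")
  if (pow2 >= pow1) {
    f <- freq[in_band2][which.max(spec[in_band2])] / 2
  } else {
    f <- freq[in_band][which.max(spec[in_band])]
  }
  f
}

# Zero-phase Butterworth low-pass with odd-reflection padding (suppresses the
# start-up transient that plain filtfilt would leak into the first strides).
lowpass_zero_phase <- function(x, fs, cutoff, order = 4) {
  wc <- cutoff / (fs / 2)
  if (wc >= 1) return(x)
  bf <- signal::butter(order, wc, type = "low")
  n <- length(x)
  pad <- min(n - 1, ceiling(3 * fs / cutoff))
  m <- mean(x)
  xc <- x - m
  left <- 2 * xc[1] - xc[(pad + 1):2]   # odd reflection: no edge discontinuity
  right <- 2 * xc[n] - xc[(n - 1):(n - pad)]
  xf <- signal::filtfilt(bf, c(left, xc, right))
  xf[(pad + 1):(pad + n)] + m
}

# Local minima with a minimum separation and a prominence floor.
# Prominence of a minimum = height you must climb (on the lower of the two
# sides) to reach a lower minimum or the signal edge.
find_minima <- function(x, min_separation, min_prominence_frac = 0.2) {
  n <- length(x)
  d <- diff(x)
  cand <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  if (!length(cand)) return(integer(0))
  prominence <- vapply(cand, function(i) {
    lo <- x[i]
    left_max <- -Inf
    j <- i - 1L
    while (j >= 1L && x[j] >= lo) { left_max <- max(left_max, x[j]); j <- j - 1L }
    if (j < 1L) left_max <- max(left_max, max(x[1:i]))
    right_max <- -Inf
    j <- i + 1L
    while (j <= n && x[j] >= lo) { right_max <- max(right_max, x[j]); j <- j + 1L }
    if (j > n) right_max <- max(right_max, max(x[i:n]))
    min(left_max, right_max) - lo
  }, numeric(1))
  keep <- prominence >= min_prominence_frac * stats::median(prominence)
  cand <- cand[keep]; prominence <- prominence[keep]
  # greedy enforcement of the minimum separation, deepest minima first
  ord <- order(x[cand])
  selected <- logical(length(cand))
  for (k in ord) {
    if (!any(selected & abs(cand - cand[k]) < min_separation)) selected[k] <- TRUE
  }
  sort(cand[selected])
}

#' Segment a trot trace into strides
#'
#' Estimates the stride frequency from the dominant spectral peak of the
#' pelvis signal in the 1.0-2.5 Hz trot band, low-pass filters both signals
#' (zero-phase Butterworth, cut-off 4 x stride frequency), and detects local
#' vertical minima (minimum separation 0.3 / stride frequency, prominence at
#' least 20% of the median oscillation prominence). Minima are paired into
#' strides by alternation, with parity fixed by the first detected minimum;
#' a trailing unpaired minimum (partial stride) is discarded.
#'
#' @param trace An `ep_trace`.
#' @param stride_band Numeric length-2, admissible stride frequencies (Hz).
#' @return An `ep_segmentation` with stride boundaries, per-signal minima
#'   indices, stride count and the stride frequency estimate. The filtered
#'   signals are kept for metric computation.
#' @export
segment_strides <- function(trace, stride_band = c(1.0, 2.5)) {
  if (!inherits(trace, "ep_trace"))
    ep_validation_error("trace must be an ep_trace")
  fs <- trace$sampling_rate
  f <- estimate_stride_frequency(trace$pelvis_z, fs, stride_band)
  head_f <- lowpass_zero_phase(trace$head_z, fs, 4 * f)
  pelvis_f <- lowpass_zero_phase(trace$pelvis_z, fs, 4 * f)
  sep <- 0.3 / f * fs
  head_min <- find_minima(head_f, sep)
  pelvis_min <- find_minima(pelvis_f, sep)
  n_strides <- min(length(head_min), length(pelvis_min)) %/% 2L
  if (n_strides < 5L)
    ep_insufficient_data("only %d complete strides detected; >= 5 required",
                         n_strides)
  # alternation check: successive minima should be ~ half a stride apart
  gaps <- c(diff(head_min), diff(pelvis_min)) / fs
  if (any(gaps < 0.25 / f) || any(gaps > 0.85 / f))
    ep_segmentation_failure("irregular minima spacing breaks side alternation")
  head_min <- head_min[seq_len(2L * n_strides)]
  pelvis_min <- pelvis_min[seq_len(2L * n_strides)]
  boundaries <- pelvis_min[seq(1L, 2L * n_strides, by = 2L)]
  structure(list(stride_frequency = f, n_strides = n_strides,
                 boundaries = boundaries,
                 head_minima = head_min, pelvis_minima = pelvis_min,
                 head_filtered = head_f, pelvis_filtered = pelvis_f),
            class = "ep_segmentation")
}

#' Compute trial-mean movement asymmetry (HDmin, PDmin)
#'
#' For each stride the difference between the filtered vertical minima of
#' the two stance phases is taken (side 1 minus side 2, sides labelled by
#' alternation from the first detected minimum); the trial mean over strides
#' is reported. A negative trial mean is converted to a positive one
#' (`side_convention = "right_positive"`), mirroring the convention of
#' reporting left-side asymmetry as positive right-side asymmetry.
#'
#' @param trace An `ep_trace`.
#' @param seg Its `ep_segmentation` (defaults to segmenting `trace`).
#' @return An `ep_asymmetry` with `hdmin`, `pdmin` (mm, >= 0), `n_strides`,
#'   `side_convention`, and the signed per-stride differences.
#' @export
compute_asymmetry <- function(trace, seg = segment_strides(trace)) {
  per_stride <- function(xf, minima) {
    i1 <- minima[seq(1L, length(minima), by = 2L)]
    i2 <- minima[seq(2L, length(minima), by = 2L)]
    xf[i1] - xf[i2]
  }
  hd <- per_stride(seg$head_filtered, seg$head_minima)
  pd <- per_stride(seg$pelvis_filtered, seg$pelvis_minima)
  convert <- function(m) if (m < 0) -m else m
  structure(list(hdmin = convert(mean(hd)), pdmin = convert(mean(pd)),
                 hdmin_signed = mean(hd), pdmin_signed = mean(pd),
                 n_strides = seg$n_strides,
                 side_convention = "right_positive",
                 per_stride_hd = hd, per_stride_pd = pd),
            class = "ep_asymmetry")
}

#' Total Asymmetry Score relative to baseline
#'
#' TAS = |HDmin_current - HDmin_baseline| / 2 + |PDmin_current - PDmin_baseline|,
#' in mm. The head term is halved because head movement asymmetry in pelvic
#' limb lameness is a compensatory signal roughly twice the size of the
#' primary pelvic asymmetry.
#'
#' @param current,baseline `ep_asymmetry` results under the same side
#'   convention.
#' @return TAS in mm (>= 0).
#' @examples
#' a <- structure(list(hdmin = 10, pdmin = 8, side_convention = "right_positive"),
#'                class = "ep_asymmetry")
#' b <- structure(list(hdmin = 4, pdmin = 2, side_convention = "right_positive"),
#'                class = "ep_asymmetry")
#' compute_tas(a, b)  # |6|/2 + |6| = 9
#' @export
compute_tas <- function(current, baseline) {
  if (!identical(current$side_convention, baseline$side_convention))
    ep_validation_error("current and baseline use different side conventions")
  abs(current$hdmin - baseline$hdmin) / 2 + abs(current$pdmin - baseline$pdmin)
}

# Average trial-level asymmetry results into one occasion-level value (used
# when an occasion has a second straight-line trot after lunging).
combine_trials <- function(results) {
  structure(list(
    hdmin = mean(vapply(results, `[[`, numeric(1), "hdmin")),
    pdmin = mean(vapply(results, `[[`, numeric(1), "pdmin")),
    n_strides = sum(vapply(results, `[[`, numeric(1), "n_strides")),
    side_convention = results[[1]]$side_convention
  ), class = "ep_asymmetry")
}

#' Occasion-level asymmetry table from traces
#'
#' Runs segmentation and asymmetry computation for every trace, averages
#' multiple trials within an occasion, and derives each occasion's TAS
#' against the horse's baseline occasion (the occasion with the smallest
#' clock time, expected at or before induction).
#'
#' @param traces List of `ep_trace` objects.
#' @param occasion_times Data.frame `horse, occasion, clock_time_h`.
#' @return Data.frame `horse, occasion, clock_time_h, hdmin_mm, pdmin_mm,
#'   tas_mm, n_strides` with `tas_mm = 0` on each horse's baseline occasion.
#' @export
occasion_asymmetry <- function(traces, occasion_times) {
  key <- vapply(traces, function(tr) paste(tr$horse_id, tr$occasion_id, sep = "\r"),
                character(1))
  rows <- lapply(split(seq_along(traces), key), function(idx) {
    res <- combine_trials(lapply(traces[idx], function(tr)
      compute_asymmetry(tr, segment_strides(tr))))
    tr <- traces[[idx[1]]]
    data.frame(horse = tr$horse_id, occasion = tr$occasion_id,
               hdmin_mm = res$hdmin, pdmin_mm = res$pdmin,
               n_strides = res$n_strides, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- merge(occasion_times, df, by = c("horse", "occasion"), sort = FALSE)
  df <- df[order(df$horse, df$clock_time_h), ]
  out <- lapply(split(df, df$horse), function(h) {
    base <- h[which.min(h$clock_time_h), ]
    h$tas_mm <- abs(h$hdmin_mm - base$hdmin_mm) / 2 +
      abs(h$pdmin_mm - base$pdmin_mm)
    h$tas_mm[which.min(h$clock_time_h)] <- 0
    h
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("horse", "occasion", "clock_time_h", "hdmin_mm", "pdmin_mm",
          "tas_mm", "n_strides")]
}
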