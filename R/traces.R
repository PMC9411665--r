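## Marker trace container, synthetic trot waveform generator, and trace I/O.
##
## Waveform model: the trunk of a trotting horse describes two vertical
## oscillations per stride; asymmetric limb loading shows up as a
## once-per-stride component that raises one of the two minima. We use
##
##   z(t) = offset + A * cos(4*pi*f*t) + (d/2) * sin(2*pi*f*t) + noise
##
## Both terms have zero derivative at t = (2k+1)/(4f), so the noise-free
## signal has exact local minima there with values offset - A + (d/2)(-1)^k:
## alternate minima differ by exactly d, the requested asymmetry (valid
## whenever A > d/8, which holds for physiological amplitudes).

#' Construct a marker trace
#'
#' Container for one trial's time-stamped vertical head and pelvis marker
#' positions (mm), as exported by optical motion capture.
#'
#' @param time Strictly increasing time stamps in seconds.
#' @param head_z,pelvis_z Vertical positions in mm, same length as `time`.
#' @param horse_id,occasion_id Identifiers.
#' @param sampling_rate Sampling rate in Hz; checked against `time` (1%).
#' @return An `ep_trace` object.
#' @export
marker_trace <- function(time, head_z, pelvis_z, horse_id = "h1",
                         occasion_id = "o1", sampling_rate = NULL) {
  n <- length(time)
  if (n < 2 || length(head_z) != n || length(pelvis_z) != n)
    ep_validation_error("time, head_z, pelvis_z must have equal length >= 2")
  if (any(diff(time) <= 0))
    ep_validation_error("time must be strictly increasing")
  if (anyNA(time) || anyNA(head_z) || anyNA(pelvis_z))
    ep_validation_error("marker trace contains missing samples")
  fs_obs <- 1 / stats::median(diff(time))
  if (is.null(sampling_rate)) sampling_rate <- fs_obs
  if (abs(fs_obs - sampling_rate) > 0.01 * sampling_rate)
    ep_validation_error(
      "sampling_rate %.1f Hz inconsistent with time vector (observed %.1f Hz)",
      sampling_rate, fs_obs)
  structure(list(horse_id = horse_id, occasion_id = occasion_id,
                 sampling_rate = sampling_rate, time = as.numeric(time),
                 head_z = as.numeric(head_z), pelvis_z = as.numeric(pelvis_z)),
            class = "ep_trace")
}

#' Specify a synthetic trot trial
#'
#' @param stride_frequency Stride frequency in Hz (trot, typically 1.3-1.5).
#' @param duration Trial duration in seconds; must yield >= 5 full strides.
#' @param head_amplitude,pelvis_amplitude Amplitude of the twice-per-stride
#'   vertical oscillation, mm.
#' @param head_asym,pelvis_asym Intended difference between alternate vertical
#'   minima (HDmin / PDmin), mm.
#' @param noise_sd Gaussian measurement noise SD, mm.
#' @param sampling_rate Hz; must be >= 20 x stride_frequency (default 200).
#' @return An `ep_trial_spec` object.
#' @export
trial_spec <- function(stride_frequency = 1.4, duration = 20,
                       head_amplitude = 45, pelvis_amplitude = 35,
                       head_asym = 0, pelvis_asym = 0, noise_sd = 0,
                       sampling_rate = 200) {
  if (stride_frequency <= 0) ep_config_error("stride_frequency must be > 0")
  if (sampling_rate < 20 * stride_frequency)
    ep_config_error("sampling_rate %.0f Hz < 20 x stride_frequency",
                    sampling_rate)
  if (duration * stride_frequency < 5)
    ep_config_error("duration %.1f s yields fewer than 5 strides", duration)
  if (head_amplitude <= 0 || pelvis_amplitude <= 0)
    ep_config_error("amplitudes must be > 0")
  if (noise_sd < 0) ep_config_error("noise_sd must be >= 0")
  structure(list(stride_frequency = stride_frequency, duration = duration,
                 head_amplitude = head_amplitude,
                 pelvis_amplitude = pelvis_amplitude,
                 head_asym = head_asym, pelvis_asym = pelvis_asym,
                 noise_sd = noise_sd, sampling_rate = sampling_rate),
            class = "ep_trial_spec")
}

#' Generate one synthetic trot trial trace
#'
#' Builds vertical head and pelvis displacement series with two minima per
#' stride; the difference between alternate noise-free minima equals the
#' requested `head_asym` / `pelvis_asym` exactly (see file header for the
#' waveform and the argument placing exact minima at t = (2k+1)/(4f)).
#'
#' @param spec An `ep_trial_spec`.
#' @param seed Integer seed for the measurement noise.
#' @param horse_id,occasion_id Identifiers stored on the trace.
#' @return An `ep_trace`.
#' @export
generate_trial_trace <- function(spec, seed = 1L, horse_id = "h1",
                                 occasion_id = "o1") {
  if (!inherits(spec, "ep_trial_spec"))
    ep_config_error("spec must be an ep_trial_spec")
  fs <- spec$sampling_rate
  f <- spec$stride_frequency
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  wave <- function(A, d) A * cos(4 * pi * f * t) + (d / 2) * sin(2 * pi * f * t)
  noise <- with_seed(seed, list(
    head = stats::rnorm(n, 0, spec$noise_sd),
    pelvis = stats::rnorm(n, 0, spec$noise_sd)
  ))
  marker_trace(time = t,
               head_z = 1450 + wave(spec$head_amplitude, spec$head_asym) +
                 noise$head,
               pelvis_z = 1250 + wave(spec$pelvis_amplitude, spec$pelvis_asym) +
                 noise$pelvis,
               horse_id = horse_id, occasion_id = occasion_id,
               sampling_rate = fs)
}

#' Write a marker trace to a tab-separated file
#'
#' Format: header `time_s<TAB>head_z_mm<TAB>pelvis_z_mm`, one sample per line.
#'
#' @param trace An `ep_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_s = sprintf("%.6f", trace$time),
                   head_z_mm = sprintf("%.4f", trace$head_z),
                   pelvis_z_mm = sprintf("%.4f", trace$pelvis_z))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    ep_stop("equipain_io_error", "failed to write trace to '%s': %s",
            path, conditionMessage(ok))
  invisible(path)
}

#' Read a marker trace from a tab-separated file
#'
#' @param path File written by [write_trace()] (columns
#'   `time_s`, `head_z_mm`, `pelvis_z_mm`).
#' @param horse_id,occasion_id Identifiers; parsed from the
#'   `{horse}_{occasion}_{trial}.tsv` filename when omitted.
#' @return An `ep_trace`.
#' @export
read_trace <- function(path, horse_id = NULL, occasion_id = NULL) {
  if (!file.exists(path))
    ep_stop("equipain_io_error", "trace file '%s' does not exist", path)
  df <- utils::read.delim(path, check.names = FALSE)
  req <- c("time_s", "head_z_mm", "pelvis_z_mm")
  if (!all(req %in% names(df)))
    ep_validation_error("trace file '%s' lacks columns %s", path,
                        paste(req, collapse = ", "))
  parts <- strsplit(sub("\\.tsv$", "", basename(path)), "_")[[1]]
  if (is.null(horse_id)) horse_id <- if (length(parts) >= 1) parts[1] else "h?"
  if (is.null(occasion_id))
    occasion_id <- if (length(parts) >= 2) parts[2] else "o?"
  marker_trace(df$time_s, df$head_z_mm, df$pelvis_z_mm,
               horse_id = horse_id, occasion_id = occasion_id)
}
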