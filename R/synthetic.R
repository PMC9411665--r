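## Synthetic study generator emulating an LPS-synovitis induction experiment:
## 8 horses, one baseline gait analysis plus serial post-induction occasions,
## a pulse-shaped Total Asymmetry Score trajectory per horse, and paired
## before/after pain assessments by three simultaneous observers on four
## scales with strong floor effects.

#' Study configuration for the synthetic-data generator
#'
#' Defaults reproduce the design of the emulated induction study: 8 horses;
#' on average 6.6 (SD 1.2) gait-analysis occasions per horse (one baseline,
#' minimum four post-induction); per-horse peak TAS log-normal with mean 27
#' and SD 26 mm; asymmetry resolved (<10% of peak) within the 52 h horizon;
#' on average 12.1 (SD 2.4) pain assessments per horse by observers 1 and 2
#' plus one of observers 3-5, on all four built-in scales.
#'
#' @param n_horses Number of horses.
#' @param baseline_hdmin,baseline_pdmin Population-mean baseline asymmetries
#'   (mm); per-horse values jitter around these.
#' @param peak_tas_mean,peak_tas_sd Population mean / SD of the per-horse
#'   peak TAS increase (mm); peaks are drawn log-normal (non-negative,
#'   right-skewed, SD comparable to the mean).
#' @param peak_time_mean Mean time-to-peak of the asymmetry pulse (h).
#' @param resolution_horizon Time by which asymmetry has resolved (h);
#'   must exceed `peak_time_mean`.
#' @param occasions_per_horse_mean,occasions_per_horse_sd Gait occasions per
#'   horse (baseline included); draws are rounded with a floor of 5
#'   (baseline + minimum four post-induction).
#' @param assessments_per_horse_mean,assessments_per_horse_sd Pain
#'   assessments per horse; with two slots (before/after gait analysis) per
#'   occasion this calibrates the slot-retention probability.
#' @param observer_params Data.frame `observer, gain, bias, noise_sd,
#'   zero_inflation_prob` for observers 1-5; heterogeneity here is what moves
#'   inter-observer reliability between poor and good.
#' @param before_effect Score units added to assessments made before (rather
#'   than after) the gait analysis.
#' @param horse_effect_sd SD of a per-horse latent pain-expressiveness offset
#'   (fraction-of-scale units); individual variation in how much pain a horse
#'   displays for the same asymmetry.
#' @param link_half_saturation Half-saturation constant (mm) of the monotone
#'   saturating TAS -> latent pain map g(TAS) = TAS / (TAS + h).
#' @param trial_noise_sd Marker measurement noise for generated traces (mm).
#' @param trial_duration Trot trial duration (s).
#' @param seed Root seed; all per-horse/per-observer substreams derive from it.
#' @return An `ep_config` list.
#' @export
study_config <- function(n_horses = 8,
                         baseline_hdmin = 6, baseline_pdmin = 3,
                         peak_tas_mean = 27, peak_tas_sd = 26,
                         peak_time_mean = 8,
                         resolution_horizon = 52,
                         occasions_per_horse_mean = 6.6,
                         occasions_per_horse_sd = 1.2,
                         assessments_per_horse_mean = 12.1,
                         assessments_per_horse_sd = 2.4,
                         observer_params = default_observer_params(),
                         before_effect = 0.6,
                         horse_effect_sd = 0.02,
                         link_half_saturation = 40,
                         trial_noise_sd = 1.5,
                         trial_duration = 20,
                         seed = 1L) {
  if (n_horses < 1) ep_config_error("n_horses must be >= 1")
  for (s in c(peak_tas_sd, occasions_per_horse_sd, assessments_per_horse_sd))
    if (s < 0) ep_config_error("standard deviations must be >= 0")
  if (resolution_horizon <= peak_time_mean)
    ep_config_error("resolution_horizon must exceed peak_time_mean")
  if (any(observer_params$zero_inflation_prob < 0 |
          observer_params$zero_inflation_prob > 1))
    ep_config_error("zero_inflation_prob must lie in [0, 1]")
  if (peak_tas_mean <= 0 || link_half_saturation <= 0)
    ep_config_error("peak_tas_mean and link_half_saturation must be > 0")
  structure(list(
    n_horses = as.integer(n_horses),
    baseline_hdmin = baseline_hdmin, baseline_pdmin = baseline_pdmin,
    peak_tas_mean = peak_tas_mean, peak_tas_sd = peak_tas_sd,
    peak_time_mean = peak_time_mean,
    resolution_horizon = resolution_horizon,
    occasions_per_horse_mean = occasions_per_horse_mean,
    occasions_per_horse_sd = occasions_per_horse_sd,
    assessments_per_horse_mean = assessments_per_horse_mean,
    assessments_per_horse_sd = assessments_per_horse_sd,
    observer_params = observer_params,
    before_effect = before_effect,
    horse_effect_sd = horse_effect_sd,
    link_half_saturation = link_half_saturation,
    trial_noise_sd = trial_noise_sd,
    trial_duration = trial_duration,
    seed = as.integer(seed)
  ), class = "ep_config")
}

#' Default per-observer scoring parameters
#'
#' Observers map the latent pain signal g(TAS) to a fraction of the scale
#' maximum with observer-specific gain, additive bias, scoring noise and a
#' zero-inflation probability (scoring 0 regardless of the signal, a known
#' floor-effect mechanism in resting pain assessment).
#'
#' @return Data.frame with one row per observer 1-5.
#' @export
default_observer_params <- function() {
  data.frame(
    observer = 1:5,
    gain = c(0.26, 0.24, 0.28, 0.20, 0.22),
    bias = c(0.005, 0.000, 0.015, 0.000, 0.020),
    noise_sd = c(0.020, 0.025, 0.040, 0.050, 0.050),
    zero_inflation_prob = c(0.08, 0.10, 0.12, 0.18, 0.18)
  )
}

# Pulse value at time t (h) for peak P (mm) and time-to-peak tau (h):
# P * (t/tau) * exp(1 - t/tau), zero at and before induction.
tas_pulse <- function(t, peak, tau) {
  ifelse(t <= 0, 0, peak * (t / tau) * exp(1 - t / tau))
}

#' Generate one horse's true TAS trajectory
#'
#' Draws a per-horse peak (log-normal, matching the configured population
#' mean/SD) and time-to-peak, then evaluates the pulse
#' P (t/tau) exp(1 - t/tau) at a baseline occasion (t <= 0, TAS 0) and at
#' post-induction occasion times drawn over (1.5 h, horizon) and sorted.
#' Time-to-peak is clamped to [5, 10] h so that every trajectory is below
#' 10% of its peak by the 52 h resolution horizon, as in the emulated study.
#'
#' @param cfg An `ep_config`.
#' @param horse_id Horse label (used to derive the substream seed).
#' @param seed Root seed (defaults to `cfg$seed`).
#' @return Data.frame `occasion, clock_time_h, true_tas` including the
#'   baseline row; also carries `peak` and `tau` as attributes.
#' @export
generate_tas_trajectory <- function(cfg, horse_id, seed = cfg$seed) {
  sub <- derive_seed(seed, "trajectory", horse_id)
  with_seed(sub, {
    sdlog <- sqrt(log(1 + (cfg$peak_tas_sd / cfg$peak_tas_mean)^2))
    meanlog <- log(cfg$peak_tas_mean) - sdlog^2 / 2
    peak <- stats::rlnorm(1, meanlog, sdlog)
    tau <- min(10, max(5, stats::rlnorm(1, log(cfg$peak_time_mean) - 0.01, 0.15)))
    n_occ <- max(5L, as.integer(round(stats::rnorm(
      1, cfg$occasions_per_horse_mean, cfg$occasions_per_horse_sd))))
    t_post <- sort(stats::runif(n_occ - 1L, 1.5, cfg$resolution_horizon))
    times <- c(-24, t_post) # baseline measured the day before induction
    out <- data.frame(
      occasion = sprintf("o%02d", seq_along(times)),
      clock_time_h = times,
      true_tas = tas_pulse(times, peak, tau)
    )
    attr(out, "peak") <- peak
    attr(out, "tau") <- tau
    out
  })
}

# Monotone saturating TAS -> latent pain map.
pain_link <- function(tas, half_saturation) tas / (tas + half_saturation)

#' Generate multi-observer pain assessments along a TAS trajectory
#'
#' For each occasion, up to two assessment slots (before and after the gait
#' analysis) are retained with a probability calibrated so the expected
#' number of assessments per horse matches the configured mean. Each retained
#' slot is scored simultaneously by observers 1, 2 and a rotating third
#' observer (one of 3-5) on every scale:
#' `score = clip(round(scale_max * (gain * g(TAS) + bias + noise) +
#' before_effect * [before]), 0, scale_max)`, set to 0 with the observer's
#' zero-inflation probability. Noise and bias allow occasional nonzero
#' pre-induction scores, as observed in practice.
#'
#' @param cfg An `ep_config`.
#' @param trajectory Data.frame from [generate_tas_trajectory()].
#' @param scales Named list of `ep_scale` (default [builtin_scales()]).
#' @param horse_id Horse label.
#' @param seed Root seed (defaults to `cfg$seed`).
#' @return Data.frame `horse, occasion, observer, scale, timing, phase,
#'   total_score` in long format.
#' @export
generate_pain_assessments <- function(cfg, trajectory,
                                      scales = builtin_scales(),
                                      horse_id = "h1", seed = cfg$seed) {
  if (!nrow(trajectory)) ep_config_error("trajectory is empty")
  for (s in scales) if (!inherits(s, "ep_scale"))
    ep_config_error("scales must be ep_scale objects")
  p_keep <- min(1, cfg$assessments_per_horse_mean /
                  (2 * cfg$occasions_per_horse_mean))
  op <- cfg$observer_params
  h_eff <- with_seed(derive_seed(seed, "horse_effect", horse_id),
                     stats::rnorm(1, 0, cfg$horse_effect_sd %||% 0))
  sub <- derive_seed(seed, "assessments", horse_id)
  with_seed(sub, {
    rows <- list()
    for (i in seq_len(nrow(trajectory))) {
      third <- sample(3:5, 1)
      for (timing in c("before_gait", "after_gait")) {
        if (stats::runif(1) > p_keep) next
        for (obs in c(1L, 2L, third)) {
          pars <- op[op$observer == obs, ]
          g <- pain_link(trajectory$true_tas[i], cfg$link_half_saturation)
          for (sc in scales) {
            latent <- pars$gain * g + pars$bias + h_eff +
              stats::rnorm(1, 0, pars$noise_sd)
            total <- round(sc$total_max * latent +
                             cfg$before_effect * (timing == "before_gait"))
            total <- min(max(total, 0), sc$total_max)
            if (stats::runif(1) < pars$zero_inflation_prob) total <- 0
            rows[[length(rows) + 1L]] <- data.frame(
              horse = horse_id, occasion = trajectory$occasion[i],
              observer = obs, scale = sc$name, timing = timing,
              phase = if (trajectory$clock_time_h[i] <= 0)
                "pre_induction" else "post_induction",
              total_score = as.integer(total), stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a complete synthetic study
#'
#' Orchestrates per-horse TAS trajectories, per-occasion marker traces whose
#' injected asymmetries reproduce the trajectory TAS (head share 40%:
#' HDmin = baseline + 0.8 TAS, PDmin = baseline + 0.6 TAS, so that
#' |dHDmin|/2 + |dPDmin| = TAS), and multi-observer pain assessments.
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg An `ep_config`.
#' @param out_dir Optional directory; when given, trace TSV files
#'   (`{horse}_{occasion}_{trial}.tsv`), `occasions.csv` and
#'   `assessments.csv` are written there.
#' @param traces Generate marker traces? (`FALSE` returns trajectory-level
#'   TAS only, for analyses that do not need the signal stage).
#' @return List with `occasions` (horse, occasion, clock_time_h, true_tas,
#'   head_asym, pelvis_asym), `assessments`, `traces` (list of `ep_trace` or
#'   NULL), and `config`.
#' @export
generate_study <- function(cfg = study_config(), out_dir = NULL,
                           traces = TRUE) {
  if (!inherits(cfg, "ep_config")) ep_config_error("cfg must be an ep_config")
  head_share <- 0.4
  occ_list <- list(); ass_list <- list(); trace_list <- list()
  horses <- sprintf("h%02d", seq_len(cfg$n_horses))
  for (h in horses) {
    traj <- generate_tas_trajectory(cfg, h)
    base_hd <- with_seed(derive_seed(cfg$seed, "baseline", h),
                         stats::rnorm(2, c(cfg$baseline_hdmin,
                                           cfg$baseline_pdmin), 0.5))
    occ <- traj
    occ$horse <- h
    occ$head_asym <- pmax(0, base_hd[1]) + 2 * head_share * occ$true_tas
    occ$pelvis_asym <- pmax(0, base_hd[2]) + (1 - head_share) * occ$true_tas
    occ_list[[h]] <- occ[, c("horse", "occasion", "clock_time_h", "true_tas",
                             "head_asym", "pelvis_asym")]
    ass_list[[h]] <- generate_pain_assessments(cfg, traj, horse_id = h)
    if (traces) {
      for (i in seq_len(nrow(occ))) {
        sp <- trial_spec(stride_frequency = 1.4,
                         duration = cfg$trial_duration,
                         head_asym = occ$head_asym[i],
                         pelvis_asym = occ$pelvis_asym[i],
                         noise_sd = cfg$trial_noise_sd)
        tr <- generate_trial_trace(
          sp, seed = derive_seed(cfg$seed, "trace", h, occ$occasion[i]),
          horse_id = h, occasion_id = occ$occasion[i])
        trace_list[[paste(h, occ$occasion[i], sep = "_")]] <- tr
      }
    }
  }
  study <- list(occasions = do.call(rbind, c(occ_list, make.row.names = FALSE)),
                assessments = do.call(rbind, c(ass_list, make.row.names = FALSE)),
                traces = if (traces) trace_list else NULL,
                config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ep_write_csv(study$occasions, file.path(out_dir, "occasions.csv"))
    ep_write_csv(study$assessments, file.path(out_dir, "assessments.csv"))
    for (nm in names(trace_list))
      write_trace(trace_list[[nm]], file.path(out_dir, paste0(nm, "_t1.tsv")))
  }
  study
}
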