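test_that("noise-free traces have alternate minima split by the requested asymmetry", {
  sp <- trial_spec(stride_frequency = 1.4, duration = 10, pelvis_asym = 10,
                   noise_sd = 0)
  tr <- generate_trial_trace(sp, seed = 1)
  # locate minima of the constructed waveform numerically and difference them
  z <- tr$pelvis_z
  idx <- which(diff(sign(diff(z))) > 0) + 1
  vals <- z[idx]
  d <- abs(mean(vals[seq(1, length(vals), 2)]) -
             mean(vals[seq(2, length(vals), 2)]))
  expect_equal(d, 10, tolerance = 1e-3) # exact up to the 200 Hz sample grid
  # symmetric head: alternate minima equal to machine precision
  zh <- tr$head_z
  idx_h <- which(diff(sign(diff(zh))) > 0) + 1
  vh <- zh[idx_h]
  expect_equal(mean(vh[seq(1, length(vh), 2)]),
               mean(vh[seq(2, length(vh), 2)]), tolerance = 1e-9)
})

test_that("TAS trajectories are pulse-shaped and calibrated to the study conditions", {
  cfg <- study_config(seed = 123)
  traj <- generate_tas_trajectory(cfg, "h01")
  expect_equal(traj$true_tas[traj$clock_time_h <= 0], 0) # baseline occasion
  peak <- attr(traj, "peak"); tau <- attr(traj, "tau")
  expect_equal(equipain:::tas_pulse(tau, peak, tau), peak) # maximum at t = tau
  # population calibration at n = 1000 horses
  peaks <- vapply(seq_len(1000), function(i)
    attr(generate_tas_trajectory(cfg, paste0("x", i)), "peak"), numeric(1))
  expect_lt(abs(mean(peaks) - 27) / 27, 0.10)
  expect_lt(abs(sd(peaks) - 26) / 26, 0.25)
  # resolution: every trajectory below 10% of its peak at the 52 h horizon
  taus <- vapply(seq_len(1000), function(i)
    attr(generate_tas_trajectory(cfg, paste0("x", i)), "tau"), numeric(1))
  frac_at_horizon <- (52 / taus) * exp(1 - 52 / taus)
  expect_true(all(frac_at_horizon < 0.10))
})

test_that("occasion counts respect the baseline-plus-minimum-four design", {
  cfg <- study_config(seed = 5)
  for (h in sprintf("h%02d", 1:10)) {
    traj <- generate_tas_trajectory(cfg, h)
    expect_gte(nrow(traj), 5)
    expect_equal(sum(traj$clock_time_h <= 0), 1)
    expect_true(all(diff(traj$clock_time_h) > 0))
    expect_true(all(traj$clock_time_h[-1] >= 1.5))
    expect_true(all(traj$clock_time_h <= cfg$resolution_horizon))
  }
})

test_that("pain assessments respect scale ranges, design and degenerate configs", {
  cfg <- study_config(seed = 9)
  traj <- generate_tas_trajectory(cfg, "h01")
  ass <- generate_pain_assessments(cfg, traj, horse_id = "h01")
  expect_setequal(unique(ass$scale), c("HGS", "EQUUS-FAP", "EPS", "CPS"))
  maxes <- c(HGS = 12, `EQUUS-FAP` = 18, EPS = 30, CPS = 39)
  expect_true(all(ass$total_score >= 0 & ass$total_score <= maxes[ass$scale]))
  expect_true(all(ass$observer[!ass$observer %in% c(1, 2)] %in% 3:5))
  # degenerate generator: zero signal, zero noise, full zero-inflation
  op <- default_observer_params()
  op$bias <- 0; op$noise_sd <- 0; op$zero_inflation_prob <- 1
  cfg0 <- study_config(observer_params = op, before_effect = 0, seed = 9)
  flat <- traj; flat$true_tas <- 0
  ass0 <- generate_pain_assessments(cfg0, flat, horse_id = "h01")
  expect_true(all(ass0$total_score == 0))
  # monotone link, no noise or zero-inflation: totals non-decreasing in TAS
  op1 <- op; op1$zero_inflation_prob <- 0
  cfg1 <- study_config(observer_params = op1, before_effect = 0, seed = 9)
  ramp <- data.frame(occasion = sprintf("o%02d", 1:6),
                     clock_time_h = c(-24, 2, 4, 6, 8, 10),
                     true_tas = c(0, 5, 10, 20, 40, 80))
  ass1 <- generate_pain_assessments(cfg1, ramp, horse_id = "h01")
  one <- ass1[ass1$observer == 1 & ass1$scale == "CPS" &
                ass1$timing == "after_gait", ]
  one <- one[order(match(one$occasion, ramp$occasion)), ]
  expect_true(all(diff(one$total_score) >= 0))
})

test_that("assessment volume and floor effect match the emulated study", {
  st <- generate_study(study_config(seed = 21), traces = FALSE)
  events <- unique(st$assessments[, c("horse", "occasion", "timing")])
  per_horse <- as.numeric(table(events$horse))
  expect_lt(abs(mean(per_horse) - 12.1), 2 * 2.4)
  maxes <- c(HGS = 12, `EQUUS-FAP` = 18, EPS = 30, CPS = 39)
  floor_frac <- mean(st$assessments$total_score <=
                       0.10 * maxes[st$assessments$scale])
  expect_gte(floor_frac, 0.5)
})

test_that("a study is reproducible from its seed and structurally complete", {
  cfg <- study_config(n_horses = 3, trial_duration = 8, seed = 77)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$occasions, s2$occasions)
  expect_identical(s1$assessments, s2$assessments)
  expect_identical(s1$traces, s2$traces)
  expect_equal(length(unique(s1$occasions$horse)), 3)
  base <- s1$occasions[s1$occasions$clock_time_h <= 0, ]
  expect_equal(as.numeric(table(base$horse)), rep(1, 3))
  # file outputs byte-identical for the same seed
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  generate_study(cfg, out_dir = d1)
  generate_study(cfg, out_dir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("generated traces round-trip through the gait stack to the injected TAS", {
  cfg <- study_config(n_horses = 2, trial_noise_sd = 0, trial_duration = 10,
                      seed = 31)
  st <- generate_study(cfg)
  occ <- occasion_asymmetry(st$traces,
                            st$occasions[, c("horse", "occasion", "clock_time_h")])
  merged <- merge(occ, st$occasions, by = c("horse", "occasion"))
  expect_lt(max(abs(merged$tas_mm - merged$true_tas)), 0.1)
})
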