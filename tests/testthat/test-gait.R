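test_that("noise-free synthetic traces segment into the analytic stride count", {
  sp <- trial_spec(stride_frequency = 1.4, duration = 10, noise_sd = 0)
  tr <- generate_trial_trace(sp, seed = 1)
  seg <- segment_strides(tr)
  expect_equal(seg$n_strides, 14) # f * T = 1.4 * 10
  expect_equal(seg$stride_frequency, 1.4, tolerance = 0.02)
  # minima sit at the analytic phase positions t = (2k+1)/(4f), +/- 1 sample
  expected_idx <- round(((2 * (0:27) + 1) / (4 * 1.4)) * sp$sampling_rate) + 1
  expect_true(all(abs(seg$pelvis_minima - expected_idx) <= 1))
  # 1 mm of noise does not change the stride count
  tr_n <- generate_trial_trace(trial_spec(stride_frequency = 1.4, duration = 10,
                                          noise_sd = 1), seed = 2)
  expect_equal(segment_strides(tr_n)$n_strides, 14)
})

test_that("too-short traces raise an insufficient-data error", {
  sp <- trial_spec(stride_frequency = 1.4, duration = 5) # 7 strides, valid spec
  tr <- generate_trial_trace(sp, seed = 1)
  short <- marker_trace(tr$time[1:400], tr$head_z[1:400], tr$pelvis_z[1:400],
                        sampling_rate = 200) # 2 strides
  expect_error(segment_strides(short), class = "equipain_insufficient_data")
  expect_error(trial_spec(stride_frequency = 1.4, duration = 1.5),
               class = "equipain_config_error")
})

test_that("aperiodic signals raise a segmentation-failure error", {
  set.seed(4)
  t <- (0:1999) / 200
  noise <- marker_trace(t, 1450 + rnorm(2000, 0, 5), 1250 + rnorm(2000, 0, 5),
                        sampling_rate = 200)
  expect_error(segment_strides(noise), class = "equipain_segmentation_failure")
})

test_that("injected asymmetries are recovered across the metric grid", {
  grid <- expand.grid(hd = c(0, 5, 10, 20), pd = c(0, 5, 10, 20))
  for (noise in c(0, 1)) {
    tol <- if (noise == 0) 0.1 else 1
    for (i in seq_len(nrow(grid))) {
      sp <- trial_spec(stride_frequency = 1.4, duration = 10,
                       head_asym = grid$hd[i], pelvis_asym = grid$pd[i],
                       noise_sd = noise)
      a <- compute_asymmetry(generate_trial_trace(sp, seed = 100 + i))
      expect_equal(a$hdmin, grid$hd[i], tolerance = tol + 1e-12,
                   ignore_attr = TRUE)
      expect_equal(a$pdmin, grid$pd[i], tolerance = tol + 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("asymmetry is invariant to amplitude doubling and mirrored traces", {
  base <- trial_spec(stride_frequency = 1.3, duration = 10, head_asym = 8,
                     pelvis_asym = 6, noise_sd = 0)
  a1 <- compute_asymmetry(generate_trial_trace(base, seed = 1))
  double <- trial_spec(stride_frequency = 1.3, duration = 10,
                       head_amplitude = 90, pelvis_amplitude = 70,
                       head_asym = 8, pelvis_asym = 6, noise_sd = 0)
  a2 <- compute_asymmetry(generate_trial_trace(double, seed = 1))
  expect_equal(a1$hdmin, a2$hdmin, tolerance = 0.05)
  expect_equal(a1$pdmin, a2$pdmin, tolerance = 0.05)
  # mirroring (side swap = negating the once-per-stride term) keeps magnitudes
  mirror <- trial_spec(stride_frequency = 1.3, duration = 10, head_asym = -8,
                       pelvis_asym = -6, noise_sd = 0)
  a3 <- compute_asymmetry(generate_trial_trace(mirror, seed = 1))
  expect_equal(a3$hdmin, a1$hdmin, tolerance = 0.05)
  expect_equal(a3$pdmin, a1$pdmin, tolerance = 0.05)
  expect_equal(a3$side_convention, "right_positive")
})

test_that("downsampling 200 to 100 Hz moves metrics by less than 0.5 mm", {
  sp200 <- trial_spec(stride_frequency = 1.4, duration = 10, head_asym = 10,
                      pelvis_asym = 7, noise_sd = 0, sampling_rate = 200)
  sp100 <- trial_spec(stride_frequency = 1.4, duration = 10, head_asym = 10,
                      pelvis_asym = 7, noise_sd = 0, sampling_rate = 100)
  a200 <- compute_asymmetry(generate_trial_trace(sp200, seed = 1))
  a100 <- compute_asymmetry(generate_trial_trace(sp100, seed = 1))
  expect_lt(abs(a200$hdmin - a100$hdmin), 0.5)
  expect_lt(abs(a200$pdmin - a100$pdmin), 0.5)
})

test_that("TAS follows the half-head-plus-pelvis change formula", {
  mk <- function(hd, pd) structure(
    list(hdmin = hd, pdmin = pd, side_convention = "right_positive"),
    class = "ep_asymmetry")
  expect_equal(compute_tas(mk(4, 2), mk(4, 2)), 0)
  expect_equal(compute_tas(mk(10, 8), mk(4, 2)), 9)   # |6|/2 + |6|
  expect_equal(compute_tas(mk(24, 5), mk(4, 5)), 10)  # only head moves, 20/2
  expect_gte(compute_tas(mk(1, 9), mk(7, 2)), 0)      # non-negative always
})

test_that("trace files round-trip through write_trace/read_trace", {
  sp <- trial_spec(stride_frequency = 1.4, duration = 6, pelvis_asym = 5,
                   noise_sd = 0.5)
  tr <- generate_trial_trace(sp, seed = 9, horse_id = "h03", occasion_id = "o02")
  path <- file.path(withr::local_tempdir(), "h03_o02_t1.tsv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$horse_id, "h03")
  expect_equal(back$occasion_id, "o02")
  expect_equal(back$pelvis_z, tr$pelvis_z, tolerance = 1e-4)
})
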