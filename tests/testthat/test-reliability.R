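test_that("ICC(2,A1) matches the ANOVA oracle and external reference values", {
  # fixed 6x3 reference matrix; expected agreement ICC and 95% CI computed
  # independently (two-way random-effects, absolute agreement, single rater)
  m <- matrix(c(1, 2, 3, 2, 4, 3, 5, 5, 6, 3, 2, 2, 7, 8, 9, 4, 4, 5),
              ncol = 3, byrow = TRUE)
  r <- icc_agreement(m)
  expect_equal(r$estimate, 0.8809524, tolerance = 1e-6)
  expect_equal(r$ci_low, 0.5996, tolerance = 1e-3)
  expect_equal(r$ci_high, 0.9806, tolerance = 1e-3)
  expect_equal(r$estimate, icc_oracle(m), tolerance = 1e-10)
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
})

test_that("identical rater columns give ICC 1 and constant ratings error", {
  m <- cbind(1:6, 1:6, 1:6)
  expect_equal(icc_agreement(m)$estimate, 1)
  expect_error(icc_agreement(matrix(3, 6, 3)),
               class = "equipain_degenerate_error")
  expect_error(icc_agreement(cbind(1:4, 2:5)),
               class = "equipain_insufficient_data")
})

test_that("ICC equals the brute-force ANOVA decomposition on random matrices", {
  set.seed(42)
  for (i in 1:20) {
    m <- matrix(sample(0:10, 30, TRUE), nrow = 10, ncol = 3)
    if (stats::var(as.vector(m)) == 0) next
    expect_equal(icc_agreement(m)$estimate, icc_oracle(m), tolerance = 1e-10)
  }
})

test_that("agreement ICC is sensitive to rater offsets and row permutation invariant", {
  set.seed(7)
  m <- matrix(rnorm(60, 5, 2), ncol = 3)
  base <- icc_agreement(m)$estimate
  shifted <- m; shifted[, 2] <- shifted[, 2] + 3
  expect_lt(icc_agreement(shifted)$estimate, base)
  expect_equal(icc_agreement(shifted)$estimate, icc_oracle(shifted),
               tolerance = 1e-10)
  expect_equal(icc_agreement(m[sample(nrow(m)), ])$estimate, base)
})

test_that("independent raters give ICC near zero at large n", {
  set.seed(13)
  m <- cbind(rnorm(500), rnorm(500))
  expect_lt(abs(icc_agreement(m)$estimate), 0.1)
})

test_that("simulation with known variance components recovers the theoretical ICC", {
  set.seed(99)
  s2_s <- 4; s2_r <- 1; s2_e <- 2
  truth <- s2_s / (s2_s + s2_r + s2_e)
  est <- replicate(200, {
    n <- 200; k <- 3
    subj <- rnorm(n, 0, sqrt(s2_s))
    rat <- rnorm(k, 0, sqrt(s2_r))
    m <- outer(subj, rep(1, k)) + outer(rep(1, n), rat) +
      matrix(rnorm(n * k, 0, sqrt(s2_e)), n, k)
    icc_agreement(m)$estimate
  })
  expect_lt(abs(mean(est) - truth), 0.03)
})

test_that("reliability labels follow the conventional bands", {
  expect_equal(classify_reliability(0.753), "good")
  expect_equal(classify_reliability(0.648), "moderate")
  expect_equal(classify_reliability(0.522), "moderate")
  expect_equal(classify_reliability(0.432), "poor")
  expect_equal(classify_reliability(c(0.95, 0.9, 0.5, 0.499)),
               c("excellent", "excellent", "moderate", "poor"))
  expect_error(classify_reliability(1.2), class = "equipain_validation_error")
})

test_that("ratings matrices pool the rotating third observer", {
  ass <- expand.grid(horse = "h01", occasion = sprintf("o%d", 1:6),
                     timing = "after_gait", scale = "HGS",
                     stringsAsFactors = FALSE)
  third <- rep(c(3, 4, 5), 2)
  rows <- do.call(rbind, lapply(seq_len(nrow(ass)), function(i) {
    data.frame(ass[i, , drop = FALSE][rep(1, 3), ],
               observer = c(1, 2, third[i]), total_score = c(i, i + 1, i))
  }))
  m <- ratings_matrix(rows, "HGS")
  expect_equal(ncol(m), 3)
  expect_true(all(!is.na(m)))
  m5 <- ratings_matrix(rows, "HGS", pool_third = FALSE)
  expect_equal(ncol(m5), 5)
  expect_equal(sum(!is.na(m5[, "rater3"])), 2)
})
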