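---
title: "Methods: linking resting pain scores to movement asymmetry in trotting horses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking resting pain scores to movement asymmetry in trotting horses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equipain)
```

## The scientific problem

Orthopedic pain in horses expresses itself during motion as lameness:
reduced loading of the painful limb produces left/right asymmetry in the
vertical motion of the head and pelvis. Whether the *same* pain is visible
at rest — in facial expressions and body behaviors scored with structured
pain scales — is much less clear, and it matters clinically: a resting pain
score that tracks movement asymmetry would help decide whether an asymmetric
horse is actually in pain.

`equipain` implements a complete, testable pipeline for studies of this
question in the transient-synovitis induction design: horses serve as their
own controls, movement asymmetry is measured objectively before induction
and serially afterwards until it resolves, and several observers score pain
at rest on multiple scales immediately before and after each gait
measurement. Because raw data from such experiments are generally not
published, the package includes a first-class synthetic-data generator that
reproduces the statistical structure of the design, so every stage of the
analysis is exercised end to end without any downloads.

## Asymmetry metrics

From each trot trial only the vertical head and pelvis marker positions are
used. The trunk of a trotting horse describes two vertical oscillations per
stride, one per diagonal stance phase. The standard impact-lameness metrics
are

* **HDmin** — the trial-mean difference between the head's minimum height
  during left and right stance,
* **PDmin** — the same for the pelvis,

with negative (left-side) trial means converted to positive right-side
means. The change in overall asymmetry relative to the horse's own baseline
is summarized as the **Total Asymmetry Score**

$$\mathrm{TAS} = \tfrac{1}{2}\,\lvert\Delta \mathrm{HD_{min}}\rvert +
\lvert\Delta \mathrm{PD_{min}}\rvert \quad [\mathrm{mm}],$$

halving the head term because compensatory head movement in pelvic-limb
lameness is roughly twice the size of the primary pelvic signal. Halving is
applied to the differenced value; this is algebraically identical to halving
before differencing.

### Stride segmentation

Published pipelines defer segmentation details to proprietary
implementations, so the package fixes a reproducible procedure:

1. stride frequency estimated from the dominant periodogram peak of the
   pelvis signal, searched in the 1.0–2.5 Hz trot band (and its first
   harmonic, since the trunk oscillates at twice the stride frequency);
2. zero-phase 4th-order Butterworth low-pass at 4 × stride frequency,
   applied to odd-reflection-padded signals so no start-up transient leaks
   into the first strides;
3. local-minima detection with a minimum separation of 0.3 / stride
   frequency and a prominence floor of 20% of the median oscillation
   prominence;
4. minima paired into strides by alternation; the parity of the first
   detected minimum fixes the side-1/side-2 labelling; a trailing unpaired
   minimum is discarded.

True left/right identity is unknowable from trunk markers alone; the
magnitude-based TAS formula is insensitive to this, and the sign convention
(`right_positive`) is applied exactly once, at the trial level. Traces with
fewer than five complete strides are rejected rather than analyzed.

### When an occasion has two trials

Study protocols sometimes add a second straight-line trot after lunging.
The combination rule is not standardized; the package averages trial means
within an occasion, the simplest symmetric choice.

## Pain scales

The four scales are represented structurally: total-score ranges 0–12
(HGS), 0–18 (EQUUS-FAP), 0–30 (EPS), 0–39 (CPS) and observation times
(2 min; 5 min for CPS). Item-level content belongs to the original scale
publications and is deliberately not reproduced — the analysis consumes
totals only, with optional user-supplied item lists validated against the
range metadata. Score summaries report median and interquartile limits with
linear interpolation between order statistics (R quantile type 7); the
interpolated quartiles reproduce the fractional quartile values seen in
published summary tables. Shapiro–Wilk normality flags accompany each cell;
constant cells are flagged "not applicable" rather than given a p-value.

## Proportional time

Each horse's induction response runs on its own clock, so series are
aligned by a piecewise-linear map: baseline → 0%, the occasion of maximum
TAS → 50%, the last measurement → 100%, with intermediate occasions
interpolated linearly *in clock time* (rank-based interpolation would
discard the actual spacing; clock-time linearity is the natural choice when
spacing is informative). Ties in the maximum resolve to the earliest
occasion. If the maximum falls on the final occasion — a geometry the
design makes unlikely but does not exclude — the 50% anchor is moved to the
preceding occasion's clock time and the case is flagged; monotonicity of
the map is preserved. A maximum at baseline leaves no usable anchors and is
an error.

Pain status is a strict threshold on the TAS change: above 10 mm
(resembling a mild lameness grade) the observation is "pain", at or below
it "no pain". The cut-off is configurable.

## Inter-observer reliability

Agreement between observers scoring the same events is quantified with the
two-way random-effects, absolute-agreement, single-rater intraclass
correlation, ICC(2,A1). From the two-way ANOVA mean squares (rows =
assessment events, columns = raters),

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}
{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with the McGraw–Wong F-based 95% confidence interval (Satterthwaite
degrees of freedom). Because the third observer rotated among three people,
the default analysis pools observers 3–5 into a single third-rater column —
mirroring the design in which every event had exactly three simultaneous
raters — with a complete-case analysis after pooling; keeping the five
observers as separate sparse columns is available as an option. Estimates
are categorized by the conventional bands (< 0.5 poor, 0.5–0.75 moderate,
0.75–0.9 good, ≥ 0.9 excellent).

## The association model

The relationship between total pain score and TAS need not be linear, so it
is modelled semiparametrically, one observer × scale at a time (the design's
rotating observers make crossed random effects unidentifiable at this size):

$$y_{ij} = \beta_0 + f(\mathrm{TAS}_{ij}) + \beta_1\,
\mathbb{1}[\text{before gait analysis}] + b_i + \varepsilon_{ij},$$

with horse random intercepts $b_i \sim N(0, \sigma^2_h)$ and AR(1)
within-horse residual correlation over the observation order (occasions
sorted by proportional time; proportional time enters *only* through this
ordering, since TAS and timing are the substantive covariates).

The smooth $f$ is a cubic B-spline with `k = 10` basis functions on
quantile-spaced knots. The roughness penalty is built from second-order
*divided* differences of the coefficients with respect to the Greville
abscissae, so its null space is exactly the affine functions for any knot
placement — this makes the infinite-smoothing limit coincide exactly with a
straight-line fit, a property the test suite exploits as a closed-form
oracle. In the mixed-model representation the null-space (linear) component
is a fixed effect and the wiggly component enters as i.i.d. random
coefficients with variance $\sigma^2/\lambda$.

Estimation maximizes the profiled restricted likelihood over
$(\sigma^2_h/\sigma^2,\ 1/\lambda,\ \varphi)$ numerically (Nelder–Mead on
log/atanh scales, multiple starts), exploiting the block-diagonal structure
over horses. Reported quantities:

* **EDF** of the smooth — trace of the corresponding block of the influence
  matrix of the penalized GLS fit; 1 means linear, ~3 a cubic-like shape.
* **Adjusted explained deviance** $R^2_{adj} = 1 - \frac{RSS/(n -
  \mathrm{edf}_{tot})}{TSS/(n-1)}$, computed from population-level fitted
  values; it is admissible below zero, which genuinely occurs on null data.
* **p(association)** — likelihood-ratio of the full model against the model
  with the smooth removed entirely (both by maximum likelihood), referred
  to $\chi^2$ with the smooth's EDF. Null simulations in the test suite
  confirm the test holds its 5% level to within two percentage points.
* **p(timing)** — Wald test of the before/after-gait-analysis coefficient.
* **Partial effect curves** — centered smooth with pointwise 95% bands from
  the coefficient covariance.

An AR(1) estimate on the boundary (|φ| > 0.98) triggers a warning and a
profile refit with φ clamped, rather than silently reporting a degenerate
correlation. A smoothing variance driven to zero is reported as λ = ∞ and
the smooth collapses to its linear component.

## Diagnostic accuracy

Population-level model predictions (random effect at zero — the clinically
relevant prediction for an unseen horse; horse-conditional predictions are
also exposed) are evaluated against the TAS-defined pain status with
empirical ROC curves. AUC is computed by the trapezoid rule, identical to
the Mann–Whitney probability with ties counted one half; the 95% CI uses
the DeLong placement-variance estimate, clipped to [0, 1]. Default accuracy
bands: ≤ 0.5 no discrimination, (0.5, 0.7) poor, [0.7, 0.8) good,
[0.8, 0.9) excellent, ≥ 0.9 outstanding; all configurable.

## The synthetic study generator

The generator emulates the induction design: 8 horses; one baseline gait
occasion (measured the day before induction) plus serial post-induction
occasions, on average 6.6 (SD 1.2) per horse with a floor of baseline +
four; per-horse asymmetry trajectories following the pulse
$P\,(t/\tau)\,e^{1-t/\tau}$ with log-normal peaks calibrated to mean 27 mm
and SD 26 mm; and on average 12.1 (SD 2.4) pain assessments per horse,
scored simultaneously by observers 1, 2 and one of observers 3–5 on all
four scales, in paired before/after-gait slots.

Key generator choices, fixed once:

* **Trace waveform.** $z(t) = A\cos(4\pi f t) + \tfrac{d}{2}\sin(2\pi f t)
  + \text{noise}$. Both terms have zero derivative at $t = (2k+1)/(4f)$, so
  the noise-free signal has exact local minima there with values
  $-A \pm d/2$: the alternate-minima difference equals the requested
  asymmetry $d$ exactly (verified numerically in the tests), which makes
  metric-recovery tolerances meaningful.
* **Time-to-peak** $\tau$: the emulated studies report first measurements at
  1.5 h and resolution within 52 h but not the peak time; τ is drawn
  log-normal around 8 h (typical of acute LPS synovitis lameness) and
  clamped to [5, 10] h, which guarantees every trajectory is below 10% of
  its peak at the 52 h horizon.
* **Occasion spacing** is uniform over (1.5 h, horizon), sorted — the
  per-horse spacing distribution is not reported in the emulated design, so
  the least-informative choice is used.
* **Injected asymmetry split.** TAS is decomposed with a fixed 40% head
  share (HDmin = baseline + 0.8 TAS, PDmin = baseline + 0.6 TAS), so the
  gait stack recovers the injected TAS exactly:
  $0.8/2 + 0.6 = 1$.
* **Observer model.** `score = clip(round(scale_max × (gain·g(TAS) + bias +
  horse_effect + noise) + before_effect·[before]), 0, scale_max)` with the
  saturating link $g(t) = t/(t+40)$ and per-observer zero-inflation
  (scoring 0 regardless of signal). Defaults were chosen once so the
  synthetic study reproduces the qualitative features of real data: a
  strong floor effect (well over half of totals at ≤ 10% of scale maximum),
  occasional nonzero pre-induction scores, moderate inter-observer
  reliability, and elevated before-gait scores. Observer heterogeneity is
  fully configurable, so reliability experiments can span poor to excellent
  agreement.
* **Seeding.** One root seed; per-horse and per-purpose substreams are
  derived by hashing labels, so outputs are reproducible and independent of
  evaluation order. Identical configuration and seed give byte-identical
  file outputs.

### What the generator does not emulate

Real motion-capture data contain soft-tissue artifacts, marker dropout,
surface and handler effects, and trial-to-trial variation in stride
frequency within a trial; real pain scores have item-level structure,
observer drift and learning effects. Passing tests on synthetic data
therefore demonstrate the *correctness of the computations* under the
assumed data-generating structure, not the clinical performance of any
scale on real horses.

## Numerical and degenerate-input policy

* Traces: missing samples, non-increasing time stamps, or a sampling rate
  inconsistent with the time vector (>1%) are rejected at construction.
* Segmentation: no dominant periodicity in the stride band, irregular
  minima spacing, or fewer than five strides are typed errors, not NAs.
* ICC: fewer than five complete cases or zero total variance are typed
  errors; perfect agreement returns estimate 1 with a degenerate CI at 1.
* ROC: single-class inputs are an explicit undefined-ROC error; degenerate
  DeLong variance collapses the CI to the point estimate with a warning.
* Model: quantile knots are computed on *distinct* covariate values so
  heavily tied TAS distributions cannot collapse knots; a smoothing
  variance within numerical zero of the boundary is treated as λ = ∞.
* TAS cut-off exactly 10 mm is "no pain" (strict inequality), and ICC and
  AUC band edges are documented closed/open above.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on synthetic data:
stride-metric grids on 10 s trials at 200 Hz; ICC oracle checks on 10 × 3
matrices; model recovery at 400 rows (8 × 50 or 16 × 25 horses × rows);
type-I error calibration with 500 null refits at 96 rows each; DeLong
coverage with 1000 replicates of 100 + 100 observations; generator
calibration at 1000 simulated horses; and the full eight-horse default
study for the end-to-end pipeline. These sizes were chosen as the smallest
that make the distributional claims they test meaningful.

## Known limitations

* Side labels are alternation parities, not anatomical left/right.
* The association model is Gaussian on bounded integer scores; with strong
  floor effects this under-covers near zero (visible as partial-effect
  bands dipping below zero score change). Ordinal or Tweedie variants are
  out of scope.
* The LRT reference for the smooth (χ² with EDF degrees of freedom) is
  approximate, as in all penalized-smooth testing; its observed level is
  checked by simulation rather than assumed.
* The ICC pools the rotating third observer; with strongly heterogeneous
  third observers this mixes rater variance into the error term, and
  results can differ from missing-data ICC algorithms applied to the
  five-column layout.
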