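---
title: "Mode-resolved perceptual templates: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mode-resolved perceptual templates: models, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modeseek)
```

## The scientific problem

In a yes/no detection task, observers judge whether a faint near-vertical
grating is present in a patch of visual white noise. False alarms — "present"
responses on pure-noise trials — are interesting because they behave like
miniature hallucinations: they should carry specific perceptual content (the
observer sees *something vertical*, not just presses the wrong key), and they
should wax and wane on a behavioral timescale. `modeseek` implements the two
analyses that make those claims testable, plus a synthetic-data generator rich
enough to validate every stage against known ground truth:

1. **Classification images in orientation space.** Each noise image is
   multiplied by the stimulus' Gaussian contrast envelope, Fourier
   transformed, and its power sampled at the grating's spatial frequency in
   60 axial orientation bins of 3°. Subtracting the mean profile on rejection
   trials from the mean profile on alarm trials yields a classification
   image; a peak near 90° means alarms were driven by noise that happened to
   contain close-to-vertical power — a perceptual template at work. The
   scalar covariate `relpower` (mean power in the 60–120° band divided by the
   mean over all bins) carries the same signal into trial-level regressions.

2. **A two-state Bernoulli GLM-HMM.** Responses \(y_t\) are modeled by
   per-state logistic regressions
   \(P(y_t = 1 \mid x_t, z_t = k) = \sigma(\beta_{s,k}\, s_t +
   \beta_{h,k}\, y_{t-1})\)
   on the current signal contrast \(s_t\) and the previous response
   \(y_{t-1}\), with a hidden two-state Markov chain \(z_t\) switching
   between an *external* state (\(\beta_s > \beta_h\): behavior tracks the
   stimulus) and an *internal* state (\(\beta_h > \beta_s\): behavior tracks
   recent experience). Trials are labeled internal/external by thresholding
   the posterior state probability at 0.5, and the two-state model is
   compared against a one-state control GLM by BIC.

## Fitting: MAP-EM for the GLM-HMM

The fit maximizes the posterior under a Gaussian prior
\(\mathcal N(0, \sigma^2 = 10)\) on each emission weight and a flat
Dirichlet (\(\alpha = 1\)) prior on each transition row:

* **E-step** — scaled forward-backward (in C++ via Rcpp) yields exact
  per-trial state posteriors, expected transition counts, and the sequence
  log-likelihood.
* **M-step** — each state's weights solve a posterior-weighted
  ridge-penalized logistic regression (penalty \(\|w\|^2 / 2\sigma^2\)) by
  Newton iterations to gradient norm \(< 10^{-8}\), with step halving so the
  update never decreases the penalized objective; the transition matrix is
  the normalized expected counts plus \(\alpha - 1\).

Numerical and structural choices, and why:

* **Initialization.** Both states start at the one-state control GLM's
  weights; the history weight is perturbed by ±10% (at least ±0.01), because
  exactly equal states are an EM fixed point. The transition matrix starts
  sticky (0.95 self-transitions), the standard prior expectation for slow
  behavioral states. The initialization is deterministic, so a fit is a pure
  function of the data; a multi-restart scheme was deliberately not made the
  default because reproducibility of a single canonical fit matters more
  here than squeezing out rare local optima, and the EM trace is exposed
  (`fit$lp_trace`) for anyone who wants to check convergence.
* **Convergence.** Absolute change of the penalized log-posterior
  \(< 10^{-4}\), at most 200 iterations; monotonicity is asserted at every
  iteration. Non-convergence returns the last iterate with
  `converged = FALSE` and a warning rather than an error, because permuted
  or near-degenerate data legitimately produce flat objectives.
* **Granularity.** One fit per participant (population numbers are
  means/SEMs across participants); a pooled fit over all participants is
  available via `pooled = TRUE`. A participant's sessions are concatenated
  into one hidden-state sequence — modes last tens of trials and plausibly
  outlive a 100-trial session — but the lagged response resets to 0 at each
  session start (`session_sequences = TRUE` gives fully independent
  sessions instead).
* **Parameter count for BIC.** One-state: 2. Two-state: 4 emission weights
  plus 2 free transition entries = 6. The initial state distribution is
  fixed uniform and not counted. BIC uses the unpenalized log-likelihood at
  the MAP parameters.
* **Contrast coding.** The stimulus regressor is the raw Michelson contrast
  by default; a `"levels"` coding {0, 1, 2} is available. The choice rescales
  coefficients but leaves the mode segmentation essentially unchanged, and
  raw contrast keeps the simulator and the fit on one scale.
* **No intercept.** The emission model has no intercept, matching the
  two-regressor formulation exactly. A consequence worth knowing: with
  \(s_t = 0\) and \(y_{t-1} = 0\) the alarm probability is exactly 0.5, so
  simulated observers have high baseline false-alarm rates. That is a
  property of the model family, not of the code.

## The synthetic-data generator

`simulate_experiment()` generates the full study: trial sequences, noise
(and its orientation-power profiles), and responses from a generative
observer with a hidden mode chain. Its defaults are the study conditions:

* Trial mix 44% low-contrast / 44% noise-only / 12% inducers; inducers at
  40% Michelson contrast and ±10° from vertical, scheduled with 4–10
  intervening trials (mean spacing 8, hence a realized inducer fraction of
  1/8 — the two published constraints, "12%" and "gaps of 4–10 trials", are
  mutually inconsistent by a few tenths of a percent and the gap rule wins);
  low-contrast orientations uniform within ±3° of vertical; 100-trial
  sessions; 14×14 d.v.a. field; 0.5 cpd carrier under a 3 d.v.a. Gaussian
  envelope; noise bounded at 60% contrast.
* **Pixel grid.** 128×128 px (≈9.14 px/degree), configurable. The carrier is
  then 7 cycles/image, far from Nyquist (64), and a 10,000-image session
  renders in well under a minute.
* **Noise distribution.** The published description ("static white noise",
  60% maximum contrast) does not pin down the pixel distribution; the
  default is uniform on [−0.6, 0.6], with a clipped Gaussian behind
  `noise_dist = "gaussian"`. Both are isotropic, which is all the analysis
  requires.
* **Mode dynamics.** The default transition matrix
  \(\begin{pmatrix}0.988 & 0.012\\ 0.030 & 0.970\end{pmatrix}\) gives a
  stationary internal occupancy of 28.6% and alternation intervals averaging
  ≈58 trials (≈2 minutes at 2 s/trial), the regime reported for human
  observers in this task. At 2 s/trial — 0.5 s stimulus, 0.5 s mask, ≈1 s
  inter-trial interval — run lengths convert to seconds by doubling. The
  symmetric 0.98/0.98 chain used in the parameter-recovery checks is
  constructed explicitly where needed; it is *not* the default because a
  50% internal occupancy does not match the reported behavior, and doubling
  the time spent in the low-sensitivity internal state also pulls the
  pooled d′ ceiling down toward the calibration target, making the d′ = 1.5
  condition fragile.
* **Template coupling.** `template_gain` adds
  \(\beta_N \,(\text{relpower}_t - 1)\) to the linear predictor — a coupling
  to the *excess* close-to-vertical noise power over a flat profile, so
  turning the template on does not move the baseline alarm rate. The default
  is 0 (the pure two-regressor observer); recovery simulations use
  \(\beta_N = 4\), a coupling strong enough that the mode-conditional
  template effects are clearly expressed at cohort sizes matching the
  original experiment (about twenty participants of 15–25 sessions).
* **Serial-dependent templates.** With `inducer_template = TRUE`, on the
  trial after an inducer at orientation θ the *internal-state* template band
  (60–120°, i.e. half-width 30°) is recentred on θ, while the external state
  keeps its vertical template. This produces the signature phenomenon:
  classification images computed after clockwise vs counter-clockwise
  inducers separate during the internal mode and not during the external
  mode. Because the recentring moves the band by only ±10°, the synthetic
  displacement is bounded by 10° and comes out at a few degrees after the
  average-vector summary — smaller than the ≈20° reported for humans, whose
  templates apparently exaggerate the inducer. The simulator makes the
  effect's *sign and mode-specificity* recoverable, not its human magnitude.
* **Calibration.** `calibrate_contrast()` bisects the low-contrast level
  until the simulated d′ (hits on low-contrast trials vs false alarms on
  noise-only trials, Gaussian-quantile formula) reaches the 1.5 target.
  Every candidate contrast is evaluated on one common simulated sequence and
  one common set of random draws, making d′ a deterministic, monotone
  function of contrast; 50,000-trial evaluations keep the Monte-Carlo error
  of d′ small. The design's default `low_contrast = 0.95` reflects this
  calibration at the default observer (the acceptance script recomputes the
  calibrated value and its achieved d′ on every run). When the target is
  within tolerance of the sensitivity ceiling, the bisection returns the
  boundary contrast rather than failing, and errors only if even full
  contrast falls short of the target by more than the tolerance.

## Spectral analysis choices

* **Sampling the spectrum.** Power at the carrier frequency is read off by
  bilinear interpolation of \(|\mathrm{FFT}|^2\) at the exact polar
  coordinates (radius 7 cycles/image, 60 angles), which is deterministic and
  grid-robust; an annulus-pooling variant (`method = "annulus"`) averages
  whole spectrum cells within half a frequency step of the radius. The two
  agree on peak locations to within one 3° bin.
* **Angle bookkeeping.** A grating's spectral energy lies perpendicular to
  its stripes; the mapping is fixed by the calibration convention that a
  vertical grating (luminance modulating horizontally) peaks in the 90° bin,
  and is verified by an oracle sweep over gratings at 0°–150°. The two
  conjugate-symmetric half-planes are averaged into one axial profile on
  [0°, 180°); bins are named by their centres (0°, 3°, …, 177°) and band
  membership is by bin centre, so the 60–120° band contains 21 bins and
  `relpower` of a flat profile is exactly 1 (ratio of means; a ratio-of-sums
  variant is available).
* **Average vectors.** A classification image is summarized by the centroid
  of its polar endpoints \((p_i \cos\theta_i, p_i \sin\theta_i)\). Negative
  bins have no polar radius; by default all bins are shifted by the minimum
  (`negative = "shift"`), with truncation at zero (`"clip"`) as the
  alternative — the choice moves the angle by a few degrees on noisy images,
  which is why both are exposed and the default is stated. Optional axial
  angle doubling (`double_angle = TRUE`) implements the circular-statistics
  convention; it is off by default because the bulk of a classification
  image's mass sits well inside one half-period, where plain averaging is
  unbiased and easier to read.

## Statistics module

`alarm_rate_model()` regresses alarms on current contrast, preceding
contrast, and `relpower` with participant random intercepts (lme4) when at
least three participants are present, falling back to a plain GLM otherwise;
random slopes were left out of the default because the simulated observers
share one parameter set, and the flag-controlled mixed structure is the
conventional minimal model. `fa_rate_by_mode()` contrasts false-alarm rates
between modes within participant × session blocks (paired t; the block
choice reproduces a degrees-of-freedom scale comparable to published
analyses, and per-participant blocking is available). Shift tests compare
per-participant average-vector angles after CW vs CCW inducers with a Welch
t, reporting the signed mean displacement toward the inducer. No
multiple-testing correction is applied anywhere, matching the analysis the
package reproduces.

## What the synthetic validation does and does not show

The generator produces exactly the structure the analysis assumes: logistic
emissions, first-order Markov modes, isotropic noise, a linear-in-log-odds
template. Green recovery tests therefore certify the *estimators* — the EM
reaches the generative parameters, the decoder reaches the generative modes,
BIC prefers the true model class, the spectral pipeline sees the planted
template, and each test statistic holds its nominal type-I level on null
data. They cannot certify that human behavior satisfies those assumptions:
real observers have lapses, drifting criteria, more-than-two states, and
templates that exaggerate rather than copy the inducer. Those questions
need the real dataset, for which `load_external_dataset()` provides the
schema-mapped entry point (the package never downloads data itself).

Problem sizes used in the shipped checks: 100 short sequences for the exact
forward-backward oracle; 20 observers × 2000 trials for parameter recovery
and model selection (with 20 within-participant permutations); 10,000
noise-only trials for template recovery; a 22-participant rendered cohort
for the shift analysis; 500 null datasets of 5 × 800 trials for the type-I
audit.

## Known limitations

* The emission model's lack of an intercept ties the baseline alarm rate to
  0.5; simulated false-alarm rates are correspondingly high.
* The synthetic inducer-following template cannot exceed a 10° displacement
  by construction; the reported human effect is about twice that.
* Mode decoding is information-limited at the recovery settings: most trials
  carry little state-discriminating evidence, so even the Bayes-optimal
  decoder (posterior decode at the true generative parameters, computed in
  the shipped checks) reaches only ~0.84 median per-trial accuracy, and the
  fitted decoder tracks that ceiling to within a few hundredths. Decoded
  labels dilute mode-conditional effect sizes accordingly. For the same
  reason, the per-observer two-state BIC advantage at 2000 trials is modest
  (tens of nats against a 30-nat parameter penalty) and occasionally
  negative for an unlucky observer.
* The permutation control preserves session boundaries but not the
  within-session autocorrelation of stimuli; that matches its purpose
  (destroying response-history structure) but is one of several defensible
  shuffling schemes.
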