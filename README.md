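# modeseek

Mode-resolved classification-image analysis of false alarms in
Gabor-in-noise detection.

## The problem

When people judge whether a faint near-vertical grating is hidden in visual
white noise, their false alarms (FAs) — "present" responses to pure noise —
are not mere lapses. Two signatures make them behave like miniature
hallucinations:

1. **Content.** FAs cluster on noise images that accidentally contain
   close-to-vertical spectral power: the observer applies a perceptual
   *template* to the noise. Subtracting the mean orientation-power profile of
   rejection trials from that of alarm trials (a classification image) makes
   the template visible as a peak near 90°.
2. **Dynamics.** Behavior alternates on a minutes-long timescale between an
   *external mode*, in which responses track the current stimulus, and an
   *internal mode*, in which they track recent experience. FAs and serial
   dependence concentrate in the internal mode, and the template itself
   shifts toward the orientation of the preceding high-contrast inducer.

`modeseek` implements the full analysis chain and a synthetic-data generator
with known ground truth for validating every stage:

* **synthesis** — trial sequences (44% low-contrast / 44% noise-only / 12%
  ±10° inducers every 4–10 trials), Gabor and noise rendering (14×14 d.v.a.,
  0.5 cpd, 3 d.v.a. Gaussian envelope, 60% max noise contrast), and a
  generative two-state Markov observer with logistic emissions, optional
  noise-template coupling, and d′-targeted contrast calibration;
* **spectral analysis** — orientation-power profiles (2-D FFT power at the
  carrier frequency in 60 × 3° axial bins), relative vertical band power,
  classification images, polar average vectors, CW/CCW shift analysis;
* **state inference** — a two-state Bernoulli GLM-HMM
  (`P(y_t=1|z_t=k) = σ(β_{s,k} s_t + β_{h,k} y_{t-1})`, transition matrix
  `A`) fitted by MAP-EM with priors `σ² = 10` on weights and Dirichlet(1) on
  transitions, BIC comparison against the one-state control GLM, posterior
  mode labeling (`P(z_t = external) > 0.5`), and a within-participant
  permutation control;
* **statistics** — mixed logistic regressions of the alarm rate (current
  contrast, preceding contrast, relative vertical power), mode-conditional
  serial dependence, paired FA-rate contrasts between modes, and Welch tests
  on classification-vector displacements.

## Worked example

```r
library(modeseek)

design   <- experiment_design(n_sessions = 20)     # 2000 trials/participant
observer <- generative_observer()                  # external/internal modes
sim <- simulate_experiment(design, observer, n_participants = 4, seed = 1)

fit    <- fit_glm_hmm(sim$trials)                  # one MAP-EM fit per participant
labels <- label_modes(fit, trial_duration = 2)
summary(labels)
#>   participant occupancy_internal mean_run_trials mean_run_seconds
#> 1           1             0.4090       153.84615         307.6923
#> 2           2             0.3000       105.26316         210.5263
#> 3           3             0.1965        55.55556         111.1111
#> 4           4             0.3135        55.55556         111.1111

delta_bic(fit)                                     # negative: two states win
#> [1] -65.60703

ci <- classification_image(sim$profiles, sim$trials$response,
                           sim$trials$stim_class == "noise")
print(ci)
#> classification_image [all]: 2156 alarms vs 1330 rejections, peak at 135 deg
average_vector(ci)
#> average_vector: angle 81.79 deg, magnitude 11.65
```

Here the four simulated observers spend ~20–40% of trials in the internal
mode in runs of tens of trials (≈2–5 minutes at 2 s/trial), the two-state
model beats the one-state control by ~66 BIC points, and — because this
observer has no template coupling (`template_gain = 0`) — the classification
image is flat noise: its peak bin lands arbitrarily (135° here) and the
average vector wobbles around 90°. Setting `template_gain = 4` plants a
vertical template that the
classification image then recovers as a stable close-to-vertical peak;
`inducer_template = TRUE` additionally makes the internal-mode template
follow the preceding inducer, the phenomenon the shift statistics test.

Statistics on a template-coupled cohort:

```r
obs2 <- generative_observer(template_gain = 4, inducer_template = TRUE)
sim2 <- simulate_experiment(design, obs2, n_participants = 6, seed = 2)
alarm_rate_model(sim2$trials)
#>            term   estimate         se statistic df             p
#> 1      contrast 2.93086150 0.07409667 39.554563 NA  0.000000e+00
#> 2 prev_contrast 0.09946068 0.05802402  1.714129 NA  8.650499e-02
#> 3      relpower 3.65671166 0.10348619 35.335262 NA 1.688567e-273
#>                                  model mode
#> 1 glmer: participant random intercepts  all
#> 2 glmer: participant random intercepts  all
#> 3 glmer: participant random intercepts  all
```

All three coefficients are positive: alarms follow the current signal, the
preceding signal (serial dependence; a small effect at six participants —
the pooled history dependence lives mostly inside the internal mode, which
`mode_conditional_serial_dependence()` resolves), and the vertical power of
the current noise (the planted template) — the content signature of
predictive-template FAs.

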