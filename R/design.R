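#' Experimental design for a Gabor-in-noise detection session
#'
#' Bundles the stimulus and procedure parameters of the detection task:
#' trial-type proportions, inducer schedule, Gabor geometry, noise bounds and
#' session structure. All orientations use an absolute axial scale on
#' \[0, 180) degrees where 90 is vertical and larger angles are clockwise of
#' vertical.
#'
#' @param p_low_contrast Proportion of trials carrying a low-contrast
#'   near-vertical Gabor (default 0.44).
#' @param p_noise_only Proportion of pure-noise trials (default 0.44).
#' @param p_inducer Nominal proportion of high-contrast inducer trials
#'   (default 0.12). Inducer positions are scheduled by the gap rule, so the
#'   realized proportion is `1/(1 + mean(inducer_gap_range))`, about 0.125
#'   at the defaults.
#' @param low_contrast Michelson contrast of the low-contrast Gabor. The
#'   study-level value comes from [calibrate_contrast()]; the default 0.95 is
#'   the level at which the default observer reaches a d' near 1.5.
#' @param inducer_contrast Michelson contrast of the inducer (default 0.40).
#' @param inducer_orientations Inducer orientations in degrees from vertical
#'   (default c(-10, 10), i.e. 80 and 100 absolute).
#' @param low_orientation_range Range of low-contrast orientations in degrees
#'   from vertical (default c(-3, 3), i.e. 87 to 93 absolute).
#' @param inducer_gap_range Integer range of non-inducer trials between
#'   consecutive inducers (default c(4, 10)).
#' @param trials_per_session Trials per session (default 100).
#' @param n_sessions Sessions per participant (default 20).
#' @param noise_max_contrast Bound on per-pixel noise contrast (default 0.60).
#' @param field_size Stimulus field width/height in degrees of visual angle
#'   (default 14).
#' @param envelope_sd Standard deviation of the Gaussian contrast envelope in
#'   d.v.a. (default 3).
#' @param spatial_freq Gabor spatial frequency in cycles/degree (default 0.5).
#' @param n_px Pixels per image side (default 128, about 9.1 px/degree; 0.5
#'   cpd is then 7 cycles/image, well below Nyquist).
#' @param noise_dist Per-pixel noise distribution: `"uniform"` on
#'   \[-noise_max_contrast, +noise_max_contrast\] (default) or `"gaussian"`
#'   (sd = noise_max_contrast/3, clipped at the bound).
#' @param stim_duration Stimulus duration in seconds (0.5).
#' @param iti_range Inter-trial-interval range in seconds (c(0.8, 1.2)).
#' @param trial_duration Nominal trial duration in seconds used to convert
#'   mode run lengths to time (default 2.0 = 0.5 s stimulus + 0.5 s mask +
#'   1.0 s mean ITI).
#'
#' @return An object of class `experiment_design` (a named list).
#' @examples
#' d <- experiment_design(n_sessions = 2)
#' d$spatial_freq * d$field_size # cycles per image
#' @export
experiment_design <- function(p_low_contrast = 0.44,
                              p_noise_only = 0.44,
                              p_inducer = 0.12,
                              low_contrast = 0.95,
                              inducer_contrast = 0.40,
                              inducer_orientations = c(-10, 10),
                              low_orientation_range = c(-3, 3),
                              inducer_gap_range = c(4L, 10L),
                              trials_per_session = 100L,
                              n_sessions = 20L,
                              noise_max_contrast = 0.60,
                              field_size = 14,
                              envelope_sd = 3,
                              spatial_freq = 0.5,
                              n_px = 128L,
                              noise_dist = c("uniform", "gaussian"),
                              stim_duration = 0.5,
                              iti_range = c(0.8, 1.2),
                              trial_duration = 2.0) {
  noise_dist <- match.arg(noise_dist)
  p <- c(p_low_contrast, p_noise_only, p_inducer)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("trial-type proportions must be nonnegative and sum to 1",
         call. = FALSE)
  if (p_inducer > 0 &&
      (length(inducer_gap_range) != 2 ||
       inducer_gap_range[1] > inducer_gap_range[2] ||
       inducer_gap_range[1] < 1))
    stop("inducer_gap_range must be an increasing pair of positive integers",
         call. = FALSE)
  if (low_contrast < 0 || low_contrast > 1 ||
      inducer_contrast < 0 || inducer_contrast > 1)
    stop("contrasts must lie in [0, 1]", call. = FALSE)
  if (n_px <= 0 || field_size <= 0 || envelope_sd <= 0)
    stop("n_px, field_size and envelope_sd must be positive", call. = FALSE)
  out <- list(
    p_low_contrast = p_low_contrast,
    p_noise_only = p_noise_only,
    p_inducer = p_inducer,
    low_contrast = low_contrast,
    inducer_contrast = inducer_contrast,
    inducer_orientations = inducer_orientations,
    low_orientation_range = low_orientation_range,
    inducer_gap_range = as.integer(inducer_gap_range),
    trials_per_session = as.integer(trials_per_session),
    n_sessions = as.integer(n_sessions),
    noise_max_contrast = noise_max_contrast,
    field_size = field_size,
    envelope_sd = envelope_sd,
    spatial_freq = spatial_freq,
    n_px = as.integer(n_px),
    noise_dist = noise_dist,
    stim_duration = stim_duration,
    iti_range = iti_range,
    trial_duration = trial_duration
  )
  class(out) <- "experiment_design"
  out
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Gabor-in-noise experiment design\n")
  cat(sprintf("  trial mix: %.0f%% low / %.0f%% noise-only / %.0f%% inducer\n",
              100 * x$p_low_contrast, 100 * x$p_noise_only, 100 * x$p_inducer))
  cat(sprintf("  contrasts: low %.2f, inducer %.2f, noise bound %.2f (%s)\n",
              x$low_contrast, x$inducer_contrast, x$noise_max_contrast,
              x$noise_dist))
  cat(sprintf("  field %g x %g dva, %d px, %.1f cpd Gabor, envelope sd %g dva\n",
              x$field_size, x$field_size, x$n_px, x$spatial_freq,
              x$envelope_sd))
  cat(sprintf("  %d sessions x %d trials\n", x$n_sessions,
              x$trials_per_session))
  invisible(x)
}

#' Generative two-state Markov observer
#'
#' Defines a simulated observer whose responses arise from a hidden two-state
#' Markov chain with logistic emissions. In the *external* state the response
#' follows the current stimulus (`beta_s > beta_h`); in the *internal* state it
#' follows the previous response (`beta_h > beta_s`). The per-trial alarm
#' probability in state k is
#' `plogis(beta_s[k] * s_t + beta_h[k] * y_{t-1} +
#' template_gain * (relpower_t - 1))` mixed with a symmetric lapse.
#' `template_gain` couples responses to the excess of close-to-vertical power
#' in the concurrent noise image over a flat profile, which is what makes
#' simulated false alarms content-specific; the default 0 gives a pure
#' stimulus/history observer.
#'
#' The default transition matrix `rbind(c(0.988, 0.012), c(0.030, 0.970))`
#' yields a stationary internal-mode occupancy of 28.6% and mode runs
#' averaging ~58 trials (~2 minutes at 2 s/trial), the regime reported for
#' human observers in this task.
#'
#' @param weights_external,weights_internal Numeric pairs `(beta_s, beta_h)`
#'   in log-odds units for the external and internal state.
#' @param transition 2x2 row-stochastic matrix; rows/cols ordered
#'   (external, internal).
#' @param template_gain Log-odds change per unit relative vertical noise power
#'   (default 0).
#' @param lapse_rate Probability of a uniform-random response (default 0).
#' @param inducer_template If `TRUE`, on trials following an inducer the
#'   template band is recentred on the inducer's orientation while the
#'   observer is in the internal state, producing serial-dependent template
#'   shifts; in the external state the band stays centred on vertical.
#' @param template_halfwidth Half-width of the template orientation band in
#'   degrees (default 30, i.e. the 60-120 degree band when centred on
#'   vertical).
#'
#' @return An object of class `generative_observer`.
#' @examples
#' obs <- generative_observer()
#' obs$transition
#' @export
generative_observer <- function(weights_external = c(beta_s = 4, beta_h = 0.2),
                                weights_internal = c(beta_s = 1, beta_h = 2),
                                transition = rbind(c(0.988, 0.012),
                                                   c(0.030, 0.970)),
                                template_gain = 0,
                                lapse_rate = 0,
                                inducer_template = FALSE,
                                template_halfwidth = 30) {
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(2, 2)) || any(transition < 0) ||
      any(abs(rowSums(transition) - 1) > 1e-8))
    stop("transition must be a 2x2 row-stochastic matrix", call. = FALSE)
  if (lapse_rate < 0 || lapse_rate >= 1)
    stop("lapse_rate must lie in [0, 1)", call. = FALSE)
  if (!(weights_external[1] > weights_external[2]))
    warning("external state usually has beta_s > beta_h", call. = FALSE)
  if (!(weights_internal[2] > weights_internal[1]))
    warning("internal state usually has beta_h > beta_s", call. = FALSE)
  out <- list(
    weights_external = stats::setNames(as.numeric(weights_external),
                                       c("beta_s", "beta_h")),
    weights_internal = stats::setNames(as.numeric(weights_internal),
                                       c("beta_s", "beta_h")),
    transition = transition,
    template_gain = template_gain,
    lapse_rate = lapse_rate,
    inducer_template = isTRUE(inducer_template),
    template_halfwidth = template_halfwidth
  )
  class(out) <- "generative_observer"
  out
}

#' @export
print.generative_observer <- function(x, ...) {
  cat("Generative two-state observer\n")
  cat(sprintf("  external: beta_s = %.2f, beta_h = %.2f\n",
              x$weights_external[1], x$weights_external[2]))
  cat(sprintf("  internal: beta_s = %.2f, beta_h = %.2f\n",
              x$weights_internal[1], x$weights_internal[2]))
  cat(sprintf("  stay probabilities: %.3f (ext), %.3f (int); template gain %g",
              x$transition[1, 1], x$transition[2, 2], x$template_gain))
  if (x$inducer_template)
    cat(sprintf("; inducer-following template (halfwidth %g deg)",
                x$template_halfwidth))
  cat(sprintf("; lapse %g\n", x$lapse_rate))
  invisible(x)
}

#' Read design/observer configuration from YAML
#'
#' Convenience constructors from YAML mappings whose keys are the arguments of
#' [experiment_design()] and [generative_observer()]. Unknown keys are an
#' error, so typos fail loudly.
#'
#' @param path Path to a YAML file.
#' @return An `experiment_design` or `generative_observer`.
#' @export
design_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  .check_config_keys(cfg, names(formals(experiment_design)), "experiment_design")
  do.call(experiment_design, cfg)
}

#' @rdname design_from_yaml
#' @export
observer_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  .check_config_keys(cfg, names(formals(generative_observer)),
                     "generative_observer")
  if (!is.null(cfg$transition))
    cfg$transition <- matrix(unlist(cfg$transition), 2, 2, byrow = TRUE)
  do.call(generative_observer, cfg)
}

.check_config_keys <- function(cfg, allowed, what) {
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop(sprintf("unknown %s fields in config: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
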