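# Synthetic experiments: trial sequences, simulated two-state observers,
# and d-prime contrast calibration.

#' Generate a trial sequence
#'
#' Lays out the stimulus sequence of a synthetic experiment: high-contrast
#' inducers separated by gaps of 4-10 intervening trials (so inducers make up
#' ~1/8 of trials), with the remaining trials split between low-contrast
#' near-vertical Gabors and pure noise in proportion to the design. Low
#' orientations are uniform within +/-3 degrees of vertical; inducers sit at
#' +/-10 degrees (clockwise = above 90).
#'
#' @param design An [experiment_design()].
#' @param seed Optional integer seed.
#' @param n_trials Total trials; defaults to
#'   `trials_per_session * n_sessions`.
#' @return A data.frame with columns `session`, `trial` (global index),
#'   `stim_class` (`"noise"`, `"low"`, `"inducer"`), `contrast`,
#'   `orientation_deg` (absolute; `NA` on noise trials).
#' @export
generate_trial_sequence <- function(design = experiment_design(), seed = NULL,
                                    n_trials = design$trials_per_session *
                                      design$n_sessions) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_trials)
  cls <- rep("noise", n)
  if (design$p_inducer > 0) {
    gaps <- design$inducer_gap_range
    # over-draw gaps, then keep positions within range
    m <- ceiling(n / (gaps[1] + 1)) + 1
    pos <- cumsum(sample(seq(gaps[1], gaps[2]), m, replace = TRUE) + 1L)
    pos <- pos[pos <= n]
    cls[pos] <- "inducer"
  }
  rest <- which(cls == "noise")
  p_low <- design$p_low_contrast / (design$p_low_contrast +
                                      design$p_noise_only)
  is_low <- stats::runif(length(rest)) < p_low
  cls[rest[is_low]] <- "low"
  contrast <- numeric(n)
  contrast[cls == "low"] <- design$low_contrast
  contrast[cls == "inducer"] <- design$inducer_contrast
  ori <- rep(NA_real_, n)
  nlow <- sum(cls == "low")
  ori[cls == "low"] <- 90 + stats::runif(nlow,
                                         design$low_orientation_range[1],
                                         design$low_orientation_range[2])
  nind <- sum(cls == "inducer")
  if (nind > 0)
    ori[cls == "inducer"] <- 90 + sample(design$inducer_orientations,
                                         nind, replace = TRUE)
  data.frame(
    session = rep(seq_len(ceiling(n / design$trials_per_session)),
                  each = design$trials_per_session)[seq_len(n)],
    trial = seq_len(n),
    stim_class = cls,
    contrast = contrast,
    orientation_deg = ori
  )
}

#' Simulate a two-state observer on a trial sequence
#'
#' Samples a hidden external/internal mode chain from the observer's
#' transition matrix (continuing across sessions: modes outlive sessions) and
#' draws each response from the active state's logistic emission
#' `plogis(beta_s * s_t + beta_h * y_{t-1} + template_gain * (relpower_t - 1))`,
#' mixed with a symmetric lapse. The coupling uses the power *excess* over a
#' flat profile, so a template-sensitive observer keeps the same baseline
#' alarm rate as a template-free one. The previous response resets to 0 at every
#' session start. When the observer's `inducer_template` is on and the
#' previous trial was an inducer, the internal-state template band is
#' recentred on the inducer's orientation, so internal-mode alarms follow
#' noise power near the inducer rather than near vertical.
#'
#' @param trials A sequence from [generate_trial_sequence()] (columns
#'   `session`, `stim_class`, `contrast`, `orientation_deg`).
#' @param observer A [generative_observer()].
#' @param profiles Optional per-trial orientation-power matrix (rows matching
#'   `trials`); required when `template_gain != 0` or `inducer_template` is
#'   on. Without it the noise coupling is evaluated at the flat-noise value 1.
#' @param seed Optional integer seed.
#' @param start_state Optional initial mode, `"external"` or `"internal"`;
#'   default: drawn from the chain's stationary distribution.
#' @param participant Participant id stored in the output (default 1).
#' @return A trial table: `participant`, `session`, `trial`, `stim_class`,
#'   `contrast`, `orientation_deg`, `response` (1 = alarm), `prev_response`,
#'   `mode_true`, `relpower`.
#' @export
simulate_observer <- function(trials, observer = generative_observer(),
                              profiles = NULL, seed = NULL,
                              start_state = NULL, participant = 1L) {
  if (!is.null(seed)) set.seed(seed)
  A <- observer$transition
  if (any(abs(rowSums(A) - 1) > 1e-8))
    stop("observer transition matrix is not row-stochastic", call. = FALSE)
  n <- nrow(trials)
  gain <- observer$template_gain
  if (is.null(profiles)) {
    if (gain != 0 || observer$inducer_template)
      stop("profiles are required for a template-coupled observer",
           call. = FALSE)
    rp_vert <- rep(1, n)
    rp_prev <- rep(1, n)
  } else {
    if (nrow(profiles) != n)
      stop("profiles and trials disagree in length", call. = FALSE)
    rp_vert <- .recentred_band_power(profiles, 90,
                                     observer$template_halfwidth)
    rp_prev <- rp_vert
    if (observer$inducer_template) {
      prev_ind <- which(c(FALSE, trials$stim_class[-n] == "inducer") &
                          c(FALSE, diff(trials$session) == 0))
      for (i in prev_ind) {
        rp_prev[i] <- .recentred_band_power(
          profiles[i, , drop = FALSE],
          trials$orientation_deg[i - 1], observer$template_halfwidth)
      }
    }
  }
  W <- rbind(observer$weights_external, observer$weights_internal)
  # stationary distribution of the 2-state chain
  p_stat <- c(A[2, 1], A[1, 2]) / (A[1, 2] + A[2, 1])
  z1 <- if (is.null(start_state)) {
    sample(1:2, 1, prob = p_stat)
  } else match(match.arg(start_state, c("external", "internal")),
               c("external", "internal"))
  u_state <- stats::runif(n)
  u_resp <- stats::runif(n)
  u_lapse <- stats::runif(n)
  lapse <- observer$lapse_rate
  s <- trials$contrast
  new_sess <- c(TRUE, diff(trials$session) != 0)
  z <- integer(n)
  y <- integer(n)
  yprev <- numeric(n)
  zc <- z1
  yp <- 0
  for (t in seq_len(n)) {
    if (t > 1) zc <- if (u_state[t] < A[zc, 1]) 1L else 2L
    if (new_sess[t]) yp <- 0
    z[t] <- zc
    yprev[t] <- yp
    rp <- if (zc == 2L) rp_prev[t] else rp_vert[t]
    eta <- W[zc, 1] * s[t] + W[zc, 2] * yp + gain * (rp - 1)
    p <- stats::plogis(eta)
    y[t] <- if (u_lapse[t] < lapse) as.integer(u_resp[t] < 0.5)
            else as.integer(u_resp[t] < p)
    yp <- y[t]
  }
  data.frame(
    participant = participant,
    session = trials$session,
    trial = trials$trial,
    stim_class = trials$stim_class,
    contrast = trials$contrast,
    orientation_deg = trials$orientation_deg,
    response = y,
    prev_response = yprev,
    mode_true = c("external", "internal")[z],
    relpower = if (is.null(profiles)) NA_real_ else rp_vert
  )
}

#' Simulate a full synthetic experiment
#'
#' Convenience wrapper: per participant, generate a trial sequence, render the
#' per-trial noise and its orientation-power profiles (optional), and simulate
#' the observer. Per-participant seeds are derived from `seed` so individual
#' participants can be regenerated independently.
#'
#' @param design An [experiment_design()].
#' @param observer A [generative_observer()] (one observer shared by all
#'   participants).
#' @param n_participants Number of simulated participants.
#' @param seed Integer root seed.
#' @param render `"profiles"` renders noise and attaches per-trial profiles
#'   and relpower; `"none"` skips rendering (fast; relpower fixed at 1).
#' @return List with `trials` (stacked trial table), `profiles` (stacked
#'   matrix or `NULL`), `design`, `observer`.
#' @export
simulate_experiment <- function(design = experiment_design(),
                                observer = generative_observer(),
                                n_participants = 1, seed = 1,
                                render = c("profiles", "none")) {
  render <- match.arg(render)
  trials <- vector("list", n_participants)
  profs <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    s_i <- derive_seed(seed, i)
    seqs <- generate_trial_sequence(design, seed = s_i)
    pr <- NULL
    if (render == "profiles")
      pr <- noise_profile_stack(nrow(seqs), design,
                                seed = derive_seed(s_i, 1))
    trials[[i]] <- simulate_observer(seqs, observer, profiles = pr,
                                     seed = derive_seed(s_i, 2),
                                     participant = i)
    profs[[i]] <- pr
  }
  list(trials = do.call(rbind, trials),
       profiles = if (render == "profiles") do.call(rbind, profs) else NULL,
       design = design, observer = observer)
}

#' Signal-detection sensitivity from hit and false-alarm rates
#'
#' `qnorm(hit) - qnorm(fa)` with rates clipped away from 0 and 1 by half a
#' trial (the standard log-linear-free correction for empirical rates).
#'
#' @param hit_rate,fa_rate Empirical rates in \[0, 1\].
#' @param n_hit_trials,n_fa_trials Trial counts behind each rate, used for
#'   the clipping bound.
#' @return d-prime.
#' @export
dprime_from_rates <- function(hit_rate, fa_rate,
                              n_hit_trials = 1e6, n_fa_trials = 1e6) {
  clip <- function(p, n) pmin(pmax(p, 0.5 / n), 1 - 0.5 / n)
  stats::qnorm(clip(hit_rate, n_hit_trials)) -
    stats::qnorm(clip(fa_rate, n_fa_trials))
}

#' Calibrate the low-contrast level to a target d-prime
#'
#' Finds, by bisection over Michelson contrast, the low-contrast level at
#' which the simulated observer's sensitivity (hits on low-contrast trials
#' versus false alarms on noise-only trials) matches `target_dprime`. Each
#' candidate contrast is evaluated on the same simulated sequence and random
#' draws (common random numbers), which makes the simulated d-prime a
#' deterministic, monotone function of contrast and the bisection exact.
#' The noise coupling, if any, is evaluated at its flat-noise level.
#'
#' @param observer A [generative_observer()].
#' @param design An [experiment_design()].
#' @param target_dprime Target sensitivity (default 1.5).
#' @param seed Integer seed for the calibration simulation.
#' @param n_trials Simulated trials per evaluation (default 50000).
#' @param tol Acceptable |d' - target| (default 0.1).
#' @return The calibrated contrast, with attribute `dprime` (the simulated
#'   sensitivity at that contrast).
#' @export
calibrate_contrast <- function(observer = generative_observer(),
                               design = experiment_design(),
                               target_dprime = 1.5, seed = 1,
                               n_trials = 50000, tol = 0.1) {
  if (target_dprime < 0)
    stop("target_dprime must be nonnegative", call. = FALSE)
  if (target_dprime == 0)
    return(structure(0, dprime = 0))
  obs <- observer
  obs$template_gain <- 0 # coupling offset is contrast-independent
  obs$inducer_template <- FALSE
  base <- generate_trial_sequence(design, seed = derive_seed(seed, 1),
                                  n_trials = n_trials)
  eval_d <- function(cc) {
    sq <- base
    sq$contrast[sq$stim_class == "low"] <- cc
    tt <- simulate_observer(sq, obs, seed = derive_seed(seed, 2))
    dprime_from_rates(mean(tt$response[tt$stim_class == "low"]),
                      mean(tt$response[tt$stim_class == "noise"]),
                      sum(tt$stim_class == "low"),
                      sum(tt$stim_class == "noise"))
  }
  d_hi <- eval_d(1)
  if (d_hi < target_dprime - tol)
    stop(sprintf(
      "target d' = %.2f unreachable: d' at full contrast is %.2f",
      target_dprime, d_hi), call. = FALSE)
  lo <- 0; hi <- 1
  for (it in 1:25) {
    mid <- (lo + hi) / 2
    if (eval_d(mid) < target_dprime) lo <- mid else hi <- mid
  }
  cc <- (lo + hi) / 2
  structure(cc, dprime = eval_d(cc))
}

#' Derive a child seed from a root seed
#'
#' Deterministic counter-based splitting so pipeline stages and participants
#' get distinct, reproducible streams from one root seed. Values stay below
#' 2^31.
#'
#' @param seed Integer root seed.
#' @param index Nonnegative stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.double(seed %% 1000003L) * 8191 + index * 2654435) %%
               2147483647)
}
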