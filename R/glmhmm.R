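# Two-state Bernoulli GLM-HMM fit by MAP-EM.
#
# Emissions: per-state logistic regressions of the alarm response on the
# current signal contrast and the previous response (no intercept). Priors:
# independent Gaussian N(0, sigma2) on every emission weight and a Dirichlet
# (alpha) prior on each transition row. The E-step is a scaled
# forward-backward pass; the M-step solves a gamma-weighted ridge-penalized
# logistic regression per state by Newton iterations and renormalizes
# expected transition counts.

#' GLM-HMM configuration
#'
#' @param n_states Number of latent states (only 2 is supported).
#' @param sigma2 Variance of the Gaussian prior over emission weights
#'   (default 10).
#' @param alpha Dirichlet concentration over transition rows (default 1,
#'   i.e. a flat prior adding nothing to the expected counts).
#' @param init_distribution Initial state distribution; fixed, not learned,
#'   and excluded from the parameter count (default uniform).
#' @param tol Convergence threshold on the absolute change of the penalized
#'   log-posterior (default 1e-4).
#' @param max_iter Maximum EM iterations (default 200).
#' @param contrast_coding How the stimulus regressor is coded:
#'   `"contrast"` uses the raw Michelson contrast (default), `"levels"` maps
#'   {zero, low, high} to {0, 1, 2}. The choice rescales coefficients but
#'   not the mode segmentation.
#' @param session_sequences If `TRUE`, each session is treated as an
#'   independent HMM sequence; default `FALSE` concatenates a participant's
#'   sessions into one sequence (modes outlast single sessions), while the
#'   previous-response regressor still resets at session starts.
#' @param perturb Relative perturbation applied to the history weight at
#'   initialization to break the two-state symmetry (default 0.1).
#' @return List of class `hmm_config`.
#' @export
hmm_config <- function(n_states = 2L, sigma2 = 10, alpha = 1,
                       init_distribution = c(0.5, 0.5), tol = 1e-4,
                       max_iter = 200L,
                       contrast_coding = c("contrast", "levels"),
                       session_sequences = FALSE, perturb = 0.1) {
  contrast_coding <- match.arg(contrast_coding)
  if (n_states != 2L) stop("only n_states = 2 is supported", call. = FALSE)
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  if (alpha < 1) stop("alpha must be >= 1", call. = FALSE)
  if (abs(sum(init_distribution) - 1) > 1e-8 || any(init_distribution < 0))
    stop("init_distribution must be a probability pair", call. = FALSE)
  structure(list(n_states = 2L, sigma2 = sigma2, alpha = alpha,
                 init_distribution = init_distribution, tol = tol,
                 max_iter = as.integer(max_iter),
                 contrast_coding = contrast_coding,
                 session_sequences = isTRUE(session_sequences),
                 perturb = perturb),
            class = "hmm_config")
}

#' Build the emission design from a trial table
#'
#' Produces the per-trial regressor pair: the stimulus regressor `s` (raw
#' contrast or level code) and the previous response `yprev`, which is the
#' within-session lagged response with 0 at each session's first trial.
#'
#' @param trials A trial table (see [simulate_observer()]); must be sorted by
#'   participant, session, trial.
#' @param contrast_coding `"contrast"` or `"levels"` (see [hmm_config()]).
#' @return A data.frame with columns `participant`, `session`, `s`, `yprev`,
#'   `y`, `first_in_session`.
#' @export
build_design <- function(trials, contrast_coding = c("contrast", "levels")) {
  contrast_coding <- match.arg(contrast_coding)
  need <- c("participant", "session", "trial", "stim_class", "contrast",
            "response")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  o <- order(trials$participant, trials$session, trials$trial)
  if (!identical(o, seq_len(nrow(trials))))
    stop("trials must be sorted by participant, session, trial",
         call. = FALSE)
  s <- if (contrast_coding == "contrast") trials$contrast
       else c(noise = 0, low = 1, inducer = 2)[trials$stim_class]
  first <- !duplicated(trials[c("participant", "session")])
  yprev <- c(0, trials$response[-nrow(trials)])
  yprev[first] <- 0
  data.frame(participant = trials$participant, session = trials$session,
             s = as.numeric(s), yprev = yprev, y = trials$response,
             first_in_session = first)
}

#' Per-trial Bernoulli log-likelihood under a logistic emission
#'
#' `log P(y_t | s_t, yprev_t, w)` for the no-intercept logistic model,
#' computed on the log scale so extreme linear predictors stay finite.
#'
#' @param weights Numeric pair `(beta_s, beta_h)`.
#' @param design A design from [build_design()].
#' @param responses 0/1 responses; defaults to `design$y`.
#' @return Numeric vector of per-trial log-likelihood contributions.
#' @export
emission_loglik <- function(weights, design, responses = design$y) {
  eta <- design$s * weights[1] + design$yprev * weights[2]
  # y*eta - log(1 + e^eta), evaluated stably for |eta| large
  responses * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))
}

#' Fit the one-state control GLM
#'
#' Maximum-likelihood logistic regression of the response on contrast and
#' previous response without an intercept. On perfect separation (or other
#' non-finite estimates) it falls back, with a warning, to the same ridge
#' penalty used inside the HMM M-step.
#'
#' @param design A design from [build_design()].
#' @param responses 0/1 responses; defaults to `design$y`.
#' @param sigma2 Ridge fallback variance (default 10).
#' @return List of class `one_state_glm`: `weights`, `loglik`, `bic`,
#'   `n_obs`, `n_params`.
#' @export
fit_one_state_glm <- function(design, responses = design$y, sigma2 = 10) {
  if (length(unique(responses)) < 2)
    stop("responses are constant; nothing to fit", call. = FALSE)
  X <- cbind(s = design$s, yprev = design$yprev)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, responses, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  w <- fit$coefficients
  if (sep || any(!is.finite(w)) || any(abs(w) > 50)) {
    warning("possible separation; refitting with ridge penalty 1/(2*sigma2)",
            call. = FALSE)
    w <- .ridge_logistic(X, responses, rep(1, nrow(X)), sigma2)$weights
  }
  w <- stats::setNames(as.numeric(w), c("beta_s", "beta_h"))
  ll <- sum(emission_loglik(w, design, responses))
  structure(list(weights = w, loglik = ll,
                 bic = compute_bic(ll, 2L, nrow(X)),
                 n_obs = nrow(X), n_params = 2L),
            class = "one_state_glm")
}

# Weighted ridge-penalized logistic regression by Newton iterations.
# Maximizes sum_t w_t [y log p + (1-y) log(1-p)] - ||beta||^2 / (2 sigma2).
.ridge_logistic <- function(X, y, wt, sigma2, beta = c(0, 0),
                            grad_tol = 1e-8, max_iter = 100) {
  obj <- function(b) {
    eta <- drop(X %*% b)
    # y*eta - log(1 + e^eta), evaluated stably
    sum(wt * (y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))) -
      sum(b^2) / (2 * sigma2)
  }
  f <- obj(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    grad <- drop(crossprod(X, wt * (y - p))) - beta / sigma2
    if (max(abs(grad)) < grad_tol) break
    H <- crossprod(X, X * (wt * p * (1 - p))) + diag(length(beta)) / sigma2
    step <- tryCatch(solve(H, grad), error = function(e) {
      warning("singular Hessian in M-step; extra regularization applied",
              call. = FALSE)
      solve(H + diag(length(beta)) * 1e-6, grad)
    })
    # step halving keeps the Newton update an ascent step
    lam <- 1
    repeat {
      cand <- beta + lam * step
      fc <- obj(cand)
      if (fc >= f - 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    beta <- beta + lam * step
    f <- obj(beta)
  }
  list(weights = beta, objective = f)
}

#' Scaled forward-backward pass
#'
#' Exact posterior state probabilities, expected transition counts and the
#' sequence log-likelihood for one HMM sequence, given per-trial per-state
#' log-likelihoods.
#'
#' @param loglik_mat T x K matrix of per-trial per-state emission
#'   log-likelihoods.
#' @param A K x K row-stochastic transition matrix.
#' @param init Initial state distribution.
#' @return List: `gamma` (T x K posterior state probabilities), `xi` (K x K
#'   expected transition counts summed over transitions), `loglik`.
#' @export
forward_backward <- function(loglik_mat, A, init = NULL) {
  loglik_mat <- as.matrix(loglik_mat)
  Tn <- nrow(loglik_mat); K <- ncol(loglik_mat)
  A <- as.matrix(A)
  if (any(abs(rowSums(A) - 1) > 1e-8))
    stop("A must be row-stochastic", call. = FALSE)
  if (is.null(init)) init <- rep(1 / K, K)
  mx <- do.call(pmax, as.data.frame(loglik_mat))
  b <- exp(loglik_mat - mx)
  res <- .fb_core(b, A, init)
  list(gamma = res$gamma, xi = res$xi, loglik = res$logc + sum(mx))
}

#' M-step for the emission weights
#'
#' Per state, maximizes the posterior-weighted Bernoulli log-likelihood minus
#' the Gaussian prior penalty `||w||^2 / (2 sigma2)` (a weighted
#' ridge-penalized logistic regression, solved by Newton iterations to
#' gradient norm < 1e-8).
#'
#' @param design A design from [build_design()].
#' @param responses 0/1 responses.
#' @param gamma T x K posterior state probabilities.
#' @param config An [hmm_config()].
#' @param start Optional K x 2 matrix of warm-start weights.
#' @return K x 2 matrix of weights (rows = states).
#' @export
m_step_weights <- function(design, responses, gamma, config = hmm_config(),
                           start = NULL) {
  X <- cbind(s = design$s, yprev = design$yprev)
  K <- ncol(gamma)
  W <- matrix(0, K, 2, dimnames = list(NULL, c("beta_s", "beta_h")))
  for (k in seq_len(K)) {
    b0 <- if (is.null(start)) c(0, 0) else start[k, ]
    W[k, ] <- .ridge_logistic(X, responses, gamma[, k], config$sigma2,
                              beta = b0)$weights
  }
  W
}

#' M-step for the transition matrix
#'
#' MAP update under the Dirichlet(alpha) row prior:
#' `A[k, j] proportional to xi[k, j] + (alpha - 1)`.
#'
#' @param xi K x K expected transition counts.
#' @param config An [hmm_config()].
#' @return Row-stochastic K x K matrix.
#' @export
m_step_transitions <- function(xi, config = hmm_config()) {
  if (is.null(xi) || !length(xi) || all(xi == 0))
    stop("no expected transitions to estimate A from", call. = FALSE)
  A <- xi + (config$alpha - 1)
  A / rowSums(A)
}

#' Bayesian Information Criterion
#'
#' `BIC = n_params * log(n_obs) - 2 * loglik`; lower is better.
#'
#' @param loglik Total log-likelihood.
#' @param n_params Number of free parameters.
#' @param n_obs Number of observations.
#' @return BIC value.
#' @export
compute_bic <- function(loglik, n_params, n_obs) {
  if (n_obs <= 0) stop("n_obs must be positive", call. = FALSE)
  n_params * log(n_obs) - 2 * loglik
}

# ---- full EM fit ----------------------------------------------------------

# Fit one participant's concatenated data. design rows are in time order;
# sequence breaks taken from `breaks` (logical, TRUE at sequence starts).
.fit_glmhmm_one <- function(design, config) {
  y <- design$y
  breaks <- if (config$session_sequences) design$first_in_session
            else !duplicated(design$participant)
  seq_id <- cumsum(breaks)
  one <- fit_one_state_glm(design, y, sigma2 = config$sigma2)
  w0 <- one$weights
  dh <- max(abs(w0[2]) * config$perturb, 0.01)
  W <- rbind(c(w0[1], w0[2] - dh), c(w0[1], w0[2] + dh))
  colnames(W) <- c("beta_s", "beta_h")
  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
  lp_prev <- -Inf
  lp_trace <- numeric(0)
  converged <- FALSE
  it <- 0
  e_step <- function(W, A) {
    ll <- cbind(emission_loglik(W[1, ], design, y),
                emission_loglik(W[2, ], design, y))
    gamma <- matrix(0, nrow(design), 2)
    xi <- matrix(0, 2, 2)
    loglik <- 0
    for (sid in unique(seq_id)) {
      idx <- which(seq_id == sid)
      fb <- forward_backward(ll[idx, , drop = FALSE], A,
                             config$init_distribution)
      gamma[idx, ] <- fb$gamma
      xi <- xi + fb$xi
      loglik <- loglik + fb$loglik
    }
    list(gamma = gamma, xi = xi, loglik = loglik)
  }
  log_prior <- function(W, A) {
    -sum(W^2) / (2 * config$sigma2) + sum((config$alpha - 1) * log(A))
  }
  es <- NULL
  while (it < config$max_iter) {
    it <- it + 1
    es <- e_step(W, A)
    lp <- es$loglik + log_prior(W, A)
    lp_trace <- c(lp_trace, lp)
    if (lp < lp_prev - 1e-6)
      warning(sprintf("EM log-posterior decreased at iteration %d", it),
              call. = FALSE)
    if (abs(lp - lp_prev) < config$tol) { converged <- TRUE; break }
    lp_prev <- lp
    W <- m_step_weights(design, y, es$gamma, config, start = W)
    A <- m_step_transitions(es$xi, config)
  }
  if (!converged)
    warning("EM did not converge within max_iter; returning last iterate",
            call. = FALSE)
  es <- e_step(W, A) # refresh posteriors at the final parameters
  # relabel: state 1 = external (largest beta_s - beta_h)
  ord <- order(W[, 1] - W[, 2], decreasing = TRUE)
  W <- W[ord, , drop = FALSE]
  A <- A[ord, ord]
  es$gamma <- es$gamma[, ord, drop = FALSE]
  es$xi <- es$xi[ord, ord]
  n_obs <- nrow(design)
  structure(list(
    weights = W, A = A, gamma = es$gamma, xi = es$xi,
    loglik = es$loglik, bic = compute_bic(es$loglik, 6L, n_obs),
    n_obs = n_obs, n_params = 6L, converged = converged, n_iter = it,
    lp_trace = lp_trace, one_state = one, config = config,
    participant = design$participant,
    session = design$session, first_in_session = design$first_in_session),
    class = "glmhmm_fit")
}

#' Fit the two-state GLM-HMM
#'
#' MAP-EM fit of the two-state Bernoulli GLM-HMM to a trial table. Both
#' states initialize at the one-state control GLM's weights with a
#' deterministic perturbation of the history weight to break the exact
#' symmetry (equal states are an EM fixed point); the transition matrix
#' initializes sticky. By default each participant receives an independent
#' fit (occupancy and weights are population-summarized across participants);
#' `pooled = TRUE` concatenates everyone into one sequence instead.
#'
#' After fitting, states are relabeled so state 1 is the external state
#' (largest `beta_s - beta_h`).
#'
#' @param trials A trial table (see [simulate_observer()]), >= 100 trials.
#' @param config An [hmm_config()].
#' @param pooled Fit one model to all participants jointly (default FALSE).
#' @return A `glmhmm_fit` (single participant or pooled) or a `glmhmm_fitset`
#'   (list of per-participant fits with summed log-likelihood/BIC).
#' @export
fit_glm_hmm <- function(trials, config = hmm_config(), pooled = FALSE) {
  if (nrow(trials) < 100)
    stop("need at least 100 trials to fit the GLM-HMM", call. = FALSE)
  design <- build_design(trials, config$contrast_coding)
  ids <- unique(design$participant)
  if (pooled || length(ids) == 1) {
    # pooled: one parameter set, forward-backward restarted at participant
    # boundaries (sequence breaks come from !duplicated(participant))
    return(.fit_glmhmm_one(design, config))
  }
  fits <- lapply(ids, function(id)
    .fit_glmhmm_one(design[design$participant == id, , drop = FALSE], config))
  names(fits) <- as.character(ids)
  structure(list(fits = fits,
                 loglik = sum(vapply(fits, `[[`, 0, "loglik")),
                 bic = sum(vapply(fits, `[[`, 0, "bic")),
                 n_obs = sum(vapply(fits, `[[`, 0, "n_obs"))),
            class = "glmhmm_fitset")
}

#' @export
print.glmhmm_fit <- function(x, ...) {
  cat("Two-state GLM-HMM fit (MAP-EM)\n")
  cat(sprintf("  external: beta_s = %.3f, beta_h = %.3f\n",
              x$weights[1, 1], x$weights[1, 2]))
  cat(sprintf("  internal: beta_s = %.3f, beta_h = %.3f\n",
              x$weights[2, 1], x$weights[2, 2]))
  cat(sprintf("  stay probabilities: %.3f / %.3f\n", x$A[1, 1], x$A[2, 2]))
  cat(sprintf("  loglik %.2f, BIC %.2f (%d trials, %s in %d iterations)\n",
              x$loglik, x$bic, x$n_obs,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @export
print.glmhmm_fitset <- function(x, ...) {
  cat(sprintf("GLM-HMM fits for %d participants: total loglik %.2f, BIC %.2f\n",
              length(x$fits), x$loglik, x$bic))
  invisible(x)
}

#' BIC difference between the two-state and one-state models
#'
#' `delta BIC = BIC(two-state) - BIC(one-state)`; negative values favor the
#' two-state GLM-HMM. For a fit set the per-participant BICs are summed.
#'
#' @param fit A `glmhmm_fit` or `glmhmm_fitset`.
#' @param one_state Optional matching one-state fit(s); by default the
#'   control GLM fitted during initialization is reused.
#' @return The BIC difference.
#' @export
delta_bic <- function(fit, one_state = NULL) {
  if (inherits(fit, "glmhmm_fitset")) {
    one_bic <- if (is.null(one_state))
      sum(vapply(fit$fits, function(f) f$one_state$bic, 0))
    else sum(vapply(one_state, `[[`, 0, "bic"))
    return(fit$bic - one_bic)
  }
  one_bic <- if (is.null(one_state)) fit$one_state$bic else one_state$bic
  fit$bic - one_bic
}

#' Decode external/internal mode labels
#'
#' Labels each trial external when the posterior probability of the external
#' state exceeds 0.5 and internal otherwise, and summarizes occupancy and run
#' lengths (in trials and, via `trial_duration`, in seconds).
#'
#' @param fit A `glmhmm_fit` or `glmhmm_fitset`.
#' @param trial_duration Seconds per trial for the time conversion
#'   (default 2).
#' @return For a single fit, a list of class `mode_labels`: `labels`
#'   (data.frame `participant`, `label`, `p_external`), `occupancy_internal`,
#'   `runs` (data.frame `label`, `length_trials`, `length_seconds`),
#'   `mean_run_trials`, `mean_run_seconds`. For a fit set, a list of
#'   `mode_labels` plus attribute-free per-participant summaries via
#'   [summary.mode_labels_set()].
#' @export
label_modes <- function(fit, trial_duration = 2) {
  if (inherits(fit, "glmhmm_fitset")) {
    out <- lapply(fit$fits, label_modes, trial_duration = trial_duration)
    class(out) <- "mode_labels_set"
    return(out)
  }
  W <- fit$weights
  d <- W[, 1] - W[, 2]
  if (sign(d[1]) == sign(d[2]) && all(d != 0))
    warning(paste("both states fall on the same side of beta_s = beta_h;",
                  "labeling by larger beta_s - beta_h"), call. = FALSE)
  p_ext <- fit$gamma[, 1]
  lab <- ifelse(p_ext > 0.5, "external", "internal")
  r <- rle(lab)
  runs <- data.frame(label = r$values, length_trials = r$lengths,
                     length_seconds = r$lengths * trial_duration)
  structure(list(
    labels = data.frame(participant = fit$participant, label = lab,
                        p_external = p_ext),
    occupancy_internal = mean(lab == "internal"),
    runs = runs,
    mean_run_trials = mean(r$lengths),
    mean_run_seconds = mean(r$lengths) * trial_duration),
    class = "mode_labels")
}

#' @export
print.mode_labels <- function(x, ...) {
  cat(sprintf(
    "mode labels: %.1f%% internal, %d runs, mean run %.1f trials (%.1f s)\n",
    100 * x$occupancy_internal, nrow(x$runs), x$mean_run_trials,
    x$mean_run_seconds))
  invisible(x)
}

#' Summarize per-participant mode labels
#'
#' @param object A `mode_labels_set` from [label_modes()] on a fit set.
#' @param ... Unused.
#' @return data.frame with one row per participant: internal occupancy and
#'   mean run length in trials and seconds.
#' @export
summary.mode_labels_set <- function(object, ...) {
  data.frame(
    participant = names(object),
    occupancy_internal = vapply(object, `[[`, 0, "occupancy_internal"),
    mean_run_trials = vapply(object, `[[`, 0, "mean_run_trials"),
    mean_run_seconds = vapply(object, `[[`, 0, "mean_run_seconds"),
    row.names = NULL)
}

# ---- permutation control --------------------------------------------------

#' Permute trial order within participants
#'
#' Returns a trial table whose rows are shuffled within each participant
#' (session labels stay attached to positions, so the session structure is
#' preserved) with the lagged-response column rebuilt from the shuffled
#' order.
#'
#' @param trials A trial table.
#' @param seed Optional integer seed.
#' @param perms Optional named list (participant id -> within-participant
#'   permutation of positions); overrides random shuffling. An identity
#'   permutation reproduces the input ordering exactly.
#' @return A permuted trial table.
#' @export
permute_trials <- function(trials, seed = NULL, perms = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- trials
  for (id in unique(trials$participant)) {
    idx <- which(trials$participant == id)
    pm <- if (!is.null(perms)) perms[[as.character(id)]]
          else sample(length(idx))
    moved <- c("stim_class", "contrast", "orientation_deg", "response")
    moved <- intersect(moved, names(trials))
    out[idx, moved] <- trials[idx[pm], moved]
  }
  d <- build_design(out)
  out$prev_response <- d$yprev
  out
}

#' Permutation control for the two-state advantage
#'
#' Refits the one-state GLM and the two-state GLM-HMM on datasets whose trial
#' order was randomly permuted within participants. Shuffling destroys the
#' temporal clustering that the hidden states capture, so the two-state
#' advantage (negative delta BIC) should be lost on permuted data.
#'
#' @param trials A trial table.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; permutation p uses `derive_seed(seed, p)`.
#' @param config An [hmm_config()].
#' @return data.frame (`perm`, `delta_bic`) with attribute
#'   `delta_bic_observed`, the unpermuted value.
#' @export
permutation_control <- function(trials, n_perm = 20, seed = 1,
                                config = hmm_config()) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  observed <- delta_bic(fit_glm_hmm(trials, config))
  db <- vapply(seq_len(n_perm), function(p) {
    tp <- permute_trials(trials, seed = derive_seed(seed, p))
    delta_bic(fit_glm_hmm(tp, config))
  }, 0)
  structure(data.frame(perm = seq_len(n_perm), delta_bic = db),
            delta_bic_observed = observed)
}
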