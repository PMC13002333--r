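# Shared fixtures and independent oracles, all built in code at test time.

# Small, fast design for unit tests (low-resolution grid where the spectral
# geometry still resolves 0.5 cpd).
tiny_design <- function(...) {
  experiment_design(n_sessions = 2, ...)
}

# Exhaustive-path HMM oracle: log-likelihood and posterior state marginals by
# brute-force summation over all K^T state paths. Independent of the
# forward-backward implementation; only usable for short sequences.
enumerate_hmm <- function(loglik_mat, A, init) {
  Tn <- nrow(loglik_mat)
  K <- ncol(loglik_mat)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  logw <- apply(paths, 1, function(z) {
    lw <- log(init[z[1]]) + loglik_mat[1, z[1]]
    if (Tn > 1)
      for (t in 2:Tn)
        lw <- lw + log(A[z[t - 1], z[t]]) + loglik_mat[t, z[t]]
    lw
  })
  m <- max(logw)
  w <- exp(logw - m)
  loglik <- m + log(sum(w))
  gamma <- matrix(0, Tn, K)
  for (t in seq_len(Tn))
    for (k in seq_len(K))
      gamma[t, k] <- sum(w[paths[, t] == k]) / sum(w)
  list(loglik = loglik, gamma = gamma)
}

# A generative observer with symmetric sticky transitions, the configuration
# used throughout the recovery checks.
recovery_observer <- function(...) {
  generative_observer(transition = rbind(c(0.98, 0.02), c(0.02, 0.98)), ...)
}

# Simulate one recovery observer's trial table (no noise rendering).
recovery_trials <- function(seed, n_trials = 2000, participant = 1L,
                            observer = recovery_observer(),
                            design = experiment_design()) {
  sq <- generate_trial_sequence(design, seed = derive_seed(seed, 1),
                                n_trials = n_trials)
  simulate_observer(sq, observer, seed = derive_seed(seed, 2),
                    participant = participant)
}

# Construct a minimal glmhmm_fit-shaped object for label/summary tests.
fake_fit <- function(p_external, weights = rbind(c(4, 0.2), c(1, 2)),
                     participant = 1L) {
  structure(list(
    weights = `colnames<-`(weights, c("beta_s", "beta_h")),
    A = rbind(c(0.98, 0.02), c(0.02, 0.98)),
    gamma = cbind(p_external, 1 - p_external),
    loglik = -1, bic = 0, n_obs = length(p_external), n_params = 6L,
    converged = TRUE, n_iter = 1L,
    one_state = list(bic = 0),
    participant = rep(participant, length(p_external))),
    class = "glmhmm_fit")
}
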