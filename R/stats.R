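# Regression and test statistics: alarm-rate predictors, mode-conditional
# serial dependence, FA rates by mode, and classification-vector shift tests.
# Ordinary logistic fits go through stats::glm, mixed fits through
# lme4::glmer (participant random intercepts), t tests through stats::t.test.

# Lag a per-trial variable within session (value for the first trial of each
# session is `fill`).
.lag_within_session <- function(x, trials, fill = 0) {
  first <- !duplicated(trials[c("participant", "session")])
  out <- c(fill, x[-length(x)])
  out[first] <- fill
  out
}

.reg_row <- function(term, estimate, se, statistic, df, p, model,
                     mode = "all") {
  data.frame(term = term, estimate = estimate, se = se,
             statistic = statistic, df = df, p = p, model = model,
             mode = mode, row.names = NULL)
}

# Fit a logistic regression with participant random intercepts when the data
# can support them, else a plain GLM; returns the coefficient table rows for
# `terms`.
.logistic_fit <- function(dat, formula_fixed, terms, method, mode = "all") {
  n_part <- length(unique(dat$participant))
  use_mixed <- switch(method,
                      glmer = TRUE,
                      glm = FALSE,
                      auto = n_part >= 3)
  if (use_mixed) {
    f <- stats::as.formula(paste(deparse(formula_fixed),
                                 "+ (1 | participant)"))
    fit <- lme4::glmer(f, data = dat, family = stats::binomial(),
                       control = lme4::glmerControl(calc.derivs = FALSE))
    co <- summary(fit)$coefficients
    model <- "glmer: participant random intercepts"
  } else {
    fit <- stats::glm(formula_fixed, data = dat, family = stats::binomial())
    co <- summary(fit)$coefficients
    model <- "glm"
  }
  do.call(rbind, lapply(terms, function(tm) {
    if (!tm %in% rownames(co))
      stop(sprintf("term '%s' missing from the fit", tm), call. = FALSE)
    .reg_row(tm, co[tm, 1], co[tm, 2], co[tm, 3], NA_real_, co[tm, 4],
             model, mode)
  }))
}

#' Predictors of the alarm rate
#'
#' Logistic regression of the alarm response on the current signal contrast,
#' the preceding trial's signal contrast, and the relative vertical power of
#' the current noise image, with participant random intercepts (lme4) when
#' three or more participants are available. Positive coefficients for the
#' preceding contrast and for relative vertical power are the signatures of,
#' respectively, a signal expectation carried over from the previous trial
#' and a vertical perceptual template applied to the noise.
#'
#' @param trials A trial table with a `relpower` column (see
#'   [simulate_experiment()] with `render = "profiles"`).
#' @param method `"auto"` (mixed model when >= 3 participants; default),
#'   `"glmer"`, or `"glm"`.
#' @param standardize Standardize the three predictors before fitting
#'   (changes coefficient scale, not z signs).
#' @return data.frame with one row per predictor: `term`, `estimate`, `se`,
#'   `statistic` (Wald z), `df`, `p`, `model`, `mode`.
#' @export
alarm_rate_model <- function(trials, method = c("auto", "glmer", "glm"),
                             standardize = FALSE) {
  method <- match.arg(method)
  if (!"relpower" %in% names(trials) || anyNA(trials$relpower))
    stop("trials must carry a complete 'relpower' column", call. = FALSE)
  dat <- data.frame(
    response = trials$response,
    contrast = trials$contrast,
    prev_contrast = .lag_within_session(trials$contrast, trials),
    relpower = trials$relpower,
    participant = factor(trials$participant))
  if (standardize)
    dat[c("contrast", "prev_contrast", "relpower")] <-
      lapply(dat[c("contrast", "prev_contrast", "relpower")],
             function(x) as.numeric(scale(x)))
  .logistic_fit(dat, response ~ contrast + prev_contrast + relpower,
                c("contrast", "prev_contrast", "relpower"), method)
}

# Resolve a labels argument (mode_labels, mode_labels_set, or character
# vector) to a per-trial label vector aligned with `trials`.
.label_vector <- function(trials, labels) {
  if (inherits(labels, "mode_labels_set"))
    lab <- unlist(lapply(labels, function(l) l$labels$label),
                  use.names = FALSE)
  else if (inherits(labels, "mode_labels")) lab <- labels$labels$label
  else lab <- as.character(labels)
  if (length(lab) != nrow(trials))
    stop("labels do not align with the trial table", call. = FALSE)
  lab
}

#' Mode-conditional serial dependence
#'
#' Logistic regression of the alarm response on the preceding trial's signal
#' contrast (controlling for the current contrast), fitted separately on
#' internal-labeled and external-labeled trials. A positive
#' preceding-contrast coefficient confined to the internal mode is the
#' mode-resolved serial-dependence effect.
#'
#' @param trials A trial table.
#' @param labels Mode labels: a `mode_labels`/`mode_labels_set` from
#'   [label_modes()] or a per-trial character vector.
#' @param method See [alarm_rate_model()].
#' @return data.frame with one `prev_contrast` row per mode.
#' @export
mode_conditional_serial_dependence <- function(trials, labels,
                                               method = c("auto", "glmer",
                                                          "glm")) {
  method <- match.arg(method)
  lab <- .label_vector(trials, labels)
  out <- lapply(c("internal", "external"), function(md) {
    sel <- lab == md
    if (sum(sel) < 50)
      warning(sprintf("fewer than 50 trials in %s mode", md), call. = FALSE)
    dat <- data.frame(
      response = trials$response[sel],
      contrast = trials$contrast[sel],
      prev_contrast = .lag_within_session(trials$contrast, trials)[sel],
      participant = factor(trials$participant[sel]))
    .logistic_fit(dat, response ~ contrast + prev_contrast,
                  "prev_contrast", method, mode = md)
  })
  do.call(rbind, out)
}

#' False-alarm rate contrast between modes
#'
#' Computes, per block, the false-alarm rate (alarms on noise-only trials)
#' separately for internal- and external-labeled trials, and tests the paired
#' internal-minus-external difference with a t statistic. Blocks are
#' participant x session units by default (`by = "participant"` aggregates to
#' one block per participant); blocks missing either mode or lacking noise
#' trials are dropped with a warning.
#'
#' @param trials A trial table.
#' @param labels See [mode_conditional_serial_dependence()].
#' @param by Blocking unit: `"participant_session"` (default) or
#'   `"participant"`.
#' @return One-row data.frame (`term = "fa_internal_minus_external"`) with
#'   the mean paired difference, its SE, the paired t statistic, df and p.
#' @export
fa_rate_by_mode <- function(trials, labels,
                            by = c("participant_session", "participant")) {
  by <- match.arg(by)
  lab <- .label_vector(trials, labels)
  noise <- trials$stim_class == "noise"
  if (!any(noise)) stop("no noise-only trials", call. = FALSE)
  block <- if (by == "participant_session")
    interaction(trials$participant, trials$session, drop = TRUE)
  else factor(trials$participant)
  sel_i <- noise & lab == "internal"
  sel_e <- noise & lab == "external"
  fa_i <- tapply(trials$response[sel_i], block[sel_i], mean)
  fa_e <- tapply(trials$response[sel_e], block[sel_e], mean)
  common <- intersect(names(fa_i)[!is.na(fa_i)], names(fa_e)[!is.na(fa_e)])
  n_blocks <- nlevels(block)
  if (length(common) < n_blocks)
    warning(sprintf("%d of %d blocks lack a mode and were dropped",
                    n_blocks - length(common), n_blocks), call. = FALSE)
  if (length(common) < 2)
    stop("fewer than 2 blocks have both modes", call. = FALSE)
  d <- fa_i[common] - fa_e[common]
  if (stats::sd(d) == 0) {
    warning("zero variance of block differences; t undefined, reported as 0",
            call. = FALSE)
    return(.reg_row("fa_internal_minus_external", mean(d), 0, 0,
                    length(d) - 1, 1, sprintf("paired t over %s blocks", by)))
  }
  tt <- stats::t.test(d)
  .reg_row("fa_internal_minus_external", mean(d),
           stats::sd(d) / sqrt(length(d)), unname(tt$statistic),
           unname(tt$parameter), tt$p.value,
           sprintf("paired t over %s blocks", by))
}

#' Classification-vector shift test
#'
#' Tests, per mode, whether the average-vector angles of classification
#' images computed after clockwise inducers differ from those computed after
#' counter-clockwise inducers across participants (Welch two-sample t), and
#' reports the mean signed displacement toward the preceding inducer
#' ([conditional_shift()]). A positive displacement means the perceptual
#' template followed the inducer's orientation.
#'
#' @param angles data.frame with columns `participant`, `mode`, `angle_cw`,
#'   `angle_ccw` (degrees), e.g. from [template_shift_angles()]. Rows with
#'   missing angles are dropped.
#' @return data.frame with one row per mode: mean displacement, its SE, the
#'   Welch t statistic with fractional df, and p.
#' @export
vector_shift_test <- function(angles) {
  need <- c("participant", "mode", "angle_cw", "angle_ccw")
  miss <- setdiff(need, names(angles))
  if (length(miss))
    stop("angles lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- lapply(unique(angles$mode), function(md) {
    a <- angles[angles$mode == md &
                  stats::complete.cases(angles[c("angle_cw", "angle_ccw")]), ]
    if (nrow(a) < 3)
      stop(sprintf("fewer than 3 participants with both conditions in %s mode",
                   md), call. = FALSE)
    disp <- conditional_shift(a$angle_cw, a$angle_ccw)
    if (stats::sd(a$angle_cw) == 0 && stats::sd(a$angle_ccw) == 0) {
      warning("all angles identical; t undefined, reported as 0",
              call. = FALSE)
      return(.reg_row("template_shift", mean(disp),
                      stats::sd(disp) / sqrt(length(disp)), 0,
                      2 * (nrow(a) - 1), 1, "Welch t: angle_cw vs angle_ccw",
                      md))
    }
    tt <- stats::t.test(a$angle_cw, a$angle_ccw)
    .reg_row("template_shift", mean(disp),
             stats::sd(disp) / sqrt(length(disp)),
             unname(tt$statistic), unname(tt$parameter), tt$p.value,
             "Welch t: angle_cw vs angle_ccw", md)
  })
  do.call(rbind, out)
}

#' Absolute displacement of average vectors from vertical
#'
#' Mean and SEM, across participants, of the absolute angular displacement of
#' classification-image average vectors from the vertical 90-degree axis.
#'
#' @param angles Numeric vector of average-vector angles in degrees (one per
#'   participant).
#' @return List: `mean`, `sem`, `n`.
#' @export
vertical_displacement <- function(angles) {
  if (length(angles) < 2)
    stop("need at least 2 participants", call. = FALSE)
  d <- abs(angles - 90)
  list(mean = mean(d), sem = stats::sd(d) / sqrt(length(d)), n = length(d))
}

#' Per-participant template-shift angles by mode
#'
#' For every participant and mode, computes classification images restricted
#' to trials immediately following a clockwise (orientation > 90) or
#' counter-clockwise (orientation < 90) inducer, and returns the
#' average-vector angles of both. Combinations without both alarms and
#' rejections yield `NA` angles.
#'
#' @param trials A trial table.
#' @param profiles Per-trial orientation-power matrix aligned with `trials`.
#' @param labels See [mode_conditional_serial_dependence()]; alternatively
#'   `"mode_true"` to use the generative labels stored in the trial table.
#' @param noise_only Restrict classification images to noise-only trials
#'   (default FALSE: all post-inducer trials contribute, which is what the
#'   simulated-recovery analyses use for statistical power).
#' @return data.frame: `participant`, `mode`, `angle_cw`, `angle_ccw`,
#'   `n_cw`, `n_ccw`.
#' @export
template_shift_angles <- function(trials, profiles, labels = "mode_true",
                                  noise_only = FALSE) {
  lab <- if (identical(labels, "mode_true")) trials$mode_true
         else .label_vector(trials, labels)
  n <- nrow(trials)
  same_seq <- trials$session[-1] == trials$session[-n] &
    trials$participant[-1] == trials$participant[-n]
  prev_ind <- c(FALSE, trials$stim_class[-n] == "inducer") &
    c(FALSE, same_seq)
  prev_ori <- c(NA, trials$orientation_deg[-n])
  after_cw <- prev_ind & prev_ori > 90
  after_ccw <- prev_ind & prev_ori < 90
  base <- if (noise_only) trials$stim_class == "noise" else rep(TRUE, n)
  ang <- function(mask) {
    ci <- tryCatch(classification_image(profiles, trials$response, mask),
                   error = function(e) NULL)
    if (is.null(ci)) NA_real_
    else tryCatch(average_vector(ci)$angle, error = function(e) NA_real_)
  }
  out <- expand.grid(participant = unique(trials$participant),
                     mode = c("external", "internal"),
                     stringsAsFactors = FALSE)
  out$angle_cw <- NA_real_
  out$angle_ccw <- NA_real_
  out$n_cw <- 0L
  out$n_ccw <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- trials$participant == out$participant[i] & lab == out$mode[i] & base
    m_cw <- sel & after_cw
    m_ccw <- sel & after_ccw
    out$n_cw[i] <- sum(m_cw)
    out$n_ccw[i] <- sum(m_ccw)
    out$angle_cw[i] <- ang(m_cw)
    out$angle_ccw[i] <- ang(m_ccw)
  }
  out
}
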