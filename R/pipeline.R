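# End-to-end orchestration and on-disk formats. Tables are UTF-8 comma-
# separated CSV with a mandatory header and '.' decimals; fits go to JSON.
# All randomness descends from one root seed split per stage with
# derive_seed(), so individual stages can be toggled and re-run bit-identically.

#' Write / read a trial table as CSV
#'
#' @param trials A trial table.
#' @param path Output path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns the
#'   trial table.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.csv(path, fileEncoding = "UTF-8")
}

#' Write / read a profile matrix as CSV
#'
#' One row per trial; 60 power columns named `power_<orientation>`.
#'
#' @param profiles Matrix from [noise_profile_stack()].
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  th <- attr(profiles, "orientation")
  if (is.null(th)) th <- orientation_bins(180 / ncol(profiles))
  df <- as.data.frame(profiles)
  names(df) <- paste0("power_", th)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  m <- as.matrix(df)
  dimnames(m) <- NULL
  attr(m, "orientation") <- as.numeric(sub("^power_", "", names(df)))
  m
}

#' Run the full synthetic analysis pipeline
#'
#' simulate -> profiles -> fit-hmm -> classify -> report, writing every stage
#' product plus a JSON manifest (seeds, stage status, file hashes) to
#' `out_dir`. Stages can be toggled off, in which case downstream stages
#' consume the prior outputs already on disk.
#'
#' @param design An [experiment_design()] (or YAML path).
#' @param observer A [generative_observer()] (or YAML path).
#' @param config An [hmm_config()].
#' @param n_participants Simulated participants.
#' @param seed Root seed; stages use `derive_seed(seed, stage)`.
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("simulate", "fit", "classify", "report")`.
#' @return The manifest (named list), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(design = experiment_design(),
                         observer = generative_observer(),
                         config = hmm_config(),
                         n_participants = 4, seed = 1, out_dir,
                         stages = c("simulate", "fit", "classify",
                                    "report")) {
  if (is.character(design)) design <- design_from_yaml(design)
  if (is.character(observer)) observer <- observer_from_yaml(observer)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  manifest <- list(seed = seed, n_participants = n_participants,
                   stages = stages, completed = character(0),
                   r_version = as.character(getRversion()))

  if ("simulate" %in% stages) {
    sim <- simulate_experiment(design, observer, n_participants,
                               seed = derive_seed(seed, 1))
    write_trials(sim$trials, p("trials.csv"))
    write_profiles(sim$profiles, p("profiles.csv"))
    manifest$completed <- c(manifest$completed, "simulate")
  }
  trials <- read_trials(p("trials.csv"))
  profiles <- read_profiles(p("profiles.csv"))

  if ("fit" %in% stages) {
    fit <- fit_glm_hmm(trials, config)
    labels <- label_modes(fit, design$trial_duration)
    fits <- if (inherits(fit, "glmhmm_fitset")) fit$fits else list(fit)
    jsonlite::write_json(list(
      seed = seed,
      delta_bic = delta_bic(fit),
      participants = lapply(fits, function(f) list(
        weights = f$weights, A = f$A, loglik = f$loglik, bic = f$bic,
        one_state = list(weights = as.list(f$one_state$weights),
                         bic = f$one_state$bic),
        converged = f$converged, n_iter = f$n_iter))),
      p("fits.json"), auto_unbox = TRUE, digits = NA)
    lab_df <- if (inherits(labels, "mode_labels_set"))
      do.call(rbind, lapply(labels, function(l) l$labels))
    else labels$labels
    utils::write.csv(lab_df, p("labels.csv"), row.names = FALSE)
    manifest$completed <- c(manifest$completed, "fit")
  }
  lab_df <- utils::read.csv(p("labels.csv"))

  if ("classify" %in% stages) {
    ci <- classification_image(profiles, trials$response,
                               trials$stim_class == "noise")
    utils::write.csv(data.frame(orientation = attr(ci, "orientation"),
                                delta_power = as.numeric(ci)),
                     p("classification_image.csv"), row.names = FALSE)
    shifts <- template_shift_angles(trials, profiles, lab_df$label)
    utils::write.csv(shifts, p("shift_angles.csv"), row.names = FALSE)
    manifest$completed <- c(manifest$completed, "classify")
  }

  if ("report" %in% stages) {
    shifts <- utils::read.csv(p("shift_angles.csv"))
    res <- rbind(alarm_rate_model(trials),
                 mode_conditional_serial_dependence(trials, lab_df$label),
                 fa_rate_by_mode(trials, lab_df$label),
                 tryCatch(vector_shift_test(shifts),
                          error = function(e) NULL))
    utils::write.csv(res, p("report.csv"), row.names = FALSE)
    manifest$completed <- c(manifest$completed, "report")
  }

  outputs <- list.files(out_dir, pattern = "\\.(csv|json)$",
                        full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest$hashes <- as.list(tools::md5sum(outputs))
  names(manifest$hashes) <- basename(outputs)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' Load an external trial dataset
#'
#' Adapter from a deposited trial-level CSV onto the package's trial-table
#' schema. Column names are mapped through `mapping` (deposit name ->
#' package name); unmapped columns ride along untouched. The loader never
#' modifies the file on disk.
#'
#' @param path Path to a delimited text file the user has already fetched
#'   (the package never downloads data).
#' @param mapping Named character vector, `package_column = deposit_column`;
#'   identity by default.
#' @return A trial table sorted by participant, session, trial.
#' @export
load_external_dataset <- function(path, mapping = NULL) {
  if (!file.exists(path))
    stop("external dataset not found at '", path,
         "' (fetch the deposit first; this package does not download data)",
         call. = FALSE)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!is.null(mapping)) {
    for (i in seq_along(mapping)) {
      from <- mapping[[i]]; to <- names(mapping)[i]
      if (!from %in% names(df))
        stop(sprintf("mapped column '%s' not in file", from), call. = FALSE)
      names(df)[names(df) == from] <- to
    }
  }
  need <- c("participant", "session", "trial", "stim_class", "contrast",
            "response")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("unrecognized layout: missing column(s) %s; found: %s",
                 paste(miss, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  if (!"orientation_deg" %in% names(df)) df$orientation_deg <- NA_real_
  df[order(df$participant, df$session, df$trial), , drop = FALSE]
}
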