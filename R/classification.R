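# Classification images and their polar summaries.

#' Classification image from per-trial profiles
#'
#' Bin-wise difference between the mean orientation-power profile on alarm
#' trials and on rejection trials. A positive bump near 90 degrees means
#' alarms were preferentially triggered by noise carrying close-to-vertical
#' power — the signature of a vertical perceptual template.
#'
#' @param profiles Numeric matrix, one row per trial, one column per
#'   orientation bin (e.g. from [noise_profile_stack()]).
#' @param responses Logical/0-1 vector of alarms, one per trial.
#' @param mask Optional logical vector selecting the trials to analyse
#'   (e.g. one mode, one inducer condition). Default: all trials.
#' @param condition Free-text label stored with the result.
#' @return An object of class `classification_image`: numeric vector
#'   `delta_power` per bin with attributes `orientation`, `n_alarm`,
#'   `n_reject`, `condition`.
#' @export
classification_image <- function(profiles, responses, mask = NULL,
                                 condition = "all") {
  profiles <- as.matrix(profiles)
  responses <- as.logical(responses)
  if (length(responses) != nrow(profiles))
    stop("profiles and responses disagree in length", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, length(responses))
  a <- mask & responses
  r <- mask & !responses
  if (!any(a) || !any(r))
    stop("need at least one alarm and one rejection trial in the mask",
         call. = FALSE)
  delta <- colMeans(profiles[a, , drop = FALSE]) -
    colMeans(profiles[r, , drop = FALSE])
  th <- attr(profiles, "orientation")
  if (is.null(th)) th <- orientation_bins(180 / ncol(profiles))
  structure(delta, orientation = th, n_alarm = sum(a), n_reject = sum(r),
            condition = condition, class = "classification_image")
}

#' @export
print.classification_image <- function(x, ...) {
  th <- attr(x, "orientation")
  cat(sprintf(
    "classification_image [%s]: %d alarms vs %d rejections, peak at %g deg\n",
    attr(x, "condition"), attr(x, "n_alarm"), attr(x, "n_reject"),
    th[which.max(x)]))
  invisible(x)
}

#' @export
plot.classification_image <- function(x, ...) {
  th <- attr(x, "orientation")
  graphics::plot(th, as.numeric(x), type = "l",
                 xlab = "orientation (deg)", ylab = "alarm - rejection power",
                 main = attr(x, "condition"), ...)
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = 90, lty = 3)
  invisible(x)
}

#' Average vector of a classification image
#'
#' Polar summary of a classification image: each bin contributes an endpoint
#' at its bin-centre angle with radius given by the bin value, and the average
#' vector is the centroid of those endpoints. Angles above 90 degrees denote
#' clockwise displacement of the template from vertical.
#'
#' Classification images can carry negative bins, for which polar radii are
#' undefined; by default all bins are shifted by the minimum bin value so
#' radii are nonnegative (`negative = "shift"`); `negative = "clip"` instead
#' truncates negative bins at zero. The two rules move the angle slightly and
#' both are exposed. With `double_angle = TRUE` the axial angles are doubled
#' before averaging and halved after (circular-statistics convention for
#' axial data).
#'
#' @param ci A [classification_image()] (or numeric vector with an
#'   `orientation` attribute).
#' @param negative How to map negative bins to radii: `"shift"` (default) or
#'   `"clip"`.
#' @param double_angle Use the axial angle-doubling convention
#'   (default FALSE).
#' @return List of class `average_vector` with elements `angle` (degrees in
#'   \[0, 180)) and `magnitude`.
#' @examples
#' ci <- structure(c(0, 1, 0), orientation = c(60, 90, 120))
#' average_vector(ci)$angle # 90
#' @export
average_vector <- function(ci, negative = c("shift", "clip"),
                           double_angle = FALSE) {
  negative <- match.arg(negative)
  th <- attr(ci, "orientation")
  if (is.null(th)) stop("ci must carry an orientation attribute", call. = FALSE)
  p <- as.numeric(ci)
  if (all(p == 0)) stop("all-zero classification image: angle undefined",
                        call. = FALSE)
  r <- if (negative == "shift") p - min(p, 0) else pmax(p, 0)
  mult <- if (double_angle) 2 else 1
  a <- mult * th * pi / 180
  cx <- mean(r * cos(a))
  cy <- mean(r * sin(a))
  if (cx == 0 && cy == 0)
    stop("degenerate classification image: centroid at origin", call. = FALSE)
  ang <- (atan2(cy, cx) * 180 / pi / mult) %% 180
  structure(list(angle = ang, magnitude = sqrt(cx^2 + cy^2)),
            class = "average_vector")
}

#' @export
print.average_vector <- function(x, ...) {
  cat(sprintf("average_vector: angle %.2f deg, magnitude %.4g\n",
              x$angle, x$magnitude))
  invisible(x)
}

#' Signed template displacement toward the preceding inducer
#'
#' Combines the average-vector angles computed after clockwise and after
#' counter-clockwise inducers into one signed displacement: positive when the
#' template shifted toward the preceding inducer's orientation (CW angles
#' above 90, CCW angles below 90).
#'
#' @param angle_cw,angle_ccw Average-vector angles (degrees) of the
#'   classification images for trials following CW and CCW inducers. May be
#'   vectors (e.g. one entry per participant).
#' @return Signed displacement(s) in degrees.
#' @examples
#' conditional_shift(100, 80) # +10
#' @export
conditional_shift <- function(angle_cw, angle_ccw) {
  if (length(angle_cw) != length(angle_ccw))
    stop("angle_cw and angle_ccw must pair up", call. = FALSE)
  if (any(is.na(angle_cw)) || any(is.na(angle_ccw)))
    stop("missing condition angles", call. = FALSE)
  ((angle_cw - 90) + (90 - angle_ccw)) / 2
}
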