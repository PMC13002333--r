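# Stimulus rendering: Gabor patches, white-noise fields, additive composition.
# Conventions: luminance contrast in [-1, 1]; image rows run down the screen;
# orientation is axial on [0, 180) with 90 = vertical stripes, larger angles
# clockwise of vertical.

#' Construct a stimulus image
#'
#' A light container for a square luminance-contrast image plus the metadata
#' the spectral analysis needs.
#'
#' @param pixels Square numeric matrix of contrast values in \[-1, 1\].
#' @param pixels_per_degree Pixels per degree of visual angle.
#' @param gabor_orientation,gabor_contrast,gabor_phase Optional Gabor
#'   parameters recorded for provenance (absolute orientation, Michelson
#'   contrast, radians).
#' @param rng_seed Optional integer seed recorded for provenance.
#' @return An object of class `stimulus_image`.
#' @export
stimulus_image <- function(pixels, pixels_per_degree,
                           gabor_orientation = NA_real_,
                           gabor_contrast = NA_real_,
                           gabor_phase = NA_real_,
                           rng_seed = NA_integer_) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != ncol(pixels))
    stop("stimulus images must be square", call. = FALSE)
  structure(list(pixels = pixels,
                 pixels_per_degree = pixels_per_degree,
                 gabor_orientation = gabor_orientation,
                 gabor_contrast = gabor_contrast,
                 gabor_phase = gabor_phase,
                 rng_seed = rng_seed),
            class = "stimulus_image")
}

#' @export
print.stimulus_image <- function(x, ...) {
  cat(sprintf("stimulus_image: %d x %d px (%.2f px/deg), range [%.3f, %.3f]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixels_per_degree,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Pixel-centre coordinate grids in dva, origin at image centre, x rightward
# (columns), y downward (rows). Cached per (n_px, field_size).
.coord_grids <- local({
  cache <- new.env(parent = emptyenv())
  function(design) {
    key <- paste(design$n_px, design$field_size)
    if (is.null(cache[[key]])) {
      n <- design$n_px
      ppd <- n / design$field_size
      ax <- ((seq_len(n) - 1) + 0.5 - n / 2) / ppd
      cache[[key]] <- list(x = matrix(ax, n, n, byrow = TRUE),
                           y = matrix(ax, n, n), ppd = ppd)
    }
    cache[[key]]
  }
})

#' Render a Gabor patch
#'
#' A sinusoidal luminance carrier at the design's spatial frequency, windowed
#' by the design's Gaussian contrast envelope. Orientation 90 gives vertical
#' stripes (luminance modulating horizontally); phase pi inverts the carrier.
#'
#' @param orientation Absolute orientation in degrees (90 = vertical).
#' @param contrast Michelson contrast in \[0, 1\].
#' @param phase Carrier phase in radians.
#' @param design An [experiment_design()].
#' @return A [stimulus_image()].
#' @examples
#' g <- render_gabor(90, 0.4, 0, experiment_design())
#' range(g$pixels)
#' @export
render_gabor <- function(orientation, contrast, phase = 0,
                         design = experiment_design()) {
  if (contrast < 0 || contrast > 1)
    stop("contrast must lie in [0, 1]", call. = FALSE)
  g <- .coord_grids(design)
  if (g$ppd <= 0)
    stop("pixels_per_degree must be positive", call. = FALSE)
  a <- (orientation - 90) * pi / 180
  u <- g$x * cos(a) + g$y * sin(a)
  env <- exp(-(g$x^2 + g$y^2) / (2 * design$envelope_sd^2))
  px <- contrast * env * cos(2 * pi * design$spatial_freq * u + phase)
  stimulus_image(px, g$ppd, gabor_orientation = orientation %% 180,
                 gabor_contrast = contrast, gabor_phase = phase)
}

#' Render a white-noise field
#'
#' Independent per-pixel contrast noise bounded by the design's
#' `noise_max_contrast`. The default distribution is uniform on the bound;
#' `noise_dist = "gaussian"` draws from a clipped normal with sd one third of
#' the bound. Either way the expected orientation-power profile is flat.
#'
#' @param design An [experiment_design()].
#' @param seed Optional integer seed for exact reproducibility.
#' @return A [stimulus_image()].
#' @export
render_noise <- function(design = experiment_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- .coord_grids(design)
  n <- design$n_px
  b <- design$noise_max_contrast
  px <- if (design$noise_dist == "uniform") {
    matrix(stats::runif(n * n, -b, b), n, n)
  } else {
    matrix(pmin(pmax(stats::rnorm(n * n, 0, b / 3), -b), b), n, n)
  }
  stimulus_image(px, g$ppd, rng_seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Additively compose two stimulus images
#'
#' Pixelwise sum clipped to the displayable contrast range \[-1, 1\].
#'
#' @param gabor,noise [stimulus_image()]s on the same pixel grid.
#' @return A [stimulus_image()] carrying the Gabor's metadata.
#' @export
compose_stimulus <- function(gabor, noise) {
  if (!identical(dim(gabor$pixels), dim(noise$pixels)))
    stop("image grids do not match", call. = FALSE)
  px <- pmin(pmax(gabor$pixels + noise$pixels, -1), 1)
  stimulus_image(px, gabor$pixels_per_degree,
                 gabor_orientation = gabor$gabor_orientation,
                 gabor_contrast = gabor$gabor_contrast,
                 gabor_phase = gabor$gabor_phase)
}
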