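#' Construct a raw single-window spectrum
#'
#' A `raw_spectrum` is one acquisition window of one cell (or of a cell-free
#' background / silicon calibration sample): a strictly monotone wavenumber
#' axis, an intensity vector of equal length, and acquisition metadata.
#'
#' @param wavenumbers Numeric vector of Raman shifts (cm^-1), strictly
#'   monotone.
#' @param intensities Numeric vector of detector counts, same length.
#' @param window Acquisition window id, `1L` (fingerprint, ~300-1800 cm^-1)
#'   or `2L` (CH-stretch, ~1800-3200 cm^-1). `NA` for stitched spectra.
#' @param cell_id,experiment_id,class_label Metadata strings.
#' @return An object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(wavenumbers, intensities, window = NA_integer_,
                         cell_id = NA_character_, experiment_id = NA_character_,
                         class_label = NA_character_) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have equal length")
  if (length(wavenumbers) < 2L)
    stop("a spectrum needs at least 2 channels")
  d <- diff(wavenumbers)
  if (!(all(d > 0) || all(d < 0)))
    stop("wavenumber axis must be strictly monotone")
  if (any(d < 0)) { # store ascending internally
    wavenumbers <- rev(wavenumbers)
    intensities <- rev(intensities)
  }
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         window = as.integer(window), cell_id = cell_id,
         experiment_id = experiment_id, class_label = class_label),
    class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat(sprintf("<raw_spectrum> %d channels, %.1f-%.1f cm^-1", length(x$wavenumbers), rng[1], rng[2]))
  if (!is.na(x$window)) cat(sprintf(", window %d", x$window))
  if (!is.na(x$cell_id)) cat(sprintf(", cell %s", x$cell_id))
  if (!is.na(x$class_label)) cat(sprintf(" [%s]", x$class_label))
  cat("\n")
  invisible(x)
}

## internal: replace the intensity vector, keeping metadata
set_intensities <- function(s, y) {
  s$intensities <- as.numeric(y)
  s
}

## internal: linear interpolation of a spectrum onto a new axis
resample_spectrum <- function(s, new_wn) {
  y <- stats::approx(s$wavenumbers, s$intensities, xout = new_wn, rule = 2)$y
  s$wavenumbers <- as.numeric(new_wn)
  s$intensities <- y
  s
}

#' Construct a processed spectrum on the analysis grid
#'
#' A `processed_spectrum` lives on the truncated analysis grid
#' ([730, 1750] U [2800, 3100] cm^-1 by default), carries the record of the
#' excised silent region, and an ordered provenance list of the preprocessing
#' steps applied with their parameters.
#'
#' @param wavenumbers,intensities Numeric vectors, equal length.
#' @param excised Numeric length-2 vector: the open interval removed from the
#'   axis (silent region), or `NULL`.
#' @param provenance List of steps already applied (each a named list with at
#'   least `$step`).
#' @param cell_id,experiment_id,class_label Metadata strings.
#' @return An object of class `processed_spectrum`.
#' @export
processed_spectrum <- function(wavenumbers, intensities, excised = NULL,
                               provenance = list(), cell_id = NA_character_,
                               experiment_id = NA_character_,
                               class_label = NA_character_) {
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have equal length")
  structure(
    list(wavenumbers = as.numeric(wavenumbers),
         intensities = as.numeric(intensities),
         excised = excised, provenance = provenance, cell_id = cell_id,
         experiment_id = experiment_id, class_label = class_label),
    class = "processed_spectrum")
}

#' @export
print.processed_spectrum <- function(x, ...) {
  cat(sprintf("<processed_spectrum> %d channels", length(x$wavenumbers)))
  if (!is.null(x$excised))
    cat(sprintf(", excised (%g, %g) cm^-1", x$excised[1], x$excised[2]))
  cat(sprintf(", %d steps applied\n", length(x$provenance)))
  invisible(x)
}

add_provenance <- function(s, step, ...) {
  s$provenance <- c(s$provenance, list(c(list(step = step), list(...))))
  s
}

## internal: evaluate a sum of Gaussian bands on an axis
gaussian_mixture <- function(wn, centers, sigmas, amplitudes) {
  y <- numeric(length(wn))
  for (k in seq_along(centers))
    y <- y + amplitudes[k] * exp(-(wn - centers[k])^2 / (2 * sigmas[k]^2))
  y
}
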