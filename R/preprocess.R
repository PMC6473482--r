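#' Remove cosmic-ray spikes
#'
#' Detects single-channel transients by the modified z-score of the second
#' differences of the intensity vector. A channel is flagged when its |z|
#' exceeds `z_threshold` and its second difference dominates those of its
#' immediate neighbours (|d2| at least 1.5x the neighbouring |d2|), the
#' signature of a one-channel event; smooth curvature, however strong, is
#' never flagged. Flagged channels are replaced by the median of the
#' nearest unflagged channels within +/- 3 channels.
#'
#' @param s A [raw_spectrum()] with at least 5 channels.
#' @param z_threshold Modified z-score threshold (default 8).
#' @return List with `spectrum` (despiked [raw_spectrum()]) and `spikes`
#'   (integer vector of replaced channel indices).
#' @export
despike <- function(s, z_threshold = 8) {
  y <- s$intensities
  if (any(!is.finite(y))) stop("non-finite intensities")
  n <- length(y)
  if (n < 5) stop("despiking needs at least 5 channels")
  d2 <- diff(y, differences = 2)              # d2[j] belongs to channel j + 1
  med <- stats::median(d2)
  mad <- stats::median(abs(d2 - med))
  z <- ad2 <- numeric(n)
  if (mad > 0) z[2:(n - 1)] <- abs(0.6745 * (d2 - med) / mad)
  ad2[2:(n - 1)] <- abs(d2)
  cand <- which(z > z_threshold)
  spikes <- cand[vapply(cand, function(i) {
    nb <- ad2[intersect(c(i - 1, i + 1), 2:(n - 1))]
    length(nb) == 0 || ad2[i] >= 1.5 * max(nb)
  }, logical(1))]
  if (length(spikes)) {
    for (i in spikes) {
      nb <- setdiff(max(1, i - 3):min(n, i + 3), spikes)
      y[i] <- stats::median(y[nb])
    }
  }
  list(spectrum = set_intensities(s, y), spikes = spikes)
}

## 3-point parabolic interpolation of the position of a sampled maximum
argmax_parabolic <- function(wn, y) {
  i <- which.max(y)
  if (i == 1L || i == length(y)) return(wn[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom == 0) return(wn[i])
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  wn[i] + delta * (wn[i + 1] - wn[i])
}

#' Calibrate the wavenumber axis against a silicon reference
#'
#' The apparent silicon peak position is located by 3-point parabolic
#' interpolation of the maximum; the whole axis is shifted by
#' delta = 520.5 - apparent position. The same delta should be applied to
#' both acquisition windows of a cell (pass the returned `delta` through
#' `delta_override` for window 2).
#'
#' @param s A [raw_spectrum()] to correct.
#' @param silicon A [raw_spectrum()] of the silicon calibration sample.
#' @param target True silicon line position, 520.5 cm^-1.
#' @param delta_override Apply this precomputed shift instead of locating
#'   the silicon peak.
#' @return List with `spectrum` (axis-shifted [raw_spectrum()]) and `delta`
#'   (applied shift, cm^-1).
#' @export
calibrate_axis <- function(s, silicon, target = 520.5, delta_override = NULL) {
  if (is.null(delta_override)) {
    y <- silicon$intensities
    prominence <- max(y) - stats::median(y)
    noise <- stats::mad(diff(y)) / sqrt(2)
    if (!(prominence > 0) || (noise > 0 && prominence < 10 * noise))
      stop("no detectable silicon peak")
    delta <- target - argmax_parabolic(silicon$wavenumbers, y)
  } else delta <- delta_override
  s$wavenumbers <- s$wavenumbers + delta
  list(spectrum = s, delta = delta)
}

#' Translate a spectrum vertically so its minimum intensity is zero
#'
#' @param s A [raw_spectrum()].
#' @return A [raw_spectrum()].
#' @export
zero_offset <- function(s) {
  set_intensities(s, s$intensities - min(s$intensities))
}

#' Average cell-free background spectra into a background model
#'
#' @param backgrounds List of background spectra: either [raw_spectrum()]
#'   objects on a common grid (single-window model) or per-replicate lists
#'   with `w1`/`w2` elements (two-window model).
#' @param window Wavenumber range (cm^-1) over which the per-cell adjustment
#'   factor is fitted (quartz substrate band region).
#' @return An object of class `background_model`: mean background per
#'   window, replicate count, and the adjustment-factor window.
#' @export
background_model <- function(backgrounds, window = c(430, 530)) {
  if (length(backgrounds) < 1L) stop("need at least one background spectrum")
  avg <- function(specs) {
    wn <- specs[[1]]$wavenumbers
    for (b in specs) if (length(b$wavenumbers) != length(wn) ||
                         max(abs(b$wavenumbers - wn)) > 1e-6)
      stop("background spectra must share one grid")
    m <- rowMeans(vapply(specs, `[[`, numeric(length(wn)), "intensities"))
    raw_spectrum(wn, m, window = specs[[1]]$window, cell_id = "mean_background")
  }
  two_window <- !inherits(backgrounds[[1]], "raw_spectrum")
  if (two_window) {
    mean_w1 <- avg(lapply(backgrounds, `[[`, "w1"))
    mean_w2 <- avg(lapply(backgrounds, `[[`, "w2"))
  } else {
    mean_w1 <- avg(backgrounds)
    mean_w2 <- NULL
  }
  structure(list(mean_w1 = mean_w1, mean_w2 = mean_w2,
                 n_spectra = length(backgrounds),
                 adjustment_factor_window = window),
            class = "background_model")
}

#' Subtract a scaled mean background from a cell spectrum
#'
#' The per-cell adjustment factor a is the least-squares scale of the mean
#' background against the cell spectrum restricted to the quartz-band window
#' (default 430-530 cm^-1), so that the quartz substrate band is fully
#' corrected; the output is s - a * mean_background.
#'
#' @param s A [raw_spectrum()] (window 1, or any window when `a` is given).
#' @param bg A [background_model()].
#' @param a Precomputed adjustment factor; when `NULL` it is fitted on the
#'   quartz window (which must lie inside the spectrum range).
#' @param residual_tol Tolerance used to flag an incomplete quartz
#'   correction in the returned report.
#' @return List with `spectrum` (corrected [raw_spectrum()]), `a` (fitted or
#'   supplied factor), `residual` (mean absolute intensity in the quartz
#'   window after subtraction) and `residual_ok`.
#' @export
subtract_background <- function(s, bg, a = NULL, residual_tol = 50) {
  mean_bg <- if (!is.na(s$window) && s$window == 2L && !is.null(bg$mean_w2))
    bg$mean_w2 else bg$mean_w1
  if (length(mean_bg$wavenumbers) != length(s$wavenumbers) ||
      max(abs(mean_bg$wavenumbers - s$wavenumbers)) > 1e-6) {
    mean_bg <- resample_spectrum(mean_bg, s$wavenumbers)
  }
  if (is.null(a)) {
    win <- bg$adjustment_factor_window
    idx <- which(s$wavenumbers >= win[1] & s$wavenumbers <= win[2])
    if (length(idx) < 2L)
      stop("adjustment-factor window lies outside the spectrum range")
    num <- sum(mean_bg$intensities[idx] * s$intensities[idx])
    den <- sum(mean_bg$intensities[idx]^2)
    if (den == 0) stop("mean background is zero on the adjustment window")
    a <- num / den
  }
  out <- set_intensities(s, s$intensities - a * mean_bg$intensities)
  win <- bg$adjustment_factor_window
  idx <- which(s$wavenumbers >= win[1] & s$wavenumbers <= win[2])
  residual <- if (length(idx)) mean(abs(out$intensities[idx])) else NA_real_
  list(spectrum = out, a = a, residual = residual,
       residual_ok = is.na(residual) || residual <= residual_tol)
}

#' Savitzky-Golay smoothing
#'
#' @param s A [raw_spectrum()].
#' @param window_pts Odd filter length in channels (> `polyorder`).
#' @param polyorder Local polynomial order.
#' @return A smoothed [raw_spectrum()].
#' @export
smooth_sg <- function(s, window_pts = 11, polyorder = 3) {
  if (window_pts %% 2 != 1) stop("window_pts must be odd")
  if (window_pts <= polyorder) stop("window_pts must exceed polyorder")
  if (window_pts >= length(s$intensities))
    stop("window_pts must be smaller than the spectrum length")
  set_intensities(s, signal::sgolayfilt(s$intensities, p = polyorder,
                                        n = window_pts))
}

#' Stitch the two acquisition windows into one spectrum
#'
#' Windows must abut or overlap (gap of at most 2 channels). On an overlap,
#' window 2 is first shifted vertically so the two windows have equal mean
#' intensity over the shared channels, then shared channels are averaged.
#'
#' @param w1,w2 [raw_spectrum()] objects of the same cell.
#' @return A stitched [raw_spectrum()] (window `NA`).
#' @export
stitch_windows <- function(w1, w2) {
  if (!is.na(w1$cell_id) && !is.na(w2$cell_id) && w1$cell_id != w2$cell_id)
    stop("windows belong to different cells")
  if (max(w1$wavenumbers) < min(w2$wavenumbers) - 1e-9) {
    step <- stats::median(diff(w1$wavenumbers))
    gap <- min(w2$wavenumbers) - max(w1$wavenumbers)
    if (gap > 2 * step + 1e-9)
      stop(sprintf("gap of %.1f cm^-1 between windows", gap))
    wn <- c(w1$wavenumbers, w2$wavenumbers)
    y <- c(w1$intensities, w2$intensities)
  } else {
    ov1 <- which(w1$wavenumbers >= min(w2$wavenumbers) - 1e-9)
    ov2 <- which(w2$wavenumbers <= max(w1$wavenumbers) + 1e-9)
    offset <- mean(w1$intensities[ov1]) - mean(w2$intensities[ov2])
    y2 <- w2$intensities + offset
    # average on shared channels (matched by wavenumber), keep the rest
    shared2 <- match(round(w1$wavenumbers[ov1], 6), round(w2$wavenumbers, 6))
    y1 <- w1$intensities
    ok <- !is.na(shared2)
    y1[ov1[ok]] <- (w1$intensities[ov1[ok]] + y2[shared2[ok]]) / 2
    keep2 <- setdiff(seq_along(y2), shared2[ok])
    keep2 <- keep2[w2$wavenumbers[keep2] > max(w1$wavenumbers) + 1e-9]
    wn <- c(w1$wavenumbers, w2$wavenumbers[keep2])
    y <- c(y1, y2[keep2])
  }
  raw_spectrum(wn, y, window = NA_integer_, cell_id = w1$cell_id,
               experiment_id = w1$experiment_id,
               class_label = w1$class_label)
}

#' Truncate a spectrum to a retained wavenumber range
#'
#' @param s A [raw_spectrum()].
#' @param keep Closed wavenumber interval to retain.
#' @return A truncated [raw_spectrum()].
#' @export
truncate_spectrum <- function(s, keep = c(730, 3100)) {
  step <- stats::median(abs(diff(s$wavenumbers)))
  if (min(s$wavenumbers) > keep[1] + step || max(s$wavenumbers) < keep[2] - step)
    stop("spectrum does not cover the retained range")
  idx <- which(s$wavenumbers >= keep[1] & s$wavenumbers <= keep[2])
  raw_spectrum(s$wavenumbers[idx], s$intensities[idx], window = s$window,
               cell_id = s$cell_id, experiment_id = s$experiment_id,
               class_label = s$class_label)
}

#' Truncate and excise a stitched spectrum onto the analysis grid
#'
#' Channels outside `keep` = [730, 3100] cm^-1 are dropped (closed
#' endpoints retained), and channels strictly inside the silent region
#' `excise` = (1750, 2800) cm^-1 are removed and recorded in the excision
#' mask.
#'
#' @param s A stitched [raw_spectrum()] covering `keep`.
#' @param keep Closed retained interval (cm^-1).
#' @param excise Open excised interval (cm^-1).
#' @return A [processed_spectrum()].
#' @export
truncate_excise <- function(s, keep = c(730, 3100), excise = c(1750, 2800)) {
  s <- truncate_spectrum(s, keep)
  inside <- s$wavenumbers > excise[1] & s$wavenumbers < excise[2]
  processed_spectrum(s$wavenumbers[!inside], s$intensities[!inside],
                     excised = excise,
                     provenance = list(list(step = "truncate_excise",
                                            keep = keep, excise = excise)),
                     cell_id = s$cell_id, experiment_id = s$experiment_id,
                     class_label = s$class_label)
}

## excision alone, for use after baseline correction in the full chain
excise_region <- function(s, excise = c(1750, 2800)) {
  inside <- s$wavenumbers > excise[1] & s$wavenumbers < excise[2]
  processed_spectrum(s$wavenumbers[!inside], s$intensities[!inside],
                     excised = excise, provenance = list(),
                     cell_id = s$cell_id, experiment_id = s$experiment_id,
                     class_label = s$class_label)
}

#' Normalize a processed spectrum so the Amide I peak is unity
#'
#' Divides all intensities by the maximum over the Amide I region
#' (1600-1690 cm^-1 by default); that maximum becomes exactly 1.
#'
#' @param s A [processed_spectrum()].
#' @param region Amide I wavenumber range.
#' @return A normalized [processed_spectrum()].
#' @export
normalize_amide1 <- function(s, region = c(1600, 1690)) {
  idx <- which(s$wavenumbers >= region[1] & s$wavenumbers <= region[2])
  if (length(idx) == 0) stop("Amide I region not present")
  m <- max(s$intensities[idx])
  if (!(m > 0)) stop("non-positive Amide I maximum")
  s$intensities <- s$intensities / m
  add_provenance(s, "normalize_amide1", region = region, max = m)
}

#' Standard normal variate standardization
#'
#' Per-spectrum standardization to mean 0, sample sd 1 over the retained
#' channels.
#'
#' @param s A [processed_spectrum()] (or [raw_spectrum()]).
#' @return The standardized spectrum.
#' @export
snv <- function(s) {
  y <- s$intensities
  if (length(y) < 2) stop("SNV needs at least 2 channels")
  sdv <- stats::sd(y)
  if (!(sdv > 0)) stop("zero variance spectrum")
  s$intensities <- (y - mean(y)) / sdv
  if (inherits(s, "processed_spectrum")) s <- add_provenance(s, "snv")
  s
}
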