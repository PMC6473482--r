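## Evaluate an expression with a temporarily fixed RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Instrument model for the synthetic generator
#'
#' Describes the emulated confocal Raman acquisition: two spectral windows
#' that share one channel at 1800 cm^-1, the channel spacing, a wavenumber
#' mis-calibration of the raw axis, additive detector noise, cosmic-ray spike
#' rate, a smooth fluorescence baseline, the broad quartz substrate band near
#' 480 cm^-1, and the overall intensity scale of a cell spectrum.
#'
#' @param window1,window2 Length-2 wavenumber ranges (cm^-1) of the two
#'   acquisition windows; they must abut or overlap.
#' @param grid_step Channel spacing in cm^-1.
#' @param miscalibration_shift Offset (cm^-1) of the reported axis: a band
#'   with true center c appears at c + shift on the raw axis.
#' @param noise_sd Additive Gaussian read/shot noise sd (counts).
#' @param cosmic_rate Expected number of cosmic-ray spikes per window
#'   spectrum (Poisson).
#' @param baseline_coeffs Polynomial coefficients (counts) of the
#'   fluorescence baseline, evaluated in the normalized coordinate
#'   t = (wavenumber - span_min) / (span_max - span_min) over the full span.
#' @param quartz_center,quartz_sigma,quartz_amplitude Gaussian parameters of
#'   the quartz substrate band (counts).
#' @param intensity_scale Mean counts of a unit-amplitude (Amide I) band.
#' @param scale_sdlog Log-sd of the per-cell overall intensity factor.
#' @param baseline_sdlog Log-sd of the per-cell baseline factor.
#' @param bg_baseline_factor Fluorescence baseline factor of cell-free
#'   background spectra relative to the nominal cell baseline.
#' @return An object of class `instrument_model`.
#' @export
instrument_model <- function(window1 = c(300, 1800), window2 = c(1800, 3200),
                             grid_step = 1, miscalibration_shift = 0,
                             noise_sd = 6, cosmic_rate = 1,
                             baseline_coeffs = c(32, 360, 240, -320),
                             quartz_center = 480, quartz_sigma = 55,
                             quartz_amplitude = 2000,
                             intensity_scale = 1200, scale_sdlog = 0.25,
                             baseline_sdlog = 0.3, bg_baseline_factor = 0.5) {
  if (grid_step <= 0) stop("grid_step must be positive")
  if (window1[2] < window2[1]) stop("windows must abut or overlap")
  if (cosmic_rate < 0) stop("cosmic_rate must be >= 0")
  structure(list(window1 = window1, window2 = window2, grid_step = grid_step,
                 miscalibration_shift = miscalibration_shift,
                 noise_sd = noise_sd, cosmic_rate = cosmic_rate,
                 baseline_coeffs = baseline_coeffs,
                 quartz_center = quartz_center, quartz_sigma = quartz_sigma,
                 quartz_amplitude = quartz_amplitude,
                 intensity_scale = intensity_scale, scale_sdlog = scale_sdlog,
                 baseline_sdlog = baseline_sdlog,
                 bg_baseline_factor = bg_baseline_factor),
            class = "instrument_model")
}

window_grid <- function(instrument, window) {
  rng <- if (window == 1L) instrument$window1 else instrument$window2
  seq(rng[1], rng[2], by = instrument$grid_step)
}

## Fluorescence baseline (counts) at true wavenumber positions.
baseline_eval <- function(instrument, wn) {
  span <- c(instrument$window1[1], instrument$window2[2])
  t <- (wn - span[1]) / (span[2] - span[1])
  y <- numeric(length(wn))
  for (k in seq_along(instrument$baseline_coeffs))
    y <- y + instrument$baseline_coeffs[k] * t^(k - 1)
  y
}

quartz_eval <- function(instrument, wn) {
  instrument$quartz_amplitude *
    exp(-(wn - instrument$quartz_center)^2 / (2 * instrument$quartz_sigma^2))
}

## Inject Poisson-many single-channel positive spikes, 10-50x local signal.
add_cosmic_spikes <- function(y, rate) {
  n <- stats::rpois(1, rate)
  if (n == 0) return(list(y = y, idx = integer(0)))
  idx <- sample.int(length(y), min(n, length(y)))
  y[idx] <- y[idx] + stats::runif(length(idx), 10, 50) * (abs(y[idx]) + 50)
  list(y = y, idx = idx)
}

## Draw the per-cell latent state shared by both acquisition windows.
draw_cell_latents <- function(profile, instrument, group_sd = 0.2,
                              bg_scale_meanlog = log(1.1),
                              bg_scale_sdlog = 0.15) {
  b <- profile$bands
  groups <- unique(b$group[!is.na(b$group)])
  g <- stats::setNames(stats::rnorm(length(groups), -group_sd^2 / 2, group_sd),
                       groups)
  eps <- stats::rnorm(nrow(b), -b$cv^2 / 2, b$cv)
  gband <- ifelse(is.na(b$group), 0, g[b$group])
  amplitudes <- b$amplitude * exp(eps + gband)
  list(
    amplitudes = amplitudes,
    scale = instrument$intensity_scale *
      exp(stats::rnorm(1, -instrument$scale_sdlog^2 / 2, instrument$scale_sdlog)),
    baseline_factor = exp(stats::rnorm(1, 0, instrument$baseline_sdlog)),
    bg_scale = exp(stats::rnorm(1, bg_scale_meanlog, bg_scale_sdlog)))
}

#' Generate one synthetic single-cell spectrum (two acquisition windows)
#'
#' The spectrum is a sum of Gaussian cellular bands (amplitudes drawn from
#' the profile's log-normal/latent-factor model, identical latents feeding
#' both windows), a smooth fluorescence baseline, the quartz substrate band
#' scaled by the per-cell background coefficient, additive Gaussian noise,
#' and Poisson-distributed one-channel cosmic-ray spikes. The wavenumber
#' axis is offset by the instrument's mis-calibration shift.
#'
#' @param profile A [cell_line_profile()].
#' @param instrument An [instrument_model()].
#' @param seed Optional integer; when given, the RNG state is restored
#'   afterwards so the draw is reproducible in isolation.
#' @param latents Optional pre-drawn latent state (see Details); drawn if
#'   `NULL`.
#' @param group_sd Sd of the shared latent factor of each covariance group.
#' @param bg_scale_meanlog,bg_scale_sdlog Log-normal parameters of the true
#'   per-cell quartz/background mixing coefficient.
#' @param cell_id,experiment_id Metadata strings.
#' @return List with `w1` and `w2` ([raw_spectrum()] objects) and `truth`,
#'   the latent record (band amplitudes, overall scale, baseline factor,
#'   background mixing coefficient, spike channels, axis shift).
#' @export
generate_cell_spectrum <- function(profile, instrument = instrument_model(),
                                   seed = NULL, latents = NULL,
                                   group_sd = 0.2,
                                   bg_scale_meanlog = log(1.1),
                                   bg_scale_sdlog = 0.15,
                                   cell_id = NA_character_,
                                   experiment_id = NA_character_) {
  if (nrow(profile$bands) < 1L) stop("profile has an empty band list")
  with_seed(seed, {
    if (is.null(latents))
      latents <- draw_cell_latents(profile, instrument, group_sd,
                                   bg_scale_meanlog, bg_scale_sdlog)
    shift <- instrument$miscalibration_shift
    out <- list()
    spikes <- list()
    for (w in 1:2) {
      wn <- window_grid(instrument, w)
      true_wn <- wn - shift
      y <- latents$scale *
        gaussian_mixture(true_wn, profile$bands$center, profile$bands$sigma,
                         latents$amplitudes) +
        latents$bg_scale * quartz_eval(instrument, true_wn) +
        latents$baseline_factor * baseline_eval(instrument, true_wn) +
        stats::rnorm(length(wn), 0, instrument$noise_sd)
      sp <- add_cosmic_spikes(y, instrument$cosmic_rate)
      spikes[[w]] <- sp$idx
      out[[w]] <- raw_spectrum(wn, sp$y, window = w, cell_id = cell_id,
                               experiment_id = experiment_id,
                               class_label = profile$name)
    }
    latents$spike_channels <- spikes
    latents$shift <- shift
    list(w1 = out[[1]], w2 = out[[2]], truth = latents)
  })
}

#' Generate a cell-free background spectrum for one window
#'
#' Quartz substrate band plus an attenuated fluorescence baseline plus
#' detector noise; no cellular bands and no cosmic spikes.
#'
#' @inheritParams generate_cell_spectrum
#' @param window Acquisition window, 1 or 2.
#' @return A [raw_spectrum()].
#' @export
generate_background_spectrum <- function(instrument = instrument_model(),
                                         seed = NULL, window = 1L,
                                         experiment_id = NA_character_) {
  with_seed(seed, {
    wn <- window_grid(instrument, window)
    true_wn <- wn - instrument$miscalibration_shift
    y <- quartz_eval(instrument, true_wn) +
      instrument$bg_baseline_factor * baseline_eval(instrument, true_wn) +
      stats::rnorm(length(wn), 0, instrument$noise_sd)
    raw_spectrum(wn, y, window = window, cell_id = "background",
                 experiment_id = experiment_id)
  })
}

#' Generate a silicon calibration spectrum
#'
#' A single narrow band whose true position is the 520.5 cm^-1 silicon line;
#' on the raw (mis-calibrated) axis its apparent maximum lies at
#' 520.5 + shift.
#'
#' @param shift Axis mis-calibration in cm^-1 (|shift| < 20).
#' @param instrument An [instrument_model()] (the silicon line must fall in
#'   window 1).
#' @param amplitude,sigma Band height (counts) and Gaussian sigma (cm^-1).
#' @return A [raw_spectrum()].
#' @export
generate_silicon_spectrum <- function(shift = 0, instrument = instrument_model(),
                                      amplitude = 10000, sigma = 2.5) {
  if (abs(shift) >= 20) stop("|shift| must be < 20 cm^-1")
  wn <- window_grid(instrument, 1L)
  y <- amplitude * exp(-(wn - shift - 520.5)^2 / (2 * sigma^2))
  raw_spectrum(wn, y, window = 1L, cell_id = "silicon")
}

#' Generator configuration for a full synthetic study dataset
#'
#' The defaults are the study conditions: five cell lines with the bundled
#' calibrated profiles and the published per-class cell counts
#' (167 SW620, 163 SW480, 89 HL60, 190 HT29, 71 HCT116; 680 cells total),
#' cells measured in experiments of at most 85 cells with five cell-free
#' background spectra and one silicon spectrum each, and a small random
#' per-experiment axis mis-calibration.
#'
#' @param profiles Named list of [cell_line_profile()] objects.
#' @param cells_per_class Named integer vector of cells per class; names must
#'   match `profiles`.
#' @param instrument An [instrument_model()].
#' @param group_sd Sd of the shared latent factor within covariance groups.
#' @param bg_scale_meanlog,bg_scale_sdlog Log-normal parameters of the true
#'   per-cell quartz/background mixing coefficient.
#' @param n_backgrounds Cell-free background spectra per experiment.
#' @param cells_per_experiment Maximum cells measured per experiment.
#' @param shift_sd Sd (cm^-1) of the per-experiment axis mis-calibration
#'   (truncated at +/- 4 cm^-1).
#' @param seed Integer RNG seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(profiles = default_profiles(),
                             cells_per_class = c(SW620 = 167, SW480 = 163,
                                                 HL60 = 89, HT29 = 190,
                                                 HCT116 = 71),
                             instrument = instrument_model(),
                             group_sd = 0.2,
                             bg_scale_meanlog = log(1.1),
                             bg_scale_sdlog = 0.15,
                             n_backgrounds = 5, cells_per_experiment = 85,
                             shift_sd = 1.2, seed = 1L) {
  if (anyDuplicated(names(profiles))) stop("duplicate class names")
  if (!all(names(cells_per_class) %in% names(profiles)))
    stop("cells_per_class names must match profiles")
  if (any(cells_per_class < 1)) stop("cells_per_class must be >= 1")
  if (bg_scale_sdlog < 0) stop("bg_scale_sdlog must be >= 0")
  structure(list(profiles = profiles,
                 cells_per_class = cells_per_class[names(cells_per_class)],
                 instrument = instrument, group_sd = group_sd,
                 bg_scale_meanlog = bg_scale_meanlog,
                 bg_scale_sdlog = bg_scale_sdlog,
                 n_backgrounds = n_backgrounds,
                 cells_per_experiment = cells_per_experiment,
                 shift_sd = shift_sd, seed = seed),
            class = "generator_config")
}

#' Generate a full labeled synthetic study dataset
#'
#' Cells of each class are split into experiments of at most
#' `cells_per_experiment` cells. Each experiment gets its own axis
#' mis-calibration, silicon calibration spectrum, and cell-free background
#' spectra; all cells of an experiment share these. The returned truth
#' record stores every latent used (band amplitudes, baseline factors,
#' background mixing coefficients, spike channels, per-experiment shifts)
#' for parameter-recovery tests.
#'
#' @param config A [generator_config()].
#' @return An object of class `spectrum_set`: list with `cells` (per cell:
#'   `w1`, `w2` raw spectra), `meta` (data.frame of cell_id / class /
#'   experiment), `experiments` (per experiment: silicon spectrum, list of
#'   background window pairs, true shift), `truth` (per-cell latent
#'   records), and the generating `config`.
#' @export
generate_study_dataset <- function(config = generator_config()) {
  with_seed(config$seed, {
    cells <- list(); truth <- list(); experiments <- list()
    meta <- list()
    for (cls in names(config$cells_per_class)) {
      n <- config$cells_per_class[[cls]]
      profile <- config$profiles[[cls]]
      n_exp <- ceiling(n / config$cells_per_experiment)
      sizes <- rep(floor(n / n_exp), n_exp)
      if ((r <- n - sum(sizes)) > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
      cell_no <- 0L
      for (e in seq_len(n_exp)) {
        exp_id <- sprintf("%s_exp%d", cls, e)
        shift <- max(-4, min(4, stats::rnorm(1, 0, config$shift_sd)))
        instr <- config$instrument
        instr$miscalibration_shift <- shift
        silicon <- generate_silicon_spectrum(shift, instr)
        backgrounds <- lapply(seq_len(config$n_backgrounds), function(i)
          list(w1 = generate_background_spectrum(instr, window = 1L,
                                                 experiment_id = exp_id),
               w2 = generate_background_spectrum(instr, window = 2L,
                                                 experiment_id = exp_id)))
        experiments[[exp_id]] <- list(silicon = silicon,
                                      backgrounds = backgrounds,
                                      shift = shift)
        for (i in seq_len(sizes[e])) {
          cell_no <- cell_no + 1L
          cid <- sprintf("%s_%03d", cls, cell_no)
          cell <- generate_cell_spectrum(
            profile, instr, group_sd = config$group_sd,
            bg_scale_meanlog = config$bg_scale_meanlog,
            bg_scale_sdlog = config$bg_scale_sdlog,
            cell_id = cid, experiment_id = exp_id)
          cells[[cid]] <- cell[c("w1", "w2")]
          truth[[cid]] <- cell$truth
          meta[[cid]] <- data.frame(cell_id = cid, class = cls,
                                    experiment = exp_id,
                                    stringsAsFactors = FALSE)
        }
      }
    }
    structure(list(cells = cells, meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
                   experiments = experiments, truth = truth, config = config),
              class = "spectrum_set")
  })
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d cells, %d classes, %d experiments\n",
              nrow(x$meta), length(unique(x$meta$class)),
              length(x$experiments)))
  print(table(x$meta$class))
  invisible(x)
}
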