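#' Preprocessing parameter set
#'
#' Defaults are the standard chain parameters: despiking threshold 8,
#' Savitzky-Golay window 11 points / order 3, asymmetric least-squares
#' baseline with lam = 1e7 and p_asym = 0.01, retained range
#' [730, 3100] cm^-1, excised silent region (1750, 2800) cm^-1, Amide I
#' normalization window 1600-1690 cm^-1, chemometrics branch truncated at
#' 3000 cm^-1, adjustment-factor window 430-530 cm^-1.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of parameters.
#' @export
preprocess_params <- function(...) {
  p <- list(despike_enabled = TRUE, z_threshold = 8,
            sg_window = 11, sg_polyorder = 3,
            lam = 1e7, p_asym = 0.01, max_iter = 50,
            keep = c(730, 3100), excise = c(1750, 2800),
            amide1_region = c(1600, 1690), chem_upper = 3000,
            bg_window = c(430, 530))
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  p
}

#' Run the full preprocessing chain on a dataset
#'
#' Per cell, in order: despike both windows; calibrate the axis with the
#' experiment's silicon spectrum (one shift per experiment, applied to both
#' windows); zero-offset; subtract the scaled mean background of the
#' experiment (adjustment factor fitted on the quartz window of window 1 and
#' applied to both windows); Savitzky-Golay smooth; stitch the windows;
#' resample onto the integer analysis grid; truncate to [730, 3100] cm^-1;
#' asymmetric least-squares baseline correction; excise (1750, 2800) cm^-1;
#' Amide-I normalize (band-analysis branch). The chemometrics branch
#' additionally truncates the upper region at 3000 cm^-1 and applies SNV.
#' A cell failing at any stage is skipped with a logged reason; the dataset
#' proceeds.
#'
#' @param set A `spectrum_set` (from [generate_study_dataset()] or
#'   [read_spectrum_set()]).
#' @param params A [preprocess_params()] list.
#' @return An object of class `preprocessed_set`: `band_matrix` (cells x
#'   retained wavenumbers, Amide-I normalized, up to 3100 cm^-1),
#'   `chem_matrix` (cells x retained wavenumbers up to 3000 cm^-1, SNV
#'   rows), `wavenumbers_band`, `wavenumbers_chem`, `meta`, `spectra`
#'   (band-branch [processed_spectrum()] per cell), `adjustment_factors`,
#'   `deltas` (per-experiment calibration shifts), `skipped` (named reasons)
#'   and `params`.
#' @export
preprocess_dataset <- function(set, params = preprocess_params()) {
  p <- params
  # per-experiment calibration shift and background model
  deltas <- list(); bg_models <- list()
  for (exp_id in names(set$experiments)) {
    ex <- set$experiments[[exp_id]]
    cal <- calibrate_axis(ex$silicon, ex$silicon)
    deltas[[exp_id]] <- cal$delta
    bgs <- lapply(ex$backgrounds, function(b) {
      b1 <- calibrate_axis(b$w1, NULL, delta_override = cal$delta)$spectrum
      b2 <- calibrate_axis(b$w2, NULL, delta_override = cal$delta)$spectrum
      if (p$despike_enabled) {
        b1 <- despike(b1, p$z_threshold)$spectrum
        b2 <- despike(b2, p$z_threshold)$spectrum
      }
      list(w1 = b1, w2 = b2)
    })
    bg_models[[exp_id]] <- background_model(bgs, window = p$bg_window)
  }

  band_rows <- list(); chem_rows <- list(); spectra <- list()
  afactors <- numeric(0); skipped <- character(0)
  wn_band <- NULL; wn_chem <- NULL

  for (ci in seq_len(nrow(set$meta))) {
    cid <- set$meta$cell_id[ci]
    exp_id <- set$meta$experiment[ci]
    res <- tryCatch({
      w1 <- set$cells[[cid]]$w1
      w2 <- set$cells[[cid]]$w2
      if (p$despike_enabled) {
        w1 <- despike(w1, p$z_threshold)$spectrum
        w2 <- despike(w2, p$z_threshold)$spectrum
      }
      delta <- deltas[[exp_id]]
      w1 <- calibrate_axis(w1, NULL, delta_override = delta)$spectrum
      w2 <- calibrate_axis(w2, NULL, delta_override = delta)$spectrum
      w1 <- zero_offset(w1)
      w2 <- zero_offset(w2)
      bg <- bg_models[[exp_id]]
      sb1 <- subtract_background(w1, bg)
      w1 <- sb1$spectrum
      w2 <- subtract_background(w2, bg, a = sb1$a)$spectrum
      w1 <- smooth_sg(w1, p$sg_window, p$sg_polyorder)
      w2 <- smooth_sg(w2, p$sg_window, p$sg_polyorder)
      st <- stitch_windows(w1, w2)
      grid <- seq(ceiling(min(st$wavenumbers)), floor(max(st$wavenumbers)), by = 1)
      st <- resample_spectrum(st, grid)
      st <- truncate_spectrum(st, p$keep)
      bl <- baseline_correct(st, lam = p$lam, p_asym = p$p_asym,
                             max_iter = p$max_iter)
      sp <- excise_region(bl$spectrum, p$excise)
      sp$provenance <- list(
        list(step = "despike", enabled = p$despike_enabled,
             z_threshold = p$z_threshold),
        list(step = "calibrate_axis", delta = delta),
        list(step = "zero_offset"),
        list(step = "subtract_background", a = sb1$a),
        list(step = "smooth_sg", window_pts = p$sg_window,
             polyorder = p$sg_polyorder),
        list(step = "stitch_windows"),
        list(step = "truncate", keep = p$keep),
        list(step = "baseline_correct", lam = p$lam, p_asym = p$p_asym),
        list(step = "excise", excise = p$excise))
      sp <- normalize_amide1(sp, p$amide1_region)
      chem <- sp
      keep_chem <- chem$wavenumbers <= p$chem_upper
      chem$wavenumbers <- chem$wavenumbers[keep_chem]
      chem$intensities <- chem$intensities[keep_chem]
      chem <- snv(chem)
      list(band = sp, chem = chem, a = sb1$a)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[cid] <- conditionMessage(res)
      next
    }
    if (is.null(wn_band)) {
      wn_band <- res$band$wavenumbers
      wn_chem <- res$chem$wavenumbers
    } else if (length(res$band$wavenumbers) != length(wn_band) ||
               max(abs(res$band$wavenumbers - wn_band)) > 1e-9) {
      skipped[cid] <- "analysis grid mismatch"
      next
    }
    band_rows[[cid]] <- res$band$intensities
    chem_rows[[cid]] <- res$chem$intensities
    spectra[[cid]] <- res$band
    afactors[cid] <- res$a
  }

  if (length(band_rows) == 0) stop("no cell survived preprocessing")
  band_matrix <- do.call(rbind, band_rows)
  chem_matrix <- do.call(rbind, chem_rows)
  colnames(band_matrix) <- as.character(wn_band)
  colnames(chem_matrix) <- as.character(wn_chem)
  meta <- set$meta[set$meta$cell_id %in% rownames(band_matrix), , drop = FALSE]
  meta <- meta[match(rownames(band_matrix), meta$cell_id), , drop = FALSE]
  structure(list(band_matrix = band_matrix, chem_matrix = chem_matrix,
                 wavenumbers_band = wn_band, wavenumbers_chem = wn_chem,
                 meta = meta, spectra = spectra,
                 adjustment_factors = afactors,
                 deltas = unlist(deltas), skipped = skipped, params = p),
            class = "preprocessed_set")
}

#' @export
print.preprocessed_set <- function(x, ...) {
  cat(sprintf("<preprocessed_set> %d cells x %d (band) / %d (chemometrics) channels; %d skipped\n",
              nrow(x$band_matrix), ncol(x$band_matrix), ncol(x$chem_matrix),
              length(x$skipped)))
  invisible(x)
}

#' Write the chemometrics feature matrix as CSV
#'
#' Rows are cells with metadata columns (`cell_id`, `experiment_id`,
#' `class`) followed by one column per retained wavenumber.
#'
#' @param pp A [preprocess_dataset()] result.
#' @param path Output CSV path.
#' @param which `"chem"` (SNV matrix) or `"band"` (Amide-I normalized).
#' @export
write_feature_matrix <- function(pp, path, which = c("chem", "band")) {
  which <- match.arg(which)
  m <- if (which == "chem") pp$chem_matrix else pp$band_matrix
  df <- cbind(data.frame(cell_id = pp$meta$cell_id,
                         experiment_id = pp$meta$experiment,
                         class = pp$meta$class, stringsAsFactors = FALSE),
              as.data.frame(m, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix CSV written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @return List with `matrix` (cells x wavenumbers), `wavenumbers`, `meta`.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_cols <- c("cell_id", "experiment_id", "class")
  m <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  rownames(m) <- df$cell_id
  list(matrix = m, wavenumbers = as.numeric(colnames(m)),
       meta = df[, intersect(meta_cols, names(df)), drop = FALSE])
}
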