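#' Channelwise class mean and variability spectrum
#'
#' @param pp A [preprocess_dataset()] result.
#' @param class_label Class to average (must have >= 2 cells).
#' @param which Matrix branch: `"band"` (Amide-I normalized) or `"chem"`.
#' @return List with `wavenumbers`, `mean`, `sd`, `n`, `class`.
#' @export
class_mean_spectrum <- function(pp, class_label, which = c("band", "chem")) {
  which <- match.arg(which)
  m <- if (which == "band") pp$band_matrix else pp$chem_matrix
  idx <- which(pp$meta$class == class_label)
  if (length(idx) == 0) stop("unknown class: ", class_label)
  if (length(idx) < 2) stop("need >= 2 spectra in class ", class_label)
  sub <- m[idx, , drop = FALSE]
  list(wavenumbers = if (which == "band") pp$wavenumbers_band else pp$wavenumbers_chem,
       mean = colMeans(sub), sd = apply(sub, 2, stats::sd),
       n = length(idx), class = class_label)
}

## default initial peaks for a named fitting region, from the catalogue
default_init_peaks <- function(region) {
  cat <- band_catalogue()
  sel <- cat$center >= region[1] & cat$center <= region[2]
  if (!any(sel)) stop("no catalogue bands in region")
  data.frame(center = cat$center[sel], sigma = cat$sigma[sel],
             assignment = cat$assignment[sel], stringsAsFactors = FALSE)
}

#' Standard fitting regions
#'
#' Amide III 1200-1320 cm^-1 (4 peaks: beta-sheet, disordered, alpha+beta,
#' alpha-helix), Amide I 1600-1700 cm^-1, CH-stretch 2800-3100 cm^-1
#' (5 peaks).
#'
#' @param name One of `"amide3"`, `"amide1"`, `"ch_stretch"`.
#' @return List with `region` (range) and `init_peaks` (data.frame).
#' @export
fit_region_spec <- function(name = c("amide3", "amide1", "ch_stretch")) {
  name <- match.arg(name)
  region <- switch(name, amide3 = c(1200, 1320), amide1 = c(1600, 1700),
                   ch_stretch = c(2800, 3100))
  init <- default_init_peaks(region)
  if (name == "amide3") {
    # the 4 secondary-structure sub-bands; drop the cytochrome c line, whose
    # contribution the alpha-helix band absorbs in a 4-Gaussian decomposition
    init <- init[init$center %in% c(1240, 1254, 1272, 1296), , drop = FALSE]
  }
  if (name == "ch_stretch")
    init <- init[init$center %in% c(2850, 2885, 2930, 2960, 3060), , drop = FALSE]
  list(region = region, init_peaks = init)
}

## coerce various spectrum representations to list(wavenumbers, intensities)
as_xy <- function(s) {
  if (!is.null(s$intensities)) list(x = s$wavenumbers, y = s$intensities)
  else if (!is.null(s$mean)) list(x = s$wavenumbers, y = s$mean)
  else stop("unrecognized spectrum object")
}

#' Gaussian decomposition of a spectral region
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of a sum of Gaussian
#' peaks with nonnegative amplitudes. With several spectra (class means)
#' and `shared = TRUE`, peak centers and sigmas are global parameters while
#' amplitudes are fitted per class, mirroring decompositions in which peak
#' position and width are fixed between cell lines.
#'
#' @param specs One spectrum or a named list of spectra (class means from
#'   [class_mean_spectrum()] or [processed_spectrum()] objects).
#' @param region Wavenumber range to fit.
#' @param init_peaks Data.frame with `center` and `sigma` columns (and
#'   optionally `assignment`); defaults from the bundled catalogue.
#' @param shared Share centers/sigmas across all spectra.
#' @param max_center_shift Bound (cm^-1) on how far a fitted center may move
#'   from its initial value.
#' @return An object of class `band_fit`: `peaks` data.frame (one row per
#'   spectrum x peak: class, center, sigma, amplitude, assignment),
#'   `region`, `shared`, `rss` (per class), `converged`.
#' @export
fit_region <- function(specs, region, init_peaks = NULL, shared = TRUE,
                       max_center_shift = 15) {
  if (!is.null(specs$wavenumbers)) specs <- list(spectrum = specs)
  if (is.null(names(specs))) names(specs) <- paste0("spectrum", seq_along(specs))
  if (is.null(init_peaks)) init_peaks <- default_init_peaks(region)
  K <- nrow(init_peaks)
  if (K < 1) stop("need at least one initial peak")
  xy <- lapply(specs, function(s) {
    v <- as_xy(s)
    sel <- v$x >= region[1] & v$x <= region[2]
    if (sum(sel) < 3 * K)
      stop("region not (sufficiently) covered by the spectrum")
    list(x = v$x[sel], y = v$y[sel])
  })
  C <- length(xy)
  if (!shared && C > 1) {
    fits <- lapply(names(specs), function(nm)
      fit_region(specs[[nm]], region, init_peaks, shared = TRUE,
                 max_center_shift = max_center_shift))
    peaks <- do.call(rbind, lapply(seq_along(fits), function(i) {
      p <- fits[[i]]$peaks; p$class <- names(specs)[i]; p
    }))
    return(structure(list(peaks = peaks, region = region, shared = FALSE,
                          rss = vapply(fits, function(f) f$rss, numeric(1)),
                          converged = all(vapply(fits, `[[`, TRUE, "converged"))),
                     class = "band_fit"))
  }

  # parameters: centers (K), log-sigmas (K), amplitudes (K per class)
  amp_init <- unlist(lapply(xy, function(v)
    pmax(stats::approx(v$x, v$y, xout = pmin(pmax(init_peaks$center, min(v$x)),
                                             max(v$x)))$y, 1e-3)))
  par0 <- c(init_peaks$center, log(init_peaks$sigma), amp_init)
  lower <- c(init_peaks$center - max_center_shift, rep(log(0.5), K),
             rep(0, K * C))
  upper <- c(init_peaks$center + max_center_shift, rep(log(80), K),
             rep(Inf, K * C))
  resid_fn <- function(par) {
    centers <- par[1:K]; sigmas <- exp(par[(K + 1):(2 * K)])
    unlist(lapply(seq_len(C), function(c) {
      amps <- par[2 * K + (c - 1) * K + 1:K]
      xy[[c]]$y - gaussian_mixture(xy[[c]]$x, centers, sigmas, amps)
    }))
  }
  fit <- minpack.lm::nls.lm(par0, lower = lower, upper = upper, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info == 0 || fit$info == 9)
    stop("band fit did not converge; residual sum of squares = ",
         format(fit$deviance))
  par <- fit$par
  centers <- par[1:K]; sigmas <- exp(par[(K + 1):(2 * K)])
  peaks <- do.call(rbind, lapply(seq_len(C), function(c) {
    data.frame(class = names(specs)[c], center = centers, sigma = sigmas,
               amplitude = par[2 * K + (c - 1) * K + 1:K],
               assignment = if (!is.null(init_peaks$assignment))
                 init_peaks$assignment else NA_character_,
               stringsAsFactors = FALSE)
  }))
  rss <- vapply(seq_len(C), function(c) {
    amps <- par[2 * K + (c - 1) * K + 1:K]
    sum((xy[[c]]$y - gaussian_mixture(xy[[c]]$x, centers, sigmas, amps))^2)
  }, numeric(1))
  names(rss) <- names(specs)
  structure(list(peaks = peaks, region = region, shared = TRUE, rss = rss,
                 converged = TRUE),
            class = "band_fit")
}

#' @export
print.band_fit <- function(x, ...) {
  cat(sprintf("<band_fit> %d peak(s) in [%g, %g] cm^-1, shared = %s\n",
              length(unique(x$peaks$center)), x$region[1], x$region[2],
              x$shared))
  print(x$peaks, digits = 4)
  invisible(x)
}

#' Mean normalized intensity of a band window
#'
#' @param spec A spectrum object (processed spectrum or class mean).
#' @param center Band center (cm^-1).
#' @param half_width Half-width of the averaging window (cm^-1).
#' @return Scalar mean intensity over [center - half_width,
#'   center + half_width]; errors if the window contains no retained
#'   channels (e.g. fully excised).
#' @export
band_intensity <- function(spec, center, half_width = 4) {
  v <- as_xy(spec)
  idx <- which(v$x >= center - half_width & v$x <= center + half_width)
  if (length(idx) == 0)
    stop("band window contains no retained channels (excised?)")
  mean(v$y[idx])
}

#' Filtered Pearson correlation analysis of band intensities
#'
#' Pearson correlation of every wavenumber pair across cells, with p-values
#' from the t-distribution transform. Entries with p above `p_threshold`
#' (default 1e-4) are zeroed in `filtered_r`; pairs with |r| above
#' `r_threshold` (default 0.3) and below-threshold p are reported, sorted
#' by |r|.
#'
#' @param m Matrix of cells x wavenumbers (numeric column names), or a
#'   [preprocess_dataset()] result (its band matrix is used).
#' @param at Optional wavenumbers at which to evaluate (nearest retained
#'   channel is used); default all columns.
#' @param p_threshold,r_threshold Filter thresholds.
#' @return An object of class `correlation_result`: `r_matrix`, `p_matrix`,
#'   `filtered_r`, `reported_pairs` (data.frame wn_i, wn_j, r, p),
#'   `constant_columns` (flagged, r set to 0), `n`.
#' @export
correlation_analysis <- function(m, at = NULL, p_threshold = 1e-4,
                                 r_threshold = 0.3) {
  if (inherits(m, "preprocessed_set")) m <- m$band_matrix
  n <- nrow(m)
  if (n < 3) stop("correlation analysis needs >= 3 cells")
  wn <- as.numeric(colnames(m))
  if (!is.null(at)) {
    cols <- vapply(at, function(w) which.min(abs(wn - w)), integer(1))
    cols <- unique(cols)
    m <- m[, cols, drop = FALSE]
    wn <- wn[cols]
  }
  sds <- apply(m, 2, stats::sd)
  constant <- which(sds == 0)
  r <- suppressWarnings(stats::cor(m))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  tstat <- r * sqrt(pmax(n - 2, 1) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  filtered <- r
  filtered[p > p_threshold] <- 0
  ut <- which(upper.tri(r) & abs(filtered) > r_threshold & filtered != 0,
              arr.ind = TRUE)
  pairs <- data.frame(wn_i = wn[ut[, 1]], wn_j = wn[ut[, 2]],
                      r = r[ut], p = p[ut])
  pairs <- pairs[order(-abs(pairs$r)), , drop = FALSE]
  rownames(pairs) <- NULL
  dimnames(r) <- dimnames(p) <- dimnames(filtered) <- list(wn, wn)
  structure(list(r_matrix = r, p_matrix = p, filtered_r = filtered,
                 reported_pairs = pairs,
                 constant_columns = wn[constant], n = n,
                 p_threshold = p_threshold, r_threshold = r_threshold),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %d wavenumbers, n = %d cells, %d reported pair(s) (|r| > %g, p <= %g)\n",
              ncol(x$r_matrix), x$n, nrow(x$reported_pairs), x$r_threshold,
              x$p_threshold))
  invisible(x)
}
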