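#' Asymmetric least-squares baseline correction
#'
#' Iteratively reweighted penalized least squares (Eilers-style asymmetric
#' smoothing): the baseline z minimizes
#' sum_i w_i (y_i - z_i)^2 + lam * sum_i (Delta^2 z_i)^2,
#' with weights w_i = p_asym where y_i > z_i and 1 - p_asym elsewhere, so
#' the estimate hugs the lower envelope of the spectrum and stays at or
#' below band apexes. Iterations stop when the weight vector changes by
#' less than `tol` on average, or at `max_iter` (with a warning).
#'
#' @param s A [raw_spectrum()] (despiked and background-subtracted).
#' @param lam Smoothness weight (second-difference penalty).
#' @param p_asym Asymmetry weight in (0, 1); small values push the baseline
#'   below the bands.
#' @param max_iter Maximum reweighting iterations.
#' @param tol Convergence tolerance on the mean absolute weight change.
#' @return List with `spectrum` (baseline-subtracted [raw_spectrum()]) and
#'   `baseline` (numeric vector).
#' @export
baseline_correct <- function(s, lam = 1e7, p_asym = 0.01, max_iter = 50,
                             tol = 1e-6) {
  y <- s$intensities
  n <- length(y)
  if (n < 4) stop("spectrum too short for baseline estimation")
  D <- Matrix::bandSparse(n - 2, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- lam * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w_new <- ifelse(y > z, p_asym, 1 - p_asym)
    if (mean(abs(w_new - w)) < tol) { converged <- TRUE; break }
    w <- w_new
  }
  if (!converged && max_iter > 2)
    warning("baseline estimation did not converge in ", max_iter,
            " iterations; returning best estimate")
  out <- set_intensities(s, y - z)
  list(spectrum = out, baseline = z)
}
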