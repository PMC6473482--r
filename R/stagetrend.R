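#' Ordinal disease-stage coding for colorectal adenocarcinoma lines
#'
#' Default mapping of the adenocarcinoma lines to ordinal Duke-stage codes:
#' SW480 (Duke B, primary) = 1, HT29 (Duke C, primary) = 2, SW620 (Duke C,
#' lymph-node metastasis) = 3.
#'
#' @param mapping Named numeric vector, class -> stage code; codes must be
#'   strictly increasing in the stated order.
#' @return An object of class `stage_coding`.
#' @export
stage_coding <- function(mapping = c(SW480 = 1, HT29 = 2, SW620 = 3)) {
  if (is.unsorted(mapping, strictly = TRUE))
    stop("stage codes must be strictly increasing with stage order")
  structure(list(mapping = mapping), class = "stage_coding")
}

#' Partial least squares regression of spectra on stage codes
#'
#' SIMPLS regression of the ordinal stage code on the spectra. Components
#' are sign-oriented so that the mean score increases with the stage code.
#'
#' @param m Cells x wavenumbers matrix (rows restricted to classes with a
#'   stage code).
#' @param stage_codes Numeric response, one per row.
#' @param n_components Components to extract (default 10).
#' @return An object of class `plsr_result`: `weights` (wavenumbers x
#'   components: the vectors R with scores = centered X \%*\% R), `scores`
#'   (cells x components), `x_loadings`, `y_loadings`, `coefficients`
#'   (regression vector using all components), `r_squared` (cumulative per
#'   component), `means`.
#' @export
plsr_fit <- function(m, stage_codes, n_components = 10) {
  y <- as.numeric(stage_codes)
  if (length(unique(y)) < 2) stop("constant response")
  m <- as.matrix(m)
  n <- nrow(m)
  if (length(y) != n) stop("response length must match rows")
  n_components <- min(n_components, n - 1, ncol(m))
  x_mean <- colMeans(m); y_mean <- mean(y)
  X <- sweep(m, 2, x_mean); yc <- y - y_mean
  p <- ncol(X)
  R <- matrix(0, p, n_components); TT <- matrix(0, n, n_components)
  P <- matrix(0, p, n_components); q <- numeric(n_components)
  V <- matrix(0, p, 0)
  s <- crossprod(X, yc)                     # p x 1
  for (a in seq_len(n_components)) {
    r <- s
    t <- X %*% r
    normt <- sqrt(sum(t^2))
    if (normt < .Machine$double.eps^0.5) { n_components <- a - 1L; break }
    t <- t / normt; r <- r / normt
    pv <- crossprod(X, t)
    qa <- sum(yc * t)
    v <- pv
    if (ncol(V) > 0) v <- v - V %*% crossprod(V, pv)
    v <- v / sqrt(sum(v^2))
    V <- cbind(V, v)
    s <- s - v %*% crossprod(v, s)
    if (qa < 0) { r <- -r; t <- -t; pv <- -pv; qa <- -qa }
    R[, a] <- r; TT[, a] <- t; P[, a] <- pv; q[a] <- qa
  }
  if (n_components < 1) stop("no usable PLS component")
  R <- R[, seq_len(n_components), drop = FALSE]
  TT <- TT[, seq_len(n_components), drop = FALSE]
  P <- P[, seq_len(n_components), drop = FALSE]
  q <- q[seq_len(n_components)]
  r2 <- vapply(seq_len(n_components), function(a) {
    yhat <- TT[, seq_len(a), drop = FALSE] %*% q[seq_len(a)] + y_mean
    1 - sum((y - yhat)^2) / sum((y - y_mean)^2)
  }, numeric(1))
  rownames(R) <- rownames(P) <- colnames(m)
  structure(list(weights = R, scores = TT, x_loadings = P, y_loadings = q,
                 coefficients = R %*% q, r_squared = r2,
                 means = list(x = x_mean, y = y_mean),
                 n_components = n_components),
            class = "plsr_result")
}

#' Predict stage codes from a PLSR fit
#'
#' @param object A [plsr_fit()] result.
#' @param newdata Cells x wavenumbers matrix.
#' @param n_components Components used for prediction (default all).
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.plsr_result <- function(object, newdata, n_components = NULL, ...) {
  a <- if (is.null(n_components)) object$n_components
       else min(n_components, object$n_components)
  B <- object$weights[, seq_len(a), drop = FALSE] %*%
    object$y_loadings[seq_len(a)]
  as.numeric(sweep(as.matrix(newdata), 2, object$means$x) %*% B +
               object$means$y)
}

#' Select PLSR components showing a significant stage-wise score increase
#'
#' A component is selected iff unpaired one-tailed two-sample t-tests show
#' its mean score strictly increasing across both adjacent stage pairs
#' (stage 1 < stage 2 and stage 2 < stage 3) at p < alpha. With
#' `pairs = "all"`, every ordered class pair must pass instead.
#'
#' @param res A [plsr_fit()] result.
#' @param labels Class labels, one per score row.
#' @param coding A [stage_coding()].
#' @param alpha Significance level (default 0.01).
#' @param pairs `"adjacent"` (default) or `"all"`.
#' @return List with `selected` (component indices), `pairwise_p` (matrix
#'   components x pairs), `alpha`.
#' @export
select_stage_components <- function(res, labels, coding = stage_coding(),
                                    alpha = 0.01,
                                    pairs = c("adjacent", "all")) {
  pairs <- match.arg(pairs)
  map <- coding$mapping
  classes <- names(map)[order(map)]
  if (length(classes) < 3) stop("need >= 3 staged classes")
  if (any(table(labels[labels %in% classes]) < 2))
    stop("every staged class needs >= 2 cells")
  idx_pairs <- if (pairs == "adjacent")
    lapply(seq_len(length(classes) - 1), function(i) classes[c(i, i + 1)])
  else utils::combn(classes, 2, simplify = FALSE)
  pmat <- matrix(NA_real_, res$n_components, length(idx_pairs),
                 dimnames = list(NULL, vapply(idx_pairs, paste,
                                              collapse = "<", "")))
  for (a in seq_len(res$n_components)) {
    sc <- res$scores[, a]
    for (j in seq_along(idx_pairs)) {
      lo <- sc[labels == idx_pairs[[j]][1]]
      hi <- sc[labels == idx_pairs[[j]][2]]
      pmat[a, j] <- stats::t.test(hi, lo, alternative = "greater",
                                  var.equal = FALSE)$p.value
    }
  }
  selected <- which(apply(pmat, 1, function(p) all(p < alpha)))
  list(selected = unname(selected), pairwise_p = pmat, alpha = alpha)
}

#' Per-class score summaries and weight export for selected components
#'
#' @param res A [plsr_fit()] result.
#' @param labels Class labels per score row.
#' @param selection A [select_stage_components()] result.
#' @param coding A [stage_coding()].
#' @return List with `summaries` (per selected component: data.frame of
#'   class, n, mean, quartiles), `scores` (long data.frame of individual
#'   cell scores), `weights` (wavenumbers x selected components),
#'   `pairwise_p`. Empty (with a warning) when nothing was selected.
#' @export
stage_report <- function(res, labels, selection, coding = stage_coding()) {
  sel <- selection$selected
  if (length(sel) == 0) {
    warning("no component passed the stage-trend selection")
    return(list(summaries = list(), scores = NULL, weights = NULL,
                pairwise_p = selection$pairwise_p))
  }
  classes <- names(coding$mapping)[order(coding$mapping)]
  summaries <- lapply(sel, function(a) {
    do.call(rbind, lapply(classes, function(cls) {
      sc <- res$scores[labels == cls, a]
      data.frame(component = a, class = cls, n = length(sc),
                 mean = mean(sc), q25 = unname(stats::quantile(sc, 0.25)),
                 median = stats::median(sc),
                 q75 = unname(stats::quantile(sc, 0.75)))
    }))
  })
  long <- do.call(rbind, lapply(sel, function(a)
    data.frame(component = a, class = labels, score = res$scores[, a])))
  long <- long[long$class %in% classes, , drop = FALSE]
  list(summaries = summaries, scores = long,
       weights = res$weights[, sel, drop = FALSE],
       pairwise_p = selection$pairwise_p[sel, , drop = FALSE])
}
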