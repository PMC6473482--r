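#' Principal component analysis of a feature matrix
#'
#' Mean-centered PCA with a fixed sign convention (the largest-|weight|
#' element of every loading is positive).
#'
#' @param m Cells x wavenumbers matrix (already SNV-standardized for the
#'   chemometrics branch).
#' @param n_components Number of components to keep (default 25).
#' @return An object of class `pca_model`: `loadings` (wavenumbers x
#'   components, orthonormal), `scores` (cells x components),
#'   `explained_variance_pct`, `center`.
#' @export
pca_fit <- function(m, n_components = 25) {
  if (nrow(m) < n_components)
    stop("need at least as many rows as components")
  rk <- min(nrow(m) - 1, ncol(m))
  if (n_components > rk) stop("components exceed matrix rank")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- vapply(seq_len(n_components), function(k) {
    v <- pc$rotation[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  varpct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = loadings, scores = scores,
                 explained_variance_pct = varpct[seq_len(n_components)],
                 center = pc$center),
            class = "pca_model")
}

#' Project new spectra onto a fitted PCA model
#'
#' @param object A [pca_fit()] model.
#' @param newdata Cells x wavenumbers matrix.
#' @param ... Unused.
#' @return Scores matrix.
#' @export
predict.pca_model <- function(object, newdata, ...) {
  sweep(newdata, 2, object$center) %*% object$loadings
}

#' One-vs-one Fisher linear discriminant model on PC scores
#'
#' For every unordered class pair a Fisher discriminant is fitted on the
#' pooled within-class covariance (ridge-regularized when singular), giving
#' C(k, 2) pairwise discriminants; prediction is by one-vs-one majority
#' vote with ties broken by the largest summed projection margin.
#'
#' @param scores Cells x components score matrix.
#' @param labels Class labels (>= 2 classes, every class with >= 2 samples).
#' @param ridge Ridge added to the pooled covariance (relative to its mean
#'   diagonal).
#' @return An object of class `lda_model` with one weight vector and
#'   threshold per class pair.
#' @export
lda_fit <- function(scores, labels, ridge = 1e-6) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes")
  cnt <- table(labels)
  if (any(cnt < 2)) stop("every class needs >= 2 samples")
  scores <- as.matrix(scores)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  lds <- lapply(pairs, function(pr) {
    xa <- scores[labels == pr[1], , drop = FALSE]
    xb <- scores[labels == pr[2], , drop = FALSE]
    ma <- colMeans(xa); mb <- colMeans(xb)
    sw <- ((nrow(xa) - 1) * stats::cov(xa) + (nrow(xb) - 1) * stats::cov(xb)) /
      (nrow(xa) + nrow(xb) - 2)
    sw <- sw + diag(ridge * mean(diag(sw)) + 1e-12, ncol(sw))
    w <- solve(sw, mb - ma)
    w <- w / sqrt(sum(w^2))
    list(classes = pr, w = w, threshold = sum(w * (ma + mb)) / 2)
  })
  structure(list(pairwise_lds = lds, classes = classes), class = "lda_model")
}

#' Predict classes from a one-vs-one LDA model
#'
#' @param object An [lda_fit()] model.
#' @param newdata Score matrix.
#' @param ... Unused.
#' @return Character vector of predicted classes.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  k <- length(object$classes)
  votes <- matrix(0, nrow(newdata), k,
                  dimnames = list(NULL, object$classes))
  margin <- votes
  for (ld in object$pairwise_lds) {
    proj <- as.numeric(newdata %*% ld$w) - ld$threshold
    to_b <- proj > 0
    votes[, ld$classes[2]] <- votes[, ld$classes[2]] + to_b
    votes[, ld$classes[1]] <- votes[, ld$classes[1]] + !to_b
    margin[, ld$classes[2]] <- margin[, ld$classes[2]] + pmax(proj, 0)
    margin[, ld$classes[1]] <- margin[, ld$classes[1]] + pmax(-proj, 0)
  }
  vapply(seq_len(nrow(newdata)), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) top <- top[which.max(margin[i, top])]
    object$classes[top]
  }, character(1))
}

## wavenumber-named data.frame for rpart (syntactic column names)
as_rpart_frame <- function(m, y = NULL) {
  df <- as.data.frame(m)
  names(df) <- paste0("wn", colnames(m))
  if (!is.null(y)) df$.class <- factor(y)
  df
}

#' Single CART-style binary classification tree on raw intensities
#'
#' Gini-splitting binary tree fitted directly on the wavenumber intensities
#' (not on PC scores); the wavenumbers used at the splits are reported.
#'
#' @param m Cells x wavenumbers matrix.
#' @param labels Class labels.
#' @param max_depth Maximum tree depth.
#' @param cp Complexity parameter passed to the tree grower.
#' @return An object of class `tree_model` with the fitted tree and the
#'   `split_wavenumbers` used.
#' @export
tree_fit <- function(m, labels, max_depth = 30, cp = 0.01) {
  df <- as_rpart_frame(m, labels)
  fit <- rpart::rpart(.class ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        maxdepth = max_depth, cp = cp, xval = 0,
                        maxcompete = 0, maxsurrogate = 0, usesurrogate = 0))
  vars <- fit$frame$var
  wns <- as.numeric(sub("^wn", "", setdiff(unique(as.character(vars)), "<leaf>")))
  structure(list(tree = fit, split_wavenumbers = sort(wns)),
            class = "tree_model")
}

#' @export
predict.tree_model <- function(object, newdata, ...) {
  as.character(predict(object$tree, as_rpart_frame(newdata), type = "class"))
}

#' Boosted small-tree ensemble with wavenumber-frequency reporting
#'
#' Adaptive boosting (SAMME) of depth-limited Gini trees: each round fits a
#' small tree to the reweighted sample, rounds vote with weight
#' log((1 - err)/err) + log(K - 1), and the wavenumbers chosen across all
#' rounds are tallied into a selection-frequency table.
#'
#' @param m Cells x wavenumbers matrix.
#' @param labels Class labels.
#' @param n_rounds Boosting rounds (>= 1).
#' @param max_depth Depth of each small tree.
#' @return An object of class `tree_ensemble`: `trees`, `alphas`, `classes`
#'   and `wavenumber_frequency` (sorted table).
#' @export
tree_ensemble_fit <- function(m, labels, n_rounds = 20, max_depth = 2) {
  if (n_rounds < 1) stop("n_rounds must be >= 1")
  y <- factor(labels)
  K <- nlevels(y)
  n <- nrow(m)
  df <- as_rpart_frame(m, y)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0); chosen <- character(0)
  for (r in seq_len(n_rounds)) {
    fit <- rpart::rpart(.class ~ ., data = df, weights = w, method = "class",
                        parms = list(split = "gini"),
                        control = rpart::rpart.control(
                          # tiny positive cp: real splits always clear it,
                          # zero-gain splits of already-pure nodes do not
                          maxdepth = max_depth, cp = 1e-6, xval = 0,
                          minsplit = max(4, round(n / 50)),
                          maxcompete = 0, maxsurrogate = 0, usesurrogate = 0))
    # training predictions straight from the fitted leaves (no model.frame)
    pred <- levels(y)[fit$frame$yval[fit$where]]
    miss <- pred != y
    err <- sum(w[miss]) / sum(w)
    vars <- setdiff(unique(as.character(fit$frame$var)), "<leaf>")
    if (err >= 1 - 1 / K) break
    err_eff <- max(err, 0.5 / n)            # floor for perfectly fitted rounds
    alpha <- log((1 - err_eff) / err_eff) + log(K - 1)
    trees[[length(trees) + 1]] <- fit
    alphas <- c(alphas, alpha)
    chosen <- c(chosen, vars)
    if (err <= 0) {
      # nothing left to upweight: restart from a bootstrap-perturbed sample
      # so later rounds keep exploring alternative split wavenumbers
      w <- tabulate(sample.int(n, n, replace = TRUE), nbins = n) / n
    } else {
      w <- w * exp(alpha * miss)
      w <- w / sum(w)
    }
  }
  freq <- sort(table(as.numeric(sub("^wn", "", chosen))), decreasing = TRUE)
  structure(list(trees = trees, alphas = alphas, classes = levels(y),
                 wavenumber_frequency = freq),
            class = "tree_ensemble")
}

#' @export
predict.tree_ensemble <- function(object, newdata, ...) {
  df <- as_rpart_frame(newdata)
  score <- matrix(0, nrow(df), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (i in seq_along(object$trees)) {
    pred <- as.character(predict(object$trees[[i]], df, type = "class"))
    score[cbind(seq_len(nrow(df)), match(pred, object$classes))] <-
      score[cbind(seq_len(nrow(df)), match(pred, object$classes))] +
      object$alphas[i]
  }
  object$classes[max.col(score, ties.method = "first")]
}

#' Soft-margin linear SVM
#'
#' Linear-kernel support vector machine (one-vs-one for more than two
#' classes), cost parameter C = 1 by default.
#'
#' @param m Cells x wavenumbers matrix.
#' @param labels Class labels.
#' @param cost Soft-margin cost C.
#' @return An object of class `svm_model`.
#' @export
svm_fit <- function(m, labels, cost = 1) {
  if (length(unique(labels)) < 2) stop("need >= 2 classes")
  fit <- e1071::svm(x = m, y = factor(labels), kernel = "linear",
                    cost = cost, scale = FALSE)
  structure(list(svm = fit), class = "svm_model")
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  as.character(predict(object$svm, newdata))
}

#' Classifier specifications for cross-validation
#'
#' Each specification bundles a `fit(m, labels)` and a `predict(model, m)`
#' closure so that every data-dependent step (PCA included) is re-fitted
#' inside each training fold.
#'
#' @param n_pc Number of principal components for the PCA+LDA pipeline.
#' @param max_depth,cp Single-tree controls.
#' @param n_rounds Ensemble boosting rounds.
#' @param cost SVM soft-margin cost.
#' @return A `classifier_spec` list with `name`, `fit`, `predict`.
#' @export
spec_pca_lda <- function(n_pc = 25) {
  structure(list(
    name = sprintf("pca(%d)+lda", n_pc),
    fit = function(m, labels) {
      pca <- pca_fit(m, n_components = min(n_pc, nrow(m) - 1, ncol(m)))
      list(pca = pca, lda = lda_fit(pca$scores, labels))
    },
    predict = function(model, m)
      predict(model$lda, predict(model$pca, m))),
    class = "classifier_spec")
}

#' @rdname spec_pca_lda
#' @export
spec_tree <- function(max_depth = 30, cp = 0.01) {
  structure(list(
    name = "tree",
    fit = function(m, labels) tree_fit(m, labels, max_depth, cp),
    predict = function(model, m) predict(model, m)),
    class = "classifier_spec")
}

#' @rdname spec_pca_lda
#' @export
spec_tree_ensemble <- function(n_rounds = 20, max_depth = 2) {
  structure(list(
    name = sprintf("tree_ensemble(%d)", n_rounds),
    fit = function(m, labels) tree_ensemble_fit(m, labels, n_rounds, max_depth),
    predict = function(model, m) predict(model, m)),
    class = "classifier_spec")
}

#' @rdname spec_pca_lda
#' @export
spec_svm <- function(cost = 1) {
  structure(list(
    name = "svm(linear)",
    fit = function(m, labels) svm_fit(m, labels, cost),
    predict = function(model, m) predict(model, m)),
    class = "classifier_spec")
}

## stratified fold assignment; re-randomized per repetition
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(sample.int(k), length(idx)))
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Stratified folds re-randomized at each repetition; all model fitting
#' (PCA included) is nested inside the training folds. The accuracy
#' standard error is sigma/sqrt(N) over the k x reps fold estimates.
#'
#' @param spec A `classifier_spec` (see [spec_pca_lda()]).
#' @param m Cells x features matrix.
#' @param labels Class labels.
#' @param k Folds (default 10).
#' @param reps Repetitions (default 5).
#' @param seed Optional RNG seed (state restored afterwards).
#' @return An object of class `cv_result`: `accuracy_mean` and
#'   `accuracy_se` (percent), `per_fold`, `confusion` (summed over
#'   repetitions), `protocol`.
#' @export
cross_validate <- function(spec, m, labels, k = 10, reps = 5, seed = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < k) stop("need at least k samples")
  classes <- sort(unique(labels))
  with_seed(seed, {
    per_fold <- numeric(0)
    confusion <- matrix(0L, length(classes), length(classes),
                        dimnames = list(truth = classes, predicted = classes))
    for (r in seq_len(reps)) {
      fold <- stratified_folds(labels, k)
      for (f in seq_len(k)) {
        test <- which(fold == f)
        train <- which(fold != f)
        if (length(unique(labels[train])) < length(classes))
          stop("a class is absent from a training fold; reduce k")
        model <- spec$fit(m[train, , drop = FALSE], labels[train])
        pred <- as.character(spec$predict(model, m[test, , drop = FALSE]))
        per_fold <- c(per_fold, 100 * mean(pred == labels[test]))
        for (i in seq_along(test))
          confusion[labels[test[i]], pred[i]] <-
            confusion[labels[test[i]], pred[i]] + 1L
      }
    }
    structure(list(accuracy_mean = mean(per_fold),
                   accuracy_se = stats::sd(per_fold) / sqrt(length(per_fold)),
                   per_fold = per_fold, confusion = confusion,
                   protocol = list(k_folds = k, repetitions = reps,
                                   stratified = TRUE, seed = seed,
                                   model = spec$name)),
              class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: %.1f +/- %.1f %% (%d-fold x %d)\n",
              x$protocol$model, x$accuracy_mean, x$accuracy_se,
              x$protocol$k_folds, x$protocol$repetitions))
  invisible(x)
}

#' Learning curve with saturating Weibull-sigmoid fit
#'
#' For each training-set size (cells per class), the classifier is fitted on
#' a random class-balanced subset and evaluated on `test_n` held-out cells;
#' this is resampled `n_resamples` times. A saturating Weibull sigmoid
#' a * (1 - exp(-(n/lambda)^kappa)) with a <= 100 is fitted to the mean
#' accuracies and its saturation parameter a reported.
#'
#' @param spec A `classifier_spec`.
#' @param m Feature matrix.
#' @param labels Class labels.
#' @param train_sizes Cells per class in the training subset.
#' @param test_n Held-out test cells per resample.
#' @param n_resamples Resamples per size (default 100).
#' @param seed Optional RNG seed.
#' @return List with `sizes`, `accuracy_mean`, `accuracy_se` (percent) and
#'   `fit` (`saturation`, `lambda`, `kappa`).
#' @export
learning_curve <- function(spec, m, labels, train_sizes, test_n = 50,
                           n_resamples = 100, seed = NULL) {
  labels <- as.character(labels)
  classes <- unique(labels)
  with_seed(seed, {
    acc_mean <- acc_se <- numeric(length(train_sizes))
    for (si in seq_along(train_sizes)) {
      sz <- train_sizes[si]
      accs <- vapply(seq_len(n_resamples), function(i) {
        train <- unlist(lapply(classes, function(cls)
          sample(which(labels == cls), sz)))
        rest <- setdiff(seq_along(labels), train)
        test <- sample(rest, min(test_n, length(rest)))
        model <- spec$fit(m[train, , drop = FALSE], labels[train])
        100 * mean(as.character(spec$predict(model, m[test, , drop = FALSE])) ==
                     labels[test])
      }, numeric(1))
      acc_mean[si] <- mean(accs)
      acc_se[si] <- stats::sd(accs) / sqrt(n_resamples)
    }
    fit <- if (diff(range(acc_mean)) < 0.5) {
      # flat curve: the sigmoid is unidentified, report the plateau directly
      list(saturation = mean(acc_mean), lambda = NA_real_, kappa = NA_real_)
    } else tryCatch({
      f <- minpack.lm::nlsLM(
        acc ~ a * (1 - exp(-(n / lambda)^kappa)),
        data = data.frame(acc = acc_mean, n = train_sizes),
        start = list(a = min(max(acc_mean) + 1, 100),
                     lambda = max(min(train_sizes) / 2, 1), kappa = 1),
        lower = c(a = 0, lambda = 1e-3, kappa = 0.1),
        upper = c(a = 100, lambda = 1e4, kappa = 10))
      cf <- stats::coef(f)
      list(saturation = unname(cf["a"]), lambda = unname(cf["lambda"]),
           kappa = unname(cf["kappa"]))
    }, error = function(e) list(saturation = NA_real_, lambda = NA_real_,
                                kappa = NA_real_))
    list(sizes = train_sizes, accuracy_mean = acc_mean, accuracy_se = acc_se,
         fit = fit)
  })
}
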