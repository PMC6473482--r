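test_that("PCA meets its orthonormality, variance and sign contracts", {
  # rank-1 data: PC1 explains everything
  v <- with_seed_test(2L, {
    base <- rnorm(20)
    outer(rnorm(30), base)
  })
  p1 <- pca_fit(v, 3)
  expect_gt(p1$explained_variance_pct[1], 99.999)

  m <- with_seed_test(3L, matrix(rnorm(200 * 40), 200, 40))
  pc <- pca_fit(m, 10)
  gram <- crossprod(pc$loadings)
  expect_lt(max(abs(gram - diag(10))), 1e-8)
  expect_true(all(diff(pc$explained_variance_pct) <= 1e-12))
  expect_lte(sum(pc$explained_variance_pct), 100 + 1e-9)
  # sign convention: largest-|weight| element positive
  for (k in 1:10) {
    v <- pc$loadings[, k]
    expect_gt(v[which.max(abs(v))], 0)
  }
  # projection of the training data reproduces the scores
  expect_equal(unname(predict(pc, m)), unname(pc$scores), tolerance = 1e-9)
  expect_error(pca_fit(m[1:5, ], 10), "rows")
})

test_that("PC1 share of isotropic noise matches a permutation oracle", {
  m <- with_seed_test(8L, matrix(rnorm(500 * 100), 500, 100))
  share <- function(x) {
    s <- stats::prcomp(x)$sdev^2
    100 * s[1] / sum(s)
  }
  obs <- share(m)
  null <- with_seed_test(9L, vapply(1:30, function(i)
    share(apply(m, 2, sample)), numeric(1)))
  expect_lt(abs(obs - mean(null)), 3 * stats::sd(null))
})

test_that("a PC separates the two default classes strongly", {
  fx <- fx_two_class()
  pc <- pca_fit(fx$pp$chem_matrix, 10)
  pvals <- vapply(1:10, function(k)
    stats::t.test(pc$scores[fx$pp$meta$class == "SW480", k],
                  pc$scores[fx$pp$meta$class == "SW620", k])$p.value,
    numeric(1))
  expect_lt(min(pvals), 1e-6)
})

test_that("pairwise Fisher discriminants separate and count correctly", {
  scores <- with_seed_test(5L, rbind(
    cbind(rnorm(40, -4), matrix(rnorm(40 * 4), 40)),
    cbind(rnorm(40, 4), matrix(rnorm(40 * 4), 40))))
  labels <- rep(c("a", "b"), each = 40)
  ld <- lda_fit(scores, labels)
  expect_length(ld$pairwise_lds, 1)
  w <- ld$pairwise_lds[[1]]$w
  expect_gt(abs(w[1]) / sqrt(sum(w^2)), 0.95)  # LD along the separating axis
  expect_equal(predict(ld, scores), labels)

  # five classes -> exactly choose(5, 2) = 10 pairwise discriminants
  s5 <- with_seed_test(6L, matrix(rnorm(100 * 6), 100))
  ld5 <- lda_fit(s5, rep(letters[1:5], each = 20))
  expect_length(ld5$pairwise_lds, 10)

  expect_error(lda_fit(scores, rep("a", 80)), ">= 2 classes")
  expect_error(lda_fit(scores[1:3, ], c("a", "a", "b")), ">= 2 samples")
})

test_that("identical class distributions yield chance-level LDA", {
  m <- with_seed_test(12L, matrix(rnorm(120 * 20), 120, 20))
  colnames(m) <- as.character(1:20)
  labels <- rep(c("a", "b"), 60)
  cv <- cross_validate(spec_pca_lda(10), m, labels, k = 5, reps = 2, seed = 3)
  se <- max(cv$accuracy_se, 100 / sqrt(4 * 120))
  expect_lt(abs(cv$accuracy_mean - 50), 3 * se)
})

test_that("single trees split where the classes separate", {
  m <- with_seed_test(21L, cbind(`800` = c(rnorm(30, 0), rnorm(30, 6)),
                                 `900` = rnorm(60)))
  labels <- rep(c("lo", "hi"), each = 30)
  tr <- tree_fit(m, labels)
  expect_equal(tr$split_wavenumbers, 800)
  expect_equal(sum(tr$tree$frame$var != "<leaf>"), 1)  # depth-1 suffices
  expect_equal(as.character(predict(tr, m)), labels)
})

test_that("XOR structure needs depth 2, matching an exhaustive split oracle", {
  # imbalanced quadrants so the greedy first split has positive Gini gain;
  # exact duplicates keep the split candidates at the two midpoints
  reps <- c(32, 20, 20, 8)
  quad <- cbind(x1 = rep(c(0, 0, 1, 1), reps), x2 = rep(c(0, 1, 0, 1), reps))
  m <- quad
  colnames(m) <- c("100", "200")
  y <- ifelse(xor(quad[, 1] == 1, quad[, 2] == 1), "A", "B")

  # exhaustive depth-1 oracle: best single-threshold accuracy on any feature
  best1 <- max(apply(m, 2, function(col) {
    cuts <- sort(unique(col))
    max(vapply(cuts, function(ct)
      max(mean((col <= ct) == (y == "A")), mean((col > ct) == (y == "A"))),
      numeric(1)))
  }))
  expect_lte(best1, 0.75)

  t1 <- tree_fit(m, y, max_depth = 1, cp = -1)
  acc1 <- mean(predict(t1, m) == y)
  expect_lte(acc1, best1 + 1e-9)
  t2 <- tree_fit(m, y, max_depth = 2, cp = -1)
  expect_equal(mean(predict(t2, m) == y), 1)
})

test_that("label-permuted data gives chance-level trees", {
  fx <- fx_two_class()
  perm <- with_seed_test(30L, sample(fx$pp$meta$class))
  cv <- cross_validate(spec_tree(), fx$pp$chem_matrix, perm, k = 5, reps = 2,
                       seed = 4)
  se <- max(cv$accuracy_se, 100 / sqrt(4 * length(perm)))
  expect_lt(abs(cv$accuracy_mean - 50), 3 * se)
})

test_that("boosted ensembles fit separable data and report wavenumbers", {
  m <- with_seed_test(31L, cbind(`780` = c(rnorm(30, 0), rnorm(30, 6)),
                                 `901` = rnorm(60)))
  labels <- rep(c("lo", "hi"), each = 30)
  en <- tree_ensemble_fit(m, labels, n_rounds = 5)
  expect_equal(as.character(predict(en, m)), labels)  # perfect by round 1
  expect_equal(names(en$wavenumber_frequency)[1], "780")

  # one round at equal depth predicts like the single tree
  en1 <- tree_ensemble_fit(m, labels, n_rounds = 1, max_depth = 2)
  t2 <- tree_fit(m, labels, max_depth = 2, cp = -1)
  expect_equal(predict(en1, m), as.character(predict(t2, m)))
})

test_that("ensemble-selected wavenumbers sit in class-different bands", {
  # artifact-free draws (no baseline/quartz/spikes) so the only class
  # signal is the cellular bands themselves: split channels must then lie
  # inside bands whose generator amplitudes differ between the profiles.
  # (In the full pipeline, baseline and normalization couple even quiet
  # channels to class, so attribution is posed on clean draws.)
  instr <- instrument_model(noise_sd = 3, cosmic_rate = 0,
                            baseline_coeffs = 0, quartz_amplitude = 0,
                            scale_sdlog = 0.1)
  profs <- default_profiles(c("SW480", "SW620"))
  rows <- with_seed_test(71L, lapply(rep(names(profs), each = 25), function(cl) {
    cell <- generate_cell_spectrum(profs[[cl]], instr)
    full <- stitch_windows(cell$w1, cell$w2)
    full$intensities / max(full$intensities[full$wavenumbers >= 1600 &
                                              full$wavenumbers <= 1690])
  }))
  m <- do.call(rbind, rows)
  colnames(m) <- as.character(stitch_windows(
    generate_cell_spectrum(profs[[1]], instr, seed = 1)$w1,
    generate_cell_spectrum(profs[[1]], instr, seed = 1)$w2)$wavenumbers)
  labels <- rep(names(profs), each = 25)
  en <- with_seed_test(72L, tree_ensemble_fit(m, labels, n_rounds = 40))
  top <- as.numeric(names(en$wavenumber_frequency)[1:3])
  cat <- band_catalogue()
  mult <- ramancell:::line_multipliers()
  diff_bands <- cat$center[mult[, "SW480"] != mult[, "SW620"]]
  ok <- vapply(top, function(wn)
    any(abs(wn - diff_bands) <= 2.5 * cat$sigma[match(diff_bands, cat$center)]),
    logical(1))
  expect_true(all(ok))
})

test_that("linear SVMs separate the default classes like PCA/LDA", {
  m <- with_seed_test(33L, cbind(c(rnorm(30, -3), rnorm(30, 3)),
                                 matrix(rnorm(60 * 5), 60)))
  colnames(m) <- as.character(1:6)
  labels <- rep(c("a", "b"), each = 30)
  sv <- svm_fit(m, labels)
  expect_equal(predict(sv, m), labels)
  expect_error(svm_fit(m, rep("a", 60)), ">= 2 classes")

  fx <- fx_two_class()
  cv_svm <- cross_validate(spec_svm(), fx$pp$chem_matrix, fx$pp$meta$class,
                           k = 5, reps = 2, seed = 9)
  cv_lda <- cross_validate(spec_pca_lda(25), fx$pp$chem_matrix,
                           fx$pp$meta$class, k = 5, reps = 2, seed = 9)
  expect_lt(abs(cv_svm$accuracy_mean - cv_lda$accuracy_mean), 2)
})

test_that("cross-validation is exact for deterministic classifiers", {
  m <- with_seed_test(41L, matrix(rnorm(60 * 4), 60))
  colnames(m) <- as.character(1:4)
  labels <- rep(c("a", "b"), 30)
  oracle <- structure(list(name = "oracle",
                           fit = function(m, l) list(keys = rownames(m)),
                           predict = function(fit, m) rep("?", nrow(m))),
                      class = "classifier_spec")
  # always-correct: predict by memorized row names
  rownames(m) <- ifelse(labels == "a", paste0("a", 1:60), paste0("b", 1:60))
  oracle$predict <- function(fit, m) substr(rownames(m), 1, 1)
  cv <- cross_validate(oracle, m, labels, k = 5, reps = 2, seed = 1)
  expect_equal(cv$accuracy_mean, 100)
  expect_equal(cv$accuracy_se, 0)
  expect_equal(sum(cv$confusion), 2 * 60)
  expect_equal(unname(rowSums(cv$confusion)), c(60, 60))

  # coin flip at n = 500: binomial oracle, within 3 se of 50%
  m2 <- matrix(0, 500, 2); colnames(m2) <- c("1", "2")
  l2 <- rep(c("a", "b"), 250)
  flip <- structure(list(name = "flip", fit = function(m, l) NULL,
                         predict = function(fit, m)
                           sample(c("a", "b"), nrow(m), replace = TRUE)),
                    class = "classifier_spec")
  cv2 <- with_seed_test(5L, cross_validate(flip, m2, l2, k = 10, reps = 1))
  expect_lt(abs(cv2$accuracy_mean - 50), 3 * 50 / sqrt(500))

  # seeded determinism
  cva <- cross_validate(spec_pca_lda(3), m, labels, k = 5, reps = 2, seed = 7)
  cvb <- cross_validate(spec_pca_lda(3), m, labels, k = 5, reps = 2, seed = 7)
  expect_identical(cva, cvb)
})

test_that("learning curves saturate below 100% by construction", {
  m <- with_seed_test(51L, cbind(c(rnorm(60, -5), rnorm(60, 5)),
                                 matrix(rnorm(120 * 3), 120)))
  colnames(m) <- as.character(1:4)
  labels <- rep(c("a", "b"), each = 60)
  lc <- learning_curve(spec_pca_lda(2), m, labels, c(5, 10, 20),
                       test_n = 30, n_resamples = 20, seed = 2)
  expect_true(all(lc$accuracy_mean > 99))       # trivially separable: flat
  expect_gt(lc$fit$saturation, 99)
  expect_lte(lc$fit$saturation, 100)

  fx <- fx_two_class()
  lc2 <- learning_curve(spec_pca_lda(10), fx$pp$chem_matrix,
                        fx$pp$meta$class, c(5, 15, 30), test_n = 20,
                        n_resamples = 15, seed = 3)
  # accuracy non-decreasing in training size within resampling error
  slack <- 3 * sqrt(lc2$accuracy_se^2 + c(lc2$accuracy_se[-1], 0)^2)
  expect_true(all(diff(lc2$accuracy_mean) > -slack[-length(slack)]))
})

test_that("nested CV does not underperform a leaky protocol on null data", {
  m <- with_seed_test(61L, matrix(rnorm(100 * 50), 100, 50))
  colnames(m) <- as.character(1:50)
  labels <- rep(c("a", "b"), 50)
  nested <- cross_validate(spec_pca_lda(10), m, labels, k = 5, reps = 2,
                           seed = 11)
  pc_all <- pca_fit(m, 10)  # leaky: components from the full data
  leaky_spec <- structure(list(name = "leaky",
                               fit = function(m, l) lda_fit(m, l),
                               predict = function(fit, m) predict(fit, m)),
                          class = "classifier_spec")
  leaky <- cross_validate(leaky_spec, pc_all$scores, labels, k = 5, reps = 2,
                          seed = 11)
  # on null data both must sit at chance; a leaky advantage is flagged
  se_n <- max(nested$accuracy_se, 100 / sqrt(400))
  se_l <- max(leaky$accuracy_se, 100 / sqrt(400))
  expect_lt(abs(nested$accuracy_mean - 50), 3 * se_n)
  expect_lt(abs(leaky$accuracy_mean - 50), 3 * se_l)
  expect_lt(leaky$accuracy_mean - nested$accuracy_mean, 3 * (se_n + se_l))
})
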