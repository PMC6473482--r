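# minimal plsr_result stand-in for exercising the selection test alone
fake_plsr <- function(scores) {
  structure(list(scores = as.matrix(scores),
                 n_components = ncol(as.matrix(scores))),
            class = "plsr_result")
}

test_that("PLS regression concentrates weight on the informative channel", {
  n <- 60
  m <- with_seed_test(5L, matrix(rnorm(n * 20), n, 20))
  colnames(m) <- as.character(700 + 1:20)
  y <- 2 * m[, 7] + 1
  fit <- plsr_fit(m, y, n_components = 3)
  w1 <- abs(fit$weights[, 1])
  expect_equal(which.max(w1), 7L, ignore_attr = TRUE)
  # noiseless linear response: with a full set of components the PLS
  # solution reaches the exact least-squares fit, R^2 = 1
  full <- plsr_fit(m, y, n_components = 20)
  expect_gt(max(full$r_squared), 1 - 1e-8)
  expect_lt(max(abs(predict(full, m) - y)), 1e-5)
  expect_error(plsr_fit(m, rep(2, n)), "constant response")
})

test_that("permuted stage codes carry no cross-validated signal", {
  fx <- fx_five_class()
  staged <- fx$pp$meta$class %in% c("SW480", "HT29", "SW620")
  m <- fx$pp$band_matrix[staged, ]
  y <- c(SW480 = 1, HT29 = 2, SW620 = 3)[fx$pp$meta$class[staged]]
  perm <- with_seed_test(9L, sample(y))
  # 5-fold cross-validated R^2 under permuted codes: null oracle around 0
  folds <- with_seed_test(10L, sample(rep_len(1:5, length(perm))))
  press <- tss <- 0
  for (f in 1:5) {
    tr <- folds != f
    fit <- plsr_fit(m[tr, ], perm[tr], n_components = 2)
    pred <- predict(fit, m[!tr, ])
    press <- press + sum((perm[!tr] - pred)^2)
    tss <- tss + sum((perm[!tr] - mean(perm[tr]))^2)
  }
  q2 <- 1 - press / tss
  expect_lt(abs(q2), 0.15)
})

test_that("stage-linear bands drive the first component's weights", {
  fx <- fx_five_class()
  staged <- fx$pp$meta$class %in% c("SW480", "HT29", "SW620")
  m <- fx$pp$band_matrix[staged, ]
  y <- c(SW480 = 1, HT29 = 2, SW620 = 3)[fx$pp$meta$class[staged]]
  fit <- plsr_fit(m, y, n_components = 5)
  wn <- as.numeric(colnames(m))
  w1 <- fit$weights[, 1]
  # lactate carbonyl rises with stage, CH2 symmetric stretch falls
  expect_gt(mean(w1[abs(wn - 1725) <= 5]), 0)
  expect_lt(mean(w1[abs(wn - 2850) <= 5]), 0)
  # sign convention: scores increase with the stage code
  expect_gt(stats::cor(fit$scores[, 1], y), 0)
})

test_that("largest component-1 weights overlap the stage-trend band set", {
  fx <- fx_five_class()
  staged <- fx$pp$meta$class %in% c("SW480", "HT29", "SW620")
  m <- fx$pp$band_matrix[staged, ]
  y <- c(SW480 = 1, HT29 = 2, SW620 = 3)[fx$pp$meta$class[staged]]
  fit <- plsr_fit(m, y, n_components = 3)
  wn <- as.numeric(colnames(m))
  # truth: channels within 1.5 sigma of bands whose calibrated multipliers
  # are strictly monotone across SW480 -> HT29 -> SW620
  cat <- band_catalogue()
  mult <- ramancell:::line_multipliers()[, c("SW480", "HT29", "SW620")]
  mono <- apply(mult, 1, function(v) all(diff(v) > 0) || all(diff(v) < 0)) &
    apply(mult, 1, function(v) max(v) / min(v) > 1.1)
  truth <- unique(unlist(lapply(which(mono), function(i)
    wn[abs(wn - cat$center[i]) <= 1.5 * cat$sigma[i]])))
  truth <- truth[truth %in% wn]
  top <- wn[order(-abs(fit$weights[, 1]))][seq_along(truth)]
  jaccard <- length(intersect(top, truth)) / length(union(top, truth))
  expect_gt(jaccard, 0.5)
})

test_that("component selection requires both adjacent increases", {
  # clear increasing means: selected (power >> 99% at these settings)
  sc <- with_seed_test(21L,
    cbind(c(rnorm(60, 0, 0.5), rnorm(60, 1, 0.5), rnorm(60, 2, 0.5))))
  labels <- rep(c("SW480", "HT29", "SW620"), each = 60)
  res <- select_stage_components(fake_plsr(sc), labels)
  expect_equal(res$selected, 1)
  expect_true(all(res$pairwise_p < 0.01))

  # non-monotone means (0, 2, 1): second adjacent pair fails
  sc2 <- with_seed_test(22L,
    cbind(c(rnorm(60, 0, 0.5), rnorm(60, 2, 0.5), rnorm(60, 1, 0.5))))
  res2 <- select_stage_components(fake_plsr(sc2), labels)
  expect_length(res2$selected, 0)

  short <- labels[c(1, 61, 121)]
  expect_error(select_stage_components(fake_plsr(sc[c(1, 61, 121), , drop = FALSE]),
                                       short), ">= 2 cells")
})

test_that("stage-null selection rate stays below alpha (type-I control)", {
  labels <- rep(c("SW480", "HT29", "SW620"), each = 30)
  n_rep <- 600
  hits <- with_seed_test(31L, vapply(seq_len(n_rep), function(i) {
    sc <- cbind(rnorm(90))
    length(select_stage_components(fake_plsr(sc), labels)$selected) > 0
  }, logical(1)))
  rate <- mean(hits)
  alpha <- 0.01
  # both one-tailed tests must pass, so the null rate is ~ alpha^2
  expect_lte(rate, alpha^2 + 3 * sqrt(alpha^2 * (1 - alpha^2) / n_rep))
  expect_lte(rate, alpha)
})

test_that("stage reports summarize selected components per class", {
  sc <- with_seed_test(41L,
    cbind(c(rnorm(50, 0, 0.4), rnorm(50, 1, 0.4), rnorm(50, 2, 0.4)),
          rnorm(150)))
  labels <- rep(c("SW480", "HT29", "SW620"), each = 50)
  res <- fake_plsr(sc)
  sel <- select_stage_components(res, labels)
  expect_equal(sel$selected, 1)
  rep1 <- stage_report(res, labels, sel)
  sm <- rep1$summaries[[1]]
  expect_equal(sm$class, c("SW480", "HT29", "SW620"))
  expect_true(all(diff(sm$median) > 0))
  expect_equal(sm$n, rep(50, 3))
  expect_equal(nrow(rep1$scores), 150)

  none <- select_stage_components(fake_plsr(cbind(rnorm(150))), labels)
  expect_warning(out <- stage_report(fake_plsr(cbind(rnorm(150))), labels, none),
                 "no component")
  expect_length(out$summaries, 0)
})

test_that("stage codings must increase with the stated stage order", {
  expect_error(stage_coding(c(SW480 = 2, HT29 = 1, SW620 = 3)),
               "strictly increasing")
  expect_equal(stage_coding()$mapping, c(SW480 = 1, HT29 = 2, SW620 = 3))
})

test_that("the default staged dataset passes selection at p < 0.001", {
  fx <- fx_five_class()
  staged <- fx$pp$meta$class %in% c("SW480", "HT29", "SW620")
  m <- fx$pp$band_matrix[staged, ]
  labels <- fx$pp$meta$class[staged]
  y <- stage_coding()$mapping[labels]
  fit <- plsr_fit(m, y, n_components = 10)
  sel <- select_stage_components(fit, labels)
  expect_gte(length(sel$selected), 1)
  expect_true(all(sel$pairwise_p[sel$selected, ] < 0.001))
})

test_that("SIMPLS agrees with an independent PLS implementation", {
  n <- 40
  m <- with_seed_test(3L, matrix(rnorm(n * 15), n))
  colnames(m) <- as.character(1:15)
  y <- with_seed_test(4L, m[, 3] - 0.5 * m[, 9] + rnorm(n, 0, 0.3))
  fit <- plsr_fit(m, y, n_components = 3)
  requireNamespace("mixOmics", quietly = TRUE)
  ref <- mixOmics::pls(m, y, ncomp = 3, mode = "regression", scale = FALSE)
  pred_ref <- predict(ref, m)$predict[, , 3]
  expect_lt(max(abs(predict(fit, m, 3) - pred_ref)), 1e-8)
  expect_equal(unname(abs(diag(stats::cor(fit$scores, ref$variates$X)))),
               rep(1, 3), tolerance = 1e-8)
})
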