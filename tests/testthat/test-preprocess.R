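test_that("despiking leaves clean spectra untouched and finds injected spikes", {
  x <- 300:800
  clean <- raw_spectrum(x, 100 * exp(-(x - 500)^2 / (2 * 20^2)))
  out <- despike(clean)
  expect_identical(out$spectrum$intensities, clean$intensities)
  expect_length(out$spikes, 0)

  flat <- raw_spectrum(x, rep(7, length(x)))
  expect_identical(despike(flat)$spectrum$intensities, flat$intensities)

  # three injected one-channel spikes, from the generator truth record
  instr <- instrument_model(cosmic_rate = 3)
  cell <- generate_cell_spectrum(cell_line_profile("SW480"), instr, seed = 21)
  truth <- sort(cell$truth$spike_channels[[1]])
  expect_length(truth, 3)
  out <- despike(cell$w1, 8)
  expect_identical(sort(out$spikes), truth)

  bad <- raw_spectrum(x, c(NA, seq_along(x)[-1]))
  expect_error(despike(bad), "non-finite")
})

test_that("silicon calibration recovers the axis shift within 0.1 cm^-1", {
  cell <- raw_spectrum(300:1800, rep(1, 1501))
  for (shift in c(3.0, 0, -2.2)) {
    sil <- generate_silicon_spectrum(shift)
    cal <- calibrate_axis(cell, sil)
    expect_lt(abs(cal$delta - (-shift)), 0.1)
  }
  # dense-grid oracle: parabolic interpolation is near-exact off-grid
  sil <- generate_silicon_spectrum(-2.2, instrument_model(grid_step = 0.05))
  expect_lt(abs(calibrate_axis(cell, sil)$delta - 2.2), 0.005)
  flat <- raw_spectrum(300:1800, rep(1, 1501))
  expect_error(calibrate_axis(cell, flat), "no detectable")
})

test_that("zero-offset translates the minimum to zero and keeps shape", {
  s <- raw_spectrum(1:3, c(5, 7, 6))
  expect_equal(zero_offset(s)$intensities, c(0, 2, 1))
  expect_equal(zero_offset(zero_offset(s))$intensities, c(0, 2, 1))
  s2 <- raw_spectrum(1:2, c(-3, -1))
  expect_equal(zero_offset(s2)$intensities, c(0, 2))
})

test_that("background subtraction recovers the mixing coefficient", {
  instr <- instrument_model(noise_sd = 0)
  bgs <- lapply(1:3, function(i) generate_background_spectrum(instr, seed = i))
  bg <- background_model(bgs, window = c(430, 530))
  # noiseless construction: cell bands + 1.3 x mean background
  wn <- bg$mean_w1$wavenumbers
  bands <- 500 * exp(-(wn - 1004)^2 / 50)
  s <- raw_spectrum(wn, bands + 1.3 * bg$mean_w1$intensities, window = 1L)
  res <- subtract_background(s, bg)
  expect_equal(res$a, 1.3, tolerance = 1e-6)
  quartz_win <- wn >= 430 & wn <= 530
  expect_lt(max(abs(res$spectrum$intensities[quartz_win])), 1e-6)

  # the mean background subtracts itself with a = 1
  res2 <- subtract_background(bg$mean_w1, bg)
  expect_equal(res2$a, 1, tolerance = 1e-9)
  expect_lt(max(abs(res2$spectrum$intensities)), 1e-6)

  # quartz-free case: a falls back to the baseline regression ratio
  instr0 <- instrument_model(noise_sd = 0, quartz_amplitude = 0)
  bg0 <- background_model(list(generate_background_spectrum(instr0)))
  s0 <- raw_spectrum(wn, 2 * instr0$bg_baseline_factor *
                       ramancell:::baseline_eval(instr0, wn), window = 1L)
  expect_equal(subtract_background(s0, bg0)$a, 2, tolerance = 1e-6)
})

test_that("Savitzky-Golay smoothing is exact on low-order polynomials", {
  x <- seq_len(200)
  y <- 2 - 0.3 * x + 0.01 * x^2 - 1e-5 * x^3
  s <- raw_spectrum(x, y)
  expect_lt(max(abs(smooth_sg(s, 11, 3)$intensities - y)), 1e-9)

  noise <- with_seed_test(4L, raw_spectrum(x, rnorm(200)))
  expect_lt(var(smooth_sg(noise)$intensities), var(noise$intensities))

  # direct-convolution oracle for the interior + peak attenuation < 1%
  wn <- 1500:1800
  g <- raw_spectrum(wn, exp(-(wn - 1655)^2 / (2 * 15^2)))
  sm <- smooth_sg(g, 11, 3)
  h <- signal::sgolay(p = 3, n = 11)[6, ]
  conv <- stats::filter(g$intensities, rev(h), sides = 2)
  interior <- 6:(length(wn) - 5)
  expect_lt(max(abs(sm$intensities[interior] - conv[interior])), 1e-10)
  expect_lt(abs(max(sm$intensities) - 1), 0.01)

  expect_error(smooth_sg(raw_spectrum(1:5, 1:5), 7, 3), "smaller")
  expect_error(smooth_sg(s, 10, 3), "odd")
})

test_that("asymmetric least-squares baseline tracks smooth backgrounds", {
  x <- seq(730, 3100)
  t <- (x - min(x)) / diff(range(x))
  base <- 400 - 300 * t + 150 * t^2 - 60 * t^3
  s <- raw_spectrum(x, base)
  res <- baseline_correct(s)
  expect_lt(max(abs(res$spectrum$intensities)) / diff(range(base)), 0.01)

  z <- baseline_correct(raw_spectrum(x, rep(0, length(x))))
  expect_lt(max(abs(z$baseline)), 1e-9)

  # bands on a known baseline: truth recovered on band-free channels
  bands <- 800 * exp(-(x - 1004)^2 / (2 * 25)) +
    1000 * exp(-(x - 1655)^2 / (2 * 256)) +
    1500 * exp(-(x - 2930)^2 / (2 * 256))
  res2 <- baseline_correct(raw_spectrum(x, base + bands))
  free <- bands < 1
  rms <- sqrt(mean((res2$baseline[free] - base[free])^2))
  expect_lt(rms / diff(range(base)), 0.05)
})

test_that("window stitching removes vertical offsets and rejects gaps", {
  w1 <- raw_spectrum(300:1800, rep(5, 1501), window = 1L, cell_id = "c1")
  w2 <- raw_spectrum(1800:3200, rep(5, 1401), window = 2L, cell_id = "c1")
  st <- stitch_windows(w1, w2)
  expect_true(all(st$intensities == 5))
  expect_equal(length(st$wavenumbers), 1501 + 1401 - 1)

  w2off <- raw_spectrum(1800:3200, rep(15, 1401), window = 2L, cell_id = "c1")
  st2 <- stitch_windows(w1, w2off)
  expect_true(all(abs(st2$intensities - 5) < 1e-9))  # offset removed

  w2far <- raw_spectrum(1850:3200, rep(5, 1351), window = 2L, cell_id = "c1")
  expect_error(stitch_windows(w1, w2far), "gap")
})

test_that("truncation and excision produce the closed-endpoint analysis grid", {
  s <- raw_spectrum(300:3200, rep(1, 2901))
  ps <- truncate_excise(s)
  expect_equal(length(ps$wavenumbers), (1750 - 730 + 1) + (3100 - 2800 + 1))
  expect_false(2000 %in% ps$wavenumbers)
  expect_true(all(c(730, 1750, 2800, 3100) %in% ps$wavenumbers))
  expect_false(any(ps$wavenumbers > 1750 & ps$wavenumbers < 2800))
})

test_that("Amide I normalization and SNV meet their contracts", {
  wn <- c(730:1750, 2800:3100)
  y <- 2 * exp(-(wn - 1655)^2 / (2 * 256)) + 0.5
  ps <- processed_spectrum(wn, 2 * y)
  norm <- normalize_amide1(ps)
  a1 <- norm$wavenumbers >= 1600 & norm$wavenumbers <= 1690
  expect_equal(max(norm$intensities[a1]), 1)
  expect_equal(norm$intensities, y / max(y[a1]))
  expect_equal(normalize_amide1(norm)$intensities, norm$intensities)
  expect_error(normalize_amide1(processed_spectrum(wn, rep(0, length(wn)))),
               "non-positive")

  sv <- snv(processed_spectrum(1:3, c(1, 2, 3)))
  expect_equal(sv$intensities, c(-1, 0, 1))
  rnd <- with_seed_test(9L, processed_spectrum(wn, rnorm(length(wn))))
  out <- snv(rnd)
  expect_lt(abs(mean(out$intensities)), 1e-12)
  expect_lt(abs(sd(out$intensities) - 1), 1e-12)
  aff <- rnd; aff$intensities <- 3.2 * rnd$intensities + 17
  expect_equal(snv(aff)$intensities, out$intensities, tolerance = 1e-9)
  expect_error(snv(processed_spectrum(1:3, rep(2, 3))), "zero variance")
})

test_that("the full chain produces both branches and skips corrupt cells", {
  fx <- fx_two_class()
  pp <- fx$pp
  expect_equal(max(pp$wavenumbers_chem), 3000)
  expect_equal(max(pp$wavenumbers_band), 3100)
  expect_false(any(pp$wavenumbers_band > 1750 & pp$wavenumbers_band < 2800))
  # normalization contracts over the whole dataset
  a1 <- pp$wavenumbers_band >= 1600 & pp$wavenumbers_band <= 1690
  expect_lt(max(abs(apply(pp$band_matrix[, a1], 1, max) - 1)), 1e-9)
  expect_lt(max(abs(rowMeans(pp$chem_matrix))), 1e-12)
  expect_lt(max(abs(apply(pp$chem_matrix, 1, sd) - 1)), 1e-12)

  # corrupt one cell: dataset proceeds with n - 1 rows and a logged skip
  set2 <- fx$set
  set2$cells[[5]]$w1$intensities[100] <- NA_real_
  pp2 <- preprocess_dataset(set2)
  expect_equal(nrow(pp2$band_matrix), nrow(pp$band_matrix) - 1)
  expect_length(pp2$skipped, 1)
  expect_match(pp2$skipped[[1]], "non-finite")
})

test_that("despiking is a no-op within the chain for spike-free data", {
  cfg <- generator_config(profiles = default_profiles("SW480"),
                          cells_per_class = c(SW480 = 3),
                          instrument = instrument_model(cosmic_rate = 0),
                          seed = 31)
  set <- generate_study_dataset(cfg)
  pp_on <- preprocess_dataset(set, preprocess_params(despike_enabled = TRUE))
  pp_off <- preprocess_dataset(set, preprocess_params(despike_enabled = FALSE))
  expect_equal(pp_on$band_matrix, pp_off$band_matrix, tolerance = 1e-12)
})

test_that("fitted adjustment factors track the generator truth", {
  fx <- fx_two_class()
  truth_a <- vapply(fx$set$truth, `[[`, numeric(1), "bg_scale")
  a <- fx$pp$adjustment_factors
  common <- intersect(names(truth_a), names(a))
  expect_gt(cor(a[common], truth_a[common]), 0.99)
  expect_lt(mean(abs(a[common] - truth_a[common]) / truth_a[common]), 0.05)
})

test_that("preprocessing a dataset twice is bit-identical", {
  cfg <- generator_config(profiles = default_profiles("SW620"),
                          cells_per_class = c(SW620 = 3), seed = 17)
  set <- generate_study_dataset(cfg)
  expect_identical(preprocess_dataset(set)$band_matrix,
                   preprocess_dataset(set)$band_matrix)
})
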