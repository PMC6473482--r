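# Small preprocessed datasets shared across test files; built once per run.

memoise_fixture <- function(builder) {
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- builder()
    cache
  }
}

# two-class SW480/SW620 set, 40 cells each
fx_two_class <- memoise_fixture(function() {
  cfg <- generator_config(profiles = default_profiles(c("SW480", "SW620")),
                          cells_per_class = c(SW480 = 40, SW620 = 40),
                          seed = 421L)
  set <- generate_study_dataset(cfg)
  list(set = set, pp = preprocess_dataset(set))
})

# all five lines at reduced counts
fx_five_class <- memoise_fixture(function() {
  cfg <- generator_config(cells_per_class = c(SW620 = 40, SW480 = 40,
                                              HL60 = 30, HT29 = 40,
                                              HCT116 = 30),
                          seed = 77L)
  set <- generate_study_dataset(cfg)
  list(set = set, pp = preprocess_dataset(set))
})

# noiseless single-class band-intensity matrix straight from the generator
# (no instrument artefacts), for correlation-structure checks
fx_band_matrix <- memoise_fixture(function() {
  instr <- instrument_model(noise_sd = 0, cosmic_rate = 0,
                            baseline_coeffs = 0, quartz_amplitude = 0,
                            intensity_scale = 1, scale_sdlog = 0.25)
  profile <- cell_line_profile("SW480")
  centers <- profile$bands$center
  m <- with_seed_test(303L, t(vapply(seq_len(300), function(i) {
    cell <- generate_cell_spectrum(profile, instr)
    full <- stitch_windows(cell$w1, cell$w2)
    amide <- max(full$intensities[full$wavenumbers >= 1600 &
                                    full$wavenumbers <= 1690])
    vapply(centers, function(cc)
      band_intensity(full, cc, 2) / amide, numeric(1))
  }, numeric(length(centers)))))
  colnames(m) <- as.character(centers)
  list(matrix = m, profile = profile)
})

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
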