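#' Pipeline run configuration
#'
#' A single configuration object driving the full workflow:
#' generate (or read) -> preprocess -> band analysis / classification /
#' stage-trend regression.
#'
#' @param generator A [generator_config()], or `NULL` when `input_dir` is
#'   given.
#' @param input_dir Directory of text spectra (see [read_spectrum_set()]);
#'   exactly one of `generator` / `input_dir` must be non-`NULL`.
#' @param preprocess A [preprocess_params()] list.
#' @param analyses Character subset of `c("bands", "classify", "stagetrend")`.
#' @param cv_folds,cv_reps Cross-validation protocol.
#' @param n_pc Principal components for the PCA+LDA classifier.
#' @param two_class Classes of the two-class comparison.
#' @param coding [stage_coding()] for the stage-trend analysis.
#' @param alpha Stage-trend selection level.
#' @param seed Seed for the cross-validation fold randomization.
#' @param output_dir Optional directory for the JSON report and CSV exports.
#' @return An object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(), input_dir = NULL,
                       preprocess = preprocess_params(),
                       analyses = c("bands", "classify", "stagetrend"),
                       cv_folds = 10, cv_reps = 5, n_pc = 25,
                       two_class = c("SW480", "SW620"),
                       coding = stage_coding(), alpha = 0.01,
                       seed = 1L, output_dir = NULL) {
  if (is.null(generator) && is.null(input_dir))
    stop("either a generator config or an input directory is required")
  if (!is.null(generator) && !is.null(input_dir))
    stop("supply a generator config or an input directory, not both")
  structure(list(generator = generator, input_dir = input_dir,
                 preprocess = preprocess, analyses = analyses,
                 cv_folds = cv_folds, cv_reps = cv_reps, n_pc = n_pc,
                 two_class = two_class, coding = coding, alpha = alpha,
                 seed = seed, output_dir = output_dir),
            class = "run_config")
}

#' Run the full pipeline and build a reproducible run report
#'
#' Executes the requested stages in order and returns (and optionally
#' writes) a report: dataset summary, preprocessing provenance, band
#' tables, correlation pairs, cross-validated accuracies with standard
#' errors, and the stage-trend component selection.
#'
#' @param cfg A [run_config()].
#' @return A `run_report` list; when `cfg$output_dir` is set, also writes
#'   `report.json`, the feature matrices and CSV exports there.
#' @export
run_pipeline <- function(cfg = run_config()) {
  set <- if (!is.null(cfg$input_dir)) read_spectrum_set(cfg$input_dir)
         else generate_study_dataset(cfg$generator)
  pp <- preprocess_dataset(set, cfg$preprocess)
  report <- list(
    package_version = as.character(utils::packageVersion("ramancell")),
    seed = cfg$seed,
    dataset = list(n_cells = nrow(set$meta),
                   per_class = as.list(table(set$meta$class)),
                   n_experiments = length(set$experiments)),
    preprocessing = list(params = pp$params, n_processed = nrow(pp$band_matrix),
                         n_skipped = length(pp$skipped),
                         skipped = as.list(pp$skipped)))

  if ("bands" %in% cfg$analyses) {
    classes <- sort(unique(pp$meta$class))
    means <- lapply(stats::setNames(classes, classes),
                    function(cl) class_mean_spectrum(pp, cl))
    a3 <- fit_region_spec("amide3")
    fit3 <- fit_region(means, a3$region, a3$init_peaks, shared = TRUE)
    corr <- correlation_analysis(pp$band_matrix,
                                 at = band_catalogue()$center)
    report$bands <- list(
      amide3_table = fit3$peaks,
      correlation_pairs = utils::head(corr$reported_pairs, 200),
      n_correlated_pairs = nrow(corr$reported_pairs))
  }

  if ("classify" %in% cfg$analyses) {
    specs <- list(pca_lda = spec_pca_lda(cfg$n_pc), tree = spec_tree(),
                  ensemble = spec_tree_ensemble(), svm = spec_svm())
    two <- pp$meta$class %in% cfg$two_class
    cv2 <- lapply(specs, function(sp)
      cross_validate(sp, pp$chem_matrix[two, , drop = FALSE],
                     pp$meta$class[two], k = cfg$cv_folds, reps = cfg$cv_reps,
                     seed = cfg$seed))
    report$two_class <- lapply(cv2, function(r)
      list(accuracy = r$accuracy_mean, se = r$accuracy_se,
           confusion = r$confusion))
    if (length(unique(pp$meta$class)) > 2) {
      cv5 <- cross_validate(spec_pca_lda(cfg$n_pc), pp$chem_matrix,
                            pp$meta$class, k = cfg$cv_folds,
                            reps = cfg$cv_reps, seed = cfg$seed)
      report$multiclass <- list(accuracy = cv5$accuracy_mean,
                                se = cv5$accuracy_se,
                                confusion = cv5$confusion,
                                n_pairwise_lds = choose(length(unique(pp$meta$class)), 2))
    }
  }

  if ("stagetrend" %in% cfg$analyses) {
    staged <- pp$meta$class %in% names(cfg$coding$mapping)
    if (sum(staged) >= 6) {
      y <- cfg$coding$mapping[pp$meta$class[staged]]
      # Amide-I-normalized branch: SNV would cancel the stage-wise CH2 contrast
      pls <- plsr_fit(pp$band_matrix[staged, , drop = FALSE], y)
      sel <- select_stage_components(pls, pp$meta$class[staged],
                                     cfg$coding, cfg$alpha)
      rep_st <- suppressWarnings(
        stage_report(pls, pp$meta$class[staged], sel, cfg$coding))
      report$stagetrend <- list(selected = sel$selected,
                                pairwise_p = sel$pairwise_p,
                                summaries = rep_st$summaries)
    }
  }

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report,
                         file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    write_feature_matrix(pp, file.path(cfg$output_dir, "chem_matrix.csv"),
                         "chem")
  }
  structure(c(report, list(preprocessed = pp)), class = "run_report")
}

#' Run the property-test battery on a configuration
#'
#' Executes the pipeline's internal contracts on a (small) dataset drawn
#' from the configuration: the SNV and Amide-I normalization contracts, the
#' excision contract, adjustment-factor recovery against the generator
#' truth, and a label-permutation null for the PCA+LDA classifier.
#'
#' @param cfg A [run_config()] (its generator is used; for speed pass a
#'   reduced `cells_per_class`).
#' @param leaky_cv Run the permutation null with whole-data PCA computed
#'   before the folds (a deliberately leaky protocol, for demonstrating
#'   that the no-leakage check flags it).
#' @return Data.frame with columns `check`, `pass`, `value`.
#' @export
validate_suite <- function(cfg = run_config(), leaky_cv = FALSE) {
  set <- if (!is.null(cfg$input_dir)) read_spectrum_set(cfg$input_dir)
         else generate_study_dataset(cfg$generator)
  pp <- preprocess_dataset(set, cfg$preprocess)
  out <- list()
  add <- function(check, pass, value)
    out[[length(out) + 1]] <<- data.frame(check = check, pass = pass,
                                          value = value)
  rows_mean <- rowMeans(pp$chem_matrix)
  rows_sd <- apply(pp$chem_matrix, 1, stats::sd)
  add("snv_rows_mean0_sd1",
      max(abs(rows_mean)) < 1e-9 && max(abs(rows_sd - 1)) < 1e-9,
      max(abs(rows_sd - 1)))
  a1 <- pp$wavenumbers_band >= 1600 & pp$wavenumbers_band <= 1690
  amide_max <- apply(pp$band_matrix[, a1, drop = FALSE], 1, max)
  add("amide1_max_unity", max(abs(amide_max - 1)) < 1e-9,
      max(abs(amide_max - 1)))
  add("excision_no_channel_in_silent_region",
      !any(pp$wavenumbers_band > 1750 & pp$wavenumbers_band < 2800), 0)
  if (!is.null(set$truth) && length(set$truth)) {
    truth_a <- vapply(set$truth, `[[`, numeric(1), "bg_scale")
    common <- intersect(names(truth_a), names(pp$adjustment_factors))
    mae <- mean(abs(pp$adjustment_factors[common] - truth_a[common]) /
                  truth_a[common])
    add("adjustment_factor_recovery_mae_lt_5pct", mae < 0.05, mae)
    add("adjustment_factor_recovery_cor_gt_0.99",
        stats::cor(pp$adjustment_factors[common], truth_a[common]) > 0.99,
        stats::cor(pp$adjustment_factors[common], truth_a[common]))
  }
  # permutation null: chance-level accuracy for PCA+LDA on shuffled labels
  perm <- with_seed(cfg$seed, sample(pp$meta$class))
  k <- length(unique(perm))
  if (leaky_cv) {
    pca_all <- pca_fit(pp$chem_matrix,
                       min(cfg$n_pc, nrow(pp$chem_matrix) - 1))
    sp <- structure(list(name = "leaky pca+lda",
                         fit = function(m, labels) lda_fit(m, labels),
                         predict = function(model, m) predict(model, m)),
                    class = "classifier_spec")
    cv <- cross_validate(sp, pca_all$scores, perm, k = min(cfg$cv_folds, 5),
                         reps = 2, seed = cfg$seed)
  } else {
    cv <- cross_validate(spec_pca_lda(cfg$n_pc), pp$chem_matrix, perm,
                         k = min(cfg$cv_folds, 5), reps = 2, seed = cfg$seed)
  }
  chance <- 100 / k
  z <- abs(cv$accuracy_mean - chance) /
    max(cv$accuracy_se, .Machine$double.eps)
  add("permutation_null_within_3se_of_chance", z <= 3, cv$accuracy_mean)
  do.call(rbind, out)
}
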