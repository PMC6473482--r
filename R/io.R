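#' Write one spectrum as a two-column text file
#'
#' WiRE-style export dialect: "#"-prefixed header lines, then tab-separated
#' wavenumber (cm^-1) and intensity columns.
#'
#' @param s A [raw_spectrum()].
#' @param path Output file path.
#' @param descending Write the axis in descending wavenumber order.
#' @export
write_spectrum_file <- function(s, path, descending = FALSE) {
  wn <- s$wavenumbers; y <- s$intensities
  if (descending) { wn <- rev(wn); y <- rev(y) }
  hdr <- c(sprintf("# cell_id: %s", s$cell_id),
           sprintf("# experiment_id: %s", s$experiment_id),
           sprintf("# class: %s", s$class_label),
           sprintf("# window: %s", s$window),
           "# wavenumber_cm-1\tintensity")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  writeLines(sprintf("%.4f\t%.6f", wn, y), con)
  invisible(path)
}

#' Read a two-column text spectrum
#'
#' Tolerates "#" comment lines and tab or space delimiters; a descending
#' axis is flipped to ascending.
#'
#' @param path File path.
#' @param window,cell_id,experiment_id,class_label Metadata overrides; when
#'   `NA`, values are taken from `# key: value` header lines if present.
#' @return A [raw_spectrum()].
#' @export
read_spectrum_file <- function(path, window = NA_integer_,
                               cell_id = NA_character_,
                               experiment_id = NA_character_,
                               class_label = NA_character_) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  get_hdr <- function(key) {
    m <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
    if (length(m) == 0) return(NA_character_)
    trimws(sub(sprintf("^#\\s*%s:\\s*", key), "", m[1]))
  }
  if (is.na(cell_id)) cell_id <- get_hdr("cell_id")
  if (is.na(experiment_id)) experiment_id <- get_hdr("experiment_id")
  if (is.na(class_label)) class_label <- get_hdr("class")
  if (is.na(window)) {
    w <- get_hdr("window")
    window <- if (is.na(w)) NA_integer_ else suppressWarnings(as.integer(w))
  }
  dat <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(dat), "[\t ]+")
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) stop("malformed data line(s) in ", path)
  wn <- as.numeric(vapply(parts, `[`, "", 1L))
  y <- as.numeric(vapply(parts, `[`, "", 2L))
  if (anyNA(wn) || anyNA(y)) stop("non-numeric data in ", path)
  raw_spectrum(wn, y, window = window, cell_id = cell_id,
               experiment_id = experiment_id, class_label = class_label)
}

#' Export a synthetic dataset as a directory of text spectra
#'
#' One sub-directory per experiment containing `cell_<id>_w<k>.txt` files,
#' `background_<i>_w<k>.txt` files and `silicon.txt`, plus a JSON truth
#' sidecar (`truth.json`) at the top level with the generator latents.
#'
#' @param set A [generate_study_dataset()] result.
#' @param dir Output directory (created if needed).
#' @param descending Write axes in descending order.
#' @return `dir`, invisibly.
#' @export
write_spectrum_set <- function(set, dir, descending = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (exp_id in names(set$experiments)) {
    ed <- file.path(dir, exp_id)
    dir.create(ed, showWarnings = FALSE)
    ex <- set$experiments[[exp_id]]
    write_spectrum_file(ex$silicon, file.path(ed, "silicon.txt"), descending)
    for (i in seq_along(ex$backgrounds)) for (w in 1:2)
      write_spectrum_file(ex$backgrounds[[i]][[w]],
                          file.path(ed, sprintf("background_%d_w%d.txt", i, w)),
                          descending)
  }
  for (cid in names(set$cells)) {
    exp_id <- set$meta$experiment[set$meta$cell_id == cid]
    for (w in 1:2)
      write_spectrum_file(set$cells[[cid]][[w]],
                          file.path(dir, exp_id,
                                    sprintf("cell_%s_w%d.txt", cid, w)),
                          descending)
  }
  truth <- list(
    shifts = lapply(set$experiments, `[[`, "shift"),
    cells = lapply(set$truth, function(t)
      list(amplitudes = t$amplitudes, scale = t$scale,
           baseline_factor = t$baseline_factor, bg_scale = t$bg_scale,
           spike_channels = t$spike_channels, shift = t$shift)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a directory-per-experiment dataset written by [write_spectrum_set()]
#'
#' @param dir Dataset directory.
#' @return A `spectrum_set` (without generator config; truth loaded from the
#'   JSON sidecar when present).
#' @export
read_spectrum_set <- function(dir) {
  exp_dirs <- list.dirs(dir, recursive = FALSE)
  if (length(exp_dirs) == 0) stop("no experiment sub-directories in ", dir)
  cells <- list(); experiments <- list(); meta <- list()
  for (ed in exp_dirs) {
    exp_id <- basename(ed)
    silicon <- read_spectrum_file(file.path(ed, "silicon.txt"))
    bg_files <- sort(list.files(ed, "^background_\\d+_w1\\.txt$"))
    backgrounds <- lapply(bg_files, function(f)
      list(w1 = read_spectrum_file(file.path(ed, f)),
           w2 = read_spectrum_file(file.path(ed, sub("_w1", "_w2", f)))))
    experiments[[exp_id]] <- list(silicon = silicon, backgrounds = backgrounds)
    cell_files <- list.files(ed, "^cell_.*_w1\\.txt$")
    for (f in cell_files) {
      w1 <- read_spectrum_file(file.path(ed, f))
      w2 <- read_spectrum_file(file.path(ed, sub("_w1", "_w2", f)))
      cid <- w1$cell_id
      cells[[cid]] <- list(w1 = w1, w2 = w2)
      meta[[cid]] <- data.frame(cell_id = cid, class = w1$class_label,
                                experiment = exp_id, stringsAsFactors = FALSE)
    }
  }
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  structure(list(cells = cells,
                 meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
                 experiments = experiments, truth = truth, config = NULL),
            class = "spectrum_set")
}
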