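#!/usr/bin/env Rscript
# Generate the default synthetic single-cell Raman datasets.
#
# Two datasets are built with the bundled calibrated cell-line profiles:
#   - the two-class SW480/SW620 metastasis model (163 + 167 cells), and
#   - the five-line panel (SW620/SW480/HL60/HT29/HCT116, 680 cells total),
# each split into experiments of <= 85 cells with five cell-free background
# spectra and one silicon calibration spectrum per experiment.
# Intermediates go to scratch/ (not part of the deliverable); a small text
# export of one experiment goes to results/ as a format illustration.

library(ramancell)

dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

seed <- 1L

message("two-class SW480/SW620 dataset ...")
cfg2 <- generator_config(profiles = default_profiles(c("SW480", "SW620")),
                         cells_per_class = c(SW480 = 163, SW620 = 167),
                         seed = seed)
set2 <- generate_study_dataset(cfg2)
print(set2)
saveRDS(set2, "scratch/dataset_two_class.rds")

message("five-line panel dataset ...")
cfg5 <- generator_config(seed = seed + 1L)
set5 <- generate_study_dataset(cfg5)
print(set5)
stopifnot(nrow(set5$meta) == 680)
saveRDS(set5, "scratch/dataset_five_class.rds")

# text-format illustration: first experiment of the two-class dataset
sub <- set2
keep <- sub$meta$experiment == sub$meta$experiment[1]
sub$meta <- sub$meta[keep, ]
sub$cells <- sub$cells[sub$meta$cell_id[1:3]]
sub$meta <- sub$meta[1:3, ]
sub$experiments <- sub$experiments[unique(sub$meta$experiment)]
sub$truth <- sub$truth[sub$meta$cell_id]
write_spectrum_set(sub, "results/example_export")
message("wrote results/example_export/ (3 cells, backgrounds, silicon, truth.json)")

counts <- as.data.frame(table(set5$meta$class))
names(counts) <- c("class", "n_cells")
write.csv(counts, "results/dataset_counts.csv", row.names = FALSE)
message("per-class counts written to results/dataset_counts.csv")
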