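#!/usr/bin/env Rscript
# PLSR of the colorectal adenocarcinoma lines against ordinal Duke stage:
# SW480 (B, primary) = 1, HT29 (C, primary) = 2, SW620 (C, metastasis) = 3.
# Components are kept only when one-tailed t-tests show the mean score
# increasing across both adjacent stage pairs at p < 0.01; per-class score
# summaries and spectral weights of the selected components are exported.

library(ramancell)

pp <- readRDS("scratch/pp_five_class.rds")
coding <- stage_coding()
staged <- pp$meta$class %in% names(coding$mapping)
m <- pp$band_matrix[staged, ]          # Amide-I-normalized branch
labels <- pp$meta$class[staged]
y <- coding$mapping[labels]

fit <- plsr_fit(m, y, n_components = 10)
sel <- select_stage_components(fit, labels, coding, alpha = 0.01)
message("selected components: ", paste(sel$selected, collapse = ", "))
message("adjacent-pair one-tailed p-values:")
print(signif(sel$pairwise_p[sel$selected, , drop = FALSE], 3))

rep <- stage_report(fit, labels, sel, coding)
for (i in seq_along(rep$summaries)) print(rep$summaries[[i]], digits = 3)

write.csv(do.call(rbind, rep$summaries), "results/plsr_score_summaries.csv",
          row.names = FALSE)
write.csv(rep$scores, "results/plsr_scores.csv", row.names = FALSE)
write.csv(cbind(wavenumber = as.numeric(rownames(rep$weights)),
                as.data.frame(rep$weights)),
          "results/plsr_component_weights.csv", row.names = FALSE)

# headline stage-trend weights of component 1
wn <- as.numeric(rownames(fit$weights))
w1 <- fit$weights[, 1]
for (b in c(1725, 810, 2850, 2930))
  message(sprintf("component-1 weight near %d cm^-1: %+.2e", b,
                  mean(w1[abs(wn - b) <= 5])))
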