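#!/usr/bin/env Rscript
# Drug-response associations: planted sensitivity/resistance effects on
# target-gene gains, on-target flags from the dependency-AUC
# correlation, direction summaries, and a single-region compound screen.
# Requires 01-03.
suppressPackageStartupMessages(library(cnagain))

build <- toy_genome()
gb <- gene_bins(toy_genes(build), build)
segments <- read_segments("results/cohort.seg")
truth <- read.delim("results/truth_genome.tsv")
samples <- sort(unique(segments$sample))
status_called <- as.matrix(read.delim("results/status.tsv", row.names = 1,
                                      check.names = FALSE))
status_true <- truth_gene_status(truth, gb, samples)

targets <- colnames(status_true)[1:12]
ann <- data.frame(compound = sprintf("CPD%02d", seq_along(targets)),
                  target = targets,
                  delta_auc = c(-0.12, -0.12, 0.12, rep(0, 9)),
                  screen = "SIM1")
dr <- simulate_drug_response(status_true, ann, seed = 31)
dep <- simulate_dependency(status_true, effects = list(), seed = 32)

rec <- target_gain_response(dr$auc, status_called, ann)
ot <- on_target_compounds(dr$auc, dep$dep, ann)
summ <- direction_summary(rec, ot)
write.table(rec, "results/drug_assoc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(summ, "results/drug_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("significant at q < 0.1: %d sensitivity, %d resistance",
                summ$n_sensitivity, summ$n_resistance))

# region screen on the most frequently gained gene bin
gain_ind <- !is.na(status_called) &
  (status_called == "arm_gain" | status_called == "focal_gain")
top_bin <- colnames(gain_ind)[which.max(colMeans(gain_ind))]
message("most frequently gained region: ", top_bin)
gained <- setNames(gain_ind[, top_bin], rownames(status_called))
region <- region_drug_screen(gained, dr$auc)
write.table(region, "results/region_screen.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("top region-screen compound: ", region$compound[1],
        sprintf(" (p %.3g, %s)", region$p[1], region$direction[1]))
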