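#!/usr/bin/env Rscript
# Bin the simulated profiles at 25 Mb, call gain/loss states, arm-level
# gains and five-way per-gene status, and write the cohort frequency and
# z-score track. Requires 01_simulate_cohort.R.
suppressPackageStartupMessages(library(cnagain))

build <- toy_genome()
th <- call_thresholds()
segments <- read_segments("results/cohort.seg")

bins <- build_bins(build, 25e6)
mat <- bin_copy_matrix(segments, bins)
states <- call_states(mat, th)
arm_tab <- call_arm_gains(segments, build, th)

genes <- toy_genes(build)
gb <- gene_bins(genes, build)
gmat <- bin_copy_matrix(segments, gb)
status <- classify_gene_status(gmat$cn, gb, arm_tab, th)
track <- frequency_zscores(cna_frequencies(states))

for (obj in c("states", "status")) {
  m <- get(obj)
  write.table(data.frame(sample = rownames(m), m, check.names = FALSE),
              sprintf("results/%s.tsv", obj), sep = "\t", quote = FALSE,
              row.names = FALSE)
}
write.table(arm_tab, "results/arm_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(track, "results/frequency_track.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("bins: %d (%d per chromosome incl. centromere)", nrow(bins),
                nrow(bins) / nrow(build)))
message(sprintf("arm gains called: %d/%d arm-sample pairs",
                sum(arm_tab$gained, na.rm = TRUE), nrow(arm_tab)))
message("gene status counts:")
print(table(status))
message("top z-score bin (gain): ",
        track$bin_id[which.max(track$z_gain)])
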