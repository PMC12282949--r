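#!/usr/bin/env Rscript
# Simulate the default synthetic cohort: 200 samples on a 4x120-Mb toy
# genome with arm-level gains/losses, focal gains and rare high-level
# amplifications, plus the truth ledger of every planted event.
suppressPackageStartupMessages(library(cnagain))

dir.create("results", showWarnings = FALSE)
cfg <- sim_config(seed = 1, n_samples = 200)
sim <- simulate_genomes(cfg)

write_segments(sim$segments, "results/cohort.seg")
write.table(sim$truth, "results/truth_genome.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ev <- table(sim$truth$kind)
message("samples: ", length(unique(sim$segments$sample)),
        "; segments: ", nrow(sim$segments))
message("planted events: ", paste(names(ev), ev, sep = "=", collapse = ", "))
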