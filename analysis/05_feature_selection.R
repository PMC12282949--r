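#!/usr/bin/env Rscript
# Elastic-net biomarker selection: model a compound's AUC from 1-Mb bin
# copy-number indicators, mutations and cancer type/subtype; triplicate
# 5-fold CV, intersection of replicates, per-feature ANOVA.
# Requires 01-02.
suppressPackageStartupMessages(library(cnagain))

build <- toy_genome()
th <- call_thresholds()
segments <- read_segments("results/cohort.seg")

bins1mb <- build_bins(build, 1e6)
mat <- bin_copy_matrix(segments, bins1mb)
states <- call_states(mat, th)
smp <- rownames(states)
set.seed(51)
mut <- matrix(rbinom(length(smp) * 15, 1, 0.2), length(smp), 15,
              dimnames = list(smp, sprintf("MUT%02d", 1:15)))
md <- data.frame(sample = smp,
                 type = sample(c("lung", "breast", "colon"), length(smp),
                               TRUE),
                 subtype = sample(c("s1", "s2"), length(smp), TRUE))
fm <- build_feature_matrix(mut, states, amp = NULL, metadata = md)
message("feature matrix: ", nrow(fm$X), " lines x ", ncol(fm$X),
        " features")

# planted response: resistance with gain of one bin, sensitivity with one
# mutation
planted <- c(grep("^gain_", colnames(fm$X), value = TRUE)[40], "mut_MUT03")
y <- 0.18 * fm$X[, planted[1]] - 0.18 * fm$X[, planted[2]] +
  rnorm(nrow(fm$X), 0.5, 0.15)

stable <- run_elastic_net(fm$X, y, enet_config(), seed_base = 11,
                          kind = fm$kind)
auc <- matrix(y, nrow(fm$X), 1, dimnames = list(rownames(fm$X), "CPD01"))
if (nrow(stable)) {
  pairs <- data.frame(compound = "CPD01", feature = stable$feature)
  stable <- cbind(stable[1:2],
                  feature_anova_all(pairs, auc, fm$X, md)[c("anova_p",
                                                            "anova_q")])
}
write.table(stable, "results/enet_features.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("planted features: ", paste(planted, collapse = ", "))
message("stable selected features:")
print(stable)
# arm-level events make 1-Mb bins on one arm near-duplicate indicators,
# so the planted bin may be represented by a correlated same-arm bin
planted_arm <- sub("^gain_(chr[0-9]+:).*", "\\1", planted[1])
proxy <- any(startsWith(stable$feature, paste0("gain_", planted_arm)))
message("planted gain signal recovered directly or via a same-arm proxy: ",
        proxy)
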