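#!/usr/bin/env Rscript
# Differential-dependency analysis on the called gene statuses: three
# simulated dependency datasets with the same planted driver genes, the
# 2-of-3 candidate rule, ranking + gene-set enrichment, mutation
# co-occurrence and expression upregulation checks.
# Requires 01 and 02.
suppressPackageStartupMessages(library(cnagain))

build <- toy_genome()
genes <- toy_genes(build)
gb <- gene_bins(genes, build)
segments <- read_segments("results/cohort.seg")
truth <- read.delim("results/truth_genome.tsv")
samples <- sort(unique(segments$sample))

status_called <- as.matrix(read.delim("results/status.tsv", row.names = 1,
                                      check.names = FALSE))
status_true <- truth_gene_status(truth, gb, samples)

# planted drivers: a MYC-like ladder plus two flat gain-dependency genes
effects <- list(
  G_chr1q_2 = c(amplification = -0.64, arm_gain = -0.44, focal_gain = -0.28),
  G_chr2p_1 = c(arm_gain = -0.35, focal_gain = -0.35),
  G_chr3q_3 = c(arm_gain = -0.30, focal_gain = -0.30))
planted <- names(effects)

recs <- lapply(1:3, function(d) {
  dep <- simulate_dependency(status_true, effects, seed = 1000 * d + 7)
  differential_dependency(dep$dep, status_called)
})
names(recs) <- c("crispr_a", "crispr_b", "rnai")
for (nm in names(recs))
  write.table(recs[[nm]], sprintf("results/dep_assoc_%s.tsv", nm),
              sep = "\t", quote = FALSE, row.names = FALSE)

cand <- select_candidates(recs)
write.table(cand, "results/candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("candidates (q < 0.3, delta < -0.05, >= 2 of 3 datasets): ",
        paste(cand$gene, collapse = ", "))
message("planted drivers recovered: ",
        sum(planted %in% cand$gene), "/", length(planted))

# rank on the first dataset and test enrichment of the planted set
metric <- ranked_metric(recs$crispr_a)
gs <- gsea_preranked(metric, list(planted_drivers = planted),
                     n_perm = 1000, seed = 42)
write.table(gs, "results/gsea.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("planted-set enrichment: NES %.2f, p %.3g", gs$NES, gs$p))

# mutation / gain co-occurrence with one planted odds ratio
mut <- simulate_mutations(status_true, odds_ratios = c(G_chr2p_1 = 2.2),
                          seed = 77)
co <- mutation_gain_cooccurrence(mut$mutations, status_called)
write.table(co, "results/mutation_cooccurrence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
hit <- co[co$gene == "G_chr2p_1", ]
message(sprintf("planted co-occurrence: OR %.2f (q %.3g)", hit$odds_ratio,
                hit$q))

# expression upregulation in gained lines for the ladder gene
expr <- simulate_expression(status_true,
                            list(G_chr1q_2 = c(arm_gain = 0.8,
                                               focal_gain = 0.8)),
                            seed = 88)
up <- expression_by_gain_status(expr$expression, status_called)
write.table(up, "results/expression_upregulation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("expression calls: ",
        paste(names(table(up$call)), table(up$call), sep = "=",
              collapse = ", "))
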