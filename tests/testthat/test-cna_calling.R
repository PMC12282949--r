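th <- call_thresholds()

test_that("state calls use strict thresholds and propagate missingness", {
  cn <- matrix(c(0.25, 0.1, -0.1, NA, 0.05, -0.4), 2, 3,
               dimnames = list(c("S1", "S2"), c("b1", "b2", "b3")))
  st <- call_states(cn, th)
  expect_equal(st["S1", "b1"], "gain")
  expect_equal(st["S2", "b1"], "neutral")   # exactly t_gain -> lower category
  expect_equal(st["S1", "b2"], "neutral")   # exactly t_loss
  expect_true(is.na(st["S2", "b2"]))
  expect_equal(st["S2", "b3"], "loss")
})

test_that("raising the gain threshold never adds gain calls", {
  set.seed(21)
  cn <- matrix(rnorm(500, 0, 0.3), 25, 20,
               dimnames = list(paste0("S", 1:25), paste0("b", 1:20)))
  n_prev <- Inf
  for (tg in c(0.05, 0.1, 0.2, 0.4)) {
    n <- sum(call_states(cn, call_thresholds(t_gain = tg)) == "gain",
             na.rm = TRUE)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("arm gain needs >80% of the covered length above threshold", {
  build <- tiny_build()  # p arm [0, 28e6)
  seg <- function(frac, cn_hi = 0.3, cn_lo = 0) {
    cut <- 28e6 * frac
    data.frame(sample = "S1", chrom = "chrA",
               start = c(0, cut), end = c(cut, 28e6), cn = c(cn_hi, cn_lo))
  }
  tab85 <- call_arm_gains(seg(0.85), build, th)
  expect_true(tab85$gained[tab85$arm_id == "chrAp"])
  tab79 <- call_arm_gains(seg(0.79), build, th)
  expect_false(tab79$gained[tab79$arm_id == "chrAp"])
  # denominator is covered length: 50% coverage, all of it gained
  half <- data.frame(sample = "S1", chrom = "chrA", start = 0, end = 14e6,
                     cn = 0.3)
  tabh <- call_arm_gains(half, build, th)
  row <- tabh[tabh$arm_id == "chrAp", ]
  expect_true(row$gained)
  expect_equal(row$covered_bp, 14e6)
  # q arm has no data at all -> NA call
  expect_true(is.na(tabh$gained[tabh$arm_id == "chrAq"]))
})

test_that("arm calls match the per-base-unit oracle on random profiles", {
  set.seed(22)
  build <- toy_genome()
  arms <- arm_intervals(build)
  for (i in 1:40) {
    segs <- random_profile(build, "S1", gap_prob = 0.4)
    tab <- call_arm_gains(segs, build, th)
    for (a in seq_len(nrow(arms))) {
      o <- oracle_arm_gain(segs, arms$chrom[a], arms$start[a], arms$end[a],
                           th$t_gain, th$arm_fraction)
      got <- tab$gained[tab$arm_id == arms$arm_id[a]]
      expect_identical(got, o, label = paste("profile", i, arms$arm_id[a]))
    }
  }
})

test_that("amplification is strictly above the sample's best arm gain", {
  arm_tab <- data.frame(sample = rep(c("S1", "S2"), each = 2),
                        arm_id = rep(c("chrAp", "chrAq"), 2),
                        chrom = "chrA", arm = c("p", "q"),
                        arm_cn = c(0.45, 0.2, 0.1, 0.0),
                        covered_fraction_gained = c(1, 1, 0, 0),
                        covered_bp = 28e6,
                        gained = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sample_max_armgain(arm_tab),
               c(S1 = 0.45, S2 = NA_real_))
  gene_cn <- matrix(c(0.9, 0.45, 0.95, 0.45), 2, 2, byrow = TRUE,
                    dimnames = list(c("S1", "S2"), c("g1", "g2")))
  amp <- call_amplifications(gene_cn, arm_tab, th)
  expect_true(amp["S1", "g1"])      # 0.9 > 0.45
  expect_false(amp["S1", "g2"])     # equal is not amplified
  expect_true(amp["S2", "g1"])      # fallback: 0.95 > 0.9
  expect_false(amp["S2", "g2"])
  gene_cn[1, 1] <- NA
  expect_true(is.na(call_amplifications(gene_cn, arm_tab, th)["S1", "g1"]))
})

test_that("gene status follows the documented precedence", {
  arm_tab <- data.frame(sample = "S1", arm_id = c("chrAp", "chrAq"),
                        chrom = "chrA", arm = c("p", "q"),
                        arm_cn = c(0.3, 0), covered_fraction_gained = c(1, 0),
                        covered_bp = 28e6, gained = c(TRUE, FALSE))
  genes <- data.frame(chrom = "chrA", start = c(1e6, 2e6, 40e6, 41e6, 3e6),
                      end = c(1.5e6, 2.5e6, 40.5e6, 41.5e6, 3.5e6),
                      gene = c("onP1", "onP2", "onQ1", "onQ2", "onP3"))
  gb <- gene_bins(genes, tiny_build())
  gene_cn <- matrix(c(0.3, 0.0, 0.3, -0.3, 1.2), 1, 5,
                    dimnames = list("S1",
                                    c("onP1", "onP2", "onQ1", "onQ2", "onP3")))
  st <- classify_gene_status(gene_cn, gb, arm_tab, th)
  expect_equal(st["S1", "onP1"], "arm_gain")    # above t_gain on gained arm
  expect_equal(st["S1", "onP2"], "neutral")     # below t_gain despite arm gain
  expect_equal(st["S1", "onQ1"], "focal_gain")  # arm not gained
  expect_equal(st["S1", "onQ2"], "loss")
  expect_equal(st["S1", "onP3"], "amplification")  # 1.2 > max arm gain 0.3
})

test_that("every (sample, gene) gets exactly one status", {
  set.seed(23)
  cfg <- sim_config(seed = 23, n_samples = 40)
  sim <- simulate_genomes(cfg)
  genes <- toy_genes(cfg$genome)
  gb <- gene_bins(genes, cfg$genome)
  gmat <- bin_copy_matrix(sim$segments, gb)
  arm_tab <- call_arm_gains(sim$segments, cfg$genome, th)
  st <- classify_gene_status(gmat$cn, gb, arm_tab, th)
  lev <- c("loss", "neutral", "arm_gain", "focal_gain", "amplification")
  expect_true(all(st[!is.na(st)] %in% lev))
  counts <- apply(st, 2, function(col) sum(table(col)) + sum(is.na(col)))
  expect_true(all(counts == nrow(st)))
  # amplification strictly exceeds every gained-arm cn in the sample
  mx <- sample_max_armgain(arm_tab)
  idx <- which(st == "amplification", arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    smp <- rownames(st)[idx[k, 1]]
    cut <- if (is.na(mx[smp])) th$amp_fallback else mx[smp]
    expect_gt(gmat$cn[idx[k, 1], idx[k, 2]], cut)
  }
})

test_that("frequencies and z-scores behave at the edges", {
  st <- matrix("neutral", 10, 4,
               dimnames = list(paste0("S", 1:10), paste0("b", 1:4)))
  expect_warning(tr <- frequency_zscores(cna_frequencies(st)), "zero variance")
  expect_true(all(tr$z_gain == 0))

  st[, "b2"] <- "gain"
  # loss frequencies are still constant at 0, so the loss track warns
  tr <- suppressWarnings(frequency_zscores(cna_frequencies(st)))
  expect_equal(tr$f_gain[tr$bin_id == "b2"], 1)
  expect_equal(which.max(tr$z_gain), 2L)
  expect_true(all(tr$f_gain + tr$f_loss <= 1))
  expect_error(cna_frequencies(st[, 1, drop = FALSE]), "2 bins")
})

test_that("observed gain frequency tracks the planted rate", {
  set.seed(24)
  n <- 500
  f_true <- c(b_hot = 0.5, b1 = 0.1, b2 = 0.1, b3 = 0.1)
  cn <- sapply(f_true, function(f)
    ifelse(rbinom(n, 1, f) == 1, 0.3, 0))
  rownames(cn) <- paste0("S", seq_len(n))
  tr <- cna_frequencies(call_states(cn, th))
  for (b in names(f_true)) {
    se <- sqrt(f_true[[b]] * (1 - f_true[[b]]) / n)
    expect_lt(abs(tr$f_gain[tr$bin_id == b] - f_true[[b]]), 3 * se)
  }
})
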