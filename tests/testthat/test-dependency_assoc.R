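status_mat <- function(st, genes = "G1") {
  matrix(st, length(st), length(genes),
         dimnames = list(sprintf("L%03d", seq_along(st)), genes))
}
dep_mat <- function(x, genes = "G1") {
  matrix(x, length(x), length(genes),
         dimnames = list(sprintf("L%03d", seq_along(x)), genes))
}

test_that("differential dependency matches the closed-form Welch oracle", {
  st <- status_mat(c(rep("focal_gain", 3), rep("neutral", 3)))
  d <- dep_mat(c(-1.0, -0.8, -0.9, 0.0, 0.1, -0.1))
  rec <- differential_dependency(d, st)
  expect_equal(rec$delta, -0.9, tolerance = 1e-12)
  o <- oracle_welch(c(-1.0, -0.8, -0.9), c(0.0, 0.1, -0.1))
  expect_equal(rec$p, o$p, tolerance = 1e-10)
  expect_equal(rec$t_stat, o$t, tolerance = 1e-10)
})

test_that("Welch p agrees with the closed form on random small groups", {
  set.seed(31)
  for (i in 1:200) {
    na <- sample(3:12, 1); nb <- sample(3:12, 1)
    a <- rnorm(na, 0, runif(1, 0.2, 2))
    b <- rnorm(nb, runif(1, -1, 1), runif(1, 0.2, 2))
    st <- status_mat(c(rep("arm_gain", na), rep("neutral", nb)))
    rec <- differential_dependency(dep_mat(c(a, b)), st)
    o <- oracle_welch(a, b)
    expect_equal(rec$p, o$p, tolerance = 1e-10)
  }
})

test_that("identical groups give delta 0 and p 1; tiny groups give NA", {
  st <- status_mat(c(rep("arm_gain", 3), rep("neutral", 3)))
  rec <- differential_dependency(dep_mat(rep(0.5, 6)), st)
  expect_equal(rec$delta, 0)
  expect_equal(rec$p, 1)
  st2 <- status_mat(c("arm_gain", rep("neutral", 5)))
  rec2 <- differential_dependency(dep_mat(rnorm(6)), st2)
  expect_true(is.na(rec2$p))
  expect_equal(rec2$n_gain, 1L)
})

test_that("the contrast switch restricts the gain group to arm-level events", {
  set.seed(32)
  st <- status_mat(c(rep("arm_gain", 10), rep("focal_gain", 10),
                     rep("neutral", 20)))
  d <- dep_mat(c(rnorm(10, -1, 0.1), rnorm(10, 0, 0.1), rnorm(20, 0, 0.1)))
  both <- differential_dependency(d, st, contrast = "combined")
  arm <- differential_dependency(d, st, contrast = "arm_only")
  expect_equal(both$n_gain, 20L)
  expect_equal(arm$n_gain, 10L)
  expect_lt(arm$delta, both$delta)   # arm-only group is the shifted one
})

test_that("a planted shift is recovered with high power", {
  set.seed(33)
  st <- status_mat(c(rep("arm_gain", 150), rep("neutral", 150)))
  d <- dep_mat(rnorm(300, 0, 0.3) + ifelse(seq_len(300) <= 150, -0.4, 0))
  rec <- differential_dependency(d, st)
  expect_lt(abs(rec$delta - (-0.4)), 0.07)
  expect_lt(rec$p, 1e-10)
})

test_that("q-values are monotone, bounded, and BH-compatible", {
  expect_identical(estimate_qvalues(numeric(0)), numeric(0))
  expect_equal(estimate_qvalues(rep(1, 20)), rep(1, 20))
  set.seed(34)
  p <- c(rep(1e-4, 10), runif(990, 0.3, 1))
  q <- estimate_qvalues(p)
  # BH closed form is the upper bound: q <= 1e-4 * 1000 / 10 = 0.01
  expect_true(all(q[1:10] <= 0.01 + 1e-12))
  expect_true(all(q <= 1 & q > 0))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # Storey q never exceeds BH (pi0 <= 1)
  expect_true(all(q <= p.adjust(p, "BH") + 1e-12))
  # small collections fall back to plain BH
  p_small <- runif(20)
  expect_equal(estimate_qvalues(p_small), p.adjust(p_small, "BH"))
  expect_error(estimate_qvalues(c(0.5, 0)), "0, 1")
})

test_that("confounded genes are removed on a strict cutoff", {
  rec <- data.frame(gene = c("A", "B", "C", "D"), p = runif(4))
  imp <- data.frame(gene = c("A", "B", "C"), importance = c(0.06, 0.05, 0.01))
  expect_warning(out <- filter_confounded(rec, imp), "retained")
  expect_setequal(out$gene, c("B", "C", "D"))  # 0.05 exactly is retained
})

test_that("ranking metric is signed -log10 q with deterministic ties", {
  rec <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    delta = c(-0.5, 0.2, -0.3, 0.0),
                    q = c(0.01, 1, 0.01, 0.2))
  r <- rank_genes(rec)
  expect_equal(r$metric[r$gene == "g1"], -2)
  expect_equal(r$metric[r$gene == "g2"], 0)
  expect_equal(r$metric[r$gene == "g4"], 0)
  # g1 and g3 tie on q; larger |delta| ranks more extreme first
  expect_equal(r$gene[r$metric == -2], c("g1", "g3"))
  # q = 0 is clamped, not infinite
  rec0 <- data.frame(gene = "g", delta = -1, q = 0)
  expect_true(is.finite(rank_genes(rec0)$metric))
})

test_that("candidate selection applies the 2-of-3 rule on both cutoffs", {
  mk <- function(q, delta) data.frame(gene = paste0("g", seq_along(q)),
                                      q = q, delta = delta)
  d1 <- mk(c(0.1, 0.29, 0.29, 0.1), c(-0.2, -0.04, -0.2, -0.2))
  d2 <- mk(c(0.1, 0.29, 0.5, 0.1), c(-0.2, -0.04, -0.2, -0.2))
  d3 <- mk(c(0.9, 0.29, 0.5, 0.9), c(-0.2, -0.04, -0.2, 0.1))
  out <- select_candidates(list(a = d1, b = d2, c = d3))
  # g1: significant in a+b -> listed; g2 fails delta; g3 only in a; g4 in a+b
  expect_setequal(out$gene, c("g1", "g4"))
  expect_true(all(out$n_datasets_significant >= 2))
  # dataset order does not matter
  out2 <- select_candidates(list(c = d3, a = d1, b = d2))
  expect_setequal(out2$gene, out$gene)
  expect_error(select_candidates(list(d1)), "two datasets")
})

test_that("co-occurrence odds ratios match the closed form", {
  st <- status_mat(c(rep("focal_gain", 100), rep("neutral", 100)))
  mut <- dep_mat(c(rep(1, 40), rep(0, 60), rep(1, 23), rep(0, 77)))
  rec <- mutation_gain_cooccurrence(mut, st)
  expect_equal(rec$odds_ratio, (40 * 77) / (60 * 23), tolerance = 1e-12)
  expect_equal(rec$direction, "co-occurring")
  expect_equal(rec$p, fisher.test(matrix(c(40, 60, 23, 77), 2,
                                         byrow = TRUE))$p.value)
  # degenerate margin: everything mutated
  rec2 <- mutation_gain_cooccurrence(dep_mat(rep(1, 200)), st)
  expect_true(rec2$untestable)
})

test_that("a planted odds ratio is recovered and the null is calm", {
  set.seed(35)
  n <- 800
  st <- status_mat(ifelse(rbinom(n, 1, 0.3) == 1, "focal_gain", "neutral"))
  gained <- st[, 1] == "focal_gain"
  odds0 <- 0.15 / 0.85
  p1 <- odds0 * 2.2 / (1 + odds0 * 2.2)
  mut <- dep_mat(rbinom(n, 1, ifelse(gained, p1, 0.15)))
  rec <- mutation_gain_cooccurrence(mut, st)
  expect_gt(rec$odds_ratio, 1.5)
  expect_lt(rec$odds_ratio, 3.2)
})

test_that("expression upregulation calls are directional", {
  set.seed(36)
  st <- status_mat(c(rep("focal_gain", 100), rep("neutral", 100)))
  up <- dep_mat(rnorm(200, 5) + ifelse(seq_len(200) <= 100, 2, 0))
  rec <- expression_by_gain_status(up, st)
  expect_equal(rec$call, "upregulated")
  flat <- dep_mat(rnorm(200, 5))
  expect_equal(expression_by_gain_status(flat, st)$call, "not_upregulated")
  # downregulation must NOT be called upregulated (one-sided test)
  dn <- dep_mat(rnorm(200, 5) - ifelse(seq_len(200) <= 100, 2, 0))
  expect_equal(expression_by_gain_status(dn, st)$call, "not_upregulated")
  st1 <- status_mat(c("focal_gain", rep("neutral", 199)))
  expect_equal(expression_by_gain_status(up, st1)$call, "unevaluable")
})

test_that("stratified contrasts localize an effect to the mutant stratum", {
  set.seed(37)
  n <- 200
  st <- status_mat(rep(c("arm_gain", "neutral"), n / 2))
  mutated <- setNames(rep(c(TRUE, FALSE), each = n / 2), rownames(st))
  gain <- st[, 1] == "arm_gain"
  d <- rnorm(n, 0, 0.3)
  d[gain & mutated] <- d[gain & mutated] - 0.6   # effect only in mutants
  rec <- stratified_dependency(dep_mat(d), st, mutated)
  expect_lt(rec$p[rec$stratum == "mutant"], 1e-6)
  expect_gt(rec$p[rec$stratum == "wildtype"], 0.01)
  # a stratum that is essentially empty is skipped
  tiny <- setNames(c(TRUE, rep(FALSE, n - 1)), rownames(st))
  expect_message(rec2 <- stratified_dependency(dep_mat(d), st, tiny),
                 "skipped")
  expect_equal(unique(rec2$stratum), "wildtype")
})
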