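lines <- function(n) sprintf("L%03d", seq_len(n))

sim_screen <- function(n = 380, delta = -0.11, n_gain = 80, seed = 51) {
  set.seed(seed)
  st <- matrix(c(rep("focal_gain", n_gain), rep("neutral", n - n_gain)),
               n, 1, dimnames = list(lines(n), "TGT"))
  auc <- matrix(rnorm(n, 0.5, 0.15), n, 1,
                dimnames = list(lines(n), "drugA"))
  auc[1:n_gain, 1] <- auc[1:n_gain, 1] + delta
  list(st = st, auc = auc,
       ann = data.frame(compound = "drugA", target = "TGT"))
}

test_that("a planted AUC drop is detected as sensitivity", {
  s <- sim_screen()
  rec <- target_gain_response(s$auc, s$st, s$ann)
  expect_equal(rec$direction, "sensitivity")
  expect_lt(abs(rec$delta_auc - (-0.11)), 0.06)
  expect_lt(rec$q, 0.1)
})

test_that("direction is a pure function of the sign of delta_auc", {
  s <- sim_screen()
  rec <- target_gain_response(s$auc, s$st, s$ann)
  flipped <- target_gain_response(-s$auc, s$st, s$ann)
  expect_equal(rec$direction, "sensitivity")
  expect_equal(flipped$direction, "resistance")
  expect_equal(flipped$delta_auc, -rec$delta_auc, tolerance = 1e-12)
  # identical groups: no direction
  auc0 <- s$auc; auc0[] <- 0.5
  rec0 <- target_gain_response(auc0, s$st, s$ann)
  expect_true(is.na(rec0$direction))
  expect_equal(rec0$delta_auc, 0)
})

test_that("amplified lines belong to neither drug-contrast group", {
  set.seed(52)
  n <- 60
  st <- matrix(c(rep("focal_gain", 20), rep("amplification", 20),
                 rep("neutral", 20)), n, 1,
               dimnames = list(lines(n), "TGT"))
  auc <- matrix(rnorm(n, 0.5, 0.1), n, 1, dimnames = list(lines(n), "drugA"))
  rec <- target_gain_response(auc, st, data.frame(compound = "drugA",
                                                  target = "TGT"))
  expect_equal(rec$n_gain, 20L)
  expect_equal(rec$n_nogain, 20L)
})

test_that("on-target flag requires both correlation strength and certainty", {
  set.seed(53)
  n <- 500
  dep <- matrix(rnorm(n), n, 1, dimnames = list(lines(n), "TGT"))
  mk_auc <- function(r) {
    y <- r * dep[, 1] + sqrt(1 - r^2) * rnorm(n)
    matrix(y, n, 1, dimnames = list(lines(n), "drugA"))
  }
  ann <- data.frame(compound = "drugA", target = "TGT")
  strong <- on_target_compounds(mk_auc(0.5), dep, ann)
  expect_true(strong$on_target)
  weak <- on_target_compounds(mk_auc(0.1), dep, ann)
  expect_false(weak$on_target)
  # r above cutoff but n too small for p < 1e-10: conjunction fails
  set.seed(54)
  dep40 <- matrix(rnorm(40), 40, 1, dimnames = list(lines(40), "TGT"))
  y40 <- 0.35 * dep40[, 1] + sqrt(1 - 0.35^2) * rnorm(40)
  auc40 <- matrix(y40, 40, 1, dimnames = list(lines(40), "drugA"))
  r40 <- on_target_compounds(auc40, dep40, ann)
  expect_false(isTRUE(r40$on_target))
  # below the shared-line minimum: untestable
  tiny <- on_target_compounds(auc40[1:10, , drop = FALSE],
                              dep40[1:10, , drop = FALSE], ann)
  expect_true(tiny$untestable)
})

test_that("direction summaries count significant calls per screen", {
  rec <- data.frame(compound = paste0("c", 1:6), target = "t",
                    screen = c("A", "A", "A", "A", "B", "B"),
                    n_gain = 10, n_nogain = 10,
                    delta_auc = c(-1, -1, 1, -1, 1, 1),
                    t_stat = 0, p = c(0.001, 0.001, 0.001, 0.9, 0.001, 0.9),
                    direction = c("sensitivity", "sensitivity", "resistance",
                                  "sensitivity", "resistance", "resistance"),
                    q = c(0.01, 0.01, 0.01, 0.9, 0.01, 0.9))
  out <- direction_summary(rec)
  expect_equal(out$n_sensitivity[out$screen == "A"], 2L)
  expect_equal(out$n_resistance[out$screen == "A"], 1L)
  expect_equal(out$n_resistance[out$screen == "B"], 1L)
  empty <- direction_summary(rec[0, ])
  expect_equal(nrow(empty), 0L)
  ot <- data.frame(compound = paste0("c", 1:6), target = "t",
                   on_target = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE))
  out2 <- direction_summary(rec, ot)
  expect_equal(out2$n_sensitivity_on_target[out2$screen == "A"], 1L)
  expect_equal(out2$n_resistance_on_target[out2$screen == "A"], 1L)
})

test_that("a region screen ranks planted compounds on top", {
  set.seed(55)
  n <- 300; n_cmp <- 100
  gained <- setNames(rbinom(n, 1, 0.3) == 1, lines(n))
  auc <- matrix(rnorm(n * n_cmp, 0.5, 0.15), n, n_cmp,
                dimnames = list(lines(n), sprintf("c%03d", 1:n_cmp)))
  planted <- c("c001", "c002", "c003", "c004")
  for (cmp in planted) auc[gained, cmp] <- auc[gained, cmp] - 0.15
  r <- region_drug_screen(gained, auc)
  expect_setequal(r$compound[1:4], planted)
  expect_true(all(r$direction[1:4] == "sensitivity"))
  # permuted labels: smallest p consistent with 100-test multiplicity
  r0 <- region_drug_screen(setNames(sample(gained), names(gained)), auc)
  expect_gt(min(r0$p) * n_cmp, 0.001)
  # a single gained line is untestable
  one <- setNames(c(TRUE, rep(FALSE, n - 1)), lines(n))
  r1 <- region_drug_screen(one, auc[, 1, drop = FALSE])
  expect_true(r1$untestable)
})

test_that("the bin-by-compound grid carries signed significance", {
  set.seed(56)
  n <- 200
  states <- matrix(sample(c("gain", "neutral"), n * 2, TRUE),
                   n, 2, dimnames = list(lines(n), c("b1", "b2")))
  auc <- matrix(rnorm(n * 2, 0.5, 0.1), n, 2,
                dimnames = list(lines(n), c("c1", "c2")))
  auc[states[, "b1"] == "gain", "c1"] <-
    auc[states[, "b1"] == "gain", "c1"] - 0.2
  g <- region_compound_grid(states, auc)
  expect_equal(dim(g), c(2L, 2L))
  expect_lt(g["b1", "c1"], -5)        # strong sensitivity signal
  expect_lt(abs(g["b2", "c2"]), 3)    # null cell stays mild
})

test_that("expression correlates concentrate on the planted arm", {
  set.seed(57)
  n <- 400
  n_arm <- 40; n_off <- 360
  genes <- c(sprintf("armg%02d", 1:n_arm), sprintf("off%03d", 1:n_off))
  drive <- rnorm(n)
  expr <- matrix(rnorm(n * length(genes)), n, length(genes),
                 dimnames = list(lines(n), genes))
  for (g in 1:30) expr[, g] <- 0.8 * drive + 0.6 * rnorm(n)
  auc <- setNames(-0.8 * drive + 0.6 * rnorm(n), lines(n))
  loc <- data.frame(gene = genes,
                    chrom = c(rep("chr6", n_arm), rep("chr2", n_off)),
                    arm = "p")
  res <- expression_response_correlates(expr, auc, loc, "chr6p")
  expect_true(res$enrichment$p < 1e-10)
  expect_gt(res$enrichment$odds_ratio, 10)
  # the Fisher p matches the hypergeometric tail computed independently
  e <- res$enrichment
  ft <- fisher.test(matrix(c(e$n_sig_on_arm, e$n_sig_off_arm,
                             e$n_ns_on_arm, e$n_ns_off_arm), 2, byrow = TRUE))
  expect_equal(e$p, ft$p.value)
  # an arm with no genes present is untestable
  res2 <- expression_response_correlates(expr, auc, loc, "chr9q")
  expect_true(res2$enrichment$untestable)
})
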