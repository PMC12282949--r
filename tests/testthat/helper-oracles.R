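# Independent brute-force oracles and fixture generators. All oracles
# are coded from the definitions, not by calling the implementation.

# Exhaustive per-base-unit weighted mean: walk every `unit`-sized base
# position of the interval, look up the segment covering it, and average.
oracle_interval_cn <- function(segs, chrom, start, end, unit = 1e4) {
  pos <- seq(start, end - unit, by = unit)
  cn <- rep(NA_real_, length(pos))
  s <- segs[segs$chrom == chrom, , drop = FALSE]
  for (k in seq_len(nrow(s))) {
    inside <- pos >= s$start[k] & pos < s$end[k]
    cn[inside] <- s$cn[k]
  }
  covered <- !is.na(cn)
  list(cn = if (any(covered)) mean(cn[covered]) else NA_real_,
       covered_fraction = mean(covered))
}

# Per-base-unit arm-gain rule: gained iff gained units / covered units
# strictly exceed arm_fraction.
oracle_arm_gain <- function(segs, chrom, arm_start, arm_end, t_gain = 0.1,
                            arm_fraction = 0.8, unit = 1e4) {
  pos <- seq(arm_start, arm_end - unit, by = unit)
  cn <- rep(NA_real_, length(pos))
  s <- segs[segs$chrom == chrom, , drop = FALSE]
  for (k in seq_len(nrow(s))) {
    inside <- pos >= s$start[k] & pos < s$end[k]
    cn[inside] <- s$cn[k]
  }
  covered <- sum(!is.na(cn))
  if (covered == 0) return(NA)
  sum(!is.na(cn) & cn > t_gain) / covered > arm_fraction
}

# Closed-form Welch two-sample t-test.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Random segmented profile on the 10-kb lattice, with optional coverage
# gaps, used by the geometry and arm-rule oracle tests.
random_profile <- function(build, sample_id, unit = 1e4, max_segs = 8L,
                           gap_prob = 0.2) {
  rows <- list()
  for (i in seq_len(nrow(build))) {
    n_bp <- sample.int(max_segs, 1)
    bp <- sort(unique(c(0, build$length[i],
                        round(runif(n_bp, 0, build$length[i]) / unit) * unit)))
    st <- bp[-length(bp)]; en <- bp[-1L]
    keep <- (en - st) > 0 & runif(length(st)) > gap_prob
    if (!any(keep)) keep[which.max(en - st)] <- TRUE
    rows[[i]] <- data.frame(sample = sample_id, chrom = build$chrom[i],
                            start = st[keep], end = en[keep],
                            cn = rnorm(sum(keep), 0, 0.5),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

tiny_build <- function() {
  genome_build("chrA", length = 60e6, cen_start = 28e6, cen_end = 32e6)
}

# direct status vector for group-contrast simulations
ladder_status <- function(n_per_group) {
  rep(c("neutral", "focal_gain", "arm_gain", "amplification"),
      each = n_per_group)
}
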