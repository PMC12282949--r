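#' Copy-number call thresholds
#'
#' Thresholds operate on the ploidy-normalized log2 scale. All
#' comparisons are strict, so values exactly at a threshold fall in the
#' lower category. `arm_fraction` is the fraction of an arm's covered
#' length that must exceed `t_gain` for an arm-level gain; `amp_fallback`
#' is the amplification cutoff used for samples without any gained arm.
#'
#' @param t_gain gain threshold (> 0), default +0.1.
#' @param t_loss loss threshold (< 0), default -0.1.
#' @param arm_fraction arm-gain covered-length fraction, default 0.8.
#' @param amp_fallback amplification fallback threshold, default +0.9.
#' @return list of class `"call_thresholds"`.
#' @export
call_thresholds <- function(t_gain = 0.1, t_loss = -0.1,
                            arm_fraction = 0.8, amp_fallback = 0.9) {
  stopifnot(t_loss < 0, t_gain > 0, arm_fraction > 0, arm_fraction < 1)
  structure(list(t_gain = t_gain, t_loss = t_loss,
                 arm_fraction = arm_fraction, amp_fallback = amp_fallback),
            class = "call_thresholds")
}

#' Discrete gain/loss states from a bin copy-number matrix
#'
#' @param mat a `"bin_cn"` object from [bin_copy_matrix()], or a plain
#'   numeric matrix of copy numbers.
#' @param th thresholds from [call_thresholds()].
#' @return character matrix with entries `"gain"`, `"loss"`, `"neutral"`
#'   or `NA` where the copy number is missing.
#' @export
call_states <- function(mat, th = call_thresholds()) {
  cn <- if (inherits(mat, "bin_cn")) mat$cn else mat
  st <- matrix(NA_character_, nrow(cn), ncol(cn), dimnames = dimnames(cn))
  st[!is.na(cn)] <- "neutral"
  st[!is.na(cn) & cn > th$t_gain] <- "gain"
  st[!is.na(cn) & cn < th$t_loss] <- "loss"
  st
}

#' Arm-level gain calls
#'
#' An arm is gained when the length with copy number above `t_gain`,
#' divided by the total length for which copy-number data are available
#' on that arm, exceeds `arm_fraction` (default >80%). The denominator is
#' the covered length, not the full arm length. Also records the
#' weighted-mean copy number of each arm.
#'
#' @param segments long segment data.frame (`sample`, `chrom`, `start`,
#'   `end`, `cn`).
#' @param build a genome build.
#' @param th thresholds from [call_thresholds()].
#' @return data.frame with one row per (sample, arm): `sample`, `arm_id`,
#'   `chrom`, `arm`, `arm_cn`, `covered_fraction_gained`, `covered_bp`,
#'   `gained`. Arms with zero covered length get `NA` calls.
#' @export
call_arm_gains <- function(segments, build, th = call_thresholds()) {
  arms <- arm_intervals(build)
  samples <- sort(unique(segments$sample))
  seg_by <- split(segments, segments$sample)
  rows <- vector("list", length(samples) * nrow(arms))
  k <- 0L
  for (smp in samples) {
    segs <- seg_by[[smp]]
    for (a in seq_len(nrow(arms))) {
      s <- segs[segs$chrom == arms$chrom[a], , drop = FALSE]
      w <- pmax(0, pmin(s$end, arms$end[a]) - pmax(s$start, arms$start[a]))
      covered <- sum(w)
      k <- k + 1L
      if (covered == 0) {
        rows[[k]] <- data.frame(sample = smp, arm_id = arms$arm_id[a],
                                chrom = arms$chrom[a], arm = arms$arm[a],
                                arm_cn = NA_real_,
                                covered_fraction_gained = NA_real_,
                                covered_bp = 0, gained = NA,
                                stringsAsFactors = FALSE)
      } else {
        frac <- sum(w[s$cn > th$t_gain]) / covered
        rows[[k]] <- data.frame(sample = smp, arm_id = arms$arm_id[a],
                                chrom = arms$chrom[a], arm = arms$arm[a],
                                arm_cn = sum(w * s$cn) / covered,
                                covered_fraction_gained = frac,
                                covered_bp = covered,
                                gained = frac > th$arm_fraction,
                                stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Highest whole-arm-gain copy number per sample
#'
#' @param arm_table output of [call_arm_gains()].
#' @return named numeric vector over all samples; `NA` for samples with
#'   no gained arm.
#' @export
sample_max_armgain <- function(arm_table) {
  samples <- sort(unique(arm_table$sample))
  g <- arm_table[!is.na(arm_table$gained) & arm_table$gained, , drop = FALSE]
  mx <- tapply(g$arm_cn, g$sample, max)
  out <- stats::setNames(rep(NA_real_, length(samples)), samples)
  out[names(mx)] <- as.numeric(mx)
  out
}

#' Sample-relative amplification calls
#'
#' A gene is amplified when its copy number strictly exceeds the highest
#' copy number of a whole-arm gain in the same sample. For samples with
#' no gained arm, the fixed `amp_fallback` threshold applies instead.
#'
#' @param gene_cn numeric matrix samples x genes of gene copy numbers
#'   (from gene-centered binning).
#' @param arm_table output of [call_arm_gains()] for the same samples.
#' @param th thresholds from [call_thresholds()].
#' @return logical matrix, `NA` where the gene copy number is missing.
#' @export
call_amplifications <- function(gene_cn, arm_table, th = call_thresholds()) {
  mx <- sample_max_armgain(arm_table)
  cutoff <- ifelse(is.na(mx[rownames(gene_cn)]), th$amp_fallback,
                   mx[rownames(gene_cn)])
  sweep_res <- gene_cn > matrix(cutoff, nrow(gene_cn), ncol(gene_cn))
  sweep_res[is.na(gene_cn)] <- NA
  sweep_res
}

#' Five-way per-gene copy-number status
#'
#' Classifies every (sample, gene) as `amplification`, `arm_gain`,
#' `focal_gain`, `loss` or `neutral`, with precedence in that order:
#' amplification beats everything; a gene above `t_gain` whose arm is
#' gained is `arm_gain`; above `t_gain` on a non-gained arm is
#' `focal_gain`; below `t_loss` is `loss`; otherwise `neutral`. A gene
#' below `t_gain` on a gained arm does not inherit the arm call.
#'
#' @param gene_cn numeric matrix samples x genes.
#' @param genes gene bin table from [gene_bins()] (provides the arm of
#'   each gene; genes overlapping the centromere are never `arm_gain`).
#' @param arm_table output of [call_arm_gains()].
#' @param th thresholds from [call_thresholds()].
#' @param amp optional logical matrix from [call_amplifications()];
#'   computed from `arm_table` if missing.
#' @return character matrix samples x genes, `NA` where the copy number
#'   is missing.
#' @export
classify_gene_status <- function(gene_cn, genes, arm_table,
                                 th = call_thresholds(), amp = NULL) {
  stopifnot(all(colnames(gene_cn) %in% genes$bin_id))
  if (is.null(amp)) amp <- call_amplifications(gene_cn, arm_table, th)
  gene_arm <- stats::setNames(paste0(genes$chrom, genes$arm), genes$bin_id)
  # per sample: which arms are gained
  gained_key <- with(arm_table[!is.na(arm_table$gained) & arm_table$gained, ],
                     paste(sample, arm_id, sep = "\r"))
  samp <- rownames(gene_cn)
  arm_of_gene <- gene_arm[colnames(gene_cn)]
  on_gained <- matrix(outer(samp, arm_of_gene,
                            function(s, a) paste(s, a, sep = "\r")) %in% gained_key,
                      nrow(gene_cn), ncol(gene_cn), dimnames = dimnames(gene_cn))
  st <- matrix(NA_character_, nrow(gene_cn), ncol(gene_cn),
               dimnames = dimnames(gene_cn))
  has <- !is.na(gene_cn)
  st[has] <- "neutral"
  st[has & gene_cn < th$t_loss] <- "loss"
  st[has & gene_cn > th$t_gain] <- "focal_gain"
  st[has & gene_cn > th$t_gain & on_gained] <- "arm_gain"
  st[has & !is.na(amp) & amp] <- "amplification"
  st
}

#' Gain/loss frequencies per bin
#'
#' The frequency is the proportion of samples with a non-missing call
#' that are called gain (resp. loss) in that bin.
#'
#' @param states character state matrix from [call_states()].
#' @return data.frame with `bin_id`, `n`, `f_gain`, `f_loss`.
#' @export
cna_frequencies <- function(states) {
  if (ncol(states) < 2L) stop("need at least 2 bins")
  n <- colSums(!is.na(states))
  f_gain <- ifelse(n > 0, colSums(states == "gain", na.rm = TRUE) / n, NA_real_)
  f_loss <- ifelse(n > 0, colSums(states == "loss", na.rm = TRUE) / n, NA_real_)
  data.frame(bin_id = colnames(states), n = n, f_gain = f_gain,
             f_loss = f_loss, row.names = NULL, stringsAsFactors = FALSE)
}

#' Standardize frequencies to z-scores across bins
#'
#' Each bin's gain (loss) frequency is centred and scaled by the mean and
#' standard deviation of the frequencies over all bins in the cohort: a
#' cohort-internal standard score highlighting recurrently gained or lost
#' regions.
#'
#' @param track output of [cna_frequencies()].
#' @return the track with `z_gain` and `z_loss` columns added.
#' @export
frequency_zscores <- function(track) {
  degenerate <- character()
  z <- function(f, which) {
    s <- stats::sd(f, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      degenerate <<- c(degenerate, which)
      return(rep(0, length(f)))
    }
    (f - mean(f, na.rm = TRUE)) / s
  }
  track$z_gain <- z(track$f_gain, "gain")
  track$z_loss <- z(track$f_loss, "loss")
  if (length(degenerate))
    warning("zero variance across bins for ",
            paste(degenerate, collapse = " and "),
            " frequencies; z-scores set to 0")
  track
}
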