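#' Drug response by copy-number status of the target gene
#'
#' For every annotated (compound, target) pair, compares the AUC (higher
#' AUC = more resistant, GDSC/CTRP orientation) between cell lines with
#' low-amplitude gain of the target gene and lines without gain (neutral
#' or loss) using a two-sided unequal-variance t-test, with q-values
#' across all tested pairs. Direction is `sensitivity` when `delta_auc`
#' (gain - no gain) is negative and `resistance` when positive.
#'
#' @param auc numeric matrix cell lines x compounds.
#' @param status character status matrix cell lines x genes.
#' @param annotation data.frame with columns `compound`, `target` and
#'   optionally `screen`; compounds absent from `auc` or with targets
#'   absent from `status` are skipped.
#' @param min_n minimum group size, default 2.
#' @return data.frame per tested pair: `compound`, `target`, `screen`,
#'   `n_gain`, `n_nogain`, `delta_auc`, `t_stat`, `p`, `q`, `direction`.
#' @export
target_gain_response <- function(auc, status, annotation, min_n = 2L) {
  if (is.null(annotation$screen)) annotation$screen <- "screen1"
  ann <- annotation[annotation$compound %in% colnames(auc) &
                    annotation$target %in% colnames(status), , drop = FALSE]
  lines <- intersect(rownames(auc), rownames(status))
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    st <- status[lines, ann$target[i]]
    y <- auc[lines, ann$compound[i]]
    ok <- !is.na(st) & !is.na(y)
    a <- y[ok & st %in% c("arm_gain", "focal_gain")]
    b <- y[ok & st %in% c("neutral", "loss")]
    rec <- data.frame(compound = ann$compound[i], target = ann$target[i],
                      screen = ann$screen[i], n_gain = length(a),
                      n_nogain = length(b), delta_auc = NA_real_,
                      t_stat = NA_real_, p = NA_real_,
                      direction = NA_character_, stringsAsFactors = FALSE)
    if (length(a) >= min_n && length(b) >= min_n) {
      rec$delta_auc <- mean(a) - mean(b)
      if (stats::sd(a) > 0 || stats::sd(b) > 0) {
        tt <- stats::t.test(a, b)
        rec$t_stat <- unname(tt$statistic)
        rec$p <- tt$p.value
      } else {
        rec$t_stat <- 0
        rec$p <- 1
      }
      rec$direction <- if (rec$delta_auc < 0) "sensitivity"
                       else if (rec$delta_auc > 0) "resistance"
                       else NA_character_
    }
    rec
  })
  out <- do.call(rbind, rows)
  out$q <- estimate_qvalues(out$p)
  out
}

#' Flag on-target compounds
#'
#' A compound is on-target for its annotated gene when the Pearson
#' correlation between dependency on the target and the compound's AUC
#' exceeds `r_min` and the correlation p-value is below `p_max` (both
#' required): more dependent lines (more negative scores) are then more
#' sensitive (lower AUC), the signature of a classical on-target
#' inhibitor.
#'
#' @param auc numeric matrix cell lines x compounds.
#' @param dep numeric matrix cell lines x genes (dependency scores).
#' @param annotation data.frame with `compound`, `target`.
#' @param r_min correlation cutoff, default 0.3.
#' @param p_max correlation p-value cutoff, default 1e-10.
#' @param min_shared minimum shared cell lines, default 30; pairs below
#'   it are flagged untestable.
#' @return data.frame per pair: `compound`, `target`, `n_shared`, `r`,
#'   `p_corr`, `on_target`, `untestable`.
#' @export
on_target_compounds <- function(auc, dep, annotation, r_min = 0.3,
                                p_max = 1e-10, min_shared = 30L) {
  ann <- annotation[annotation$compound %in% colnames(auc) &
                    annotation$target %in% colnames(dep), , drop = FALSE]
  lines <- intersect(rownames(auc), rownames(dep))
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    x <- dep[lines, ann$target[i]]
    y <- auc[lines, ann$compound[i]]
    ok <- !is.na(x) & !is.na(y)
    rec <- data.frame(compound = ann$compound[i], target = ann$target[i],
                      n_shared = sum(ok), r = NA_real_, p_corr = NA_real_,
                      on_target = NA, untestable = TRUE,
                      stringsAsFactors = FALSE)
    if (sum(ok) >= min_shared && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      rec$r <- unname(ct$estimate)
      rec$p_corr <- ct$p.value
      rec$on_target <- rec$r > r_min && rec$p_corr < p_max
      rec$untestable <- FALSE
    }
    rec
  })
  do.call(rbind, rows)
}

#' Count significant sensitivity/resistance associations
#'
#' @param records output of [target_gain_response()].
#' @param on_target optional output of [on_target_compounds()]; when
#'   supplied, on-target subtotals are included.
#' @param q_sig significance cutoff, default 0.1.
#' @return data.frame per screen: `screen`, `n_tested`, `n_sensitivity`,
#'   `n_resistance`, and with flags `n_sensitivity_on_target`,
#'   `n_resistance_on_target`.
#' @export
direction_summary <- function(records, on_target = NULL, q_sig = 0.1) {
  if (nrow(records) == 0L)
    return(data.frame(screen = character(), n_tested = integer(),
                      n_sensitivity = integer(), n_resistance = integer()))
  if (!is.null(on_target)) {
    key <- paste(records$compound, records$target)
    okey <- paste(on_target$compound, on_target$target)
    records$on_target <- on_target$on_target[match(key, okey)] %in% TRUE
  }
  sig <- !is.na(records$q) & records$q < q_sig
  out <- do.call(rbind, lapply(split(records, records$screen), function(r) {
    s <- !is.na(r$q) & r$q < q_sig
    d <- data.frame(screen = r$screen[1], n_tested = sum(!is.na(r$p)),
                    n_sensitivity = sum(s & r$direction %in% "sensitivity"),
                    n_resistance = sum(s & r$direction %in% "resistance"),
                    stringsAsFactors = FALSE)
    if (!is.null(r$on_target)) {
      d$n_sensitivity_on_target <-
        sum(s & r$on_target & r$direction %in% "sensitivity")
      d$n_resistance_on_target <-
        sum(s & r$on_target & r$direction %in% "resistance")
    }
    d
  }))
  rownames(out) <- NULL
  out
}

#' Screen every compound against one genomic region's gain status
#'
#' Volcano-style screen: per compound, two-sided Welch t-test of AUC
#' between lines with and without gain of the given bin.
#'
#' @param gained named logical vector per cell line (gain of the bin).
#' @param auc numeric matrix cell lines x compounds.
#' @param min_n minimum group size, default 2.
#' @return data.frame per compound: `compound`, `n_gain`, `n_nogain`,
#'   `delta_auc`, `p`, `q`, `direction`, `untestable`.
#' @export
region_drug_screen <- function(gained, auc, min_n = 2L) {
  lines <- intersect(rownames(auc), names(gained)[!is.na(gained)])
  rows <- lapply(colnames(auc), function(cmp) {
    y <- auc[lines, cmp]
    ok <- !is.na(y)
    a <- y[ok & gained[lines]]
    b <- y[ok & !gained[lines]]
    rec <- data.frame(compound = cmp, n_gain = length(a), n_nogain = length(b),
                      delta_auc = NA_real_, p = NA_real_,
                      direction = NA_character_, untestable = TRUE,
                      stringsAsFactors = FALSE)
    if (length(a) >= min_n && length(b) >= min_n &&
        (stats::sd(a) > 0 || stats::sd(b) > 0)) {
      tt <- stats::t.test(a, b)
      rec$delta_auc <- mean(a) - mean(b)
      rec$p <- tt$p.value
      rec$direction <- if (rec$delta_auc < 0) "sensitivity" else "resistance"
      rec$untestable <- FALSE
    }
    rec
  })
  out <- do.call(rbind, rows)
  out$q <- estimate_qvalues(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Signed significance grid over a bin range and compound set
#'
#' Heatmap-ready matrix of signed -log10 p (negative = sensitivity when
#' the bin is gained) for each (bin, compound) combination.
#'
#' @param states character state matrix cell lines x bins (from
#'   [call_states()]).
#' @param auc numeric matrix cell lines x compounds.
#' @param bins,compounds subsets of column names to use (default all).
#' @return numeric matrix bins x compounds of signed -log10 p.
#' @export
region_compound_grid <- function(states, auc, bins = colnames(states),
                                 compounds = colnames(auc)) {
  out <- matrix(NA_real_, length(bins), length(compounds),
                dimnames = list(bins, compounds))
  for (b in bins) {
    gained <- stats::setNames(states[, b] == "gain", rownames(states))
    r <- region_drug_screen(gained, auc[, compounds, drop = FALSE])
    out[b, r$compound] <- ifelse(r$untestable, NA_real_,
                                 -log10(pmax(r$p, .Machine$double.xmin)) *
                                   sign(r$delta_auc))
  }
  out
}

#' Expression correlates of compound response with positional enrichment
#'
#' Correlates every gene's expression with a compound's AUC (Pearson),
#' computes q-values, and tests whether significant correlates are
#' enriched on a target chromosome arm via Fisher's exact test on the
#' 2x2 (significant x on-arm) table.
#'
#' @param expression numeric matrix cell lines x genes.
#' @param auc_vec named numeric AUC vector per cell line (one compound).
#' @param gene_location data.frame with `gene`, `chrom`, `arm`.
#' @param target_arm arm id to test, e.g. `"chr1p"` (chrom + arm pasted).
#' @param q_sig significance cutoff for a correlate, default 0.05.
#' @param min_shared minimum shared lines, default 30.
#' @return list with `genes` (per-gene `r`, `p`, `q`, `significant`,
#'   `on_arm`) and `enrichment` (Fisher `p`, `odds_ratio`, counts, or
#'   untestable when the arm has no genes in the matrix).
#' @export
expression_response_correlates <- function(expression, auc_vec, gene_location,
                                           target_arm, q_sig = 0.05,
                                           min_shared = 30L) {
  lines <- intersect(rownames(expression), names(auc_vec)[!is.na(auc_vec)])
  if (length(lines) < min_shared)
    stop("fewer than ", min_shared, " shared cell lines")
  y <- auc_vec[lines]
  res <- lapply(colnames(expression), function(g) {
    x <- expression[lines, g]
    ok <- !is.na(x)
    if (sum(ok) < min_shared || stats::sd(x[ok]) == 0) return(NULL)
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(gene = g, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, res)
  genes$q <- estimate_qvalues(genes$p)
  genes$significant <- genes$q < q_sig
  loc_arm <- paste0(gene_location$chrom, gene_location$arm)
  genes$on_arm <- loc_arm[match(genes$gene, gene_location$gene)] == target_arm
  genes$on_arm[is.na(genes$on_arm)] <- FALSE
  n11 <- sum(genes$significant & genes$on_arm)
  n12 <- sum(genes$significant & !genes$on_arm)
  n21 <- sum(!genes$significant & genes$on_arm)
  n22 <- sum(!genes$significant & !genes$on_arm)
  if (n11 + n21 == 0L) {
    enrich <- list(untestable = TRUE, p = NA_real_, odds_ratio = NA_real_)
  } else {
    ft <- stats::fisher.test(matrix(c(n11, n12, n21, n22), 2, byrow = TRUE))
    enrich <- list(untestable = FALSE, p = ft$p.value,
                   odds_ratio = unname(ft$estimate),
                   n_sig_on_arm = n11, n_sig_off_arm = n12,
                   n_ns_on_arm = n21, n_ns_off_arm = n22)
  }
  list(genes = genes, enrichment = enrich)
}
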