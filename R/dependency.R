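#' Differential gene dependency by copy-number status
#'
#' For every gene present in both matrices, compares the CRISPR/RNAi
#' dependency score of that gene between cell lines whose copy-number
#' status of the same gene is a low-amplitude gain (arm-level and focal
#' gain combined, or arm-level only) and lines with a neutral copy
#' number. Dependency scores are oriented so that more negative means
#' more dependent; a negative `delta` therefore means lines with gain are
#' more dependent on the gene.
#'
#' @param dep numeric matrix, cell lines x genes, dependency scores.
#' @param status character matrix, cell lines x genes, five-way status
#'   from [classify_gene_status()].
#' @param contrast `"combined"` (arm_gain + focal_gain vs neutral,
#'   default) or `"arm_only"`.
#' @param min_n minimum group size for a valid test (default 2); genes
#'   failing it are reported with `NA` statistics.
#' @param pooled use the pooled-variance two-sample t-test instead of the
#'   default unequal-variance (Welch) test.
#' @return data.frame with one row per tested gene: `gene`, `n_gain`,
#'   `n_neutral`, `delta` (mean gain - mean neutral), `t_stat`, `p`, `q`.
#' @export
differential_dependency <- function(dep, status,
                                    contrast = c("combined", "arm_only"),
                                    min_n = 2L, pooled = FALSE) {
  contrast <- match.arg(contrast)
  gain_levels <- if (contrast == "combined") c("arm_gain", "focal_gain")
                 else "arm_gain"
  genes <- intersect(colnames(dep), colnames(status))
  lines <- intersect(rownames(dep), rownames(status))
  if (!length(genes) || !length(lines))
    stop("dependency and status matrices share no genes or no cell lines")
  skipped <- setdiff(colnames(dep), genes)
  if (length(skipped))
    message(length(skipped), " gene(s) absent from the status matrix; skipped")
  rows <- lapply(genes, function(g) {
    st <- status[lines, g]
    d <- dep[lines, g]
    a <- d[!is.na(st) & st %in% gain_levels & !is.na(d)]
    b <- d[!is.na(st) & st == "neutral" & !is.na(d)]
    rec <- data.frame(gene = g, n_gain = length(a), n_neutral = length(b),
                      delta = NA_real_, t_stat = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    if (length(a) >= min_n && length(b) >= min_n &&
        (stats::sd(a) > 0 || stats::sd(b) > 0)) {
      tt <- stats::t.test(a, b, var.equal = pooled)
      rec$delta <- mean(a) - mean(b)
      rec$t_stat <- unname(tt$statistic)
      rec$p <- tt$p.value
    } else if (length(a) >= min_n && length(b) >= min_n) {
      rec$delta <- mean(a) - mean(b)   # identical constant groups
      rec$t_stat <- 0
      rec$p <- 1
    }
    rec
  })
  out <- do.call(rbind, rows)
  out$q <- estimate_qvalues(out$p)
  out
}

#' Remove genes whose dependency signal is confounded
#'
#' Drops genes whose combined experimental-confounder importance in an
#' external dependency-prediction model exceeds the cutoff (strictly).
#' Genes absent from the importance table are retained with a warning.
#'
#' @param records association table with a `gene` column.
#' @param importance data.frame with columns `gene`, `importance`.
#' @param cutoff importance cutoff, default 0.05.
#' @return filtered records.
#' @export
filter_confounded <- function(records, importance, cutoff = 0.05) {
  imp <- stats::setNames(importance$importance, importance$gene)
  known <- records$gene %in% names(imp)
  if (!all(known))
    warning(sum(!known), " gene(s) absent from the importance table; retained")
  drop <- known & imp[records$gene] > cutoff
  records[!drop, , drop = FALSE]
}

#' Signed significance metric for ranking genes
#'
#' metric = sign(delta) * (-log10 q): strongly significant genes that are
#' more dependent when gained get large negative values. Ties are broken
#' by |delta| (larger first) and then gene label, so the ordering is
#' deterministic. q-values of 0 are clamped to the smallest positive
#' double.
#'
#' @param records data.frame with `gene`, `delta`, `q` (rows with missing
#'   q are dropped).
#' @return data.frame sorted by decreasing metric, with a `metric` column.
#' @export
rank_genes <- function(records) {
  r <- records[!is.na(records$q) & !is.na(records$delta), , drop = FALSE]
  q <- pmax(r$q, .Machine$double.xmin)
  r$metric <- sign(r$delta) * (-log10(q))
  r$metric[r$delta == 0] <- 0
  r[order(-r$metric, -abs(r$delta), r$gene), , drop = FALSE]
}

#' Named, sorted ranking metric for enrichment analysis
#' @param records association table (see [rank_genes()]).
#' @return named numeric vector sorted decreasing.
#' @export
ranked_metric <- function(records) {
  r <- rank_genes(records)
  stats::setNames(r$metric, r$gene)
}

#' Cross-dataset candidate gene selection
#'
#' A gene is a candidate when it shows a significantly lower dependency
#' score in lines with low-amplitude gain (q < `q_max` and delta <
#' `delta_max`, both strict) in at least `min_datasets` of the supplied
#' datasets.
#'
#' @param records_list named list of association tables from
#'   [differential_dependency()].
#' @param q_max q-value cutoff, default 0.3.
#' @param delta_max dependency-difference cutoff, default -0.05.
#' @param min_datasets minimum number of datasets, default 2.
#' @return data.frame with `gene`, `n_datasets_significant`, and
#'   per-dataset `q_<name>` / `delta_<name>` evidence columns, sorted by
#'   gene; attribute `"params"` records the cutoffs.
#' @export
select_candidates <- function(records_list, q_max = 0.3, delta_max = -0.05,
                              min_datasets = 2L) {
  if (length(records_list) < 2L) stop("need at least two datasets")
  if (is.null(names(records_list)))
    names(records_list) <- paste0("dataset", seq_along(records_list))
  genes <- sort(unique(unlist(lapply(records_list, `[[`, "gene"))))
  sig <- sapply(records_list, function(r) {
    ok <- !is.na(r$q) & !is.na(r$delta) & r$q < q_max & r$delta < delta_max
    genes %in% r$gene[ok]
  })
  n_sig <- rowSums(sig)
  keep <- n_sig >= min_datasets
  out <- data.frame(gene = genes[keep],
                    n_datasets_significant = n_sig[keep],
                    stringsAsFactors = FALSE)
  for (nm in names(records_list)) {
    r <- records_list[[nm]]
    out[[paste0("q_", nm)]] <- r$q[match(out$gene, r$gene)]
    out[[paste0("delta_", nm)]] <- r$delta[match(out$gene, r$gene)]
  }
  rownames(out) <- NULL
  attr(out, "params") <- list(q_max = q_max, delta_max = delta_max,
                              min_datasets = min_datasets)
  out
}

#' Mutation / low-amplitude-gain co-occurrence
#'
#' Per gene, tests the 2x2 table of mutation status against
#' low-amplitude-gain status (arm or focal gain vs any other non-missing
#' status) with Fisher's exact test. Direction `co-occurring` for odds
#' ratio > 1, `exclusive` for < 1.
#'
#' @param mutations binary matrix samples x genes (1 = mutated).
#' @param status character status matrix samples x genes.
#' @return data.frame per shared gene: counts `n_mut_gain`, `n_mut_nogain`,
#'   `n_wt_gain`, `n_wt_nogain`, `odds_ratio`, `p`, `q`, `direction`,
#'   `untestable`.
#' @export
mutation_gain_cooccurrence <- function(mutations, status) {
  genes <- intersect(colnames(mutations), colnames(status))
  lines <- intersect(rownames(mutations), rownames(status))
  rows <- lapply(genes, function(g) {
    mut <- mutations[lines, g]
    st <- status[lines, g]
    ok <- !is.na(mut) & !is.na(st)
    gain <- st[ok] %in% c("arm_gain", "focal_gain")
    mut <- mut[ok] == 1
    tab <- c(sum(mut & gain), sum(mut & !gain), sum(!mut & gain),
             sum(!mut & !gain))
    rec <- data.frame(gene = g, n_mut_gain = tab[1], n_mut_nogain = tab[2],
                      n_wt_gain = tab[3], n_wt_nogain = tab[4],
                      odds_ratio = NA_real_, p = NA_real_,
                      direction = NA_character_, untestable = TRUE,
                      stringsAsFactors = FALSE)
    m <- matrix(tab, 2, byrow = TRUE)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      ft <- stats::fisher.test(m)
      or <- (tab[1] * tab[4]) / (tab[2] * tab[3])
      rec$odds_ratio <- or
      rec$p <- ft$p.value
      rec$direction <- if (is.nan(or) || or == 1) NA_character_
                       else if (or > 1) "co-occurring" else "exclusive"
      rec$untestable <- FALSE
    }
    rec
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$q[!out$untestable] <- estimate_qvalues(out$p[!out$untestable])
  out
}

#' Expression upregulation in lines with low-amplitude gain
#'
#' One-sided unequal-variance t-test (gain > neutral) of a gene's
#' expression between lines with low-amplitude gain of that gene and
#' neutral lines; `upregulated` when q < `q_max`.
#'
#' @param expression numeric matrix samples x genes.
#' @param status character status matrix.
#' @param q_max significance cutoff, default 0.05.
#' @param min_n minimum per-group size, default 2.
#' @return data.frame per gene: `gene`, `n_gain`, `n_neutral`, `delta`,
#'   `p`, `q`, `call` in {upregulated, not_upregulated, unevaluable}.
#' @export
expression_by_gain_status <- function(expression, status, q_max = 0.05,
                                      min_n = 2L) {
  genes <- intersect(colnames(expression), colnames(status))
  lines <- intersect(rownames(expression), rownames(status))
  rows <- lapply(genes, function(g) {
    st <- status[lines, g]
    e <- expression[lines, g]
    a <- e[!is.na(st) & st %in% c("arm_gain", "focal_gain") & !is.na(e)]
    b <- e[!is.na(st) & st == "neutral" & !is.na(e)]
    rec <- data.frame(gene = g, n_gain = length(a), n_neutral = length(b),
                      delta = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    if (length(a) >= min_n && length(b) >= min_n &&
        (stats::sd(a) > 0 || stats::sd(b) > 0)) {
      tt <- stats::t.test(a, b, alternative = "greater")
      rec$delta <- mean(a) - mean(b)
      rec$p <- tt$p.value
    }
    rec
  })
  out <- do.call(rbind, rows)
  out$q <- estimate_qvalues(out$p)
  out$call <- ifelse(is.na(out$p), "unevaluable",
                     ifelse(!is.na(out$q) & out$q < q_max, "upregulated",
                            "not_upregulated"))
  out
}

#' Dependency contrast stratified by mutation status
#'
#' Runs [differential_dependency()] separately within mutated and
#' wild-type cell lines (e.g. hotspot-mutant vs non-mutant lines for the
#' same gene). Strata with fewer than `min_n` lines per group are skipped.
#'
#' @param dep,status as in [differential_dependency()].
#' @param mutated named logical vector per cell line.
#' @param ... passed to [differential_dependency()].
#' @return data.frame of association records with a `stratum` column
#'   ("mutant" / "wildtype").
#' @export
stratified_dependency <- function(dep, status, mutated, ...) {
  lines <- intersect(intersect(rownames(dep), rownames(status)),
                     names(mutated)[!is.na(mutated)])
  out <- list()
  for (stratum in c("mutant", "wildtype")) {
    keep <- lines[if (stratum == "mutant") mutated[lines] else !mutated[lines]]
    if (length(keep) < 4L) {
      message("stratum ", stratum, " has too few lines; skipped")
      next
    }
    r <- differential_dependency(dep[keep, , drop = FALSE],
                                 status[keep, , drop = FALSE], ...)
    r$stratum <- stratum
    out[[stratum]] <- r
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
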