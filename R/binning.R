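#' Build centromere-aware genomic bins
#'
#' Tiles each chromosome from 0 in `bin_size` steps and inserts both
#' centromere boundaries so that no bin spans the two arms. Consecutive
#' distinct boundaries define bins; each bin is labelled `p` (ends at or
#' before the centromere start), `q` (starts at or after the centromere
#' end) or `cen` (inside the centromere, typically missing-valued
#' downstream).
#'
#' @param build a genome build, see [genome_build()].
#' @param bin_size bin width in base pairs (> 0).
#' @param per_arm if `TRUE`, restart the tiling at the start of each arm
#'   instead of tiling the whole chromosome from 0.
#' @return data.frame with columns `chrom`, `start`, `end`, `arm`,
#'   `bin_id` (coordinates 0-based, half-open; bins per chromosome are
#'   disjoint, ordered, and cover `[0, length)`).
#' @export
build_bins <- function(build, bin_size, per_arm = FALSE) {
  stopifnot(inherits(build, "genome_build"))
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stop("bin_size must be a single positive number")
  res <- lapply(seq_len(nrow(build)), function(i) {
    len <- build$length[i]; cs <- build$cen_start[i]; ce <- build$cen_end[i]
    if (per_arm) {
      b <- c(seq(0, cs, by = bin_size), cs,
             seq(ce, len, by = bin_size), ce, len)
    } else {
      b <- c(seq(0, len, by = bin_size), len, cs, ce)
    }
    b <- sort(unique(b))
    data.frame(chrom = build$chrom[i],
               start = b[-length(b)], end = b[-1L],
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, res)
  bins <- merge(bins, build, by = "chrom", sort = FALSE)
  bins$arm <- ifelse(bins$end <= bins$cen_start, "p",
                     ifelse(bins$start >= bins$cen_end, "q", "cen"))
  bins <- bins[order(match(bins$chrom, build$chrom), bins$start),
               c("chrom", "start", "end", "arm")]
  bins$bin_id <- sprintf("%s:%d-%d", bins$chrom, as.integer(bins$start / 1e3),
                         as.integer(bins$end / 1e3))
  bins$bin_id <- paste0(bins$bin_id, "kb")
  rownames(bins) <- NULL
  bins
}

#' Gene-centered bins from an annotation table
#'
#' Uses gene start/end as bin boundaries: one bin per gene, labelled with
#' the arm the gene lies on (`cen` if it overlaps the centromere).
#'
#' @param genes data.frame with columns `chrom`, `start`, `end`, `gene`
#'   (0-based half-open, e.g. from [read_gene_bed()]).
#' @param build a genome build.
#' @return data.frame like [build_bins()] output, `bin_id` = gene name.
#' @export
gene_bins <- function(genes, build) {
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(genes)))
  bad <- setdiff(genes$chrom, build$chrom)
  if (length(bad)) stop("gene(s) on chromosome(s) absent from build: ",
                        paste(unique(bad), collapse = ", "))
  b <- merge(genes, as.data.frame(build), by = "chrom", sort = FALSE)
  b$arm <- ifelse(b$end <= b$cen_start, "p",
                  ifelse(b$start >= b$cen_end, "q", "cen"))
  out <- data.frame(chrom = b$chrom, start = b$start, end = b$end,
                    arm = b$arm, bin_id = b$gene, stringsAsFactors = FALSE)
  out[order(match(out$chrom, build$chrom), out$start), , drop = FALSE]
}

#' Weighted-mean copy number of one interval
#'
#' The interval copy number is the mean of overlapping segment values
#' weighted by overlap length; the covered fraction is the summed overlap
#' divided by the interval length. With no overlapping segment the copy
#' number is `NA` and the covered fraction 0.
#'
#' @param segments data.frame of one sample's segments (`chrom`, `start`,
#'   `end`, `cn`), 0-based half-open, non-overlapping per chromosome.
#' @param chrom,start,end the query interval.
#' @return named numeric `c(cn =, covered_fraction =)`.
#' @export
interval_copy_number <- function(segments, chrom, start, end) {
  if (!is.numeric(start) || !is.numeric(end) || is.na(start) || is.na(end) ||
      start >= end)
    stop("malformed interval: need start < end")
  s <- segments[segments$chrom == chrom, , drop = FALSE]
  w <- pmax(0, pmin(s$end, end) - pmax(s$start, start))
  keep <- w > 0
  if (!any(keep)) return(c(cn = NA_real_, covered_fraction = 0))
  cn <- if (sum(keep) == 1L) s$cn[keep]   # exact for a single segment
        else sum(w[keep] * s$cn[keep]) / sum(w[keep])
  c(cn = cn, covered_fraction = sum(w[keep]) / (end - start))
}

#' Samples-by-bins weighted-mean copy-number matrix
#'
#' Applies the weighted-mean rule of [interval_copy_number()] to every
#' (sample, bin) pair. Segments on chromosomes absent from the bin set
#' are skipped with a warning reporting the count.
#'
#' @param segments long data.frame of segments with columns `sample`,
#'   `chrom`, `start`, `end`, `cn` (0-based half-open).
#' @param bins bin table from [build_bins()] or [gene_bins()].
#' @return list of class `"bin_cn"` with elements `cn` and
#'   `covered_fraction` (numeric matrices, rows = samples sorted, columns
#'   = `bins$bin_id` in bin order) and `bins`.
#' @export
bin_copy_matrix <- function(segments, bins) {
  if (nrow(segments) == 0L || nrow(bins) == 0L)
    stop("segments and bins must be non-empty")
  samples <- sort(unique(segments$sample))
  known <- segments$chrom %in% bins$chrom
  if (!all(known)) {
    warning(sum(!known), " segment(s) on chromosomes absent from the bin set; skipped")
    segments <- segments[known, , drop = FALSE]
  }
  cn <- matrix(NA_real_, length(samples), nrow(bins),
               dimnames = list(samples, bins$bin_id))
  cov <- matrix(0, length(samples), nrow(bins),
                dimnames = list(samples, bins$bin_id))
  width <- bins$end - bins$start
  seg_by <- split(segments, segments$sample)
  for (smp in names(seg_by)) {
    segs <- seg_by[[smp]]
    for (chr in unique(segs$chrom)) {
      jj <- which(bins$chrom == chr)
      if (!length(jj)) next
      s <- segs[segs$chrom == chr, , drop = FALSE]
      # overlap length of every segment with every bin of this chromosome
      w <- outer(s$end, bins$end[jj], pmin) -
           outer(s$start, bins$start[jj], pmax)
      w[w < 0] <- 0
      tot <- colSums(w)
      num <- colSums(w * s$cn)
      has <- tot > 0
      cn[smp, jj[has]] <- num[has] / tot[has]
      cov[smp, jj] <- tot / width[jj]
    }
  }
  structure(list(cn = cn, covered_fraction = cov, bins = bins),
            class = "bin_cn")
}

#' @export
print.bin_cn <- function(x, ...) {
  cat("bin copy-number matrix:", nrow(x$cn), "samples x", ncol(x$cn), "bins\n")
  cat(sprintf("  missing entries: %d (%.1f%%)\n", sum(is.na(x$cn)),
              100 * mean(is.na(x$cn))))
  invisible(x)
}

#' Read segmented copy-number profiles (SEG-like TSV)
#'
#' Columns `sample`, `chrom`, `start`, `end`, `cn` (header required;
#' extra columns ignored). Input coordinates are 1-based inclusive by
#' default and converted to the internal 0-based half-open convention.
#' Exact duplicate rows are dropped with a warning; overlapping segments
#' within a sample/chromosome are an error.
#'
#' @param path file path.
#' @param dialect `"1-based-inclusive"` (default) or `"0-based-half-open"`.
#' @return long segment data.frame (`sample`, `chrom`, `start`, `end`, `cn`).
#' @export
read_segments <- function(path, dialect = c("1-based-inclusive",
                                            "0-based-half-open")) {
  dialect <- match.arg(dialect)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "cn")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("segment file missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!is.finite(suppressWarnings(as.numeric(d$cn))))
  if (length(bad)) stop("non-numeric segment value at data line ", bad[1])
  d <- d[need]
  d$cn <- as.numeric(d$cn)
  if (anyDuplicated(d)) {
    warning("dropped ", sum(duplicated(d)), " exact duplicate segment row(s)")
    d <- unique(d)
  }
  if (dialect == "1-based-inclusive") d$start <- d$start - 1
  validate_segments(d)
  d[order(d$sample, d$chrom, d$start), , drop = FALSE]
}

validate_segments <- function(d) {
  if (any(d$start >= d$end)) stop("segment with start >= end")
  by <- split(d, paste(d$sample, d$chrom, sep = "\r"))
  for (key in names(by)) {
    s <- by[[key]]
    o <- order(s$start)
    if (any(s$start[o][-1] < s$end[o][-nrow(s)])) {
      stop("overlapping segments in sample ", s$sample[1],
           " on ", s$chrom[1])
    }
  }
  invisible(d)
}

#' Write segments as SEG-like TSV (1-based inclusive)
#' @param segments long segment data.frame (internal 0-based half-open).
#' @param path output path.
#' @export
write_segments <- function(segments, path) {
  out <- segments[c("sample", "chrom", "start", "end", "cn")]
  out$start <- out$start + 1
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file of gene locations
#'
#' BED is 0-based half-open already; only the first four columns are used.
#'
#' @param path file path (no header, tab-separated).
#' @return data.frame with `chrom`, `start`, `end`, `gene`.
#' @export
read_gene_bed <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 4L) stop("BED file needs at least 4 columns (chrom, start, end, name)")
  stats::setNames(d[1:4], c("chrom", "start", "end", "gene"))
}
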