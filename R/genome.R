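#' Genome builds and chromosome arms
#'
#' A genome build is a data frame with one row per chromosome and columns
#' `chrom` (character), `length`, `cen_start`, `cen_end` (base pairs).
#' All internal coordinates are 0-based, half-open.
#'
#' @param chrom character vector of chromosome names (unique).
#' @param length chromosome lengths in base pairs.
#' @param cen_start,cen_end centromere interval, `0 < cen_start < cen_end < length`.
#' @return A `data.frame` with class `c("genome_build", "data.frame")`.
#' @export
genome_build <- function(chrom, length, cen_start, cen_end) {
  chrom <- as.character(chrom)
  if (length(chrom) == 0L) stop("genome build must contain at least one chromosome")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  length <- as.numeric(length); cen_start <- as.numeric(cen_start)
  cen_end <- as.numeric(cen_end)
  ok <- cen_start > 0 & cen_start < cen_end & cen_end < length
  if (!all(ok)) {
    stop("invalid centromere for chromosome(s): ",
         paste(chrom[!ok], collapse = ", "),
         " (need 0 < cen_start < cen_end < length)")
  }
  out <- data.frame(chrom = chrom, length = length,
                    cen_start = cen_start, cen_end = cen_end,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_build", "data.frame")
  out
}

#' Read a genome build from TSV
#'
#' Expects columns `chrom`, `length`, `cen_start`, `cen_end`.
#'
#' @param path file path.
#' @return A genome build, see [genome_build()].
#' @export
read_genome_build <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "length", "cen_start", "cen_end")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("genome build file missing column(s): ",
                         paste(miss, collapse = ", "))
  genome_build(d$chrom, d$length, d$cen_start, d$cen_end)
}

#' Chromosome-arm intervals of a genome build
#'
#' The p arm runs from 0 to the centromere start, the q arm from the
#' centromere end to the chromosome end. The centromere interior belongs
#' to neither arm.
#'
#' @param build a genome build.
#' @return data.frame with columns `chrom`, `arm` ("p"/"q"), `arm_id`
#'   (e.g. "chr1p"), `start`, `end`.
#' @export
arm_intervals <- function(build) {
  stopifnot(inherits(build, "genome_build"))
  p <- data.frame(chrom = build$chrom, arm = "p",
                  start = 0, end = build$cen_start, stringsAsFactors = FALSE)
  q <- data.frame(chrom = build$chrom, arm = "q",
                  start = build$cen_end, end = build$length,
                  stringsAsFactors = FALSE)
  out <- rbind(p, q)
  out$arm_id <- paste0(out$chrom, out$arm)
  out <- out[order(match(out$chrom, build$chrom), out$start),
             c("chrom", "arm", "arm_id", "start", "end")]
  rownames(out) <- NULL
  out
}

#' Toy genome build used by the simulator
#'
#' Four 120-Mb chromosomes with centromeres at 58-62 Mb: large enough to
#' separate arm-level from focal events at 25-Mb and 1-Mb binning, small
#' enough that exhaustive per-base-unit oracles remain cheap.
#'
#' @param n_chrom number of chromosomes (default 4).
#' @return A genome build.
#' @export
toy_genome <- function(n_chrom = 4) {
  genome_build(paste0("chr", seq_len(n_chrom)),
               length = rep(120e6, n_chrom),
               cen_start = rep(58e6, n_chrom),
               cen_end = rep(62e6, n_chrom))
}
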