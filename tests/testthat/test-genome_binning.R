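test_that("bin boundaries are the tiling union with centromere splits", {
  b <- build_bins(tiny_build(), 25e6)
  expect_equal(b$start, c(0, 25e6, 28e6, 32e6, 50e6))
  expect_equal(b$end, c(25e6, 28e6, 32e6, 50e6, 60e6))
  expect_equal(b$arm, c("p", "p", "cen", "q", "q"))
})

test_that("duplicate boundaries collapse when centromere hits the tiling", {
  g <- genome_build("chrA", 50e6, 25e6, 30e6)
  b <- build_bins(g, 25e6)
  expect_equal(nrow(b), 3L)
  expect_equal(b$start, c(0, 25e6, 30e6))
  expect_equal(b$arm, c("p", "cen", "q"))
})

test_that("oversized bins still yield a valid 3-bin chromosome", {
  b <- build_bins(tiny_build(), 500e6)
  expect_equal(nrow(b), 3L)
  expect_equal(b$arm, c("p", "cen", "q"))
})

test_that("bins tile each chromosome exactly, without overlap", {
  build <- toy_genome()
  for (size in c(1e6, 7.3e6, 25e6)) {
    bins <- build_bins(build, size)
    for (chr in build$chrom) {
      bc <- bins[bins$chrom == chr, ]
      expect_equal(bc$start[1], 0)
      expect_equal(bc$end[nrow(bc)], build$length[build$chrom == chr])
      expect_equal(bc$start[-1], bc$end[-nrow(bc)])  # no gaps, no overlap
      expect_true(all(bc$arm != "cen" |
                        (bc$start >= build$cen_start[build$chrom == chr] |
                           bc$end <= build$cen_end[build$chrom == chr])))
    }
  }
  expect_error(build_bins(tiny_build(), 0), "positive")
})

test_that("per-arm tiling mode restarts bins at each arm", {
  b <- build_bins(tiny_build(), 25e6, per_arm = TRUE)
  q <- b[b$arm == "q", ]
  expect_equal(q$start[1], 32e6)   # q tiling starts at the centromere end
  expect_equal(q$end, c(57e6, 60e6))
})

test_that("gene-centered bins use gene boundaries, one bin per gene", {
  genes <- data.frame(chrom = "chrA", start = c(1e6, 40e6),
                      end = c(2e6, 41e6), gene = c("g1", "g2"))
  gb <- gene_bins(genes, tiny_build())
  expect_equal(nrow(gb), 2L)
  expect_equal(gb$bin_id, c("g1", "g2"))
  expect_equal(gb$arm, c("p", "q"))
  bad <- data.frame(chrom = "chrZ", start = 1, end = 2, gene = "g")
  expect_error(gene_bins(bad, tiny_build()), "absent")
})

test_that("interval copy number is the overlap-weighted mean", {
  segs <- data.frame(chrom = "chrA", start = c(20e6, 35e6),
                     end = c(35e6, 50e6), cn = c(0.6, 0.0))
  r <- interval_copy_number(segs, "chrA", 25e6, 50e6)
  expect_equal(unname(r["cn"]), (10 * 0.6 + 15 * 0.0) / 25)
  expect_equal(unname(r["covered_fraction"]), 1.0)

  r2 <- interval_copy_number(segs, "chrA", 55e6, 60e6)
  expect_true(is.na(r2["cn"]))
  expect_equal(unname(r2["covered_fraction"]), 0)

  one <- data.frame(chrom = "chrA", start = 10e6, end = 12e6, cn = -0.3)
  r3 <- interval_copy_number(one, "chrA", 10e6, 15e6)
  expect_equal(unname(r3["cn"]), -0.3)
  expect_equal(unname(r3["covered_fraction"]), 0.4)

  expect_error(interval_copy_number(segs, "chrA", 5e6, 5e6), "malformed")
})

test_that("a fully covering segment returns its cn exactly and splitting is invariant", {
  set.seed(11)
  for (i in 1:20) {
    cn <- rnorm(1)
    seg <- data.frame(chrom = "chrA", start = 0, end = 60e6, cn = cn)
    r <- interval_copy_number(seg, "chrA", 13e6, 27e6)
    expect_identical(unname(r["cn"]), cn)
    # refinement invariance: split at an arbitrary internal point
    cut <- runif(1, 1e6, 59e6)
    split2 <- data.frame(chrom = "chrA", start = c(0, cut),
                         end = c(cut, 60e6), cn = cn)
    r2 <- interval_copy_number(split2, "chrA", 13e6, 27e6)
    expect_equal(unname(r2["cn"]), cn)
  }
})

test_that("splitting any segment leaves bin matrices unchanged", {
  set.seed(12)
  build <- tiny_build()
  segs <- random_profile(build, "S1", gap_prob = 0.3)
  bins <- build_bins(build, 10e6)
  m1 <- bin_copy_matrix(segs, bins)
  k <- which.max(segs$end - segs$start)
  at <- (segs$start[k] + segs$end[k]) / 2
  split_seg <- rbind(segs[-k, ],
                     transform(segs[k, ], end = at),
                     transform(segs[k, ], start = at))
  m2 <- bin_copy_matrix(split_seg, bins)
  expect_equal(m2$cn, m1$cn, tolerance = 1e-12)
  expect_equal(m2$covered_fraction, m1$covered_fraction, tolerance = 1e-12)
})

test_that("bin matrix matches the exhaustive per-base-unit oracle", {
  set.seed(13)
  build <- toy_genome()
  bins <- build_bins(build, 25e6)
  segs <- do.call(rbind, lapply(1:50, function(i)
    random_profile(build, sprintf("S%03d", i))))
  m <- suppressWarnings(bin_copy_matrix(segs, bins))
  for (smp in sample(rownames(m$cn), 10)) {
    s <- segs[segs$sample == smp, ]
    for (j in sample(ncol(m$cn), 8)) {
      o <- oracle_interval_cn(s, bins$chrom[j], bins$start[j], bins$end[j])
      expect_equal(unname(m$cn[smp, j]), o$cn, tolerance = 1e-9)
      expect_equal(unname(m$covered_fraction[smp, j]), o$covered_fraction,
                   tolerance = 1e-9)
    }
  }
})

test_that("profiles with no segments give all-missing rows", {
  build <- tiny_build()
  bins <- build_bins(build, 25e6)
  segs <- data.frame(sample = c("S1", "S2"),
                     chrom = c("chrA", "chrZ"),
                     start = c(0, 0), end = c(60e6, 60e6), cn = c(0.2, 1))
  expect_warning(m <- bin_copy_matrix(segs, bins), "skipped")
  expect_true(all(is.na(m$cn["S2", ])))
  expect_true(all(m$covered_fraction["S2", ] == 0))
  # missing iff covered_fraction == 0
  expect_identical(is.na(m$cn), m$covered_fraction == 0)
})

test_that("SEG reader converts dialects, deduplicates, and validates", {
  f <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\tcn",
               "S1\tchr1\t1\t25000000\t0.3",
               "S2\tchr1\t1\t10000000\t-0.2",
               "S1\tchr1\t25000001\t50000000\t0.0"), f)
  segs <- read_segments(f)
  expect_equal(nrow(segs), 3L)
  s1 <- segs[segs$sample == "S1", ]
  expect_equal(s1$start, c(0, 25000000))   # 1-based inclusive -> 0-based
  expect_equal(s1$end, c(25000000, 50000000))
  expect_equal(nrow(segs[segs$sample == "S2", ]), 1L)

  writeLines(c("sample\tchrom\tstart\tend\tcn",
               "S1\tchr1\t1\t100\t0.3",
               "S1\tchr1\t1\t100\t0.3"), f)
  expect_warning(d <- read_segments(f), "duplicate")
  expect_equal(nrow(d), 1L)

  writeLines(c("sample\tchrom\tstart\tend\tcn",
               "S1\tchr1\t1\t100\t0.3",
               "S1\tchr1\t50\t150\t0.1"), f)
  expect_error(read_segments(f), "S1")

  writeLines(c("sample\tchrom\tstart\tend\tcn",
               "S1\tchr1\t1\t100\tNOPE"), f)
  expect_error(read_segments(f), "line")
})

test_that("segment writer round-trips through the reader", {
  set.seed(14)
  segs <- random_profile(tiny_build(), "S1")
  f <- withr::local_tempfile(fileext = ".seg")
  write_segments(segs, f)
  back <- read_segments(f)
  expect_equal(back$start, segs$start)
  expect_equal(back$end, segs$end)
  expect_equal(back$cn, segs$cn, tolerance = 1e-12)
})
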