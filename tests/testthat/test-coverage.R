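test_that("bedGraph loading materializes per-base values with implicit zeros", {
  sizes <- c(chr1 = 20L)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t10\t2.0", path)
  tr <- load_track(path, sizes)
  expect_equal(tr$values$chr1, c(rep(2, 10), rep(0, 10)))
  expect_false(tr$normalized)

  writeLines(character(0), path)
  expect_equal(load_track(path, sizes)$values$chr1, rep(0, 20))
})

test_that("bedGraph loading validates bounds and overlap", {
  sizes <- c(chr1 = 20L)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t10\t1", "chr1\t5\t15\t2"), path)
  expect_error(load_track(path, sizes), "overlapping")
  writeLines("chr1\t0\t30\t1", path)
  expect_error(load_track(path, sizes), "beyond chromosome end")
  writeLines("chr9\t0\t10\t1", path)
  expect_error(load_track(path, sizes), "chr9")
})

test_that("bedGraph round trip reproduces per-base values and library size", {
  set.seed(50)
  tr <- random_track(c(chrA = 500L, chrB = 300L))
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, path)
  tr2 <- load_track(path, c(chrA = 500L, chrB = 300L))
  expect_identical(tr2$values$chrA, tr$values$chrA)
  expect_identical(tr2$values$chrB, tr$values$chrB)
  expect_equal(tr2$library_size, tr$library_size)
})

test_that("bigWig tracks load to the same per-base values as bedGraph", {
  v <- c(rep(2, 50), rep(0, 30), rep(1.5, 20))
  gr <- GenomicRanges::GRanges("chrZ",
                               IRanges::IRanges(start = c(1, 81),
                                                end = c(50, 100)),
                               score = c(2, 1.5))
  GenomeInfoDb::seqlengths(gr) <- c(chrZ = 100)
  bw <- withr::local_tempfile(fileext = ".bw")
  rtracklayer::export(gr, bw, format = "BigWig")
  tr <- load_track(bw, c(chrZ = 100L))
  expect_equal(tr$values$chrZ, v)
})

test_that("depth normalization is CPM-style, linear, and one-shot", {
  tr <- coverage_track(list(chr1 = c(3, 0, 6)), library_size = 2e6)
  n1 <- normalize_depth(tr)
  expect_equal(n1$values$chr1, c(1.5, 0, 3))
  expect_true(n1$normalized)
  expect_error(normalize_depth(n1), "already normalized")
  expect_error(normalize_depth(tr, library_size = 0), "positive")

  id <- normalize_depth(coverage_track(list(chr1 = c(1, 2)),
                                       library_size = 1e6))
  expect_equal(id$values$chr1, c(1, 2))

  # linearity: normalize(a * track) = a * normalize(track)
  set.seed(51)
  v <- runif(100, 0, 5)
  a <- 3.7
  t1 <- normalize_depth(coverage_track(list(c1 = v), library_size = 5e5))
  t2 <- normalize_depth(coverage_track(list(c1 = a * v), library_size = 5e5))
  expect_equal(t2$values$c1, a * t1$values$c1)

  # total signal scales by 1e6 / library_size
  set.seed(52)
  tr <- random_track(c(c1 = 400L))
  tot <- sum(tr$values$c1)
  nn <- normalize_depth(tr, library_size = 3e6)
  expect_equal(sum(nn$values$c1), 1e6 * tot / 3e6)
})

test_that("region totals equal per-base summation", {
  tr <- coverage_track(list(chr1 = rep(2, 10)))
  expect_equal(region_total(tr, "chr1", 0, 10), 20)
  expect_equal(region_total(coverage_track(list(chr1 = rep(0, 10))),
                            "chr1", 2, 8), 0)
  expect_error(region_total(tr, "chr1", 5, 15), "out of bounds")

  set.seed(53)
  tr <- random_track(c(c1 = 1000L))
  for (i in 1:20) {
    s <- sample.int(900, 1) - 1L
    e <- s + sample.int(100, 1)
    expect_equal(region_total(tr, "c1", s, e), sum(tr$values$c1[(s + 1):e]))
  }
})

test_that("extract_matrix reproduces constant and delta fields", {
  tr <- coverage_track(list(chr1 = rep(3.5, 10000)))
  anchors <- interval_set("chr1", c(4000, 6000), c(4001, 6001))
  pm <- extract_matrix(tr, anchors, flank_bp = 500, bin_width = 10)
  expect_equal(dim(pm$values), c(2L, 100L))
  expect_true(all(pm$values == 3.5))

  v <- rep(0, 10000); v[5001] <- 9  # base 5000 (0-based)
  tr <- coverage_track(list(chr1 = v), library_size = 1)
  anchors <- interval_set("chr1", 5000, 5001)
  pm <- extract_matrix(tr, anchors, flank_bp = 100, bin_width = 1)
  row <- pm$values[1, ]
  expect_equal(row[101], 9)  # column at offset 0 holds the center base
  expect_equal(sum(row), 9)
})

test_that("extract_matrix matches the per-base oracle with strand mirroring", {
  set.seed(54)
  tr <- random_track(c(c1 = 8000L, c2 = 6000L))
  anchors <- random_interval_set(100, chroms = c("c1", "c2"),
                                 chrom_len = 6000, max_width = 300)
  pm <- extract_matrix(tr, anchors, flank_bp = 400, bin_width = 10)
  centers <- interval_center(anchors)
  for (i in seq_len(nrow(anchors))) {
    expect_equal(pm$values[i, ],
                 oracle_extract(tr$values, anchors$chrom[i], centers[i],
                                anchors$strand[i], 400, 10),
                 tolerance = 1e-12)
  }
})

test_that("edge windows are masked, not zero-filled", {
  tr <- coverage_track(list(chr1 = rep(1, 1000)))
  anchors <- interval_set("chr1", c(50, 500), c(51, 501))
  pm <- extract_matrix(tr, anchors, flank_bp = 200, bin_width = 10)
  expect_true(all(is.na(pm$values[1, 1:15])))   # bins before base 0
  expect_true(all(pm$values[1, 16:40] == 1))
  expect_true(all(pm$values[2, ] == 1))
})

test_that("bin means conserve the window total for in-bounds rows", {
  set.seed(55)
  tr <- random_track(c(c1 = 5000L))
  anchors <- interval_set("c1", 2000, 2001)
  bw <- 25
  pm <- extract_matrix(tr, anchors, flank_bp = 500, bin_width = bw)
  expect_equal(sum(pm$values[1, ]) * bw,
               region_total(tr, "c1", 1500, 2500), tolerance = 1e-6)
})

test_that("minus-strand rows are mirror images of plus-strand rows", {
  set.seed(56)
  tr <- random_track(c(c1 = 4000L))
  plus <- interval_set("c1", 2000, 2001, strand = "+")
  minus <- interval_set("c1", 2000, 2001, strand = "-")
  p1 <- extract_matrix(tr, plus, 300, 10)$values[1, ]
  p2 <- extract_matrix(tr, minus, 300, 10)$values[1, ]
  expect_equal(p2, rev(p1))
})

test_that("extract_matrix validates geometry and chromosome names", {
  tr <- coverage_track(list(chr1 = rep(1, 100)))
  a <- interval_set("chr1", 50, 51)
  expect_error(extract_matrix(tr, a, flank_bp = 25, bin_width = 10),
               "divisible")
  expect_error(extract_matrix(tr, interval_set("chrX", 5, 6), 20, 10),
               "chrX")
})
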