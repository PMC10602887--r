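test_that("enhancer calls respect half-open overlap semantics", {
  enh <- interval_set("chr1", c(0, 0), c(500, 500),
                      name = c("e1", "e2"))
  calls <- call_enhancers(enh[1, ], interval_set("chr1", 0, 500,
                                                 name = "arA"))
  expect_true(calls$ar_positive)
  expect_equal(calls$ar_peak_ids, "arA")

  calls2 <- call_enhancers(enh[1, ], interval_set("chr1", 500, 600))
  expect_false(calls2$ar_positive)
  expect_equal(calls2$ar_peak_ids, "")
  expect_warning(call_enhancers(empty_set <- interval_set(character(0),
                                                          integer(0),
                                                          integer(0)),
                                enh), "empty")
})

test_that("AR-positive flags match the all-pairs oracle on random peaks", {
  set.seed(80)
  enh <- random_interval_set(1000, chrom_len = 500000)
  ar <- random_interval_set(1000, chrom_len = 500000)
  calls <- call_enhancers(enh, ar, min_overlap_bp = 1)
  expect_identical(calls$ar_positive, oracle_overlap(enh, ar, 1))
  calls50 <- call_enhancers(enh, ar, min_overlap_bp = 50)
  expect_identical(calls50$ar_positive, oracle_overlap(enh, ar, 50))
  # flag is true iff at least one AR peak id was recorded
  expect_identical(calls$ar_positive, nzchar(calls$ar_peak_ids))
})

make_calls <- function(chrom, start, end, ar_positive,
                       ids = sprintf("e%03d", seq_along(start))) {
  out <- data.frame(enhancer_id = ids, chrom = chrom, start = start,
                    end = end, ar_positive = ar_positive,
                    ar_peak_ids = ifelse(ar_positive, "ar", ""),
                    stringsAsFactors = FALSE)
  class(out) <- c("enhancer_calls", "data.frame")
  out
}

test_that("nearest linking handles containment and the hand-computed case", {
  genes <- gene_records(c("gin", "gmid"), "chr1", c(40, 1000),
                        c(1040, 2000), c("+", "+"))
  genes$tss <- c(50L, 1000L)  # place anchors explicitly
  enh <- make_calls("chr1", c(0, 2000), c(100, 2100), c(TRUE, TRUE))
  links <- link_nearest(genes, enh)
  expect_equal(links$distance_bp, c(0L, 901L))
  expect_equal(links$enhancer_id, c("e001", "e001"))
  expect_equal(links$direction, c("overlapping", "upstream"))
})

test_that("direction is reported relative to gene strand", {
  enh <- make_calls("chr1", 5000, 5100, TRUE)
  plus <- gene_records("gp", "chr1", 10000, 11000, "+")
  minus <- gene_records("gmn", "chr1", 10000, 11000, "-")
  expect_equal(link_nearest(plus, enh)$direction, "upstream")
  # for the minus gene the TSS is at 10999 and the enhancer lies 3' of it
  expect_equal(link_nearest(minus, enh)$direction, "downstream")
})

test_that("random linking matches the exhaustive oracle with tie-breaks", {
  set.seed(81)
  for (rep in 1:10) {
    n_genes <- sample(50:200, 1)
    n_enh <- sample(20:100, 1)
    genes <- gene_records(sprintf("g%03d", seq_len(n_genes)),
                          sample(c("c1", "c2"), n_genes, TRUE),
                          s <- sample.int(2e5, n_genes),
                          s + sample.int(5000, n_genes),
                          sample(c("+", "-"), n_genes, TRUE))
    enh <- make_calls(sample(c("c1", "c2"), n_enh, TRUE),
                      es <- sample.int(2e5, n_enh),
                      es + sample.int(800, n_enh),
                      runif(n_enh) < 0.5)
    links <- suppressMessages(link_nearest(genes, enh))
    oracle <- oracle_nearest(genes, enh)
    expect_equal(nrow(links), if (is.null(oracle)) 0L else nrow(oracle))
    if (nrow(links) > 0) {
      expect_identical(links$gene_id, oracle$gene_id)
      expect_identical(links$enhancer_id, oracle$enhancer_id)
      expect_identical(links$distance_bp, oracle$distance_bp)
    }
    # dropping the AR restriction can only bring enhancers closer
    all_links <- suppressMessages(link_nearest(genes, enh,
                                               require_ar_positive = FALSE))
    common <- intersect(links$gene_id, all_links$gene_id)
    expect_true(all(
      all_links$distance_bp[match(common, all_links$gene_id)] <=
        links$distance_bp[match(common, links$gene_id)]))
    # determinism, including tie-breaks
    again <- suppressMessages(link_nearest(genes, enh))
    expect_identical(links, again)
  }
})

test_that("distance zero and direction overlapping coincide", {
  set.seed(82)
  genes <- gene_records(sprintf("g%02d", 1:50), "c1",
                        s <- sample.int(5e4, 50), s + 1000,
                        sample(c("+", "-"), 50, TRUE))
  enh <- make_calls("c1", es <- sample.int(5e4, 30), es + 500,
                    rep(TRUE, 30))
  links <- suppressMessages(link_nearest(genes, enh))
  expect_identical(links$distance_bp == 0L,
                   links$direction == "overlapping")
})

test_that("link summaries use interpolated medians", {
  mk_links <- function(d) {
    n <- length(d)
    out <- data.frame(gene_id = paste0("g", seq_len(n)),
                      enhancer_id = rep("e", n),
                      enhancer_chrom = rep("c1", n),
                      enhancer_start = rep(0L, n),
                      enhancer_end = rep(10L, n),
                      distance_bp = d,
                      direction = ifelse(d == 0, "overlapping", "upstream"),
                      stringsAsFactors = FALSE)
    class(out) <- c("enhancer_links", "data.frame")
    out
  }
  expect_equal(link_summary(mk_links(c(0, 10, 20)))$median_distance_bp, 10)
  expect_equal(link_summary(mk_links(c(0, 10)))$median_distance_bp, 5)
  s <- link_summary(mk_links(c(0, 0, 30)))
  expect_equal(s$fraction_overlapping, 2 / 3)
  expect_equal(s$mean_distance_bp, 10)
  expect_error(link_summary(mk_links(c(1, 2))[0, ]), "no links")

  set.seed(83)
  d <- sample.int(1e6, 101)
  expect_equal(link_summary(mk_links(d))$median_distance_bp, sort(d)[51])
})
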