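test_that("geometric profile reproduces identical rows and the hand case", {
  v <- c(0, 1, 2.5, 7)
  pm <- make_pm(matrix(rep(v, each = 5), nrow = 5))
  gp <- geometric_profile(pm)
  expect_equal(gp$gm, v)
  expect_equal(gp$n, rep(5L, 4))

  # two rows {0, 8} with pseudocount 1: exp((ln1 + ln9)/2) - 1 = 2
  pm <- make_pm(matrix(c(0, 8), nrow = 2, ncol = 1))
  expect_equal(geometric_profile(pm, pseudocount = 1)$gm, 2)

  expect_error(geometric_profile(make_pm(matrix(numeric(0), 0, 3))),
               "empty")
  expect_error(geometric_profile(pm, pseudocount = 0), "positive")
})

test_that("per-bin geometric mean never exceeds the arithmetic mean", {
  set.seed(60)
  m <- matrix(rexp(200 * 50, rate = 0.2), nrow = 200)
  gp <- geometric_profile(make_pm(m), pseudocount = 1)
  am <- colMeans(m + 1) - 1
  expect_true(all(gp$gm <= am + 1e-12))
  # and matches the direct per-column oracle
  for (j in c(1, 25, 50))
    expect_equal(gp$gm[j], oracle_geometric_mean(m[, j]), tolerance = 1e-12)
})

test_that("geometric mean resists a single outlier region", {
  truth <- 5
  for (K in c(10, 100, 1000)) {
    m <- matrix(truth, nrow = 100, ncol = 10)
    m[1, ] <- truth * K
    gp <- geometric_profile(make_pm(m))
    am <- colMeans(m)
    expect_true(all(abs(gp$gm - truth) < abs(am - truth)))
  }
})

test_that("pseudocounted GM approaches scale equivariance as pc -> 0", {
  set.seed(61)
  m <- matrix(runif(100 * 20, 1, 10), nrow = 100)
  a <- 4.2
  g1 <- geometric_profile(make_pm(m), pseudocount = 1e-9)$gm
  g2 <- geometric_profile(make_pm(a * m), pseudocount = 1e-9)$gm
  expect_equal(g2, a * g1, tolerance = 1e-6)
})

test_that("masked cells are excluded and fully masked bins propagate NA", {
  m <- matrix(c(2, NA, 4, NA, NA, NA), nrow = 3)
  gp <- geometric_profile(make_pm(m))
  expect_equal(gp$n, c(2L, 0L))
  expect_equal(gp$gm[1], oracle_geometric_mean(c(2, 4)))
  expect_true(is.na(gp$gm[2]))
})

test_that("metagene profiles are length-invariant under constant coverage", {
  tr <- coverage_track(list(chr1 = rep(2.5, 220000)))
  genes <- gene_records(c("short", "long"), "chr1",
                        c(5000, 20000), c(6000, 120000), c("+", "-"))
  mm <- metagene_matrix(tr, genes, body_bins = 100, flank_bp = 1000,
                        flank_bin_width = 10)
  expect_equal(ncol(mm$values), 100 + 200)
  expect_true(all(mm$values == 2.5))
  expect_equal(mm$values[1, ], mm$values[2, ])
})

test_that("metagene body bins match the fractional-apportionment oracle", {
  set.seed(62)
  L <- 30000
  v <- seq(0, 10, length.out = L)  # linear ramp
  tr <- coverage_track(list(chr1 = v), library_size = 1)
  gs <- 12345; ge <- gs + 777     # length not divisible by body bins
  genes <- gene_records("g1", "chr1", gs, ge, "+")
  mm <- metagene_matrix(tr, genes, body_bins = 50, flank_bp = 1000,
                        flank_bin_width = 10)
  body <- mm$values[1, 101:150]
  expect_equal(body, oracle_body_bins(v, gs, ge, 50), tolerance = 1e-9)

  # random coverage too
  v2 <- runif(L, 0, 8)
  tr2 <- coverage_track(list(chr1 = v2), library_size = 1)
  mm2 <- metagene_matrix(tr2, genes, body_bins = 50)
  expect_equal(mm2$values[1, 101:150], oracle_body_bins(v2, gs, ge, 50),
               tolerance = 1e-9)
})

test_that("a minus-strand gene over mirrored coverage matches its plus twin", {
  set.seed(63)
  L <- 20000
  v <- runif(L, 0, 5)
  tr_fwd <- coverage_track(list(chr1 = v), library_size = 1)
  tr_rev <- coverage_track(list(chr1 = rev(v)), library_size = 1)
  gs <- 8000; ge <- 9500
  plus <- gene_records("gp", "chr1", gs, ge, "+")
  minus <- gene_records("gm", "chr1", L - ge, L - gs, "-")
  r1 <- metagene_matrix(tr_fwd, plus)$values[1, ]
  r2 <- metagene_matrix(tr_rev, minus)$values[1, ]
  expect_equal(r2, r1, tolerance = 1e-9)
})

test_that("short genes warn but stay defined; flank overhangs are masked", {
  tr <- coverage_track(list(chr1 = rep(1, 3000)))
  tiny <- gene_records("t", "chr1", 1500, 1550, "+")
  expect_warning(mm <- metagene_matrix(tr, tiny, body_bins = 100),
                 "shorter")
  expect_true(all(is.finite(mm$values[1, 101:200])))
  edge <- gene_records("e", "chr1", 100, 1100, "+")
  mm2 <- metagene_matrix(tr, edge, flank_bp = 1000, flank_bin_width = 100)
  expect_true(any(is.na(mm2$values[1, 1:10])))  # upstream flank off the end
})

test_that("boxplot summaries use interpolated quartiles and 1.5 IQR whiskers", {
  b <- boxplot_summary(c(1, 2, 3, 4, 5))
  expect_equal(b$median, 3); expect_equal(b$q1, 2); expect_equal(b$q3, 4)
  expect_equal(b$whisker_low, 1); expect_equal(b$whisker_high, 5)
  expect_length(b$outliers, 0)

  b1 <- boxplot_summary(7)
  expect_equal(b1$median, 7); expect_equal(b1$q1, 7); expect_equal(b1$q3, 7)
  expect_length(b1$outliers, 0)
  expect_error(boxplot_summary(numeric(0)), "empty")

  set.seed(64)
  x <- c(rnorm(200), 50)  # one far outlier
  b2 <- boxplot_summary(x)
  xs <- sort(x)
  expect_equal(b2$median, xs[101])  # sort-and-pick oracle, n = 201
  expect_equal(b2$q1, unname(quantile(x, 0.25)))
  expect_true(50 %in% b2$outliers)
  expect_true(b2$q1 <= b2$median && b2$median <= b2$q3)
})

test_that("profile overlays export and re-import losslessly", {
  set.seed(65)
  m1 <- matrix(rexp(40), nrow = 4)
  m2 <- matrix(rexp(40), nrow = 4)
  p1 <- geometric_profile(make_pm(m1))
  p2 <- geometric_profile(make_pm(m2))
  single <- overlay_profiles(list(only = p1))
  expect_equal(nrow(single), 10L)

  path <- withr::local_tempfile(fileext = ".tsv")
  overlay_profiles(list(t0 = p1, t4 = p2, t12 = p1, t24 = p2), path = path)
  back <- read_profile_tsv(path)
  expect_equal(nrow(back), 40L)
  expect_equal(unique(back$condition), c("t0", "t4", "t12", "t24"))
  expect_identical(back$gm[back$condition == "t4"], p2$gm)

  short <- geometric_profile(make_pm(matrix(1, 2, 5)))
  expect_error(overlay_profiles(list(a = p1, b = short)), "geometry")
})
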