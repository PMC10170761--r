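const_track <- function(v, L = 10000, bin = 50, lib = 1e6) {
  lay <- genome_layout("chrS", L)
  signal_track(lay, bin, list(chrS = rep(v, ceiling(L / bin))),
               library_size = lib)
}

test_that("RPKM conversion scales by bin kb and library millions", {
  tr <- const_track(10, lib = 1e6)
  tr$counts$chrS[3] <- 10
  r <- to_rpkm(tr)
  expect_equal(r$counts$chrS[3], 10 / (50 / 1000) / (1e6 / 1e6)) # 200
  tr0 <- const_track(0)
  expect_true(all(to_rpkm(tr0)$counts$chrS == 0))
  tr2 <- const_track(10, lib = 2e6)
  expect_equal(to_rpkm(tr2)$counts$chrS, to_rpkm(const_track(10))$counts$chrS / 2)
  expect_error(signal_track(genome_layout("chrS", 100), 50,
                            list(chrS = c(0, 0)), library_size = 0),
               "library_size")
})

test_that("reference-point matrix is constant on constant tracks", {
  tr <- const_track(4)
  anchors <- data.frame(chrom = "chrS", pos = c(3000, 6000),
                        strand = c("+", "-"))
  m <- reference_point_matrix(tr, anchors, flank = 1000, bin = 50)
  expect_equal(dim(m$values), c(2, 40))
  expect_true(all(m$values == 4))
})

test_that("a spike at the anchor lands at the center, mirrored on minus", {
  tr <- const_track(0)
  tr$counts$chrS[3000 / 50 + 1] <- 100 # covers bp [3000, 3050)
  anchors <- data.frame(chrom = "chrS", pos = c(3000, 3000),
                        strand = c("+", "-"))
  m <- reference_point_matrix(tr, anchors, flank = 1000, bin = 50)
  ctr <- 1000 / 50 # column index just left of the anchor
  expect_equal(which.max(m$values[1, ]), ctr + 1)
  expect_equal(which.max(m$values[2, ]), ctr) # reversed
})

test_that("cells past the chromosome edge are missing, not zero", {
  tr <- const_track(5, L = 5000)
  anchors <- data.frame(chrom = c("chrS", "nochr"), pos = c(400, 100),
                        strand = "+")
  m <- reference_point_matrix(tr, anchors, flank = 1000, bin = 100)
  expect_true(all(is.na(m$values[1, 1:6]))) # window starts at -600
  expect_true(all(m$values[1, 7:20] == 5))
  expect_true(all(is.na(m$values[2, ]))) # off-layout anchor flagged missing
})

test_that("reference-point matrix equals the per-bp oracle", {
  set.seed(401)
  tr <- const_track(0, L = 50000)
  tr$counts$chrS <- runif(1000, 0, 10)
  tr <- to_rpkm(tr)
  sbp <- perbp_signal(tr, "chrS")
  anchors <- data.frame(chrom = "chrS",
                        pos = sample(2000:48000, 50),
                        strand = sample(c("+", "-"), 50, replace = TRUE))
  m <- reference_point_matrix(tr, anchors, flank = 2000, bin = 50)
  for (i in seq_len(50)) {
    want <- perbp_refpoint_row(sbp, anchors$pos[i], anchors$strand[i],
                               2000, 50)
    expect_equal(m$values[i, ], want, tolerance = 1e-9)
  }
})

test_that("scaled matrix is length-invariant and matches the per-bp oracle", {
  # constant track: constant matrix regardless of gene length
  tr <- const_track(7, L = 100000)
  genes <- gene_models(c("a", "b"), "chrS", c(10000, 50000),
                       c(11000, 60000), "+")
  m <- scaled_region_matrix(tr, genes, body_bins = 20, flank = 1000, bin = 50)
  expect_true(all(m$values == 7))
  # identical relative shape -> identical rows
  tr2 <- const_track(0, L = 100000)
  v <- tr2$counts$chrS
  # gene a: 1 kb body [10000,11000); gene b: 10 kb body [50000,60000)
  v[(10000 / 50 + 1):(10500 / 50)] <- 3  # first half of body a
  v[(50000 / 50 + 1):(55000 / 50)] <- 3  # first half of body b
  tr2$counts$chrS <- v
  m2 <- scaled_region_matrix(tr2, genes, body_bins = 20, flank = 0, bin = 50)
  expect_equal(m2$values[1, ], m2$values[2, ])
  # random track vs per-bp oracle (gene lengths divisible by body_bins)
  set.seed(402)
  tr3 <- const_track(0, L = 50000)
  tr3$counts$chrS <- runif(1000, 0, 5)
  sbp <- perbp_signal(tr3, "chrS")
  g3 <- gene_models(c("p", "m"), "chrS", c(12000, 30000),
                    c(12000 + 2600, 30000 + 5200), c("+", "-"))
  m3 <- scaled_region_matrix(tr3, g3, body_bins = 13, flank = 1000, bin = 50)
  for (i in 1:2)
    expect_equal(m3$values[i, ],
                 perbp_scaled_row(sbp, g3$start[i], g3$end[i], g3$strand[i],
                                  13, 1000, 50),
                 tolerance = 1e-9)
})

test_that("matrix construction commutes with RPKM scaling", {
  set.seed(403)
  tr <- const_track(0, L = 30000, lib = 5e5)
  tr$counts$chrS <- rpois(600, 3) * 1.0
  anchors <- data.frame(chrom = "chrS", pos = c(5000, 12000, 25000),
                        strand = c("+", "-", "+"))
  m_raw <- reference_point_matrix(tr, anchors, flank = 2000, bin = 100)
  m_rpkm <- reference_point_matrix(to_rpkm(tr), anchors, flank = 2000,
                                   bin = 100)
  f <- 1 / (tr$bin_size / 1000) / (tr$library_size / 1e6)
  expect_equal(m_rpkm$values, m_raw$values * f, tolerance = 1e-12)
  genes <- gene_models("g", "chrS", 8000, 12000, "+")
  s_raw <- scaled_region_matrix(tr, genes, body_bins = 10, flank = 500,
                                bin = 50)
  s_rpkm <- scaled_region_matrix(to_rpkm(tr), genes, body_bins = 10,
                                 flank = 500, bin = 50)
  expect_equal(s_rpkm$values, s_raw$values * f, tolerance = 1e-12)
})

test_that("row sums conserve the windowed track total", {
  set.seed(404)
  tr <- const_track(0, L = 20000)
  tr$counts$chrS <- runif(400, 0, 4)
  sbp <- perbp_signal(tr, "chrS")
  pos <- 10000
  m <- reference_point_matrix(tr, data.frame(chrom = "chrS", pos = pos,
                                             strand = "+"),
                              flank = 1000, bin = 50)
  expect_equal(sum(m$values[1, ]) * 50,
               sum(sbp[(pos - 1000 + 1):(pos + 1000)]),
               tolerance = 1e-9)
})

test_that("average profile excludes missing cells and flags empty columns", {
  m <- signal_matrix(rbind(c(0, 0, NA), c(2, 2, NA)),
                     data.frame(pos = c(1, 2)), "reference_point")
  pr <- average_profile(m)
  expect_equal(pr$mean[1:2], c(1, 1))
  expect_true(is.na(pr$mean[3]))
  expect_equal(pr$n, c(2, 2, 0))
  single <- signal_matrix(matrix(1:4, 1), data.frame(pos = 1),
                          "reference_point")
  expect_equal(average_profile(single)$mean, 1:4)
})

test_that("heatmap rows sort by descending mean with coordinate ties", {
  m <- signal_matrix(rbind(c(3, 3), c(1, 1), c(2, 2)),
                     data.frame(chrom = "chrS", pos = c(10, 20, 30)),
                     "reference_point")
  expect_equal(order_heatmap_rows(m), c(1, 3, 2))
  eq <- signal_matrix(matrix(5, 4, 2),
                      data.frame(chrom = "chrS", pos = c(40, 10, 30, 20)),
                      "reference_point")
  expect_equal(order_heatmap_rows(eq), c(2, 4, 3, 1)) # by coordinate
  set.seed(405)
  rnd <- signal_matrix(matrix(runif(60), 10, 6),
                       data.frame(chrom = "chrS", pos = 1:10),
                       "reference_point")
  perm <- order_heatmap_rows(rnd)
  expect_true(all(diff(rowMeans(rnd$values)[perm]) <= 0))
})

test_that("strand-randomized profile is the average of both orientations", {
  set.seed(406)
  tr <- const_track(0, L = 30000)
  tr$counts$chrS <- runif(600, 0, 3)
  pos <- sample(5000:25000, 20)
  mp <- reference_point_matrix(tr, data.frame(chrom = "chrS", pos = pos,
                                              strand = "+"),
                               flank = 1000, bin = 50)
  mm <- reference_point_matrix(tr, data.frame(chrom = "chrS", pos = pos,
                                              strand = "-"),
                               flank = 1000, bin = 50)
  both <- reference_point_matrix(
    tr, data.frame(chrom = rep("chrS", 40), pos = c(pos, pos),
                   strand = rep(c("+", "-"), each = 20)),
    flank = 1000, bin = 50)
  expect_equal(average_profile(both)$mean,
               (average_profile(mp)$mean + average_profile(mm)$mean) / 2,
               tolerance = 1e-12)
})
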