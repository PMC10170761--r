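make_pc <- function(name, s, e, chrom = "chrS") {
  peak_collection(name, gintervals(chrom, s, e))
}

test_that("identical replicates are fully concordant; disjoint ones are not", {
  a <- make_pc("r1", c(0, 1000, 5000), c(400, 1400, 5400))
  conc <- replicate_concordance(list(a, a, a))
  expect_equal(conc$common_peak_count, 3)
  expect_true(all(conc$pairwise_pearson == 1))
  b <- make_pc("r2", c(10000, 20000), c(10400, 20400))
  expect_equal(replicate_concordance(list(a, b))$common_peak_count, 0)
  expect_error(replicate_concordance(list(a)), "at least 2")
  expect_error(replicate_concordance(
    list(a, peak_collection("empty", gintervals("x", 1, 2)[0, ]))), "empty")
})

test_that("concordance recovers a planted sharing rate and exact pearson", {
  set.seed(301)
  n <- 500
  starts <- sort(sample(seq(0, 2e6, by = 3000), n))
  shared <- runif(n) < 0.9
  r1 <- peak_collection("r1", gintervals("chrS", starts, starts + 400))
  s2 <- starts[shared] + round(rnorm(sum(shared), 0, 20))
  r2 <- peak_collection("r2", gintervals("chrS", pmax(0, s2), pmax(0, s2) + 400))
  conc <- replicate_concordance(list(r1, r2))
  expect_lt(abs(conc$common_peak_count - sum(shared)), 0.05 * sum(shared))
  # pearson equals the direct covariance formula
  lay <- genome_layout("chrS", 3e6)
  tr1 <- simulate_track(r1, sim_config(seed = 5), lay, stream = "a")
  tr2 <- simulate_track(r2, sim_config(seed = 5), lay, stream = "b")
  conc2 <- replicate_concordance(list(r1, r2), tracks = list(tr1, tr2))
  union <- merge_intervals(rbind(r1$intervals, r2$intervals), gap = 0)
  bins <- tssmap:::tile_intervals(union, 50)
  v1 <- track_mean(to_rpkm(tr1), bins$chrom, bins$start, bins$end)
  v2 <- track_mean(to_rpkm(tr2), bins$chrom, bins$start, bins$end)
  expect_equal(conc2$pairwise_pearson[1, 2], pearson_direct(v1, v2),
               tolerance = 1e-12)
})

test_that("consensus keeps only peaks supported by every replicate", {
  one <- make_pc("r1", 100, 500)
  expect_equal(as.data.frame(consensus_peaks(list(one, one, one))$intervals
  )[, c("start", "end")],
  data.frame(start = 100, end = 500))
  # present in 2 of 3 replicates -> excluded
  r1 <- make_pc("r1", c(100, 5000), c(500, 5400))
  r2 <- make_pc("r2", c(120, 5050), c(520, 5450))
  r3 <- make_pc("r3", 130, 530)
  cons <- consensus_peaks(list(r1, r2, r3))
  expect_equal(nrow(cons$intervals), 1)
  expect_equal(cons$intervals$start, 100)
  expect_equal(cons$intervals$end, 530)
  expect_error(consensus_peaks(list(r1)), "at least 2")
})

test_that("consensus equals the brute-force mask oracle on random triplicates", {
  set.seed(302)
  for (rep in 1:8) {
    reps <- lapply(1:3, function(i)
      peak_collection(sprintf("r%d", i), random_intervals(sample(10:40, 1))))
    got <- consensus_peaks(reps)$intervals
    want <- mask_consensus(reps, 1e5)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("consensus of identical collections equals a gap-0 merge", {
  set.seed(303)
  s <- random_intervals(40)
  pc <- peak_collection("s", s)
  got <- consensus_peaks(list(pc, pc, pc))$intervals
  want <- merge_intervals(s, 0)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
})

test_that("TSS proximity uses the midpoint and is strand-aware", {
  genes <- gene_models(c("gp", "gm"), "chrS", c(50000, 90000),
                       c(60000, 95000), c("+", "-"))
  # plus gene TSS at 50000; peak midpoint 999 bp away (inside window)
  near <- gintervals("chrS", 50949, 51050) # midpoint 50999
  far <- gintervals("chrS", 50951, 51052)  # midpoint 51001
  prox <- tss_proximity(near, genes, window = 1000)
  expect_true(prox$per_peak$proximal)
  expect_equal(prox$per_peak$signed_distance, 999)
  expect_false(tss_proximity(far, genes, window = 1000)$per_peak$proximal)
  # minus gene TSS at 94999; a peak upstream in genome is downstream of TSS
  pk <- gintervals("chrS", 94400, 94600) # midpoint 94500, 499 bp left of TSS
  pp <- tss_proximity(pk, genes, window = 1000)$per_peak
  expect_equal(pp$nearest_gene, "gm")
  expect_equal(pp$signed_distance, 499)
  expect_error(tss_proximity(near, genes[0, ]), "gene")
})

test_that("proximity percent is monotone non-decreasing in the window", {
  set.seed(304)
  genes <- gene_models(sprintf("g%d", 1:20), "chrS",
                       seq(1000, 96000, by = 5000),
                       seq(1000, 96000, by = 5000) + 2000, "+")
  peaks <- random_intervals(100)
  pct <- vapply(c(100, 500, 1000, 2000, 5000), function(w)
    tss_proximity(peaks, genes, window = w)$summary$percent, numeric(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("region size bins use half-open boundaries and sum to n", {
  counts <- bin_region_sizes(c(1500, 3000, 7000, 12000))
  expect_equal(unname(counts), c(1, 1, 1, 1))
  expect_equal(unname(bin_region_sizes(2000)), c(0, 1, 0, 0)) # exactly 2 kb
  expect_equal(unname(bin_region_sizes(10000)), c(0, 0, 0, 1))
  set.seed(305)
  lens <- sample(100:20000, 500)
  expect_equal(sum(bin_region_sizes(lens)), 500)
})

test_that("accessible co-occupancy handles identity, disjoint and planted cases", {
  a <- make_pc("p", c(0, 5000), c(400, 5400))
  self <- accessible_cooccupancy(a, a)
  expect_equal(self$pct_peaks_near_accessible, 100)
  expect_equal(self$pct_accessible_occupied, 100)
  b <- make_pc("acc", c(50000, 80000), c(50400, 80400))
  off <- accessible_cooccupancy(a, b)
  expect_equal(off$pct_peaks_near_accessible, 0)
  expect_equal(off$n_accessible_occupied, 0)
  # planted: peaks on exactly 170 of 1000 accessible regions
  starts <- seq(0, by = 3000, length.out = 1000)
  acc <- make_pc("acc", starts, starts + 500)
  pk <- make_pc("p", starts[1:170] + 100, starts[1:170] + 300)
  got <- accessible_cooccupancy(pk, acc)
  expect_equal(got$pct_accessible_occupied, 17)
  expect_equal(got$n_accessible_occupied, 170)
})

test_that("gene occupancy classes honor the inclusive broad threshold", {
  # gene 1000 bp with a single 250 bp TSS-proximal peak: coverage exactly 0.25
  g <- gene_models("g1", "chrS", 10000, 11000, "+")
  pk <- gintervals("chrS", 10000, 10250)
  cls <- classify_gene_occupancy(pk, g)
  expect_equal(cls$class, "broad")
  expect_equal(cls$body_coverage, 0.25)
  # long gene with only a TSS peak: narrow
  g2 <- gene_models("g2", "chrS", 10000, 20000, "+")
  cls2 <- classify_gene_occupancy(gintervals("chrS", 10000, 10400), g2)
  expect_equal(cls2$class, "narrow")
  expect_equal(cls2$body_coverage, 0.04)
  # no TSS-proximal peak: unoccupied even with body coverage
  g3 <- gene_models("g3", "chrS", 10000, 14000, "+")
  cls3 <- classify_gene_occupancy(gintervals("chrS", 12000, 13900), g3)
  expect_equal(cls3$class, "unoccupied")
  expect_false(cls3$tss_peak)
})

test_that("broad count is monotone non-increasing in the broad threshold", {
  sim <- simulate_all(small_sim_config(seed = 31))
  ths <- c(0.1, 0.25, 0.5, 0.9)
  n_broad <- vapply(ths, function(th)
    sum(classify_gene_occupancy(sim$canonical, sim$genes,
                                broad_threshold = th)$class == "broad"),
    numeric(1))
  expect_true(all(diff(n_broad) <= 0))
})

test_that("broad genes are shorter than narrow genes when planted that way", {
  sim <- simulate_all(small_sim_config(seed = 32))
  cls <- classify_gene_occupancy(sim$canonical, sim$genes)
  len <- gene_length(sim$genes)
  expect_lt(median(len[cls$class == "broad"]),
            median(len[cls$class == "narrow"]))
})
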