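test_that("genome simulation is deterministic and respects its contract", {
  cfg <- small_sim_config(seed = 21)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$genes), 300)
  # non-overlapping bodies per chromosome
  for (ch in g1$layout$chrom) {
    gg <- g1$genes[g1$genes$chrom == ch, ]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  check_layout(as_gintervals(as.data.frame(g1$genes)[, c("chrom", "start",
                                                         "end")]),
               g1$layout)
  expect_error(simulate_genome(sim_config(seed = 1, n_chroms = 1,
                                          chrom_length = 1e5, n_genes = 500)),
               "density")
})

test_that("gene lengths match the log-normal expectation at scale", {
  cfg <- sim_config(seed = 22, n_genes = 5000, n_chroms = 8,
                    chrom_length = 2e7)
  g <- simulate_genome(cfg)
  expected <- exp(cfg$gene_len_meanlog + cfg$gene_len_sdlog^2 / 2)
  expect_lt(abs(mean(gene_length(g$genes)) - expected) / expected, 0.1)
})

test_that("expression zeros appear at the configured rate", {
  cfg <- sim_config(seed = 23, n_genes = 4000, n_chroms = 8,
                    chrom_length = 1e7, p_zero_tpm = 0.25)
  g <- simulate_genome(cfg)
  ex <- simulate_expression(g$genes, cfg)
  expect_lt(abs(mean(ex$truth$true_tpm == 0) - 0.25), 0.02)
  all_zero <- simulate_expression(g$genes, sim_config(seed = 23,
                                                      p_zero_tpm = 1))
  expect_true(all(all_zero$truth$true_tpm == 0))
  ex2 <- simulate_expression(g$genes, cfg)
  expect_identical(ex, ex2)
})

test_that("zero jitter and zero dropout make replicates identical", {
  cfg <- small_sim_config(seed = 24, rep_jitter_sd = 0, rep_drop_rate = 0)
  g <- simulate_genome(cfg)
  ex <- simulate_expression(g$genes, cfg)
  pk <- simulate_peaks(g$genes, ex$truth, cfg, g$layout)
  iv <- lapply(pk$replicates, function(r)
    as.data.frame(r$intervals)[, c("chrom", "start", "end")])
  expect_identical(iv[[1]], iv[[2]])
  expect_identical(iv[[1]], iv[[3]])
  cons <- consensus_peaks(pk$replicates)
  merged1 <- merge_intervals(pk$replicates[[1]]$intervals, 0)
  expect_equal(cons$intervals$start, merged1$start)
  expect_equal(cons$intervals$end, merged1$end)
})

test_that("an impossible occupancy logistic yields only background peaks", {
  cfg <- small_sim_config(seed = 25, occ_intercept = -1e9, occ_slope = 0)
  g <- simulate_genome(cfg)
  ex <- simulate_expression(g$genes, cfg)
  pk <- simulate_peaks(g$genes, ex$truth, cfg, g$layout)
  expect_true(all(pk$truth$peaks$origin == "background" |
                    nrow(pk$truth$peaks) == 0))
})

test_that("peak offsets concentrate at the planted +1 nucleosome mode", {
  cfg <- sim_config(seed = 26)
  g <- simulate_genome(cfg)
  ex <- simulate_expression(g$genes, cfg)
  pk <- simulate_peaks(g$genes, ex$truth, cfg, g$layout)
  tssp <- pk$truth$peaks[pk$truth$peaks$origin == "tss", ]
  prox <- tss_proximity(as_gintervals(tssp[, c("chrom", "start", "end")]),
                        g$genes)
  d <- prox$per_peak$signed_distance
  # primary mode downstream, secondary upstream, ~3:1 weights
  expect_gt(mean(d > 0), 0.65)
  expect_lt(abs(median(d[d > 0]) - cfg$offset_primary), 40)
  expect_lt(abs(median(d[d < 0]) - cfg$offset_secondary), 40)
  # widths recover the configured mean
  expect_lt(abs(mean(tssp$end - tssp$start) - cfg$peak_width_mean), 15)
})

test_that("simulated tracks are reproducible with planted signal shape", {
  cfg <- small_sim_config(seed = 27)
  g <- simulate_genome(cfg)
  ex <- simulate_expression(g$genes, cfg)
  pk <- simulate_peaks(g$genes, ex$truth, cfg, g$layout)
  tr1 <- simulate_track(pk$canonical, cfg, g$layout)
  tr2 <- simulate_track(pk$canonical, cfg, g$layout)
  expect_identical(tr1, tr2)
  # pure background has mean ~ lambda
  bg <- simulate_track(pk$canonical$intervals[0, ], cfg, g$layout)
  expect_lt(abs(mean(unlist(bg$counts)) - cfg$background_lambda), 0.01)
  # profile argmax within 1 bin of the planted +150 bp mode
  occg <- g$genes[pk$truth$genes$class != "unoccupied", ]
  pr <- average_profile(reference_point_matrix(to_rpkm(tr1),
                                               anchors_from_tss(occg),
                                               flank = 2000, bin = 50))
  rel_center <- -2000 + 50 * (which.max(pr$mean) - 0.5)
  expect_lte(abs(rel_center - cfg$offset_primary), 50 + 25)
})

test_that("DE generator plants an exactly recoverable consistent core", {
  cfg <- small_sim_config(seed = 28, de_core_size = 40, de_core_down = 25)
  g <- simulate_genome(cfg)
  de <- simulate_de_tables(g$genes, cfg)
  meta <- de_meta_intersection(de$tables, alpha = cfg$de_alpha)
  expect_setequal(meta$genes, de$truth$core)
  expect_equal(meta$counts$down, 25)
  expect_equal(meta$counts$up, 15)
  expect_equal(meta$counts$discordant, 0)
  avg <- average_de_stats(meta)
  expect_setequal(avg$gene_id[avg$direction == "down"], de$truth$down)
  # empty core -> empty intersection
  cfg0 <- small_sim_config(seed = 28, de_core_size = 0, de_extra_rate = 0.2)
  de0 <- simulate_de_tables(g$genes, cfg0)
  expect_equal(de_meta_intersection(de0$tables)$counts$consistent, 0)
  expect_identical(simulate_de_tables(g$genes, cfg)$tables, de$tables)
})

test_that("accessible regions plant the configured occupied fraction", {
  cfg <- small_sim_config(seed = 29)
  g <- simulate_genome(cfg)
  ex <- simulate_expression(g$genes, cfg)
  pk <- simulate_peaks(g$genes, ex$truth, cfg, g$layout)
  ac <- simulate_accessible(pk$truth$peaks, cfg, g$layout)
  got <- accessible_cooccupancy(pk$canonical, ac$accessible)
  expect_equal(got$n_accessible_occupied, ac$truth$n_occupied)
  expect_lt(abs(got$pct_accessible_occupied - 17), 0.5) # rounding of n only
})

test_that("Ct generator recovers planted folds exactly at zero noise", {
  sim0 <- simulate_ct(sim_config(seed = 30, ct_noise_sd = 0))
  res <- chip_qpcr_analysis(sim0$ct, "H3cs1", ref_condition = "WT")
  m <- merge(res$summary, sim0$truth, by = c("target", "condition"))
  expect_equal(m$mean_fold, m$true_fold, tolerance = 1e-12)
  expect_identical(simulate_ct(sim_config(seed = 30))$ct,
                   simulate_ct(sim_config(seed = 30))$ct)
})

test_that("emitted files parse back losslessly through the readers", {
  cfg <- small_sim_config(seed = 34)
  sim <- simulate_all(cfg)
  d <- withr::local_tempdir()
  write_bed(sim$canonical$intervals, file.path(d, "c.bed"))
  back <- read_bed(file.path(d, "c.bed"))
  expect_equal(back[, c("chrom", "start", "end")],
               as.data.frame(sim$canonical$intervals)[, c("chrom", "start",
                                                          "end")],
               ignore_attr = TRUE)
  write_gtf(sim$genes, file.path(d, "g.gtf"))
  g2 <- read_gtf(file.path(d, "g.gtf"))
  expect_equal(as.data.frame(g2), as.data.frame(sim$genes),
               ignore_attr = TRUE)
  write_tsv_table(sim$expr, file.path(d, "e.tsv"))
  expect_equal(read_tsv_table(file.path(d, "e.tsv")), sim$expr,
               tolerance = 1e-9)
})
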