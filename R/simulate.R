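#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: peaks
#' concentrated at TSSs of expressed genes with the primary mode at the +1
#' nucleosome (~ +150 bp) and a secondary mode at the -1 nucleosome
#' (~ -150 bp), mean peak width near 488 bp, 90% of peaks TSS-targeted, a
#' minority of short highly expressed genes carrying broad peak-positive
#' regions covering at least 25% of the gene body, three concordant
#' replicates, three-timepoint DE tables sharing a 672-gene consistent core
#' split 386 down / 286 up, and Ct values with 0.2-cycle noise.
#'
#' @param seed integer seed fixing every draw.
#' @param ... overrides for any default field (see the returned list).
#' @return A list with class `"sim_config"`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    # genome
    n_chroms = 4, chrom_length = 10e6,
    n_genes = 2000,
    gene_len_meanlog = log(3000), gene_len_sdlog = 0.7,
    # expression
    p_zero_tpm = 0.25, tpm_meanlog = log(10), tpm_sdlog = 1.2,
    n_expr_reps = 3, expr_rep_noise_sd = 0.1,
    # occupancy and peaks
    occ_intercept = -4, occ_slope = 2,
    peak_width_mean = 488, peak_width_sd = 80, peak_width_min = 50,
    offset_primary = 150, offset_secondary = -150,
    w_primary = 0.75, w_secondary = 0.25, offset_jitter_sd = 30,
    tss_target_fraction = 0.9, tss_window = 1000, background_min = 20,
    broad_fraction = 0.05, broad_max_gene_length = 10000,
    broad_cov_min = 0.25, broad_cov_max = 1.0,
    body_gap_min = 150, body_gap_max = 800,
    n_replicates = 3, rep_jitter_sd = 15, rep_drop_rate = 0.05,
    # accessible regions
    accessible_occupied_fraction = 0.17,
    accessible_width_mean = 500, accessible_width_sd = 100,
    # track
    track_bin = 50, peak_height = 20, background_lambda = 0.2,
    # DE tables
    de_core_size = 672, de_core_down = 386, de_extra_rate = 0.15,
    de_alpha = 0.05, n_timepoints = 3,
    # qPCR
    ct_noise_sd = 0.2, n_bio_reps = 3, n_tech_reps = 4,
    ct_baseline_range = c(18, 22),
    qpcr_true_folds = c(GENEA_TSS = 4, GENEB_TSS = 3, GENEC_TSS = 2.5,
                        CTSB_TSS = 3.5, CTSB_body = 2, gene_desert = 0.15),
    qpcr_knockdown_reduction = c(GENEA_TSS = 4, GENEB_TSS = 4, GENEC_TSS = 4,
                                 CTSB_TSS = 4, CTSB_body = 4, gene_desert = 1)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop_fmt("unknown sim_config field(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

#' Short content hash of a configuration
#'
#' Embedded in output file headers so that outputs are traceable to the
#' exact configuration that produced them.
#'
#' @param cfg any R object (typically a [sim_config()]).
#' @return 8-hex-character string.
#' @export
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967291
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Simulate a genome layout and non-overlapping gene models
#'
#' Gene lengths are log-normal; genes are assigned to chromosomes and placed
#' with random (uniformly partitioned) intergenic gaps so bodies never
#' overlap. Strands are random. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `layout` ([genome_layout()]) and `genes`
#'   ([gene_models()]).
#' @export
simulate_genome <- function(config) {
  with_stream(config$seed, "genome", {
    n <- config$n_genes
    lens <- round(rlnorm(n, config$gene_len_meanlog, config$gene_len_sdlog))
    lens <- pmax(lens, 200)
    chroms <- sprintf("chr%d", seq_len(config$n_chroms))
    layout <- genome_layout(chroms, rep(config$chrom_length, config$n_chroms))
    if (sum(lens) > 0.8 * sum(layout$length))
      stop_fmt("infeasible gene density: %d gene bp in %d genome bp",
               sum(lens), sum(layout$length))
    chrom_of <- sample(chroms, n, replace = TRUE)
    gene_list <- list()
    for (ch in chroms) {
      idx <- which(chrom_of == ch)
      if (!length(idx)) next
      l <- lens[idx]
      avail <- config$chrom_length - sum(l)
      if (avail < 0) stop_fmt("genes do not fit on %s", ch)
      g <- runif(length(idx) + 1)
      gaps <- floor(g / sum(g) * avail)
      starts <- cumsum(gaps[-length(gaps)]) + cumsum(c(0, l[-length(l)]))
      gene_list[[ch]] <- data.frame(idx = idx, start = starts,
                                    end = starts + l,
                                    stringsAsFactors = FALSE)
    }
    ord <- do.call(rbind, lapply(names(gene_list), function(ch)
      cbind(gene_list[[ch]], chrom = ch)))
    ord <- ord[order(ord$idx), ]
    genes <- gene_models(
      gene_id = sprintf("gene%04d", seq_len(n)),
      chrom = ord$chrom, start = ord$start, end = ord$end,
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
    list(layout = layout, genes = genes)
  })
}

#' Simulate a gene expression table
#'
#' Each gene's true TPM is 0 with probability `p_zero_tpm`, else a log-normal
#' draw; replicate columns add multiplicative log-normal noise.
#'
#' @param genes a [gene_models()] data frame.
#' @param config a [sim_config()].
#' @return list with `expr` (data frame gene_id + tpm_rep columns) and
#'   `truth` (data frame gene_id, true_tpm).
#' @export
simulate_expression <- function(genes, config) {
  with_stream(config$seed, "expression", {
    n <- nrow(genes)
    zero <- runif(n) < config$p_zero_tpm
    tpm <- ifelse(zero, 0, rlnorm(n, config$tpm_meanlog, config$tpm_sdlog))
    expr <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
    for (r in seq_len(config$n_expr_reps))
      expr[[sprintf("tpm_rep%d", r)]] <-
        tpm * exp(rnorm(n, 0, config$expr_rep_noise_sd))
    list(expr = expr,
         truth = data.frame(gene_id = genes$gene_id, true_tpm = tpm,
                            stringsAsFactors = FALSE))
  })
}

# nearest-TSS distance for a set of midpoints (generator-internal arithmetic)
nearest_tss_distance <- function(chrom, mid, genes) {
  out <- rep(Inf, length(mid))
  t <- tss(genes)
  for (ch in unique(chrom)) {
    ti <- sort(t[genes$chrom == ch])
    if (!length(ti)) next
    idx <- which(chrom == ch)
    lo <- findInterval(mid[idx], ti)
    d_lo <- ifelse(lo >= 1, mid[idx] - ti[pmax(lo, 1)], Inf)
    d_hi <- ifelse(lo < length(ti), ti[pmin(lo + 1, length(ti))] - mid[idx], Inf)
    out[idx] <- pmin(abs(d_lo), abs(d_hi))
  }
  out
}

# sample positions uniformly on a chromosome set, rejecting those within
# `margin` of any position in `avoid` (named list chrom -> sorted positions)
sample_positions_avoiding <- function(n, layout, avoid, margin) {
  out_chrom <- character(0); out_pos <- numeric(0)
  len <- layout_lengths(layout)
  guard <- 0
  while (length(out_pos) < n && guard < 200) {
    guard <- guard + 1
    m <- 2 * (n - length(out_pos)) + 10
    ch <- sample(names(len), m, replace = TRUE, prob = len / sum(len))
    pos <- floor(runif(m) * len[ch])
    keep <- rep(TRUE, m)
    for (cc in unique(ch)) {
      av <- avoid[[cc]]
      if (is.null(av) || !length(av)) next
      idx <- which(ch == cc)
      lo <- findInterval(pos[idx], av)
      d1 <- ifelse(lo >= 1, pos[idx] - av[pmax(lo, 1)], Inf)
      d2 <- ifelse(lo < length(av), av[pmin(lo + 1, length(av))] - pos[idx], Inf)
      keep[idx] <- pmin(abs(d1), abs(d2)) > margin
    }
    out_chrom <- c(out_chrom, ch[keep])
    out_pos <- c(out_pos, pos[keep])
  }
  if (length(out_pos) < n) stop_fmt("could not place %d avoided positions", n)
  data.frame(chrom = out_chrom[seq_len(n)], pos = out_pos[seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Simulate replicate peak collections with planted truth
#'
#' Occupancy is a logistic draw in `log(TPM + 1)`. Each occupied gene gets a
#' TSS peak of truncated-normal width, centered at a strand-aware offset drawn
#' from the +1 / -1 nucleosome mixture. A configured fraction of occupied
#' short genes additionally get a broad region: a train of peaks tiling the
#' first `U(cov_min, cov_max)` fraction of the gene body with gaps small
#' enough to be bridged at the region-merge gap. Background peaks are placed
#' in intergenic space away from TSSs, in the number that makes the planted
#' fraction of TSS-proximal peaks equal `tss_target_fraction`. Replicates
#' jitter peak boundaries and drop peaks independently; the canonical
#' (pre-jitter) collection is also returned, and truth occupancy classes are
#' defined by applying the package's classification rule to it.
#'
#' @param genes a [gene_models()] data frame.
#' @param expr_truth truth data frame from [simulate_expression()]
#'   (`gene_id`, `true_tpm`).
#' @param config a [sim_config()].
#' @param layout a [genome_layout()].
#' @return list with `replicates` (list of [peak_collection()]),
#'   `canonical` (a [peak_collection()]) and `truth` (list: `peaks` data
#'   frame with per-peak origin and planted proximity, `genes` data frame
#'   with occupancy class and TSS-peak flag).
#' @export
simulate_peaks <- function(genes, expr_truth, config, layout) {
  with_stream(config$seed, "peaks", {
    n <- nrow(genes)
    tpm <- expr_truth$true_tpm[match(genes$gene_id, expr_truth$gene_id)]
    p_occ <- stats::plogis(config$occ_intercept +
                             config$occ_slope * log(tpm + 1))
    occupied <- runif(n) < p_occ
    t <- tss(genes)
    plus <- genes$strand == "+"
    L <- gene_length(genes)
    len <- layout_lengths(layout)

    draw_width <- function(k) {
      w <- round(rnorm(k, config$peak_width_mean, config$peak_width_sd))
      while (any(bad <- w <= config$peak_width_min))
        w[bad] <- round(rnorm(sum(bad), config$peak_width_mean,
                              config$peak_width_sd))
      w
    }

    rows <- list()
    add <- function(chrom, start, end, gene, origin) {
      rows[[length(rows) + 1]] <<- data.frame(
        chrom = chrom, start = start, end = end, gene = gene,
        origin = origin, stringsAsFactors = FALSE)
    }

    occ_idx <- which(occupied)
    if (length(occ_idx)) {
      k <- length(occ_idx)
      mode <- ifelse(runif(k) < config$w_primary / (config$w_primary +
                                                      config$w_secondary),
                     config$offset_primary, config$offset_secondary)
      off <- round(mode + rnorm(k, 0, config$offset_jitter_sd))
      w <- draw_width(k)
      center <- ifelse(plus[occ_idx], t[occ_idx] + off, t[occ_idx] - off)
      s <- pmax(0, center - floor(w / 2))
      e <- pmin(len[genes$chrom[occ_idx]], s + w)
      add(genes$chrom[occ_idx], s, e, genes$gene_id[occ_idx], "tss")
    }

    broad <- occupied & L < config$broad_max_gene_length &
      runif(n) < config$broad_fraction
    planted_cov <- rep(NA_real_, n)
    for (i in which(broad)) {
      cv <- runif(1, config$broad_cov_min, config$broad_cov_max)
      planted_cov[i] <- cv
      span <- round(cv * L[i])
      # tile the body from just past the TSS peak to TSS + span
      pos <- round(config$peak_width_mean / 2) +
        round(runif(1, config$body_gap_min, config$body_gap_max))
      while (pos < span) {
        w <- draw_width(1)
        s_rel <- pos
        e_rel <- min(pos + w, span)
        if (e_rel - s_rel >= config$peak_width_min) {
          if (plus[i]) add(genes$chrom[i], t[i] + s_rel, t[i] + e_rel,
                           genes$gene_id[i], "body")
          else add(genes$chrom[i], t[i] - e_rel + 1, t[i] - s_rel + 1,
                   genes$gene_id[i], "body")
        }
        pos <- e_rel + round(runif(1, config$body_gap_min,
                                   config$body_gap_max))
      }
    }

    planted <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 gene = character(), origin = character(),
                 stringsAsFactors = FALSE)
    mid <- floor((planted$start + planted$end) / 2)
    d <- nearest_tss_distance(planted$chrom, mid, genes)
    planted$proximal <- if (nrow(planted)) d <= config$tss_window else logical()

    f <- config$tss_target_fraction
    P <- sum(planted$proximal)
    # top up with intergenic background to the planted TSS-targeted fraction,
    # with a floor so degenerate configs still carry background peaks
    n_bg <- max(config$background_min, round(P / f) - nrow(planted))
    if (n_bg > 0) {
      tss_by_chrom <- lapply(split(t, genes$chrom), sort)
      bg <- sample_positions_avoiding(n_bg, layout, tss_by_chrom,
                                      margin = config$tss_window + 200)
      w <- draw_width(n_bg)
      s <- pmax(0, bg$pos - floor(w / 2))
      e <- pmin(len[bg$chrom], s + w)
      planted <- rbind(planted,
                       data.frame(chrom = bg$chrom, start = s, end = e,
                                  gene = NA_character_, origin = "background",
                                  proximal = FALSE, stringsAsFactors = FALSE))
    }

    canon_iv <- as_gintervals(data.frame(
      chrom = planted$chrom, start = planted$start, end = planted$end,
      name = sprintf("pk%05d", seq_len(nrow(planted))),
      stringsAsFactors = FALSE))
    canonical <- peak_collection("canonical", canon_iv,
                                 provenance = "planted pre-jitter peaks")

    replicates <- lapply(seq_len(config$n_replicates), function(r) {
      keep <- runif(nrow(planted)) >= config$rep_drop_rate
      s <- planted$start[keep] + round(rnorm(sum(keep), 0, config$rep_jitter_sd))
      e <- planted$end[keep] + round(rnorm(sum(keep), 0, config$rep_jitter_sd))
      s <- pmax(0, s)
      e <- pmax(s + config$peak_width_min, e)
      e <- pmin(len[planted$chrom[keep]], e)
      s <- pmin(s, e - 1)
      peak_collection(sprintf("rep%d", r),
                      as_gintervals(data.frame(chrom = planted$chrom[keep],
                                               start = s, end = e,
                                               stringsAsFactors = FALSE)),
                      provenance = sprintf("replicate %d (jitter sd %g, drop %g)",
                                           r, config$rep_jitter_sd,
                                           config$rep_drop_rate))
    })

    # truth occupancy class: the classification rule applied to the
    # canonical peaks at the generator's own thresholds
    cls <- classify_gene_occupancy(canonical, genes,
                                   tss_window = config$tss_window,
                                   broad_threshold = config$broad_cov_min,
                                   region_merge_gap = 1000)
    truth_genes <- data.frame(gene_id = genes$gene_id, true_tpm = tpm,
                              occupied_draw = occupied,
                              planted_broad = broad,
                              planted_coverage = planted_cov,
                              class = cls$class,
                              stringsAsFactors = FALSE)
    mid_order <- order(planted$chrom, planted$start, planted$end,
                       method = "radix")
    truth_peaks <- planted[mid_order, ]
    rownames(truth_peaks) <- NULL
    list(replicates = replicates, canonical = canonical,
         truth = list(peaks = truth_peaks, genes = truth_genes,
                      planted_proximal_fraction =
                        mean(truth_peaks$proximal)))
  })
}

#' Simulate accessible (open-chromatin) regions
#'
#' One accessible region is planted over the TSS peak of a configured
#' fraction of peak-occupied loci (so that exactly that fraction of all
#' accessible regions is peak-occupied); the remainder are placed in regions
#' free of any peak.
#'
#' @param peaks_truth the `truth$peaks` data frame from [simulate_peaks()].
#' @param config a [sim_config()].
#' @param layout a [genome_layout()].
#' @return list with `accessible` (a [peak_collection()]) and `truth`
#'   (list: `n`, `n_occupied`).
#' @export
simulate_accessible <- function(peaks_truth, config, layout) {
  with_stream(config$seed, "accessible", {
    tssp <- peaks_truth[peaks_truth$origin == "tss", ]
    n_occ <- nrow(tssp)
    f <- config$accessible_occupied_fraction
    n_total <- round(n_occ / f)
    len <- layout_lengths(layout)
    draw_w <- function(k) pmax(100, round(rnorm(k, config$accessible_width_mean,
                                                config$accessible_width_sd)))
    w <- draw_w(n_occ)
    mid <- floor((tssp$start + tssp$end) / 2)
    s1 <- pmax(0, mid - floor(w / 2))
    e1 <- pmin(len[tssp$chrom], s1 + w)
    n_free <- n_total - n_occ
    allmid <- floor((peaks_truth$start + peaks_truth$end) / 2)
    avoid <- lapply(split(allmid, peaks_truth$chrom), sort)
    free <- sample_positions_avoiding(n_free, layout, avoid, margin = 3000)
    w2 <- draw_w(n_free)
    s2 <- pmax(0, free$pos - floor(w2 / 2))
    e2 <- pmin(len[free$chrom], s2 + w2)
    iv <- as_gintervals(data.frame(
      chrom = c(tssp$chrom, free$chrom), start = c(s1, s2), end = c(e1, e2),
      stringsAsFactors = FALSE))
    list(accessible = peak_collection("accessible", iv,
                                      provenance = "simulated ATAC regions"),
         truth = list(n = n_total, n_occupied = n_occ,
                      occupied_fraction = n_occ / n_total))
  })
}

#' Simulate a binned coverage track from peaks
#'
#' Coverage is the sum of per-peak triangular bumps (peaked at the peak
#' midpoint, spanning the peak) plus Poisson background; the library size is
#' the total of all counts.
#'
#' @param peaks a [peak_collection()] or `gintervals`.
#' @param config a [sim_config()].
#' @param layout a [genome_layout()].
#' @param stream name of the random stream, so per-replicate tracks draw
#'   independent background noise (default `"track"`).
#' @return A [signal_track()] in count units.
#' @export
simulate_track <- function(peaks, config, layout, stream = "track") {
  with_stream(config$seed, stream, {
    x <- if (inherits(peaks, "peak_collection")) peaks$intervals else peaks
    b <- config$track_bin
    len <- layout_lengths(layout)
    counts <- lapply(len, function(L) rpois(ceiling(L / b),
                                            config$background_lambda) * 1.0)
    for (i in seq_len(nrow(x))) {
      ch <- x$chrom[i]
      b0 <- floor(x$start[i] / b); b1 <- ceiling(x$end[i] / b) - 1
      b1 <- min(b1, length(counts[[ch]]) - 1)
      bins <- b0:b1
      binmid <- (bins + 0.5) * b
      c0 <- (x$start[i] + x$end[i]) / 2
      half <- (x$end[i] - x$start[i]) / 2
      wgt <- pmax(0, 1 - abs(binmid - c0) / half)
      counts[[ch]][bins + 1] <- counts[[ch]][bins + 1] +
        config$peak_height * wgt
    }
    signal_track(layout, b, counts)
  })
}

#' Simulate differential-expression tables over timepoints
#'
#' A planted core of genes is significant (adjusted p below `de_alpha`) at
#' every timepoint with a consistent sign split (`de_core_down` down, the
#' rest up); a further `de_extra_rate` of genes are significant at a strict
#' subset of timepoints; everything else has adjusted p at or above the
#' cutoff.
#'
#' @param genes a [gene_models()] data frame.
#' @param config a [sim_config()].
#' @return list with `tables` (named list of data frames gene_id, log2fc,
#'   padj) and `truth` (core/down/up gene ids).
#' @export
simulate_de_tables <- function(genes, config) {
  with_stream(config$seed, "de", {
    n <- nrow(genes)
    if (config$de_core_size > n) stop_fmt("DE core larger than gene universe")
    ids <- genes$gene_id
    core <- sample(ids, config$de_core_size)
    down <- core[seq_len(config$de_core_down)]
    up <- setdiff(core, down)
    rest <- setdiff(ids, core)
    # extras: significant at a strict, non-empty subset of timepoints
    is_extra <- runif(length(rest)) < config$de_extra_rate
    n_tp <- config$n_timepoints
    extra_k <- ifelse(is_extra, sample(seq_len(n_tp - 1),
                                       length(rest), replace = TRUE), 0)
    extra_tp <- lapply(seq_along(rest), function(i)
      if (extra_k[i] > 0) sample(seq_len(n_tp), extra_k[i]) else integer(0))
    alpha <- config$de_alpha
    tables <- list()
    for (tp in seq_len(n_tp)) {
      padj <- runif(n, alpha, 1)
      lfc <- rnorm(n, 0, 0.3)
      ic <- match(core, ids)
      padj[ic] <- runif(length(ic), 1e-8, alpha * 0.98)
      sgn <- ifelse(core %in% down, -1, 1)
      lfc[ic] <- sgn * (0.2 + abs(rnorm(length(ic), 1.2, 0.6)))
      ie <- match(rest[vapply(extra_tp, function(s) tp %in% s, logical(1))],
                  ids)
      if (length(ie)) {
        padj[ie] <- runif(length(ie), 1e-8, alpha * 0.98)
        lfc[ie] <- rnorm(length(ie), 0, 1.5)
      }
      tables[[sprintf("tp%d", tp)]] <-
        data.frame(gene_id = ids, log2fc = lfc, padj = padj,
                   stringsAsFactors = FALSE)
    }
    list(tables = tables,
         truth = list(core = sort(core), down = sort(down), up = sort(up)))
  })
}

#' Simulate a ChIP-qPCR Ct table with planted folds
#'
#' Per locus and condition, the IP channel Ct is
#' `baseline - log2(true fold) + N(0, sd)` per technical replicate and the
#' total-H3 control channel Ct is `baseline + N(0, sd)`; the per-locus,
#' per-biological-replicate baseline cancels in the fold-over-H3 ratio.
#' Condition `"WT"` uses the configured true folds; condition `"KD"` divides
#' them by the configured knockdown reduction.
#'
#' @param config a [sim_config()].
#' @return list with `ct` (a [ct_table()]) and `truth` (data frame: target,
#'   condition, true_fold).
#' @export
simulate_ct <- function(config) {
  with_stream(config$seed, "ct", {
    folds <- config$qpcr_true_folds
    redu <- config$qpcr_knockdown_reduction[names(folds)]
    rows <- list()
    truth <- list()
    for (tg in names(folds)) {
      for (cond in c("WT", "KD")) {
        tf <- if (cond == "WT") folds[[tg]] else folds[[tg]] / redu[[tg]]
        truth[[length(truth) + 1]] <-
          data.frame(target = tg, condition = cond, true_fold = tf,
                     stringsAsFactors = FALSE)
        for (br in seq_len(config$n_bio_reps)) {
          base <- runif(1, config$ct_baseline_range[1],
                        config$ct_baseline_range[2])
          ip <- base - log2(tf) + rnorm(config$n_tech_reps, 0,
                                        config$ct_noise_sd)
          h3 <- base + rnorm(config$n_tech_reps, 0, config$ct_noise_sd)
          mk <- function(channel, ct) {
            d <- data.frame(target = tg, channel = channel, condition = cond,
                            bio_rep = br, stringsAsFactors = FALSE)
            for (j in seq_along(ct)) d[[sprintf("ct%d", j)]] <- ct[j]
            d
          }
          rows[[length(rows) + 1]] <- mk("H3cs1", ip)
          rows[[length(rows) + 1]] <- mk("H3", h3)
        }
      }
    }
    list(ct = ct_table(do.call(rbind, rows)),
         truth = do.call(rbind, truth))
  })
}

#' Run every generator under one configuration
#'
#' @param config a [sim_config()].
#' @return list with `layout`, `genes`, `expr`, `replicates`, `canonical`,
#'   `accessible`, `track`, `de_tables`, `ct`, `truth` (per-component truth
#'   tables) and `config`.
#' @export
simulate_all <- function(config = sim_config()) {
  g <- simulate_genome(config)
  ex <- simulate_expression(g$genes, config)
  pk <- simulate_peaks(g$genes, ex$truth, config, g$layout)
  ac <- simulate_accessible(pk$truth$peaks, config, g$layout)
  tr <- simulate_track(pk$canonical, config, g$layout)
  rep_tracks <- lapply(seq_along(pk$replicates), function(i)
    simulate_track(pk$replicates[[i]], config, g$layout,
                   stream = sprintf("track_rep%d", i)))
  de <- simulate_de_tables(g$genes, config)
  ct <- simulate_ct(config)
  list(layout = g$layout, genes = g$genes, expr = ex$expr,
       replicates = pk$replicates, canonical = pk$canonical,
       accessible = ac$accessible, track = tr, rep_tracks = rep_tracks,
       de_tables = de$tables, ct = ct$ct,
       truth = list(expression = ex$truth,
                    peaks = pk$truth$peaks,
                    genes = pk$truth$genes,
                    planted_proximal_fraction =
                      pk$truth$planted_proximal_fraction,
                    accessible = ac$truth, de = de$truth, ct = ct$truth),
       config = config)
}
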