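#' Default pipeline configuration
#'
#' @param seed global seed.
#' @param ... overrides: any [sim_config()] field under `simulation`, or the
#'   analysis-stage fields shown in the returned list.
#' @return nested configuration list.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    simulation = list(),
    peaks = list(tss_window = 1000, broad_threshold = 0.25,
                 region_merge_gap = 1000, pseudocount = 0.5,
                 concordance_bin = 50),
    profiles = list(flank = 2000, bin = 50, body_bins = 100),
    expression = list(alpha = 0.05),
    qpcr = list(ip_channel = "H3cs1", h3_channel = "H3",
                ref_condition = "WT", welch = FALSE)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_fmt("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  do.call(pipeline_config,
          c(list(seed = config$seed %||% 1),
            config[setdiff(names(config), "seed")]))
}

stage_path <- function(out, name) file.path(out, paste0(name, ".json"))

write_stage <- function(out, name, data) {
  jsonlite::write_json(data, stage_path(out, name), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(data)
}

read_stage <- function(out, name) {
  p <- stage_path(out, name)
  if (!file.exists(p))
    stop_fmt("stage dependency unmet: '%s' output missing (%s); run that stage first",
             name, p)
  jsonlite::read_json(p, simplifyVector = TRUE)
}

#' Run the full analysis pipeline
#'
#' Simulates (or, in principle, ingests) inputs, then runs peak analytics,
#' signal profiles, expression integration and qPCR statistics, writing all
#' intermediate files and a machine-readable `report.json` plus a human
#' summary `report.md` to `out`. Stages are selectable and resumable: each
#' stage persists its result as `<stage>.json`, and the report is assembled
#' from those, so skipping a stage and resuming from cached intermediates
#' yields the identical report.
#'
#' @param config a configuration list from [pipeline_config()], or a path to
#'   a YAML file with the same structure.
#' @param out output directory (created if needed).
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "peaks", "profiles", "expression", "qpcr", "report")`.
#' @return The report (a list, class `"analysis_report"`), invisibly when
#'   the report stage is skipped.
#' @export
run_pipeline <- function(config = pipeline_config(), out = tempfile("tssmap_"),
                         stages = c("simulate", "peaks", "profiles",
                                    "expression", "qpcr", "report")) {
  cfg <- read_pipeline_config(config)
  all_stages <- c("simulate", "peaks", "profiles", "expression", "qpcr",
                  "report")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop_fmt("unknown stage(s): %s", paste(bad, collapse = ", "))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$simulation))
  hash <- config_hash(cfg)
  note <- function(stage, msg, ...)
    message(sprintf("[%s] (config %s) %s", stage, hash, sprintf(msg, ...)))

  if ("simulate" %in% stages) {
    sim <- simulate_all(scfg)
    note("simulate", "%d genes, %d canonical peaks, %d replicates",
         nrow(sim$genes), n_peaks(sim$canonical), length(sim$replicates))
    write_gtf(sim$genes, file.path(out, "genes.gtf"))
    write_tsv_table(sim$expr, file.path(out, "expression.tsv"))
    for (i in seq_along(sim$replicates))
      write_bed(sim$replicates[[i]]$intervals,
                file.path(out, sprintf("peaks_rep%d.bed", i)))
    write_bed(sim$canonical$intervals, file.path(out, "peaks_canonical.bed"))
    write_bed(sim$accessible$intervals, file.path(out, "accessible.bed"))
    write_track_bedgraph(sim$track, file.path(out, "coverage.bedgraph"))
    for (i in seq_along(sim$rep_tracks))
      write_track_bedgraph(sim$rep_tracks[[i]],
                           file.path(out, sprintf("coverage_rep%d.bedgraph", i)))
    for (nm in names(sim$de_tables))
      write_tsv_table(sim$de_tables[[nm]],
                      file.path(out, sprintf("de_%s.tsv", nm)))
    write_tsv_table(as.data.frame(sim$ct), file.path(out, "ct.tsv"))
    write_tsv_table(sim$truth$genes, file.path(out, "truth_genes.tsv"))
    write_stage(out, "simulate", list(
      n_genes = nrow(sim$genes),
      n_replicates = length(sim$replicates),
      n_canonical_peaks = n_peaks(sim$canonical),
      planted_proximal_fraction = sim$truth$planted_proximal_fraction,
      layout = as.list(setNames(sim$layout$length, sim$layout$chrom)),
      de_core = length(sim$truth$de$core),
      de_down = length(sim$truth$de$down),
      de_up = length(sim$truth$de$up),
      accessible_n = sim$truth$accessible$n,
      accessible_occupied = sim$truth$accessible$n_occupied
    ))
  }

  load_layout <- function() {
    s <- read_stage(out, "simulate")
    genome_layout(names(s$layout), unlist(s$layout))
  }
  load_genes <- function() read_gtf(file.path(out, "genes.gtf"))

  if ("peaks" %in% stages) {
    layout <- load_layout()
    genes <- load_genes()
    rep_files <- sort(list.files(out, "^peaks_rep[0-9]+\\.bed$",
                                 full.names = TRUE))
    reps <- lapply(seq_along(rep_files), function(i)
      peak_collection(sprintf("rep%d", i), read_bed(rep_files[i])))
    pc <- cfg$peaks
    track_files <- sort(list.files(out, "^coverage_rep[0-9]+\\.bedgraph$",
                                   full.names = TRUE))
    tracks <- if (length(track_files) == length(reps))
      lapply(track_files, read_track_bedgraph, layout = layout) else NULL
    conc <- replicate_concordance(reps, tracks = tracks,
                                  bin = pc$concordance_bin)
    cons <- consensus_peaks(reps)
    write_bed(cons$intervals, file.path(out, "peaks_consensus.bed"))
    note("peaks", "%d consensus peaks; %d common peaks; min pairwise r %.3f",
         n_peaks(cons), conc$common_peak_count,
         min(conc$pairwise_pearson[upper.tri(conc$pairwise_pearson)]))
    prox <- tss_proximity(cons, genes, window = pc$tss_window)
    annot <- annotate_elements(genes, layout,
                               promoter_flank = pc$tss_window,
                               tts_flank = pc$tss_window)
    enr <- element_enrichment(cons, annot, layout,
                              pseudocount = pc$pseudocount)
    write_tsv_table(enr, file.path(out, "element_enrichment.tsv"))
    regions <- merge_intervals(cons$intervals, gap = pc$region_merge_gap)
    bins <- bin_region_sizes(regions)
    acc <- peak_collection("accessible",
                           read_bed(file.path(out, "accessible.bed")))
    coocc <- accessible_cooccupancy(cons, acc, window = pc$tss_window)
    occ <- classify_gene_occupancy(cons, genes,
                                   tss_window = pc$tss_window,
                                   broad_threshold = pc$broad_threshold,
                                   region_merge_gap = pc$region_merge_gap)
    write_tsv_table(occ, file.path(out, "occupancy_classes.tsv"))
    broad_genes <- genes[genes$gene_id %in%
                           occ$gene_id[occ$class == "broad"], , drop = FALSE]
    write_bed(as_gintervals(data.frame(chrom = broad_genes$chrom,
                                       start = broad_genes$start,
                                       end = broad_genes$end,
                                       name = broad_genes$gene_id,
                                       strand = broad_genes$strand,
                                       stringsAsFactors = FALSE)),
              file.path(out, "broad_genes.bed"))
    write_stage(out, "peaks", list(
      concordance = list(common_peak_count = conc$common_peak_count,
                         min_pairwise_pearson =
                           min(conc$pairwise_pearson[upper.tri(conc$pairwise_pearson)])),
      consensus_peak_count = n_peaks(cons),
      tss_proximity = prox$summary,
      element_enrichment = enr,
      size_bins = as.list(bins),
      size_bin_summary = size_bin_summary(bins),
      accessible_cooccupancy = coocc,
      occupancy_classes = as.list(table(occ$class))
    ))
  }

  if ("profiles" %in% stages) {
    layout <- load_layout()
    genes <- load_genes()
    track <- read_track_bedgraph(file.path(out, "coverage.bedgraph"), layout)
    rt <- to_rpkm(track)
    pf <- cfg$profiles
    cons <- peak_collection("consensus",
                            read_bed(file.path(out, "peaks_consensus.bed")))
    m_pk <- reference_point_matrix(rt, anchors_from_midpoints(cons),
                                   flank = pf$flank, bin = pf$bin)
    occ <- read_tsv_table(file.path(out, "occupancy_classes.tsv"))
    occ_genes <- genes[genes$gene_id %in%
                         occ$gene_id[occ$class != "unoccupied"], , drop = FALSE]
    m_tss <- reference_point_matrix(rt, anchors_from_tss(occ_genes),
                                    flank = pf$flank, bin = pf$bin)
    prof <- average_profile(m_tss)
    rel <- -pf$flank + pf$bin * (seq_along(prof$mean) - 0.5)
    write_tsv_table(data.frame(rel_bp = rel, mean_rpkm = prof$mean,
                               n = prof$n),
                    file.path(out, "tss_profile.tsv"))
    m_sc <- scaled_region_matrix(rt, occ_genes, body_bins = pf$body_bins,
                                 flank = pf$flank, bin = pf$bin)
    sc_prof <- average_profile(m_sc)
    write_tsv_table(data.frame(column = seq_along(sc_prof$mean),
                               mean_rpkm = sc_prof$mean, n = sc_prof$n),
                    file.path(out, "scaled_body_profile.tsv"))
    note("profiles", "TSS profile peak at %+d bp", round(rel[which.max(prof$mean)]))
    write_stage(out, "profiles", list(
      tss_profile_argmax_bp = rel[which.max(prof$mean)],
      tss_profile_max_rpkm = max(prof$mean, na.rm = TRUE),
      peak_profile_columns = ncol(m_pk$values),
      scaled_columns = ncol(m_sc$values),
      n_profiled_genes = nrow(occ_genes)
    ))
  }

  if ("expression" %in% stages) {
    ex <- cfg$expression
    expr <- read_tsv_table(file.path(out, "expression.tsv"),
                           required = "gene_id")
    groups <- expression_groups(expr)
    write_tsv_table(groups, file.path(out, "expression_groups.tsv"))
    occ <- read_tsv_table(file.path(out, "occupancy_classes.tsv"))
    by_grp <- occupancy_by_expression(groups, occ)
    de_files <- sort(list.files(out, "^de_tp[0-9]+\\.tsv$", full.names = TRUE))
    tables <- lapply(de_files, read_tsv_table,
                     required = c("gene_id", "log2fc", "padj"))
    names(tables) <- sub("^de_(tp[0-9]+)\\.tsv$", "\\1", basename(de_files))
    meta <- de_meta_intersection(tables, alpha = ex$alpha)
    write_tsv_table(average_de_stats(meta), file.path(out, "meta_de.tsv"))
    jsonlite::write_json(as.list(meta$venn), file.path(out, "venn.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tpm_of <- setNames(groups$mean_tpm, groups$gene_id)
    broad_tpm <- tpm_of[occ$gene_id[occ$class == "broad"]]
    narrow_tpm <- tpm_of[occ$gene_id[occ$class == "narrow"]]
    wl <- if (length(broad_tpm) >= 2 && length(narrow_tpm) >= 2)
      compare_group_expression(log(broad_tpm + 1), log(narrow_tpm + 1))
    else list(statistic = NA, p = NA, method = "insufficient")
    note("expression", "%d consistent DE genes (%d down / %d up)",
         meta$counts$consistent, meta$counts$down, meta$counts$up)
    write_stage(out, "expression", list(
      group_occupancy = by_grp,
      meta_de = meta$counts,
      venn = as.list(meta$venn),
      n_excluded = meta$n_excluded,
      broad_vs_narrow_tpm = list(statistic = wl$statistic, p = wl$p,
                                 method = wl$method,
                                 median_broad = median(broad_tpm),
                                 median_narrow = median(narrow_tpm))
    ))
  }

  if ("qpcr" %in% stages) {
    qc <- cfg$qpcr
    ct <- read_ct_table(file.path(out, "ct.tsv"))
    res <- chip_qpcr_analysis(ct, ip_channel = qc$ip_channel,
                              h3_channel = qc$h3_channel,
                              ref_condition = qc$ref_condition,
                              welch = qc$welch)
    write_tsv_table(res$folds, file.path(out, "qpcr_folds.tsv"))
    write_tsv_table(res$summary, file.path(out, "qpcr_summary.tsv"))
    note("qpcr", "%d target/condition summaries", nrow(res$summary))
    write_stage(out, "qpcr", list(summary = res$summary,
                                  ref_condition = res$ref_condition))
  }

  if ("report" %in% stages) {
    report <- structure(list(
      tool = "tssmap",
      version = as.character(packageVersion("tssmap")),
      seed = cfg$seed,
      config_hash = hash,
      simulate = read_stage(out, "simulate"),
      peaks = read_stage(out, "peaks"),
      profiles = read_stage(out, "profiles"),
      expression = read_stage(out, "expression"),
      qpcr = read_stage(out, "qpcr"),
      generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ), class = "analysis_report")
    validate_report(report)
    jsonlite::write_json(unclass(report), file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(render_report_md(report), file.path(out, "report.md"))
    note("report", "written to %s", file.path(out, "report.json"))
    return(invisible(report))
  }
  invisible(NULL)
}

#' Validate an analysis report against the shipped schema
#'
#' Checks the section structure described in
#' `system.file("schema", "report.schema.json", package = "tssmap")`:
#' required sections present and key quantities numeric and finite.
#'
#' @param report a report list (from [run_pipeline()] or parsed from
#'   `report.json`).
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
validate_report <- function(report) {
  need <- c("tool", "version", "seed", "config_hash", "simulate", "peaks",
            "profiles", "expression", "qpcr")
  miss <- setdiff(need, names(report))
  if (length(miss))
    stop_fmt("report missing section(s): %s", paste(miss, collapse = ", "))
  num <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
      stop_fmt("report field %s is not a finite number", what)
  }
  num(report$peaks$consensus_peak_count, "peaks.consensus_peak_count")
  num(report$peaks$tss_proximity$percent, "peaks.tss_proximity.percent")
  num(report$expression$meta_de$consistent, "expression.meta_de.consistent")
  if (report$expression$meta_de$consistent !=
      report$expression$meta_de$down + report$expression$meta_de$up +
      report$expression$meta_de$discordant)
    stop_fmt("meta_de partition does not sum to the consistent set")
  invisible(TRUE)
}

render_report_md <- function(r) {
  c(sprintf("# tssmap analysis report (seed %s, config %s)", r$seed,
            r$config_hash),
    "",
    sprintf("- Genes simulated: %d; canonical peaks: %d",
            r$simulate$n_genes, r$simulate$n_canonical_peaks),
    sprintf("- Consensus peaks: %d (common across replicates: %d, min pairwise Pearson %.3f)",
            r$peaks$consensus_peak_count,
            r$peaks$concordance$common_peak_count,
            r$peaks$concordance$min_pairwise_pearson),
    sprintf("- TSS-proximal peaks: %d of %d (%.1f%%)",
            r$peaks$tss_proximity$proximal_count,
            r$peaks$tss_proximity$total, r$peaks$tss_proximity$percent),
    sprintf("- Peak-positive regions over 2 kb: %.1f%%",
            r$peaks$size_bin_summary$pct_over_2kb),
    sprintf("- Accessible regions occupied: %.1f%%",
            r$peaks$accessible_cooccupancy$pct_accessible_occupied),
    sprintf("- Occupancy classes: %s",
            paste(sprintf("%s=%s", names(r$peaks$occupancy_classes),
                          unlist(r$peaks$occupancy_classes)),
                  collapse = ", ")),
    sprintf("- TSS profile maximum at %+d bp", round(r$profiles$tss_profile_argmax_bp)),
    sprintf("- Consistent DE genes: %d (%d down / %d up)",
            r$expression$meta_de$consistent, r$expression$meta_de$down,
            r$expression$meta_de$up),
    sprintf("- qPCR summaries: %d rows (reference condition %s)",
            nrow(as.data.frame(r$qpcr$summary)), r$qpcr$ref_condition))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(render_report_md(x), sep = "\n")
  invisible(x)
}
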