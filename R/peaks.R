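#' Peak collection
#'
#' A named set of called-peak intervals for one replicate or condition.
#'
#' @param name collection name (e.g. replicate id).
#' @param intervals a `gintervals` data frame.
#' @param provenance free text describing origin (caller, replicate).
#' @return A list with class `"peak_collection"`.
#' @export
peak_collection <- function(name, intervals, provenance = "") {
  stopifnot(is.character(name), inherits(intervals, "gintervals"))
  structure(list(name = name, intervals = intervals, provenance = provenance),
            class = "peak_collection")
}

#' @export
print.peak_collection <- function(x, ...) {
  cat(sprintf("<peak_collection> '%s': %d peak(s)%s\n", x$name,
              nrow(x$intervals),
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

n_peaks <- function(pc) nrow(pc$intervals)

peak_midpoints <- function(x) floor((x$start + x$end) / 2)

# point GRanges at interval midpoints (1-based)
midpoint_granges <- function(x) {
  m <- peak_midpoints(x)
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(m + 1, m + 1))
}

#' Replicate concordance of peak sets
#'
#' Counts the peaks of the first collection that overlap (>= 1 bp) a peak in
#' every other collection, and computes a pairwise Pearson correlation matrix
#' over the union of all peak regions. With per-replicate signal tracks the
#' correlation is computed on binned RPKM values; without tracks it falls
#' back to binary per-bin occupancy.
#'
#' @param reps list of two or more [peak_collection()]s.
#' @param tracks optional list of [signal_track()]s, one per replicate.
#' @param bin bin size in bp for the correlation vectors (default 50).
#' @return A list with `common_peak_count`, `pairwise_pearson` (matrix), and
#'   `n_bins` used.
#' @export
replicate_concordance <- function(reps, tracks = NULL, bin = 50) {
  if (length(reps) < 2) stop_fmt("need at least 2 replicate collections")
  for (r in reps) if (n_peaks(r) == 0)
    stop_fmt("empty peak collection: %s", r$name)
  grs <- lapply(reps, function(r) as_granges(r$intervals))
  in_all <- rep(TRUE, n_peaks(reps[[1]]))
  for (j in 2:length(reps))
    in_all <- in_all & IRanges::overlapsAny(grs[[1]], grs[[j]],
                                            ignore.strand = TRUE)
  union <- merge_intervals(do.call(rbind, lapply(reps, function(r)
    r$intervals[, c("chrom", "start", "end", "strand", "score")])), gap = 0)
  bins <- tile_intervals(union, bin)
  vecs <- if (is.null(tracks)) {
    bin_gr <- as_granges(bins)
    lapply(grs, function(g)
      as.numeric(IRanges::overlapsAny(bin_gr, g, ignore.strand = TRUE)))
  } else {
    stopifnot(length(tracks) == length(reps))
    lapply(tracks, function(tr) {
      rt <- to_rpkm(tr)
      track_mean(rt, bins$chrom, bins$start, bins$end)
    })
  }
  mat <- do.call(cbind, vecs)
  colnames(mat) <- vapply(reps, function(r) r$name, character(1))
  pearson <- suppressWarnings(cor(mat))
  # constant vectors (e.g. identical replicates fully covering the union
  # under binary occupancy) have undefined correlation: identical pairs are
  # perfectly concordant, differing constant pairs are not
  for (i in seq_len(ncol(mat))) for (j in seq_len(ncol(mat)))
    if (is.na(pearson[i, j]))
      pearson[i, j] <- as.numeric(all(mat[, i] == mat[, j]))
  list(common_peak_count = sum(in_all),
       pairwise_pearson = pearson,
       n_bins = nrow(bins))
}

# split intervals into consecutive bins of `bin` bp (last bin may be short)
tile_intervals <- function(x, bin) {
  starts <- unlist(lapply(seq_len(nrow(x)), function(i)
    seq(x$start[i], x$end[i] - 1, by = bin)), use.names = FALSE)
  chrom <- rep(x$chrom, ceiling(interval_width(x) / bin))
  ends <- starts + bin
  upper <- rep(x$end, ceiling(interval_width(x) / bin))
  as_gintervals(data.frame(chrom = chrom, start = starts,
                           end = pmin(ends, upper), stringsAsFactors = FALSE))
}

#' Consensus peaks supported by every replicate
#'
#' Retains the intervals (from any replicate) that overlap >= 1 bp with a
#' peak in every replicate, then union-merges the retained set at gap 0.
#'
#' @param reps list of two or more [peak_collection()]s.
#' @param name name for the output collection.
#' @return A [peak_collection()] of merged consensus intervals.
#' @export
consensus_peaks <- function(reps, name = "consensus") {
  if (length(reps) < 2) stop_fmt("need at least 2 replicate collections")
  grs <- lapply(reps, function(r) as_granges(r$intervals))
  kept <- list()
  for (i in seq_along(reps)) {
    keep <- rep(TRUE, n_peaks(reps[[i]]))
    for (j in seq_along(reps)) {
      if (i == j) next
      keep <- keep & IRanges::overlapsAny(grs[[i]], grs[[j]],
                                          ignore.strand = TRUE)
    }
    kept[[i]] <- reps[[i]]$intervals[keep, c("chrom", "start", "end",
                                             "strand", "score")]
  }
  merged <- merge_intervals(do.call(rbind, kept), gap = 0)
  peak_collection(name, merged,
                  provenance = sprintf("consensus of %d replicates",
                                       length(reps)))
}

#' TSS proximity of peaks
#'
#' A peak is TSS-proximal iff the distance between its midpoint
#' (`floor((start+end)/2)`) and the nearest gene TSS is at most `window` bp.
#' The signed distance is strand-aware: positive means downstream of the TSS
#' in the gene's orientation.
#'
#' @param peaks a [peak_collection()] or `gintervals` data frame.
#' @param genes a [gene_models()] data frame.
#' @param window proximity window in bp (default 1000).
#' @return A list with `per_peak` (data frame: midpoint, nearest_gene,
#'   signed_distance, proximal) and `summary`
#'   (`proximal_count`, `total`, `percent`).
#' @export
tss_proximity <- function(peaks, genes, window = 1000) {
  stopifnot(window > 0)
  x <- if (inherits(peaks, "peak_collection")) peaks$intervals else peaks
  if (nrow(genes) == 0) stop_fmt("no gene models supplied")
  mids <- peak_midpoints(x)
  tss_pos <- tss(genes)
  tss_gr <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(tss_pos + 1, tss_pos + 1))
  mid_gr <- midpoint_granges(x)
  hit <- GenomicRanges::nearest(mid_gr, tss_gr, ignore.strand = TRUE,
                                select = "arbitrary")
  d <- mids - tss_pos[hit]
  signed <- ifelse(genes$strand[hit] == "+", d, -d)
  proximal <- !is.na(hit) & abs(d) <= window
  per_peak <- data.frame(
    chrom = x$chrom, start = x$start, end = x$end,
    midpoint = mids,
    nearest_gene = ifelse(is.na(hit), NA_character_, genes$gene_id[hit]),
    signed_distance = signed,
    proximal = proximal,
    stringsAsFactors = FALSE
  )
  list(per_peak = per_peak,
       summary = proximity_summary(sum(proximal), nrow(x)))
}

#' Summarize a proximal / total peak count as a percentage
#'
#' @param proximal_count number of proximal peaks.
#' @param total total peaks.
#' @return list with `proximal_count`, `total`, `percent` (0-100).
#' @export
proximity_summary <- function(proximal_count, total) {
  list(proximal_count = proximal_count, total = total,
       percent = 100 * proximal_count / total)
}

#' Region size bins
#'
#' Counts merged peak-positive regions in the half-open length bins
#' `[0, 2 kb)`, `[2, 5 kb)`, `[5, 10 kb)` and `[10 kb, Inf)`.
#'
#' @param regions a `gintervals` data frame (or numeric lengths).
#' @return Named integer vector of counts (`lt2kb`, `kb2to5`, `kb5to10`,
#'   `gt10kb`) summing to the number of regions.
#' @export
bin_region_sizes <- function(regions) {
  len <- if (is.numeric(regions)) regions else interval_width(regions)
  breaks <- c(0, 2000, 5000, 10000, Inf)
  counts <- tabulate(findInterval(len, breaks), nbins = 4)
  setNames(counts, c("lt2kb", "kb2to5", "kb5to10", "gt10kb"))
}

#' Summary of region-size bins
#'
#' @param counts a 4-bin count vector as returned by [bin_region_sizes()].
#' @return list with `total`, `over_2kb`, `pct_over_2kb`.
#' @export
size_bin_summary <- function(counts) {
  stopifnot(length(counts) == 4)
  total <- sum(counts)
  over <- sum(counts[2:4])
  list(total = total, over_2kb = over, pct_over_2kb = 100 * over / total)
}

#' Co-occupancy of peaks and accessible regions
#'
#' A peak is "near accessible" iff its midpoint lies within `window` bp of
#' the span of any accessible interval (distance 0 when overlapping). An
#' accessible region is "occupied" iff it overlaps >= 1 bp with any peak.
#'
#' @param peaks,accessible [peak_collection()]s or `gintervals`.
#' @param window distance window in bp (default 1000).
#' @return list with `pct_peaks_near_accessible`, `n_accessible_occupied`,
#'   `pct_accessible_occupied`.
#' @export
accessible_cooccupancy <- function(peaks, accessible, window = 1000) {
  p <- if (inherits(peaks, "peak_collection")) peaks$intervals else peaks
  a <- if (inherits(accessible, "peak_collection")) accessible$intervals else accessible
  if (nrow(p) == 0 || nrow(a) == 0) stop_fmt("both peak sets must be non-empty")
  a_gr <- as_granges(a)
  dtn <- GenomicRanges::distanceToNearest(midpoint_granges(p), a_gr,
                                          ignore.strand = TRUE)
  gap <- rep(Inf, nrow(p))
  gap[S4Vectors::queryHits(dtn)] <- S4Vectors::mcols(dtn)$distance
  near <- gap < window  # gap counts bp strictly between; < window == dist <= window
  occupied <- IRanges::overlapsAny(a_gr, as_granges(p), ignore.strand = TRUE)
  list(pct_peaks_near_accessible = 100 * mean(near),
       n_accessible_occupied = sum(occupied),
       pct_accessible_occupied = 100 * mean(occupied))
}

#' Classify gene occupancy as unoccupied, narrow or broad
#'
#' A gene is occupied iff at least one peak is TSS-proximal to it under the
#' [tss_proximity()] rule (the peak's nearest TSS is this gene's and the
#' midpoint lies within `tss_window`). Occupied genes are "broad" iff the
#' peak-positive regions overlapping the gene body, union-merged bridging
#' gaps up to `region_merge_gap`, cover at least `broad_threshold` of the
#' body; otherwise "narrow".
#'
#' @param peaks a [peak_collection()] (typically consensus peaks) or
#'   `gintervals`.
#' @param genes a [gene_models()] data frame.
#' @param tss_window TSS proximity window in bp (default 1000).
#' @param broad_threshold body-coverage fraction for "broad"
#'   (default 0.25, inclusive).
#' @param region_merge_gap gap bridged when building peak-positive regions
#'   over the gene body (default 1000 bp).
#' @return A data frame (gene_id, class, tss_peak, body_coverage) with one
#'   row per gene; `class` is one of `"unoccupied"`, `"narrow"`, `"broad"`.
#' @export
classify_gene_occupancy <- function(peaks, genes, tss_window = 1000,
                                    broad_threshold = 0.25,
                                    region_merge_gap = 1000) {
  stopifnot(tss_window > 0, broad_threshold > 0, broad_threshold <= 1,
            region_merge_gap >= 0)
  x <- if (inherits(peaks, "peak_collection")) peaks$intervals else peaks
  if (any(gene_length(genes) <= 0)) stop_fmt("gene of non-positive length")
  prox <- tss_proximity(x, genes, window = tss_window)$per_peak
  occ_genes <- unique(prox$nearest_gene[prox$proximal])
  tss_peak <- genes$gene_id %in% occ_genes

  body_cov <- numeric(nrow(genes))
  if (nrow(x)) {
    hits <- GenomicRanges::findOverlaps(as_granges(genes), as_granges(x),
                                        ignore.strand = TRUE)
    by_gene <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    for (k in names(by_gene)) {
      gi <- as.integer(k)
      m <- merge_se(x$start[by_gene[[k]]], x$end[by_gene[[k]]],
                    gap = region_merge_gap)
      cov_bp <- sum(pmax(0, pmin(m$end, genes$end[gi]) -
                           pmax(m$start, genes$start[gi])))
      body_cov[gi] <- cov_bp / (genes$end[gi] - genes$start[gi])
    }
  }
  class <- ifelse(!tss_peak, "unoccupied",
                  ifelse(body_cov >= broad_threshold, "broad", "narrow"))
  data.frame(gene_id = genes$gene_id, class = class, tss_peak = tss_peak,
             body_coverage = body_cov, stringsAsFactors = FALSE)
}
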