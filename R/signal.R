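#' Binned signal track
#'
#' Per-chromosome binned coverage with a recorded library size, convertible
#' to RPKM with [to_rpkm()]. The library size is carried explicitly and never
#' inferred from a (possibly subset) track, so RPKM values cannot be silently
#' inflated by subsetting.
#'
#' @param layout a [genome_layout()].
#' @param bin_size bin width in bp.
#' @param counts named list (one numeric vector per chromosome) of per-bin
#'   counts; each vector must have `ceiling(chrom_length / bin_size)` bins.
#' @param library_size total counted units (> 0); defaults to the sum of all
#'   counts.
#' @param units `"counts"` or `"rpkm"`.
#' @return A list with class `"signal_track"`.
#' @export
signal_track <- function(layout, bin_size, counts,
                         library_size = NULL, units = "counts") {
  stopifnot(bin_size > 0)
  len <- layout_lengths(layout)
  miss <- setdiff(names(len), names(counts))
  if (length(miss))
    stop_fmt("counts missing for chromosome(s): %s", paste(miss, collapse = ", "))
  for (ch in names(len)) {
    want <- ceiling(len[[ch]] / bin_size)
    if (length(counts[[ch]]) != want)
      stop_fmt("chromosome %s: expected %d bins, got %d", ch, want,
               length(counts[[ch]]))
    if (any(counts[[ch]] < 0)) stop_fmt("negative counts on %s", ch)
  }
  if (is.null(library_size)) library_size <- sum(vapply(counts, sum, numeric(1)))
  if (library_size <= 0) stop_fmt("library_size must be > 0")
  structure(list(layout = layout, bin_size = bin_size,
                 counts = counts[names(len)], library_size = library_size,
                 units = units),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %d chrom(s), bin %d bp, library %.4g, units %s\n",
              length(x$counts), x$bin_size, x$library_size, x$units))
  invisible(x)
}

#' Convert a track to RPKM
#'
#' Each bin count `c` becomes `c / (bin_size/1000) / (library_size/1e6)`.
#'
#' @param track a [signal_track()] in count units.
#' @return The track with RPKM values.
#' @export
to_rpkm <- function(track) {
  if (identical(track$units, "rpkm")) return(track)
  stopifnot(track$library_size > 0, track$bin_size > 0)
  f <- 1 / (track$bin_size / 1000) / (track$library_size / 1e6)
  track$counts <- lapply(track$counts, function(v) v * f)
  track$units <- "rpkm"
  track
}

# Integral of the piecewise-constant per-bp signal from 0 to x (x may be
# fractional), per chromosome. Returns a function-like evaluation.
track_integral <- function(track, chrom, x) {
  b <- track$bin_size
  out <- numeric(length(x))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    v <- track$counts[[ch]]
    if (is.null(v)) stop_fmt("chromosome %s not in track", ch)
    C0 <- c(0, cumsum(v * b))
    k <- pmin(floor(x[idx] / b), length(v) - 1)
    out[idx] <- C0[k + 1] + (x[idx] - k * b) * v[k + 1]
  }
  out
}

#' Mean track signal over intervals
#'
#' Length-weighted mean of the per-bp signal (each bp carries its bin's
#' value) over `[start, end)`; boundaries may be fractional.
#'
#' @param track a [signal_track()].
#' @param chrom,start,end parallel vectors of query intervals.
#' @return Numeric vector of means.
#' @export
track_mean <- function(track, chrom, start, end) {
  stopifnot(all(end > start))
  (track_integral(track, chrom, end) - track_integral(track, chrom, start)) /
    (end - start)
}

# Evaluate cell means for an n x (ncol+1) boundary grid in one pass.
# Cells extending past a chromosome edge (or on a chromosome absent from
# the layout) are NA.
fill_cells <- function(track, chrom, edges, len) {
  n <- nrow(edges); ncol <- ncol(edges) - 1
  vals <- matrix(NA_real_, n, ncol)
  known <- chrom %in% names(len)
  lo <- edges[, -ncol(edges), drop = FALSE]
  hi <- edges[, -1, drop = FALSE]
  ok <- known & lo >= 0 & hi <= len[chrom]  # recycled column-wise
  idx <- which(ok)
  if (length(idx)) {
    ch <- rep(chrom, ncol)[idx]
    vals[idx] <- track_mean(track, ch, lo[idx], hi[idx])
  }
  vals
}

#' Signal matrix over anchors
#'
#' @param values numeric matrix (rows = anchors, columns = relative bins).
#' @param anchors data frame describing rows.
#' @param mode `"reference_point"` or `"scaled_region"`.
#' @param ... grid metadata (`bin`, `flank`, `body_bins`).
#' @return A list with class `"signal_matrix"`.
#' @export
signal_matrix <- function(values, anchors, mode, ...) {
  stopifnot(is.matrix(values), nrow(values) == nrow(anchors))
  structure(c(list(values = values, anchors = anchors, mode = mode),
              list(...)),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %s: %d row(s) x %d column(s)\n",
              x$mode, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Anchor table from gene TSSs or peak midpoints
#'
#' @param genes a [gene_models()] data frame.
#' @return data frame (chrom, pos, strand, id) usable as
#'   [reference_point_matrix()] anchors.
#' @export
anchors_from_tss <- function(genes) {
  data.frame(chrom = genes$chrom, pos = tss(genes), strand = genes$strand,
             id = genes$gene_id, stringsAsFactors = FALSE)
}

#' @rdname anchors_from_tss
#' @param peaks a [peak_collection()] or `gintervals`.
#' @export
anchors_from_midpoints <- function(peaks) {
  x <- if (inherits(peaks, "peak_collection")) peaks$intervals else peaks
  data.frame(chrom = x$chrom, pos = peak_midpoints(x),
             strand = ifelse(x$strand %in% c("+", "-"), x$strand, "+"),
             id = sprintf("%s:%s-%s", x$chrom, format_bp(x$start),
                          format_bp(x$end)),
            stringsAsFactors = FALSE)
}

#' Reference-point signal matrix
#'
#' One row per anchor (a TSS or a peak midpoint), `2*flank/bin` columns of
#' mean signal over consecutive `bin`-bp cells spanning `[pos - flank,
#' pos + flank)`. Rows of minus-strand anchors are reversed so downstream is
#' always rightward. Cells extending past a chromosome edge are `NA`
#' (missing), never zero; an anchor on a chromosome absent from the track
#' gives an all-`NA` row.
#'
#' @param track a [signal_track()].
#' @param anchors data frame with columns `chrom`, `pos`, `strand` (see
#'   [anchors_from_tss()]).
#' @param flank half-window in bp; must be a multiple of `bin`.
#' @param bin cell width in bp (default 50).
#' @return A [signal_matrix()] in `"reference_point"` mode.
#' @export
reference_point_matrix <- function(track, anchors, flank = 2000, bin = 50) {
  stopifnot(flank %% bin == 0, flank > 0)
  ncol <- 2 * flank / bin
  len <- layout_lengths(track$layout)
  # n x (ncol+1) boundary grid, evaluated in one vectorized pass
  edges <- outer(anchors$pos - flank, bin * (0:ncol), `+`)
  vals <- fill_cells(track, anchors$chrom, edges, len)
  rev_rows <- which(anchors$strand == "-")
  vals[rev_rows, ] <- vals[rev_rows, ncol:1, drop = FALSE]
  signal_matrix(vals, anchors, "reference_point", bin = bin, flank = flank)
}

#' Scaled gene-body signal matrix
#'
#' Each row spans an upstream flank, the gene body rescaled to `body_bins`
#' equal-width slices (so bodies of different lengths are comparable, e.g.
#' all scaled to a 5 kb equivalent), and a downstream flank. Slice values are
#' length-weighted mean signal over the slice's bp; minus-strand genes are
#' reversed so TSS is always leftmost.
#'
#' @param track a [signal_track()].
#' @param genes a [gene_models()] data frame.
#' @param body_bins number of body slices (default 100, i.e. a 5 kb
#'   equivalent at 50 bp cells).
#' @param flank flank width in bp; multiple of `bin`.
#' @param bin flank cell width in bp.
#' @return A [signal_matrix()] in `"scaled_region"` mode.
#' @export
scaled_region_matrix <- function(track, genes, body_bins = 100,
                                 flank = 2000, bin = 50) {
  stopifnot(body_bins >= 1, flank %% bin == 0)
  nf <- flank / bin
  ncol <- 2 * nf + body_bins
  len <- layout_lengths(track$layout)
  gl <- genes$end - genes$start
  body <- genes$start + outer(gl, (0:body_bins) / body_bins, `*`)
  edges <- if (nf > 0)
    cbind(outer(genes$start - flank, bin * (0:(nf - 1)), `+`), body,
          outer(genes$end, bin * (1:nf), `+`))
  else body
  vals <- fill_cells(track, genes$chrom, edges, len)
  rev_rows <- which(genes$strand == "-")
  vals[rev_rows, ] <- vals[rev_rows, ncol:1, drop = FALSE]
  signal_matrix(vals, as.data.frame(genes), "scaled_region",
                bin = bin, flank = flank, body_bins = body_bins)
}

#' Column-mean profile of a signal matrix
#'
#' Missing cells are excluded from the means; a column with no non-missing
#' rows is reported as `NA` with count 0.
#'
#' @param m a [signal_matrix()].
#' @return list with `mean` (column means) and `n` (non-missing rows per
#'   column).
#' @export
average_profile <- function(m) {
  stopifnot(nrow(m$values) >= 1)
  n <- colSums(!is.na(m$values))
  mu <- suppressWarnings(colMeans(m$values, na.rm = TRUE))
  mu[n == 0] <- NA_real_
  list(mean = mu, n = n)
}

#' Heatmap row order
#'
#' Rows sorted by descending row mean (missing cells excluded); ties broken
#' by anchor coordinate (chrom, then position), so the order is
#' deterministic.
#'
#' @param m a [signal_matrix()].
#' @return An integer permutation of row indices.
#' @export
order_heatmap_rows <- function(m) {
  mu <- rowMeans(m$values, na.rm = TRUE)
  mu[is.nan(mu)] <- -Inf
  pos <- m$anchors$pos %||% m$anchors$start
  order(-mu, m$anchors$chrom, pos)
}

#' Write / read a signal track as bedGraph
#'
#' One record per non-zero bin; a `# library_size=` header comment carries
#' the library size so RPKM conversion of a re-read track is faithful.
#'
#' @param track a [signal_track()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# library_size=%s bin_size=%d",
                     format_bp(track$library_size), track$bin_size), con)
  b <- track$bin_size
  len <- layout_lengths(track$layout)
  for (ch in names(track$counts)) {
    v <- track$counts[[ch]]
    nz <- which(v != 0)
    if (!length(nz)) next
    writeLines(paste(ch, format_bp((nz - 1) * b),
                     format_bp(pmin(nz * b, len[[ch]])),
                     format(v[nz], scientific = FALSE, trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_track_bedgraph
#' @param layout a [genome_layout()] for the re-read track.
#' @param bin_size bin width; default taken from the file header.
#' @param library_size library size; default taken from the file header.
#' @return For `read_track_bedgraph`, a [signal_track()].
#' @export
read_track_bedgraph <- function(path, layout, bin_size = NULL,
                                library_size = NULL) {
  header <- readLines(path, n = 1)
  if (startsWith(header, "#")) {
    if (is.null(library_size) && grepl("library_size=", header))
      library_size <- as.numeric(sub(".*library_size=([0-9.eE+-]+).*", "\\1",
                                     header))
    if (is.null(bin_size) && grepl("bin_size=", header))
      bin_size <- as.integer(sub(".*bin_size=([0-9]+).*", "\\1", header))
  }
  if (is.null(bin_size))
    stop_fmt("bin_size not given and not recorded in %s", path)
  if (is.null(library_size))
    stop_fmt("library_size not given and not recorded in %s", path)
  recs <- read_bedgraph(path)
  len <- layout_lengths(layout)
  counts <- lapply(len, function(L) numeric(ceiling(L / bin_size)))
  unknown <- setdiff(unique(recs$chrom), names(counts))
  if (length(unknown))
    stop_fmt("%s: chromosome %s not in layout", path, unknown[1])
  b0 <- floor(recs$start / bin_size)
  b1 <- ceiling(recs$end / bin_size) - 1
  single <- b0 == b1
  add_weighted <- function(chrom, bin0, s, e, score) {
    # bp-weighted mean contribution of [s, e) to bin `bin0` (0-based)
    binlen <- pmin((bin0 + 1) * bin_size, len[chrom]) - bin0 * bin_size
    w <- score * (pmin(e, (bin0 + 1) * bin_size, len[chrom]) -
                    pmax(s, bin0 * bin_size)) / binlen
    for (ch in unique(chrom)) {
      i <- chrom == ch
      agg <- rowsum(w[i], bin0[i])
      counts[[ch]][as.integer(rownames(agg)) + 1] <<-
        counts[[ch]][as.integer(rownames(agg)) + 1] + agg[, 1]
    }
  }
  if (any(single))
    add_weighted(recs$chrom[single], b0[single], recs$start[single],
                 recs$end[single], recs$score[single])
  for (i in which(!single)) {
    for (b in b0[i]:b1[i])
      add_weighted(recs$chrom[i], b, recs$start[i], recs$end[i],
                   recs$score[i])
  }
  signal_track(layout, bin_size, counts, library_size = library_size)
}
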