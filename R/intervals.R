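#' Genomic intervals
#'
#' The atom of every set operation in the package: a data frame of stranded,
#' 0-based half-open genomic intervals `[start, end)`, BED-style. Extra
#' columns (e.g. the narrowPeak statistics columns) are carried along as an
#' opaque payload and survive round trips through [write_bed()]/[read_bed()].
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors; 0-based inclusive start, exclusive end,
#'   with `0 <= start < end`.
#' @param strand `"+"`, `"-"` or `"*"` (unstranded); recycled.
#' @param score optional numeric score; recycled, may be `NA`.
#' @param name optional interval name; recycled.
#' @param ... further columns kept as opaque payload.
#'
#' @return A `data.frame` with class `"gintervals"`, sorted by
#'   (chrom, start, end).
#' @examples
#' gintervals("chr1", c(0, 100), c(50, 200), strand = "+")
#' @export
gintervals <- function(chrom, start, end, strand = "*", score = NA_real_,
                       name = NA_character_, ...) {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    strand = rep_len(as.character(strand), n),
    score = rep_len(as.numeric(score), n),
    name = rep_len(as.character(name), n),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  as_gintervals(df)
}

#' Coerce a data frame to genomic intervals
#'
#' Validates coordinates and strand, sorts deterministically by
#' (chrom, start, end), and attaches the `"gintervals"` class.
#'
#' @param df a data frame with at least `chrom`, `start`, `end` columns.
#' @return A sorted `gintervals` data frame.
#' @export
as_gintervals <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("missing required column(s): %s", paste(miss, collapse = ", "))
  if (!"strand" %in% names(df)) df$strand <- "*"
  if (!"score" %in% names(df)) df$score <- NA_real_
  if (nrow(df)) {
    bad <- which(!(df$start >= 0 & df$start < df$end))
    if (length(bad))
      stop_fmt("invalid coordinates (need 0 <= start < end) at row(s): %s",
               paste(utils::head(bad, 5), collapse = ", "))
    badstr <- which(!df$strand %in% c("+", "-", "*"))
    if (length(badstr))
      stop_fmt("unknown strand token '%s' at row %d",
               df$strand[badstr[1]], badstr[1])
  }
  df <- df[order(df$chrom, df$start, df$end, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- unique(c("gintervals", class(df)))
  df
}

#' @export
print.gintervals <- function(x, ...) {
  cat(sprintf("<gintervals> %d interval(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Interval lengths in bp
#' @param x a `gintervals` data frame.
#' @return numeric vector `end - start`.
#' @export
interval_width <- function(x) x$end - x$start

#' Genome layout (chromosome sizes)
#'
#' @param chrom character vector of chromosome names.
#' @param length chromosome lengths in bp.
#' @return A `data.frame` with class `"genome_layout"`.
#' @export
genome_layout <- function(chrom, length) {
  stopifnot(length(chrom) == base::length(length), all(length > 0),
            !anyDuplicated(chrom))
  out <- data.frame(chrom = as.character(chrom), length = as.numeric(length),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genome_layout", class(out))
  out
}

layout_lengths <- function(layout) setNames(layout$length, layout$chrom)

#' Check intervals against a genome layout
#'
#' Errors if any interval's chromosome is absent from the layout or extends
#' beyond the chromosome end.
#'
#' @param x a `gintervals` data frame.
#' @param layout a [genome_layout()].
#' @return `x`, invisibly.
#' @export
check_layout <- function(x, layout) {
  len <- layout_lengths(layout)
  unknown <- setdiff(unique(x$chrom), names(len))
  if (length(unknown))
    stop_fmt("chromosome(s) not in layout: %s", paste(unknown, collapse = ", "))
  over <- which(x$end > len[x$chrom])
  if (length(over))
    stop_fmt("interval extends past chromosome end at row %d", over[1])
  invisible(x)
}

# 0-based half-open -> 1-based closed GRanges; strand "*" kept as "*".
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  )
}

from_granges <- function(gr) {
  gintervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Overlap between two intervals in bp
#'
#' @param a,b single intervals (one-row `gintervals` or lists with
#'   `chrom`, `start`, `end`).
#' @return Overlapping base pairs; 0 when chromosomes differ or the
#'   half-open intervals merely abut.
#' @examples
#' overlap_bp(gintervals("chr1", 0, 100), gintervals("chr1", 50, 150)) # 50
#' @export
overlap_bp <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) return(0)
  max(0, min(a$end[1], b$end[1]) - max(a$start[1], b$start[1]))
}

#' Merge intervals, bridging gaps up to a tolerance
#'
#' Union-merges a set of intervals: two intervals merge iff the distance
#' between them is at most `gap` bp (overlapping or abutting intervals always
#' merge). The result is sorted and pairwise disjoint; strand and payload are
#' dropped since merged intervals are composites.
#'
#' @param x a `gintervals` data frame.
#' @param gap non-negative bp; gaps of at most this size are bridged.
#' @return A merged `gintervals` data frame.
#' @examples
#' merge_intervals(gintervals("chr1", c(0, 15), c(10, 20)), gap = 5)
#' @export
merge_intervals <- function(x, gap = 0) {
  stopifnot(gap >= 0)
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end", "strand", "score")])
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = gap + 1,
                              ignore.strand = TRUE)
  from_granges(gr)
}

# merge numeric [s, e) pairs on one chromosome, bridging gaps <= gap;
# returns list(start, end) sorted and disjoint (fast path used by
# per-gene classification; semantics identical to merge_intervals)
merge_se <- function(s, e, gap = 0) {
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  n <- length(s)
  if (n <= 1) return(list(start = s, end = e))
  emax <- cummax(e)
  brk <- which(s[-1] > emax[-n] + gap)
  starts <- s[c(1, brk + 1)]
  ends <- emax[c(brk, n)]
  list(start = starts, end = ends)
}

#' Fraction of a target interval covered by a set of regions
#'
#' Base pairs covered by the union of `regions` (double-covered bp counted
#' once), clipped to the target, divided by the target length.
#'
#' @param regions a `gintervals` data frame.
#' @param target a single interval (one-row `gintervals`).
#' @return A fraction in `[0, 1]`.
#' @examples
#' covered_fraction(gintervals("chr1", c(0, 100), c(200, 300)),
#'                  gintervals("chr1", 0, 1000)) # 0.3
#' @export
covered_fraction <- function(regions, target) {
  tw <- target$end[1] - target$start[1]
  if (tw <= 0) stop_fmt("target interval has non-positive length")
  if (nrow(regions) == 0) return(0)
  hit <- regions[regions$chrom == target$chrom[1], , drop = FALSE]
  if (nrow(hit) == 0) return(0)
  s <- pmax(hit$start, target$start[1])
  e <- pmin(hit$end, target$end[1])
  keep <- e > s
  if (!any(keep)) return(0)
  clipped <- gintervals(target$chrom[1], s[keep], e[keep])
  sum(interval_width(merge_intervals(clipped, gap = 0))) / tw
}
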