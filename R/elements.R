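#' Genomic element annotation
#'
#' An ordered list of element classes, each a set of intervals. The order is
#' the precedence used to resolve every genomic bp (and every peak midpoint)
#' to exactly one class: a bp belongs to the first class in the list whose
#' intervals contain it. The last class is conventionally `intergenic` and
#' may simply span the whole genome, acting as the fall-through.
#'
#' @param classes named list of `gintervals`, in precedence order.
#' @return A list with class `"element_annotation"`.
#' @export
element_annotation <- function(classes) {
  stopifnot(is.list(classes), !is.null(names(classes)),
            all(nzchar(names(classes))))
  for (nm in names(classes))
    if (!inherits(classes[[nm]], "gintervals"))
      stop_fmt("class '%s' is not a gintervals data frame", nm)
  structure(list(classes = classes), class = "element_annotation")
}

#' @export
print.element_annotation <- function(x, ...) {
  cat("<element_annotation> precedence:",
      paste(names(x$classes), collapse = " > "), "\n")
  invisible(x)
}

# strand-aware block [a, b) bp downstream of the TSS, as 0-based half-open
downstream_block <- function(genes, a, b) {
  t <- tss(genes)
  plus <- genes$strand == "+"
  data.frame(chrom = genes$chrom,
             start = ifelse(plus, t + a, t - b + 1),
             end = ifelse(plus, t + b, t - a + 1),
             stringsAsFactors = FALSE)
}

#' Build a six-class element annotation from gene models
#'
#' Synthesizes the canonical promoter > TTS > 5'UTR > exon > intron >
#' intergenic annotation from gene bodies alone: the promoter is TSS +/-
#' `promoter_flank`, the TTS class is TES +/- `tts_flank`, the 5'UTR is the
#' first `utr5_len` bp of the gene body (in transcription orientation),
#' the remaining body alternates exons of `exon_len` and introns of
#' `intron_len` bp, and intergenic is the genome-wide fall-through.
#'
#' @param genes a [gene_models()] data frame.
#' @param layout a [genome_layout()].
#' @param promoter_flank,tts_flank flank half-widths in bp (default 1000).
#' @param utr5_len 5'UTR length in bp (default 1200).
#' @param exon_len,intron_len alternating block lengths in bp.
#' @return An [element_annotation()].
#' @export
annotate_elements <- function(genes, layout, promoter_flank = 1000,
                              tts_flank = 1000, utr5_len = 1200,
                              exon_len = 300, intron_len = 700) {
  len <- layout_lengths(layout)
  clip <- function(df) {
    df$start <- pmax(df$start, 0)
    df$end <- pmin(df$end, len[df$chrom])
    as_gintervals(df[df$end > df$start, , drop = FALSE])
  }
  t <- tss(genes); e <- tes(genes)
  promoter <- clip(data.frame(chrom = genes$chrom, start = t - promoter_flank,
                              end = t + promoter_flank + 1))
  ttsr <- clip(data.frame(chrom = genes$chrom, start = e - tts_flank,
                          end = e + tts_flank + 1))
  L <- gene_length(genes)
  utr5 <- clip(downstream_block(genes, 0, pmin(utr5_len, L)))
  exon <- list(); intron <- list()
  period <- exon_len + intron_len
  for (i in seq_len(nrow(genes))) {
    off <- utr5_len
    while (off < L[i]) {
      exon[[length(exon) + 1]] <-
        downstream_block(genes[i, ], off, min(off + exon_len, L[i]))
      if (off + exon_len < L[i])
        intron[[length(intron) + 1]] <-
          downstream_block(genes[i, ], off + exon_len,
                           min(off + period, L[i]))
      off <- off + period
    }
  }
  bind_or_empty <- function(lst) {
    if (!length(lst)) return(gintervals(character(), numeric(), numeric())[0, ])
    clip(do.call(rbind, lst))
  }
  intergenic <- as_gintervals(data.frame(chrom = layout$chrom, start = 0,
                                         end = layout$length,
                                         stringsAsFactors = FALSE))
  element_annotation(list(promoter = promoter, TTS = ttsr, utr5 = utr5,
                          exon = bind_or_empty(exon),
                          intron = bind_or_empty(intron),
                          intergenic = intergenic))
}

#' Assign peak midpoints to element classes by precedence
#'
#' @param peaks a [peak_collection()] or `gintervals`.
#' @param annot an [element_annotation()].
#' @return A character vector, one class per peak (`NA` if no class matched).
#' @export
assign_elements <- function(peaks, annot) {
  x <- if (inherits(peaks, "peak_collection")) peaks$intervals else peaks
  mid_gr <- midpoint_granges(x)
  out <- rep(NA_character_, nrow(x))
  for (nm in names(annot$classes)) {
    cls <- annot$classes[[nm]]
    if (!nrow(cls)) next
    todo <- is.na(out)
    if (!any(todo)) break
    hit <- IRanges::overlapsAny(mid_gr[todo], as_granges(cls),
                                ignore.strand = TRUE)
    out[todo][hit] <- nm
  }
  out
}

#' Genomic-element enrichment of peaks over random background
#'
#' Each peak is assigned to exactly one element class by its midpoint under
#' the annotation's precedence. For each class the log2 enrichment of the
#' observed peak fraction over the random-background fraction (the class's
#' precedence-resolved bp share of the genome) is
#' `log2(((obs + c) / (total + k c)) / background_fraction)` with pseudocount
#' `c` (default 0.5) and `k` the number of classes, keeping the ratio finite
#' for zero-count classes; `pseudocount = 0` gives the raw ratio.
#'
#' @param peaks a [peak_collection()] or `gintervals`.
#' @param annot an [element_annotation()].
#' @param layout a [genome_layout()].
#' @param pseudocount pseudocount `c` (default 0.5).
#' @return A data frame (class, observed_count, observed_fraction,
#'   background_fraction, log2_enrichment), rows in precedence order.
#' @export
element_enrichment <- function(peaks, annot, layout, pseudocount = 0.5) {
  x <- if (inherits(peaks, "peak_collection")) peaks$intervals else peaks
  genome_bp <- sum(layout$length)
  nms <- names(annot$classes)
  k <- length(nms)
  # precedence-resolved background bp: what each class adds on top of the
  # classes above it
  resolved <- numeric(k)
  cols3 <- function(d) as.data.frame(d)[, c("chrom", "start", "end")]
  cum <- NULL
  cum_bp <- 0
  for (i in seq_len(k)) {
    cls <- cols3(annot$classes[[i]])
    cum <- if (is.null(cum)) cls else rbind(cum, cls)
    cum <- cols3(merge_intervals(as_gintervals(cum), gap = 0))
    new_bp <- sum(cum$end - cum$start)
    resolved[i] <- new_bp - cum_bp
    cum_bp <- new_bp
  }
  if (any(resolved <= 0))
    stop_fmt("element class '%s' has zero background bp after precedence",
             nms[which(resolved <= 0)[1]])
  bg_frac <- resolved / genome_bp
  assigned <- assign_elements(x, annot)
  obs <- unname(vapply(nms, function(nm) sum(assigned == nm, na.rm = TRUE),
                       numeric(1)))
  total <- nrow(x)
  obs_frac <- obs / total
  smoothed <- (obs + pseudocount) / (total + k * pseudocount)
  data.frame(class = nms,
             observed_count = obs,
             observed_fraction = obs_frac,
             background_fraction = bg_frac,
             log2_enrichment = log2(smoothed / bg_frac),
             stringsAsFactors = FALSE, row.names = NULL)
}
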