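#' Gene models
#'
#' Stranded gene bodies with 0-based half-open coordinates. The TSS of a
#' plus-strand gene is `start`; of a minus-strand gene, `end - 1` (both as
#' 0-based bp positions). The TES is the opposite end.
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open gene body coordinates.
#' @param strand `"+"` or `"-"` only; genes must be oriented.
#' @param biotype free-text biotype, default `"protein_coding"`.
#' @return A `data.frame` with class `"gene_models"`, sorted by
#'   (chrom, start, end).
#' @examples
#' g <- gene_models("g1", "chr1", 100, 500, "+")
#' tss(g) # 100
#' @export
gene_models <- function(gene_id, chrom, start, end, strand,
                        biotype = "protein_coding") {
  n <- length(gene_id)
  df <- data.frame(
    gene_id = as.character(gene_id),
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    strand = rep_len(as.character(strand), n),
    biotype = rep_len(as.character(biotype), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$gene_id))
    stop_fmt("duplicated gene_id: %s", df$gene_id[anyDuplicated(df$gene_id)])
  if (any(df$start < 0 | df$start >= df$end))
    stop_fmt("invalid gene coordinates (need 0 <= start < end)")
  if (any(!df$strand %in% c("+", "-")))
    stop_fmt("gene strand must be '+' or '-'")
  df <- df[order(df$chrom, df$start, df$end, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_models", class(df))
  df
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d gene(s)\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Transcription start sites (0-based bp)
#' @param genes a `gene_models` data frame.
#' @return numeric vector of strand-aware TSS positions.
#' @export
tss <- function(genes) ifelse(genes$strand == "+", genes$start, genes$end - 1)

#' Transcription end sites (0-based bp)
#' @param genes a `gene_models` data frame.
#' @return numeric vector of strand-aware TES positions.
#' @export
tes <- function(genes) ifelse(genes$strand == "+", genes$end - 1, genes$start)

#' Gene body lengths in bp
#' @param genes a `gene_models` data frame.
#' @return numeric vector `end - start`.
#' @export
gene_length <- function(genes) genes$end - genes$start
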