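#' Read a BED / narrowPeak file
#'
#' BED is consumed natively: 0-based half-open coordinates. Columns beyond
#' the first six (e.g. narrowPeak signalValue/pValue/qValue/peak) are kept
#' as opaque payload columns `extra1`, `extra2`, ... and written back verbatim
#' by [write_bed()].
#'
#' @param path file path.
#' @return A `gintervals` data frame.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(track|browser|#)", lines)
  lnum <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(gintervals(character(), numeric(), numeric())[0, ])
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3))
    stop_fmt("%s line %d: BED needs at least 3 columns", path, lnum[which(ncols < 3)[1]])
  nc <- min(ncols)
  get <- function(i) vapply(parts, function(p) p[i], character(1))
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop_fmt("%s line %d: invalid BED coordinates '%s'",
             path, lnum[bad[1]], lines[bad[1]])
  df <- data.frame(chrom = get(1), start = start, end = end,
                   stringsAsFactors = FALSE)
  df$name <- if (nc >= 4) get(4) else NA_character_
  df$name[df$name == "."] <- NA_character_
  df$score <- if (nc >= 5) suppressWarnings(as.numeric(get(5))) else NA_real_
  if (nc >= 6) {
    strand <- get(6)
    strand[strand == "."] <- "*"
    badstr <- which(!strand %in% c("+", "-", "*"))
    if (length(badstr))
      stop_fmt("%s line %d: unknown strand token '%s'",
               path, lnum[badstr[1]], get(6)[badstr[1]])
    df$strand <- strand
  } else df$strand <- "*"
  if (nc >= 7)
    for (i in 7:nc) df[[paste0("extra", i - 6)]] <- get(i)
  as_gintervals(df)
}

#' Write intervals as BED
#'
#' Emits tab-separated, newline-terminated lines with no trailing whitespace.
#' `NA` names are written as `"."`, `NA` scores as `0`, unstranded intervals
#' as `"."`; payload columns `extra*` follow in order.
#'
#' @param x a `gintervals` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- ifelse(is.na(x$name %||% rep(NA, nrow(x))), ".", x$name)
  score <- ifelse(is.na(x$score), 0, x$score)
  strand <- ifelse(x$strand == "*", ".", x$strand)
  cols <- list(x$chrom, format_bp(x$start), format_bp(x$end),
               name, score, strand)
  extras <- grep("^extra[0-9]+$", names(x), value = TRUE)
  for (nm in extras[order(as.integer(sub("extra", "", extras)))])
    cols <- c(cols, list(x[[nm]]))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read gene models from a GTF file
#'
#' GTF is 1-based inclusive and converted to 0-based half-open on read.
#' Records are grouped by `gene_id`; each gene's model spans the outermost
#' coordinates of its records. Only `+`/`-` stranded records are accepted.
#'
#' @param path file path.
#' @param feature if non-`NULL`, restrict to this feature type (column 3),
#'   e.g. `"gene"`; by default all records contribute to the outermost span.
#' @return A [gene_models()] data frame.
#' @export
read_gtf <- function(path, feature = NULL) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path)
  lnum <- which(nzchar(lines) & !startsWith(lines, "#"))
  lines <- lines[lnum]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 9)
  if (length(short))
    stop_fmt("%s line %d: GTF needs 9 tab-separated columns", path, lnum[short[1]])
  get <- function(i) vapply(parts, function(p) p[i], character(1))
  feat <- get(3)
  sel <- if (is.null(feature)) rep(TRUE, length(feat)) else feat == feature
  if (!any(sel)) stop_fmt("%s: no matching GTF records", path)
  start1 <- suppressWarnings(as.numeric(get(4)))[sel]
  end1 <- suppressWarnings(as.numeric(get(5)))[sel]
  strand <- get(7)[sel]
  attrs <- get(9)[sel]
  ln <- lnum[sel]
  bad <- which(is.na(start1) | is.na(end1) | start1 < 1 | end1 < start1)
  if (length(bad))
    stop_fmt("%s line %d: invalid GTF coordinates", path, ln[bad[1]])
  badstr <- which(!strand %in% c("+", "-"))
  if (length(badstr))
    stop_fmt("%s line %d: unknown strand token '%s'", path, ln[badstr[1]],
             strand[badstr[1]])
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", attrs)
  nogid <- which(gid == attrs)
  if (length(nogid))
    stop_fmt("%s line %d: missing gene_id attribute", path, ln[nogid[1]])
  bt <- rep(NA_character_, length(attrs))
  has_bt <- grepl('gene_biotype "', attrs, fixed = TRUE)
  bt[has_bt] <- sub('.*gene_biotype "([^"]+)".*', "\\1", attrs[has_bt])
  chrom <- get(1)[sel]
  agg <- split(seq_along(gid), gid)
  first <- vapply(agg, `[`, integer(1), 1L)
  gene_models(
    gene_id = names(agg),
    chrom = chrom[first],
    start = vapply(agg, function(i) min(start1[i]), numeric(1)) - 1,
    end = vapply(agg, function(i) max(end1[i]), numeric(1)),
    strand = strand[first],
    biotype = ifelse(is.na(bt[first]), "protein_coding", bt[first])
  )
}

#' Write gene models as GTF gene records
#'
#' Coordinates are converted back to 1-based inclusive.
#'
#' @param genes a `gene_models` data frame.
#' @param path output file path.
#' @param source source tag for column 2.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path, source = "tssmap") {
  attrs <- sprintf('gene_id "%s"; gene_biotype "%s";',
                   genes$gene_id, genes$biotype)
  writeLines(paste(genes$chrom, source, "gene",
                   format_bp(genes$start + 1), format_bp(genes$end),
                   ".", genes$strand, ".", attrs, sep = "\t"), path)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path file path.
#' @return A `gintervals` data frame whose `score` holds the bedGraph value.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path)
  lnum <- which(nzchar(lines) & !grepl("^(track|browser|#)", lines))
  lines <- lines[lnum]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 4)
  if (length(short))
    stop_fmt("%s line %d: bedGraph needs 4 columns", path, lnum[short[1]])
  get <- function(i) vapply(parts, function(p) p[i], character(1))
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  val <- suppressWarnings(as.numeric(get(4)))
  bad <- which(is.na(start) | is.na(end) | is.na(val) | start < 0 | start >= end)
  if (length(bad))
    stop_fmt("%s line %d: invalid bedGraph record", path, lnum[bad[1]])
  as_gintervals(data.frame(chrom = get(1), start = start, end = end,
                           score = val, stringsAsFactors = FALSE))
}

#' Read / write a TSV table with a header row
#'
#' Plain tab-separated values with a header line; all writers in the package
#' emit tab-separated, newline-terminated output with no trailing whitespace,
#' so `read_tsv_table(write_tsv_table(x, p))` round-trips.
#'
#' @param path file path.
#' @param required character vector of column names that must be present.
#' @return A plain `data.frame`.
#' @export
read_tsv_table <- function(path, required = NULL) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_fmt("%s: missing required column(s): %s", path,
             paste(miss, collapse = ", "))
  df
}

#' @rdname read_tsv_table
#' @param x a data frame to write.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
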