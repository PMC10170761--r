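#' Expression groups by TPM quartile
#'
#' Splits all genes evenly into four contiguous groups by ascending mean TPM
#' (none < low < medium < high). Genes are sorted by (mean TPM, gene_id) and
#' cut into groups of size `floor(n/4)`, with the remainder `r` assigned one
#' extra gene to the lowest `r` groups, so group sizes differ by at most 1.
#'
#' @param expr data frame with a `gene_id` column and one numeric TPM column
#'   per replicate (or a single `tpm` column).
#' @return data frame (gene_id, mean_tpm, group) with `group` an ordered
#'   factor none < low < medium < high.
#' @export
expression_groups <- function(expr) {
  stopifnot("gene_id" %in% names(expr))
  if (anyDuplicated(expr$gene_id)) stop_fmt("duplicated gene_id in expression table")
  num <- vapply(expr, is.numeric, logical(1)) & names(expr) != "gene_id"
  if (!any(num)) stop_fmt("no numeric TPM column found")
  tpm <- rowMeans(as.matrix(expr[, num, drop = FALSE]))
  if (any(tpm < 0)) stop_fmt("negative TPM")
  n <- nrow(expr)
  if (n < 4) stop_fmt("need at least 4 genes to form quartile groups")
  ord <- order(tpm, expr$gene_id, method = "radix")
  base <- n %/% 4
  r <- n %% 4
  sizes <- base + (seq_len(4) <= r)
  labels <- c("none", "low", "medium", "high")
  grp <- rep(labels, times = sizes)
  out <- data.frame(gene_id = expr$gene_id[ord], mean_tpm = tpm[ord],
                    group = factor(grp, levels = labels, ordered = TRUE),
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, method = "radix"), , drop = FALSE]
}

#' Occupancy fraction per expression group
#'
#' @param groups output of [expression_groups()].
#' @param occupancy output of [classify_gene_occupancy()]; genes absent from
#'   `groups` are an error (the two must share a gene universe), genes absent
#'   from `occupancy` count as unoccupied.
#' @return data frame (group, n_genes, n_occupied, fraction_occupied),
#'   ordered none to high.
#' @export
occupancy_by_expression <- function(groups, occupancy) {
  extra <- setdiff(occupancy$gene_id, groups$gene_id)
  if (length(extra))
    stop_fmt("gene(s) in occupancy but not in expression groups: %s",
             paste(utils::head(extra, 5), collapse = ", "))
  occ_ids <- occupancy$gene_id[occupancy$class != "unoccupied"]
  occ <- groups$gene_id %in% occ_ids
  lv <- levels(groups$group)
  data.frame(
    group = factor(lv, levels = lv, ordered = TRUE),
    n_genes = as.integer(table(groups$group)[lv]),
    n_occupied = vapply(lv, function(g) sum(occ[groups$group == g]), numeric(1)),
    fraction_occupied = vapply(lv, function(g) mean(occ[groups$group == g]),
                               numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Meta-intersection of differential-expression tables
#'
#' A gene belongs to the consistent set iff its adjusted p-value is below
#' `alpha` in every table (strict inequality). Direction is `"down"` if the
#' log2 fold change is negative at all timepoints, `"up"` if positive at all,
#' else `"discordant"`. Genes missing from any table are excluded and
#' counted. Venn region sizes over all significance patterns are returned.
#'
#' @param tables named list of >= 2 data frames with columns `gene_id`,
#'   `log2fc`, `padj`.
#' @param alpha significance cutoff on adjusted p (default 0.05).
#' @return A list with class `"meta_de"`: `genes` (consistent ids), `lfc` and
#'   `padj` (matrices, consistent genes x timepoints), `direction`, `counts`
#'   (`consistent`, `down`, `up`, `discordant`), `venn` (named region sizes),
#'   `n_excluded`, `alpha`.
#' @export
de_meta_intersection <- function(tables, alpha = 0.05) {
  if (length(tables) < 2) stop_fmt("need at least 2 DE tables")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- paste0("t", seq_along(tables))
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    miss <- setdiff(c("gene_id", "log2fc", "padj"), names(tb))
    if (length(miss))
      stop_fmt("DE table '%s' missing column(s): %s", nm,
               paste(miss, collapse = ", "))
    if (any(tb$padj < 0 | tb$padj > 1, na.rm = TRUE))
      stop_fmt("DE table '%s': padj outside [0, 1]", nm)
  }
  all_ids <- unique(unlist(lapply(tables, `[[`, "gene_id")))
  shared <- Reduce(intersect, lapply(tables, `[[`, "gene_id"))
  n_excluded <- length(all_ids) - length(shared)
  if (n_excluded)
    message(sprintf("de_meta_intersection: %d gene(s) missing from some table, excluded",
                    n_excluded))
  lfc <- sapply(tables, function(tb)
    tb$log2fc[match(shared, tb$gene_id)])
  padj <- sapply(tables, function(tb)
    tb$padj[match(shared, tb$gene_id)])
  if (length(shared) == 1) { lfc <- t(lfc); padj <- t(padj) }
  sig <- padj < alpha
  pattern <- apply(sig, 1, function(s) paste(names(tables)[s], collapse = "&"))
  pattern[pattern == ""] <- "none"
  venn <- table(pattern)
  consistent <- which(rowSums(sig) == length(tables))
  dirs <- apply(lfc[consistent, , drop = FALSE], 1, function(l)
    if (all(l < 0)) "down" else if (all(l > 0)) "up" else "discordant")
  structure(list(
    genes = shared[consistent],
    lfc = lfc[consistent, , drop = FALSE],
    padj = padj[consistent, , drop = FALSE],
    direction = unname(dirs),
    counts = list(consistent = length(consistent),
                  down = sum(dirs == "down"), up = sum(dirs == "up"),
                  discordant = sum(dirs == "discordant")),
    venn = setNames(as.integer(venn), names(venn)),
    n_excluded = n_excluded,
    alpha = alpha
  ), class = "meta_de")
}

#' @export
print.meta_de <- function(x, ...) {
  cat(sprintf("<meta_de> %d consistent gene(s): %d down, %d up, %d discordant (alpha %.3g)\n",
              x$counts$consistent, x$counts$down, x$counts$up,
              x$counts$discordant, x$alpha))
  invisible(x)
}

#' Averaged DE statistics over the consistent set
#'
#' Arithmetic mean across timepoints of the log2 fold change and the adjusted
#' p-value, per consistent gene.
#'
#' @param result a [de_meta_intersection()] result.
#' @return data frame (gene_id, mean_log2fc, mean_padj, direction).
#' @export
average_de_stats <- function(result) {
  stopifnot(inherits(result, "meta_de"))
  data.frame(gene_id = result$genes,
             mean_log2fc = rowMeans(result$lfc),
             mean_padj = rowMeans(result$padj),
             direction = result$direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sided Wilcoxon rank-sum comparison of two expression groups
#'
#' Uses the exact null distribution of the Mann-Whitney U statistic when both
#' groups have at most 8 values and there are no ties; otherwise the normal
#' approximation with tie-corrected variance. All-identical pooled values
#' give p = 1.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param exact_max exact-branch group-size cutoff (default 8).
#' @return list with `statistic` (U for group `a`), `p`, and `method`
#'   (`"exact"` or `"normal"`).
#' @export
compare_group_expression <- function(a, b, exact_max = 8) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (length(unique(pooled)) == 1)
    return(list(statistic = na * nb / 2, p = 1, method = "degenerate"))
  ties <- any(duplicated(pooled))
  if (na <= exact_max && nb <= exact_max && !ties) {
    p <- if (U > na * nb / 2) {
      2 * (1 - pwilcox(U - 1, na, nb))
    } else {
      2 * pwilcox(U, na, nb)
    }
    return(list(statistic = U, p = min(1, p), method = "exact"))
  }
  n <- na + nb
  tt <- table(pooled)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
  # continuity-corrected normal approximation with tie-corrected variance
  z <- max(0, abs(U - na * nb / 2) - 0.5) / sqrt(sigma2)
  list(statistic = U, p = min(1, 2 * pnorm(-z)), method = "normal")
}
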