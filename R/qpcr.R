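#' qPCR cycle-threshold table
#'
#' Long-format Ct measurements: one row per (target locus or gene, channel,
#' condition, biological replicate), with one or more technical-replicate Ct
#' columns `ct1..ctK`. The channel distinguishes e.g. the IP antibody in
#' ChIP-qPCR (cleaved-H3 vs total H3) or the transcript vs housekeeping gene
#' in RT-qPCR.
#'
#' @param df data frame with columns `target`, `channel`, `condition`,
#'   `bio_rep` and at least one `ct*` column of positive cycle values.
#' @return The validated data frame with class `"ct_table"`.
#' @export
ct_table <- function(df) {
  need <- c("target", "channel", "condition", "bio_rep")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("Ct table missing column(s): %s", paste(miss, collapse = ", "))
  ctc <- grep("^ct[0-9]*$", names(df), value = TRUE)
  if (!length(ctc)) stop_fmt("Ct table has no ct columns")
  vals <- as.matrix(df[, ctc, drop = FALSE])
  if (any(vals <= 0, na.rm = TRUE)) stop_fmt("Ct values must be > 0")
  if (any(rowSums(!is.na(vals)) == 0))
    stop_fmt("each row needs at least one technical-replicate Ct")
  class(df) <- c("ct_table", class(df))
  df
}

#' Read a Ct table from TSV
#' @param path file path.
#' @return a [ct_table()].
#' @export
read_ct_table <- function(path) {
  ct_table(read_tsv_table(path, required = c("target", "channel",
                                             "condition", "bio_rep")))
}

#' Mean Ct over technical replicates
#'
#' Technical replicates are averaged on the Ct (cycle) scale, before any
#' exponentiation to fold changes.
#'
#' @param cts numeric Ct values (NA dropped).
#' @return mean Ct.
#' @export
aggregate_technical <- function(cts) {
  cts <- cts[!is.na(cts)]
  if (!length(cts)) stop_fmt("no Ct values to aggregate")
  mean(cts)
}

# mean Ct per (target, channel, condition, bio_rep)
mean_ct_by_row <- function(ct) {
  ctc <- grep("^ct[0-9]*$", names(ct), value = TRUE)
  vals <- as.matrix(as.data.frame(ct)[, ctc, drop = FALSE])
  rowMeans(vals, na.rm = TRUE)
}

#' Relative expression by the delta-delta-Ct method
#'
#' `2^-((ct_target_s - ct_house_s) - (ct_target_ref - ct_house_ref))`:
#' expression of a target gene in a sample relative to a reference condition,
#' each normalized to a housekeeping gene.
#'
#' @param ct_target_s,ct_house_s mean Cts of target and housekeeping gene in
#'   the sample.
#' @param ct_target_ref,ct_house_ref the same in the reference condition.
#' @return fold change (1 = no change).
#' @export
ddct_expression <- function(ct_target_s, ct_house_s,
                            ct_target_ref, ct_house_ref) {
  ddct <- (ct_target_s - ct_house_s) - (ct_target_ref - ct_house_ref)
  2^(-ddct)
}

#' ChIP-qPCR fold change over total H3
#'
#' `2^-(ip_ct - h3_ct)`: enrichment of an IP (e.g. cleaved-H3 antibody)
#' relative to total histone H3 occupancy at the same locus.
#'
#' @param ip_ct,h3_ct mean Cts of the IP and the H3 control IP.
#' @return fold over H3.
#' @export
fold_over_h3 <- function(ip_ct, h3_ct) 2^(-(ip_ct - h3_ct))

#' Significance stars for p-values
#'
#' `ns` for p > 0.05, then `*` < 0.05, `**` < 0.005, `***` < 0.0005,
#' `****` < 0.00005 (strict inequalities; p exactly 0.05 is `ns`).
#'
#' @param p p-value(s).
#' @return character vector of labels.
#' @export
star_label <- function(p) {
  cut_pts <- c(0.00005, 0.0005, 0.005, 0.05)
  labs <- c("****", "***", "**", "*", "ns")
  # number of thresholds strictly above p decides the label
  labs[5L - rowSums(outer(p, cut_pts, `<`))]
}

#' Compare fold changes between two conditions by t-test
#'
#' Two-sided unpaired Student t-test on biological-replicate fold changes,
#' pooled-variance by default (Welch by flag), with the star annotation of
#' [star_label()]. Two zero-variance groups with equal means give p = 1.
#'
#' @param folds_a,folds_b numeric fold changes (each >= 2 biological
#'   replicates).
#' @param welch use Welch's unequal-variance test (default `FALSE`).
#' @return list with `t`, `df`, `p`, `stars`.
#' @export
compare_conditions <- function(folds_a, folds_b, welch = FALSE) {
  stopifnot(length(folds_a) >= 2, length(folds_b) >= 2)
  if (var(folds_a) == 0 && var(folds_b) == 0) {
    if (mean(folds_a) == mean(folds_b))
      return(list(t = 0, df = length(folds_a) + length(folds_b) - 2,
                  p = 1, stars = "ns"))
    return(list(t = sign(mean(folds_a) - mean(folds_b)) * Inf,
                df = length(folds_a) + length(folds_b) - 2, p = 0,
                stars = "****"))
  }
  tt <- t.test(folds_a, folds_b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, stars = star_label(tt$p.value))
}

#' Per-replicate ChIP-qPCR folds and condition comparison
#'
#' For each (target, condition, biological replicate): technical replicates
#' are averaged on the Ct scale, the IP channel's mean Ct is compared with
#' the H3 channel's ([fold_over_h3()]). Fold means and standard deviations
#' across biological replicates are computed on the fold scale, and
#' conditions are compared per target with [compare_conditions()].
#'
#' @param ct a [ct_table()].
#' @param ip_channel channel name of the IP of interest.
#' @param h3_channel channel name of the total-H3 control (default `"H3"`).
#' @param ref_condition condition compared against every other condition.
#' @param welch passed to [compare_conditions()].
#' @return list with `folds` (per target/condition/bio_rep) and `summary`
#'   (per target/condition mean, sd, and vs-reference p and stars).
#' @export
chip_qpcr_analysis <- function(ct, ip_channel, h3_channel = "H3",
                               ref_condition = NULL, welch = FALSE) {
  df <- as.data.frame(ct)
  df$mean_ct <- mean_ct_by_row(ct)
  ip <- df[df$channel == ip_channel, ]
  h3 <- df[df$channel == h3_channel, ]
  if (!nrow(ip) || !nrow(h3))
    stop_fmt("channel '%s' or '%s' absent from Ct table", ip_channel, h3_channel)
  key <- function(d) paste(d$target, d$condition, d$bio_rep, sep = "\r")
  m <- match(key(ip), key(h3))
  if (anyNA(m))
    stop_fmt("missing H3 control for %s", key(ip)[which(is.na(m))[1]])
  folds <- data.frame(target = ip$target, condition = ip$condition,
                      bio_rep = ip$bio_rep,
                      fold = fold_over_h3(ip$mean_ct, h3$mean_ct[m]),
                      stringsAsFactors = FALSE)
  if (is.null(ref_condition)) ref_condition <- folds$condition[1]
  smry <- do.call(rbind, lapply(split(folds, folds[c("target", "condition")],
                                      drop = TRUE), function(d) {
    data.frame(target = d$target[1], condition = d$condition[1],
               n = nrow(d), mean_fold = mean(d$fold), sd_fold = sd(d$fold),
               stringsAsFactors = FALSE)
  }))
  smry$p <- NA_real_; smry$stars <- NA_character_
  for (i in seq_len(nrow(smry))) {
    if (smry$condition[i] == ref_condition) next
    fa <- folds$fold[folds$target == smry$target[i] &
                       folds$condition == ref_condition]
    fb <- folds$fold[folds$target == smry$target[i] &
                       folds$condition == smry$condition[i]]
    if (length(fa) >= 2 && length(fb) >= 2) {
      cmp <- compare_conditions(fa, fb, welch = welch)
      smry$p[i] <- cmp$p
      smry$stars[i] <- cmp$stars
    }
  }
  rownames(smry) <- NULL
  list(folds = folds, summary = smry, ref_condition = ref_condition)
}
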