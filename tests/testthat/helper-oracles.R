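# Independent brute-force oracles used to check the interval algebra and
# the profile machinery. These deliberately avoid the package's own set
# operations: everything is done on per-basepair boolean masks or explicit
# per-bp vectors, feasible on genomes up to ~100 kb.

# random intervals on a small single-chromosome genome
random_intervals <- function(n, genome_len = 1e5, max_width = 2000,
                             chrom = "chrS") {
  start <- floor(runif(n, 0, genome_len - max_width))
  width <- pmax(1, floor(runif(n, 1, max_width)))
  gintervals(chrom, start, pmin(start + width, genome_len))
}

# per-bp boolean mask of interval coverage (mask[i] == bp i-1 covered)
mask_of <- function(x, genome_len) {
  m <- logical(genome_len)
  for (i in seq_len(nrow(x))) m[(x$start[i] + 1):x$end[i]] <- TRUE
  m
}

# merge via the mask: bridge gaps <= gap bp, then read off runs
mask_merge <- function(x, gap, genome_len) {
  m <- mask_of(x, genome_len)
  if (gap > 0) {
    r <- rle(m)
    off <- cumsum(c(0, r$lengths))
    inside <- which(!r$values & r$lengths <= gap &
                      seq_along(r$values) > 1 &
                      seq_along(r$values) < length(r$values))
    for (k in inside) m[(off[k] + 1):off[k + 1]] <- TRUE
  }
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# consensus via brute force: keep any interval overlapping >= 1 bp with some
# interval in every replicate, then mask-merge at gap 0
mask_consensus <- function(reps, genome_len) {
  masks <- lapply(reps, function(r) mask_of(r$intervals, genome_len))
  kept <- list()
  for (i in seq_along(reps)) {
    iv <- reps[[i]]$intervals
    ok <- vapply(seq_len(nrow(iv)), function(j) {
      span <- (iv$start[j] + 1):iv$end[j]
      all(vapply(seq_along(reps), function(k)
        k == i || any(masks[[k]][span]), logical(1)))
    }, logical(1))
    kept[[i]] <- iv[ok, , drop = FALSE]
  }
  all_kept <- do.call(rbind, kept)
  if (!nrow(all_kept)) return(data.frame(start = numeric(), end = numeric()))
  mask_merge(as_gintervals(all_kept), 0, genome_len)
}

# per-bp signal vector for a single-chromosome track
perbp_signal <- function(track, chrom) {
  v <- track$counts[[chrom]]
  L <- layout_lengths(track$layout)[[chrom]]
  rep(v, each = track$bin_size)[seq_len(L)]
}

# brute-force reference-point row: mean per-bp signal in each cell of
# [pos - flank, pos + flank), reversed for minus strand; NA outside genome
perbp_refpoint_row <- function(sbp, pos, strand, flank, bin) {
  ncol <- 2 * flank / bin
  L <- length(sbp)
  cell <- rep(NA_real_, ncol)
  for (j in seq_len(ncol)) {
    lo <- pos - flank + (j - 1) * bin
    hi <- lo + bin
    if (lo >= 0 && hi <= L) cell[j] <- mean(sbp[(lo + 1):hi])
  }
  if (strand == "-") cell <- rev(cell)
  cell
}

# brute-force scaled-region row for a gene whose length is divisible by
# body_bins (so slice boundaries are integral)
perbp_scaled_row <- function(sbp, start, end, strand, body_bins, flank, bin) {
  L <- length(sbp)
  nf <- flank / bin
  gl <- end - start
  stopifnot(gl %% body_bins == 0)
  sw <- gl / body_bins
  edges <- c(start - flank + bin * (0:(nf - 1)),
             start + sw * (0:body_bins),
             end + bin * (1:nf))
  cell <- rep(NA_real_, 2 * nf + body_bins)
  for (j in seq_along(cell)) {
    lo <- edges[j]; hi <- edges[j + 1]
    if (lo >= 0 && hi <= L) cell[j] <- mean(sbp[(lo + 1):hi])
  }
  if (strand == "-") cell <- rev(cell)
  cell
}

# full-enumeration two-sided rank-sum p for distinct values
enumerate_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)))
  na <- length(a)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(length(pooled), na)
  U_all <- apply(sets, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  m <- na * length(b) / 2
  min(1, 2 * min(mean(U_all <= U_obs), mean(U_all >= U_obs)))
}

# tiny helper: pearson from the direct covariance formula
pearson_direct <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

small_sim_config <- function(seed = 11, ...) {
  sim_config(seed = seed, n_chroms = 2, chrom_length = 2e6, n_genes = 300,
             de_core_size = 50, de_core_down = 30, ...)
}
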