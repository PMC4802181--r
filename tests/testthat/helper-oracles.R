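# Independent brute-force oracles. Deliberately naive (loops, all-pairs,
# exhaustive enumeration) and kept free of the package's code paths.

# reads/bins as plain vectors; counts reads overlapping each bin
bf_bin_counts <- function(read_start, read_end, chrom_len, bin_size) {
  n_bins <- ceiling(chrom_len / bin_size)
  counts <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    bs <- (b - 1) * bin_size + 1
    be <- min(b * bin_size, chrom_len)
    counts[b] <- sum(read_start <= be & read_end >= bs)
  }
  counts
}

# centred truncated running mean then log2(pseudocount + mean)
bf_smooth <- function(counts, h, pseudocount) {
  n <- length(counts)
  vapply(seq_len(n), function(i) {
    w <- max(1, i - h):min(n, i + h)
    log2(pseudocount + mean(counts[w]))
  }, numeric(1))
}

# merge 1-based closed intervals (same chromosome)
bf_merge <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out <- NULL
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1) me <- max(me, end[i])
    else { out <- rbind(out, c(ms, me)); ms <- start[i]; me <- end[i] }
  }
  rbind(out, c(ms, me))
}

# point-in-any-interval membership
bf_point_in <- function(pts, start, end)
  vapply(pts, function(p) any(p >= start & p <= end), logical(1))

# all-pairs minimum distances for one cell's spot channels
bf_min_distances <- function(R, V, C) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  t(vapply(seq_len(nrow(R)), function(i) {
    dg <- min(vapply(seq_len(nrow(V)), function(j) d(R[i, ], V[j, ]),
                     numeric(1)))
    dcs <- vapply(seq_len(nrow(C)), function(j) d(R[i, ], C[j, ]),
                  numeric(1))
    k <- which.min(dcs)
    dcv <- min(vapply(seq_len(nrow(V)), function(j) d(C[k, ], V[j, ]),
                      numeric(1)))
    c(d_gene = dg, d_cb = min(dcs), d_cb_vgoi = dcv)
  }, numeric(3)))
}

# two-sided Fisher by exhaustive hypergeometric enumeration
bf_fisher <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a)
    stats::dhyper(a, r1, r2, c1), numeric(1))
  p_obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# per-gene group-by tally of unique junction keys
bf_gene_summary <- function(df) {
  key <- paste(df$chrom, df$donor, df$acceptor, df$strand, df$gene_id)
  df <- df[!duplicated(key), , drop = FALSE]
  df <- df[!(df$gene_id %in% c("intergenic", "ambiguous")), , drop = FALSE]
  sapply(split(df, df$gene_id), nrow)
}

# small genome + track builders shared across tests
tg2 <- function() toy_genome(c(chrA = 2e5, chrB = 1e5))

make_track <- function(counts_by_chrom, bin_size = 10000) {
  genome <- toy_genome(vapply(counts_by_chrom, function(x)
    length(x) * bin_size, 0))
  tr <- bin_reads(GenomicRanges::GRanges(seqinfo = genome), genome,
                  bin_size = bin_size)
  S4Vectors::mcols(tr)$count <- unlist(counts_by_chrom, use.names = FALSE)
  tr
}

make_profile <- function(values_by_chrom, bin_size = 10000) {
  tr <- make_track(values_by_chrom, bin_size)
  S4Vectors::mcols(tr) <- NULL
  S4Vectors::mcols(tr)$value <- unlist(values_by_chrom, use.names = FALSE)
  S4Vectors::metadata(tr) <- list(bin_size = bin_size, window = 1e5,
                                  pseudocount = 0.1)
  tr
}
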