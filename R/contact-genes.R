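#' Extend contact regions symmetrically and merge overlaps
#'
#' Grows each region by `window` bp on both sides, clips to chromosome
#' bounds, and merges any resulting overlapping or adjacent-after-overlap
#' intervals.
#'
#' @param regions GRanges of contact regions.
#' @param window Extension in bp on each side (>= 0); the study design
#'   uses 10, 25 and 50 kb.
#' @return Merged GRanges.
#' @export
extend_regions <- function(regions, window) {
  stopifnot(window >= 0)
  # widening may transiently exceed the chromosome ends; trim() clips it
  ext <- GenomicRanges::trim(suppressWarnings(regions + window))
  GenomicRanges::reduce(ext, ignore.strand = TRUE)
}

#' Select genes whose midpoint falls in a region set
#'
#' A gene is included iff its midpoint lies within any of the (typically
#' extended) regions. On 1-based closed coordinates the midpoint is
#' `(start - 1 + end) %/% 2 + 1`, which matches the floor-midpoint of the
#' corresponding 0-based half-open interval.
#'
#' @param genes GRanges of genes.
#' @param regions GRanges (e.g. from [extend_regions()]).
#' @return The subset of `genes` whose midpoint overlaps `regions`.
#' @export
intersect_genes_midpoint <- function(genes, regions) {
  mid <- (BiocGenerics::start(genes) - 1 + BiocGenerics::end(genes)) %/% 2 + 1
  pts <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                                IRanges::IRanges(mid, width = 1))
  hit <- IRanges::overlapsAny(pts, regions, ignore.strand = TRUE)
  genes[hit]
}

#' Expression filter: top fraction of all genes, ties kept
#'
#' The threshold is the k-th largest expression value with
#' `k = ceiling(fraction * n)` over ALL genes (nearest rank); every gene
#' at or above the threshold passes, so ties at the cutoff are kept
#' inclusively.
#'
#' @param genes GRanges with an `expression` metadata column.
#' @param fraction Fraction of genes to keep (default 0.05).
#' @return The passing subset of `genes`.
#' @export
select_expressed_top_fraction <- function(genes, fraction = 0.05) {
  if (length(genes) == 0) stop("empty gene list")
  stopifnot(fraction > 0, fraction <= 1)
  expr <- S4Vectors::mcols(genes)$expression
  k <- ceiling(fraction * length(genes))
  thr <- sort(expr, decreasing = TRUE)[k]
  genes[expr >= thr]
}

#' Build the 4C-positive gene set
#'
#' Genes whose midpoint overlaps the extended contact regions AND whose
#' expression is in the top `fraction` of all genes.
#'
#' @param genes GRanges with `expression`.
#' @param regions Raw contact regions (extended here by `window`).
#' @param window Extension in bp (default 10000).
#' @param fraction Expression top fraction (default 0.05).
#' @return The 4C-positive subset of `genes`.
#' @export
define_positive_set <- function(genes, regions, window = 10000,
                                fraction = 0.05) {
  top <- select_expressed_top_fraction(genes, fraction)
  intersect_genes_midpoint(top, extend_regions(regions, window))
}

#' Build the 4C-negative control gene set
#'
#' Genes in the top `fraction` of expression whose interval lies entirely
#' more than `distance` bp from every contact region.
#'
#' @param genes GRanges with `expression`.
#' @param regions Raw contact regions.
#' @param distance Minimum distance in bp (default 50000; strict `>`).
#' @param fraction Expression top fraction (default 0.05).
#' @return The 4C-negative subset of `genes`.
#' @export
define_negative_set <- function(genes, regions, distance = 50000,
                                fraction = 0.05) {
  top <- select_expressed_top_fraction(genes, fraction)
  if (length(regions) == 0) return(top)
  d <- GenomicRanges::distanceToNearest(top, regions, ignore.strand = TRUE)
  dist <- rep(Inf, length(top))  # no region on the gene's chromosome
  dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  top[dist > distance]
}

# fast midpoint-in-merged-intervals counter used inside permutation loops;
# mids: list per chrom of sorted gene midpoints, iv: data.frame chrom/start/end
# (intervals disjoint and sorted within chrom)
.count_mid_in_intervals <- function(mids, iv) {
  total <- 0L
  for (ch in unique(iv$chrom)) {
    m <- mids[[ch]]
    if (is.null(m)) next
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    idx <- findInterval(m, sub$start)
    total <- total + sum(idx > 0 & m <= sub$end[pmax(idx, 1L)])
  }
  total
}

.merge_intervals <- function(chrom, start, end) {
  o <- order(chrom, start)
  chrom <- chrom[o]; start <- start[o]; end <- end[o]
  keep_c <- character(0); keep_s <- numeric(0); keep_e <- numeric(0)
  for (i in seq_along(start)) {
    k <- length(keep_s)
    if (k > 0 && chrom[i] == keep_c[k] && start[i] <= keep_e[k] + 1) {
      keep_e[k] <- max(keep_e[k], end[i])
    } else {
      keep_c <- c(keep_c, chrom[i]); keep_s <- c(keep_s, start[i])
      keep_e <- c(keep_e, end[i])
    }
  }
  data.frame(chrom = keep_c, start = keep_s, end = keep_e)
}

#' Permutation enrichment of gene classes near contact regions
#'
#' The observed statistic is the number of target-class genes whose
#' midpoint lies within `window` bp of a contact region. Each null sample
#' redraws the contact regions as random non-overlapping intervals of
#' matching count, length and chromosome, placed uniformly, and recomputes
#' the statistic. The empirical P value uses the add-one correction
#' `(1 + #\{null >= observed\}) / (1 + n_samples)`, so its minimum is
#' `1 / (n_samples + 1)`, never zero.
#'
#' @param regions GRanges of contact regions (non-empty).
#' @param genes GRanges with `gene_class`.
#' @param target_classes Gene classes counted (default the small-RNA and
#'   histone classes).
#' @param window Proximity window in bp (default 10000).
#' @param n_samples Number of random samples (default 100).
#' @param seed Integer seed.
#' @return List of class `enrichment_result`: observed, null_counts,
#'   empirical_p, n_samples, seed.
#' @export
permutation_enrichment <- function(regions, genes,
                                   target_classes = c("snRNA", "snoRNA",
                                                      "scaRNA", "histone"),
                                   window = 10000, n_samples = 100,
                                   seed = 1L) {
  if (length(regions) == 0) stop("regions must be non-empty")
  sl <- .seqlen(GenomeInfoDb::seqinfo(regions))
  chrom <- as.character(GenomeInfoDb::seqnames(regions))
  len <- BiocGenerics::width(regions)
  if (any(len > sl[chrom]))
    stop("a region is longer than its chromosome")
  withr::local_seed(seed)

  tg <- genes[S4Vectors::mcols(genes)$gene_class %in% target_classes]
  gmid <- (BiocGenerics::start(tg) - 1 + BiocGenerics::end(tg)) %/% 2 + 1
  gch <- as.character(GenomeInfoDb::seqnames(tg))
  mids <- lapply(split(gmid, gch), sort)

  count_for <- function(start, end) {
    iv <- .merge_intervals(chrom, pmax(start - window, 1),
                           pmin(end + window, sl[chrom]))
    .count_mid_in_intervals(mids, iv)
  }
  observed <- count_for(BiocGenerics::start(regions),
                        BiocGenerics::end(regions))

  null_counts <- integer(n_samples)
  for (s in seq_len(n_samples)) {
    repeat {
      start <- 1 + floor(stats::runif(length(len)) * (sl[chrom] - len + 1))
      end <- start + len - 1
      # reject placements where same-chromosome intervals overlap
      ok <- TRUE
      for (ch in unique(chrom)) {
        i <- chrom == ch
        if (sum(i) > 1) {
          o <- order(start[i])
          ss <- start[i][o]; ee <- end[i][o]
          if (any(ss[-1] <= ee[-length(ee)])) { ok <- FALSE; break }
        }
      }
      if (ok) break
    }
    null_counts[s] <- count_for(start, end)
  }
  structure(list(observed = observed, null_counts = null_counts,
                 empirical_p = (1 + sum(null_counts >= observed)) /
                   (1 + n_samples),
                 n_samples = n_samples, window = window, seed = seed),
            class = "enrichment_result")
}
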