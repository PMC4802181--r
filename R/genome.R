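#' Construct a toy genome
#'
#' A toy genome is a [GenomeInfoDb::Seqinfo] object: a small set of named
#' chromosomes with lengths, standing in for a real assembly at desk scale.
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp
#'   (names are chromosome names), or a data.frame with columns `name` and
#'   `length`.
#' @return A `Seqinfo` object.
#' @examples
#' toy_genome(c(chr1 = 2e6, chr2 = 1e6))
#' @export
toy_genome <- function(chromosomes) {
  if (is.data.frame(chromosomes)) {
    nm <- as.character(chromosomes$name)
    len <- as.numeric(chromosomes$length)
  } else {
    nm <- names(chromosomes)
    len <- as.numeric(chromosomes)
  }
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("every chromosome must be named")
  if (anyDuplicated(nm)) stop("chromosome names must be unique")
  if (anyNA(len) || any(len <= 0)) stop("chromosome lengths must be > 0")
  GenomeInfoDb::Seqinfo(seqnames = nm, seqlengths = as.integer(len))
}

#' @keywords internal
.seqlen <- function(genome) {
  stats::setNames(GenomeInfoDb::seqlengths(genome),
                  GenomeInfoDb::seqnames(genome))
}

.check_within_genome <- function(gr, genome, what = "range") {
  sl <- .seqlen(genome)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  bad <- which(!(chrom %in% names(sl)))
  if (length(bad))
    stop(sprintf("%s %d lies on unknown chromosome '%s'",
                 what, bad[1], chrom[bad[1]]))
  bad <- which(BiocGenerics::start(gr) < 1 |
                 BiocGenerics::end(gr) > sl[chrom])
  if (length(bad))
    stop(sprintf("%s %d (%s:%d-%d) lies outside the genome", what, bad[1],
                 chrom[bad[1]], BiocGenerics::start(gr)[bad[1]],
                 BiocGenerics::end(gr)[bad[1]]))
  invisible(TRUE)
}

#' Simulate a non-overlapping gene annotation with class labels
#'
#' Places non-overlapping genes on a toy genome and assigns each a gene
#' class (snRNA, snoRNA, scaRNA, histone, coding, other) drawn from a
#' user-supplied mixture, plus a reference-condition expression level.
#' Genes are laid on a jittered grid so that placement is uniform-ish and
#' overlap-free by construction.
#'
#' Expression is log-normal on the log2 scale (location/scale per class via
#' `expr_log2_mean`/`expr_log2_sd`), emulating the very wide dynamic range of
#' small-RNA expression; snRNA/snoRNA/scaRNA/histone classes default to a
#' higher location than coding/other.
#'
#' @param genome A `Seqinfo` from [toy_genome()].
#' @param n_genes Total number of genes to place.
#' @param class_mix Named numeric vector of class proportions summing to 1.
#' @param gene_length Gene length in bp (single value or range to sample
#'   uniformly).
#' @param min_gap Minimum gap between adjacent genes in bp.
#' @param expr_log2_mean,expr_log2_sd Named vectors (by class, with a
#'   `.default` entry) giving the log2-FPKM location and scale.
#' @param seed Integer seed; identical seeds give identical annotations.
#' @return A [GenomicRanges::GRanges] with metadata columns `gene_id`,
#'   `gene_class` and `expression` (FPKM).
#' @export
simulate_gene_annotation <- function(genome, n_genes,
                                     class_mix = c(snRNA = 0.05, snoRNA = 0.1,
                                                   scaRNA = 0.05,
                                                   histone = 0.05,
                                                   coding = 0.65,
                                                   other = 0.1),
                                     gene_length = c(2000, 10000),
                                     min_gap = 1000,
                                     expr_log2_mean = c(snRNA = 8, snoRNA = 6,
                                                        scaRNA = 6,
                                                        histone = 7,
                                                        .default = 3),
                                     expr_log2_sd = c(.default = 3),
                                     seed = 1L) {
  stopifnot(n_genes >= 1)
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix proportions must be non-negative and sum to 1")
  if (is.null(names(class_mix))) stop("class_mix must be named")
  withr::local_seed(seed)

  sl <- .seqlen(genome)
  max_len <- max(gene_length)
  pitch <- max_len + min_gap
  # candidate slots per chromosome, proportional to length
  slots <- lapply(names(sl), function(ch) {
    n_slot <- floor(sl[[ch]] / pitch)
    if (n_slot < 1) return(NULL)
    data.frame(chrom = ch, slot = seq_len(n_slot) - 1L)
  })
  slots <- do.call(rbind, slots)
  if (is.null(slots) || nrow(slots) < n_genes)
    stop("genome too small to host ", n_genes, " non-overlapping genes")
  pick <- slots[sample.int(nrow(slots), n_genes), , drop = FALSE]

  len <- if (length(gene_length) == 1) rep(gene_length, n_genes) else
    round(stats::runif(n_genes, gene_length[1], gene_length[2]))
  jitter_max <- pmax(pitch - len - min_gap, 0)
  start <- pick$slot * pitch + 1L + floor(stats::runif(n_genes) * (jitter_max + 1))
  cls <- sample(names(class_mix), n_genes, replace = TRUE, prob = class_mix)

  lookup <- function(tbl, cls) {
    out <- unname(tbl[cls])
    out[is.na(out)] <- unname(tbl[".default"])
    if (anyNA(out)) stop("expression parameter table needs a '.default' entry")
    out
  }
  expr <- 2^stats::rnorm(n_genes, lookup(expr_log2_mean, cls),
                         lookup(expr_log2_sd, cls))

  gr <- GenomicRanges::GRanges(pick$chrom,
                               IRanges::IRanges(start, width = len),
                               strand = sample(c("+", "-"), n_genes, TRUE),
                               gene_class = cls,
                               expression = expr,
                               seqinfo = genome)
  gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  S4Vectors::mcols(gr)$gene_id <- sprintf("G%04d", seq_len(n_genes))
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, c("gene_id", "gene_class",
                                                   "expression")]
  gr
}
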