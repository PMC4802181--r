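.junction_key <- function(df)
  paste(df$chrom, df$donor, df$acceptor, df$strand, sep = ":")

.check_junctions <- function(df) {
  need <- c("chrom", "donor", "acceptor", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("junction table is missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!(df$donor < df$acceptor))
  if (length(bad))
    stop("malformed junction at record ", bad[1],
         ": donor must be < acceptor")
  if ("count" %in% names(df) && any(df$count < 0))
    stop("junction counts must be >= 0")
  invisible(TRUE)
}

#' Flag junctions as annotated or unannotated
#'
#' Annotation status is an exact match on the full
#' (chrom, donor, acceptor, strand) key: a junction whose donor is off by
#' a single base is unannotated.
#'
#' @param junctions data.frame with columns chrom, donor, acceptor,
#'   strand (and typically count, sample, gene_id).
#' @param annotation data.frame of annotated junctions keyed by the same
#'   four columns.
#' @return `junctions` with a logical `annotated` column added.
#' @export
classify_annotated <- function(junctions, annotation) {
  .check_junctions(junctions)
  .check_junctions(annotation)
  junctions$annotated <- .junction_key(junctions) %in%
    .junction_key(annotation)
  junctions
}

#' Junctions detected uniquely in one condition group
#'
#' A junction is "detected" in a sample iff its count is at least
#' `min_count`; it is detected in a group if any member sample detects it
#' (or, with `require_all = TRUE`, every member). A junction is unique to
#' a group when it is detected there and in no other group. Uniqueness
#' sets of different groups are disjoint by construction.
#'
#' @param junctions data.frame with columns sample, condition, chrom,
#'   donor, acceptor, strand, count.
#' @param groups Named list mapping group name to the condition labels it
#'   contains; default: one group per distinct condition.
#' @param min_count Detection threshold (default 1).
#' @param require_all Require detection in every member sample of the
#'   group (default FALSE: any member).
#' @return Named list (one element per group) of data.frames of the
#'   junction keys unique to that group (chrom, donor, acceptor, strand).
#' @export
unique_to_condition <- function(junctions, groups = NULL, min_count = 1,
                                require_all = FALSE) {
  .check_junctions(junctions)
  if (is.null(groups)) {
    conds <- unique(junctions$condition)
    groups <- stats::setNames(as.list(conds), conds)
  }
  if (length(groups) < 2) stop("need at least two condition groups")
  key <- .junction_key(junctions)
  det <- junctions$count >= min_count
  detected_in <- lapply(groups, function(conds) {
    sub <- junctions$condition %in% conds
    if (require_all) {
      samp <- unique(junctions$sample[sub])
      per_sample <- lapply(samp, function(s)
        unique(key[sub & junctions$sample == s & det]))
      Reduce(intersect, per_sample)
    } else unique(key[sub & det])
  })
  out <- lapply(names(groups), function(g) {
    others <- unlist(detected_in[setdiff(names(groups), g)])
    uk <- setdiff(detected_in[[g]], others)
    idx <- match(uk, key)
    junctions[idx, c("chrom", "donor", "acceptor", "strand"), drop = FALSE]
  })
  stats::setNames(out, names(groups))
}

#' Assign junctions to genes by containment
#'
#' A junction belongs to a gene when both its donor and acceptor fall
#' inside the gene interval; junctions inside no gene go to
#' `"intergenic"`, junctions contained in more than one (overlapping)
#' gene to `"ambiguous"`.
#'
#' @param junctions data.frame with chrom, donor, acceptor, strand.
#' @param genes GRanges with a `gene_id` metadata column.
#' @return `junctions` with a `gene_id` column added/overwritten.
#' @export
assign_junction_genes <- function(junctions, genes) {
  .check_junctions(junctions)
  jr <- GenomicRanges::GRanges(junctions$chrom,
                               IRanges::IRanges(junctions$donor,
                                                junctions$acceptor))
  hits <- GenomicRanges::findOverlaps(jr, genes, type = "within",
                                      ignore.strand = TRUE)
  nhit <- tabulate(S4Vectors::queryHits(hits), nbins = length(jr))
  gene_id <- rep("intergenic", length(jr))
  one <- which(nhit == 1)
  first <- S4Vectors::subjectHits(hits)[match(one, S4Vectors::queryHits(hits))]
  gene_id[one] <- S4Vectors::mcols(genes)$gene_id[first]
  gene_id[nhit > 1] <- "ambiguous"
  junctions$gene_id <- gene_id
  junctions
}

#' Per-gene summary of unannotated junction burden
#'
#' @param junctions data.frame of (typically unannotated) junctions with a
#'   `gene_id` column; duplicated keys within a gene are counted once.
#' @return List: `per_gene` (data.frame gene_id, n_junctions),
#'   `n_genes` (genes with >= 1, excluding intergenic/ambiguous buckets),
#'   `frac_multi` (fraction of those with more than one),
#'   `n_intergenic` (junctions assigned to no gene).
#' @export
per_gene_unannotated_summary <- function(junctions) {
  if (!"gene_id" %in% names(junctions))
    stop("junctions must carry a gene_id column (see assign_junction_genes)")
  if (nrow(junctions) == 0)
    return(list(per_gene = data.frame(gene_id = character(0),
                                      n_junctions = integer(0)),
                n_genes = 0L, frac_multi = NA_real_, n_intergenic = 0L))
  uk <- !duplicated(paste(.junction_key(junctions), junctions$gene_id))
  jj <- junctions[uk, , drop = FALSE]
  real <- !(jj$gene_id %in% c("intergenic", "ambiguous"))
  tab <- table(jj$gene_id[real])
  per_gene <- data.frame(gene_id = names(tab),
                         n_junctions = as.integer(tab))
  per_gene <- per_gene[order(-per_gene$n_junctions, per_gene$gene_id), ]
  rownames(per_gene) <- NULL
  list(per_gene = per_gene,
       n_genes = nrow(per_gene),
       frac_multi = if (nrow(per_gene)) mean(per_gene$n_junctions > 1)
       else NA_real_,
       n_intergenic = sum(jj$gene_id == "intergenic"))
}

#' Depth- and expression-normalized junction coverage metrics
#'
#' The four metrics adjust junction detection for sequencing depth and
#' host-gene transcription: `reads_per_million = coverage / millions of
#' reads` (knockdown), `expected_at_depth = wild-type millions of reads x
#' reads_per_million`, `reads_per_fpkm = coverage / knockdown FPKM`, and
#' `expected_at_fpkm = wild-type FPKM x reads_per_fpkm`. Zero or negative
#' denominators make the affected metrics `NA` with an `undefined` flag --
#' never silent zeros.
#'
#' @param coverage Junction read coverage in the knockdown sample (>= 0).
#' @param mreads_kd,mreads_wt Millions of mapped reads in knockdown /
#'   wild type.
#' @param fpkm_kd,fpkm_wt Host-gene FPKM in knockdown / wild type.
#' @return List: reads_per_million, expected_at_depth, reads_per_fpkm,
#'   expected_at_fpkm, undefined (character vector of undefined metrics).
#' @export
normalization_metrics <- function(coverage, mreads_kd, mreads_wt,
                                  fpkm_kd, fpkm_wt) {
  if (coverage < 0) stop("coverage must be >= 0")
  undefined <- character(0)
  rpm <- if (mreads_kd > 0) coverage / mreads_kd else {
    undefined <- c(undefined, "reads_per_million"); NA_real_
  }
  ead <- if (!is.na(rpm) && mreads_wt > 0) mreads_wt * rpm else {
    undefined <- c(undefined, "expected_at_depth"); NA_real_
  }
  rpf <- if (fpkm_kd > 0) coverage / fpkm_kd else {
    undefined <- c(undefined, "reads_per_fpkm"); NA_real_
  }
  eaf <- if (!is.na(rpf) && fpkm_wt > 0) fpkm_wt * rpf else {
    undefined <- c(undefined, "expected_at_fpkm"); NA_real_
  }
  list(reads_per_million = rpm, expected_at_depth = ead,
       reads_per_fpkm = rpf, expected_at_fpkm = eaf,
       undefined = undefined)
}

#' Proportion spliced in and its between-condition difference
#'
#' `PSI = inclusion / (inclusion + exclusion)`, undefined (NA) when both
#' counts are zero; `delta_psi` propagates NA.
#'
#' @param inclusion,exclusion Non-negative read counts (vectorized).
#' @return Numeric PSI in [0, 1] or NA.
#' @export
psi <- function(inclusion, exclusion) {
  if (any(inclusion < 0) || any(exclusion < 0))
    stop("counts must be >= 0")
  tot <- inclusion + exclusion
  ifelse(tot == 0, NA_real_, inclusion / tot)
}

#' @rdname psi
#' @param psi_a,psi_b PSI in conditions a and b.
#' @return `delta_psi`: `psi_b - psi_a` (NA if either is NA).
#' @export
delta_psi <- function(psi_a, psi_b) psi_b - psi_a

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided P by the probability-mass convention: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' no more probable than the observed one. Undefined (NA) when a margin
#' is all zero.
#'
#' @param m 2x2 matrix of non-negative integer counts.
#' @return Two-sided exact P value, or NA.
#' @export
fisher_2x2 <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2, 2))) stop("m must be 2x2")
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(NA_real_)
  stats::fisher.test(m)$p.value
}
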