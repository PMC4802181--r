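#' Fragments per kilobase per million mapped reads
#'
#' `FPKM = count / ((length / 1e3) * (total / 1e6))`. Scale-invariant in
#' the sense that doubling both the count and the mapped total leaves the
#' value unchanged.
#'
#' @param counts Genes x samples matrix (or vector) of read counts.
#' @param lengths Gene lengths in bp (> 0), recycled over rows.
#' @param totals Per-sample mapped read totals (> 0), recycled over
#'   columns.
#' @return FPKM matrix with the same dimnames as `counts`.
#' @export
compute_fpkm <- function(counts, lengths, totals) {
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  if (any(totals <= 0)) stop("mapped totals must be > 0")
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be >= 0")
  sweep(sweep(counts, 1, lengths / 1e3, "/"), 2, totals / 1e6, "/")
}

#' Per-condition expression as the mean of replicate log2 FPKM values
#'
#' Each condition's expression is `mean(log2(FPKM + pseudocount))` over
#' its replicates. With two replicates x and 4x (pseudocount 0) this is
#' `log2(x) + 1`: the log of the geometric mean.
#'
#' @param fpkm Genes x samples FPKM matrix.
#' @param condition_map Named character vector mapping sample (column)
#'   name to condition.
#' @param pseudocount Added inside the log (default 0.01); recorded in the
#'   result's `pseudocount` attribute.
#' @return Genes x conditions matrix of log2 expression.
#' @export
log2_average_replicates <- function(fpkm, condition_map, pseudocount = 0.01) {
  fpkm <- as.matrix(fpkm)
  miss <- setdiff(colnames(fpkm), names(condition_map))
  if (length(miss))
    stop("samples without a condition: ", paste(miss, collapse = ", "))
  lg <- log2(fpkm + pseudocount)
  conds <- unique(unname(condition_map[colnames(fpkm)]))
  out <- vapply(conds, function(cd) {
    cols <- colnames(fpkm)[condition_map[colnames(fpkm)] == cd]
    rowMeans(lg[, cols, drop = FALSE])
  }, numeric(nrow(fpkm)))
  out <- matrix(out, nrow = nrow(fpkm),
                dimnames = list(rownames(fpkm), conds))
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Two-control concordant differential expression call
#'
#' A gene is called `decreased` iff the knockdown value sits at least
#' `lfc_threshold` log2 units below BOTH controls, `increased`
#' symmetrically, otherwise `unchanged`. The rule is anti-symmetric: a
#' discordant pair of controls can never produce a call.
#'
#' @param log2_expr Genes x conditions matrix from
#'   [log2_average_replicates()].
#' @param kd Knockdown condition (column) name.
#' @param control_1,control_2 Control condition names (defaults
#'   `"control_1"`, `"control_2"`).
#' @param lfc_threshold Log2 fold-change threshold (default 1).
#' @return data.frame: gene_id, lfc_vs_control_1, lfc_vs_control_2,
#'   direction (`increased`/`decreased`/`unchanged`).
#' @export
concordant_differential_call <- function(log2_expr, kd,
                                         control_1 = "control_1",
                                         control_2 = "control_2",
                                         lfc_threshold = 1) {
  need <- c(kd, control_1, control_2)
  miss <- setdiff(need, colnames(log2_expr))
  if (length(miss))
    stop("missing condition columns: ", paste(miss, collapse = ", "))
  k <- log2_expr[, kd]
  c1 <- log2_expr[, control_1]
  c2 <- log2_expr[, control_2]
  dec <- (c1 - k) >= lfc_threshold & (c2 - k) >= lfc_threshold
  inc <- (k - c1) >= lfc_threshold & (k - c2) >= lfc_threshold
  data.frame(gene_id = if (is.null(rownames(log2_expr)))
    as.character(seq_along(k)) else rownames(log2_expr),
    lfc_vs_control_1 = unname(k - c1),
    lfc_vs_control_2 = unname(k - c2),
    direction = ifelse(dec, "decreased",
                       ifelse(inc, "increased", "unchanged")))
}

#' Nearest-rank quartile labels (Q1-Q4)
#'
#' Cutoffs are the nearest-rank 25/50/75% quantiles of the supplied
#' (reference-condition) values; a value equal to a cutoff is assigned to
#' the upper bin, so a constant vector is labelled entirely Q4 (inclusive
#' tie policy).
#'
#' @param values Numeric vector (length >= 4).
#' @return Factor with levels Q1-Q4.
#' @export
quartile_bins <- function(values) {
  if (length(values) < 4) stop("need at least 4 values")
  s <- sort(values)
  n <- length(s)
  cut25 <- s[ceiling(0.25 * n)]
  cut50 <- s[ceiling(0.50 * n)]
  cut75 <- s[ceiling(0.75 * n)]
  lab <- ifelse(values >= cut75, "Q4",
                ifelse(values >= cut50, "Q3",
                       ifelse(values >= cut25, "Q2", "Q1")))
  factor(lab, levels = c("Q1", "Q2", "Q3", "Q4"))
}

#' qPCR relative quantification by the 2^-ddCt method
#'
#' `dCt = Ct_target - Ct_reference` per condition;
#' `ddCt = dCt_treated - dCt_control`; fold change `2^-ddCt`. Swapping the
#' treated and control conditions inverts the fold change.
#'
#' @param ct_target_treated,ct_ref_treated Target and reference-gene Ct in
#'   the treated condition (cycles, finite, > 0).
#' @param ct_target_control,ct_ref_control Same for the control condition.
#' @return Fold change of the target relative to its basal abundance.
#' @export
fold_change_ddct <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control,
           ct_ref_control)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop("Ct values must be finite and > 0")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
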