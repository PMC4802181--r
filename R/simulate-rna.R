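#' Describe a synthetic small-RNA expression experiment
#'
#' Log-normal baseline expression per gene (log2-FPKM location/scale), a
#' planted knockdown effect applied only to genes flagged CB-proximal, and
#' independent replicate noise. The wide `baseline_log2_sd` default emulates
#' the enormous dynamic range of small-RNA expression.
#'
#' @param n_genes Number of genes.
#' @param baseline_log2_mean,baseline_log2_sd Location and scale of the
#'   log2-FPKM baseline.
#' @param kd_effect Planted log2 fold change applied to CB-proximal genes in
#'   knockdown conditions (default -2: a four-fold reduction).
#' @param frac_cb_proximal Fraction of genes flagged CB-proximal.
#' @param replicate_noise Replicate sd on the log2-FPKM scale.
#' @param gene_length Gene length range in bp (uniform).
#' @param mapped_total Mapped reads per sample (for the count table).
#' @return An object of class `expression_model`.
#' @export
expression_model <- function(n_genes = 1000, baseline_log2_mean = 4,
                             baseline_log2_sd = 4, kd_effect = -2,
                             frac_cb_proximal = 0.1, replicate_noise = 0.25,
                             gene_length = c(100, 2000),
                             mapped_total = 1e7) {
  stopifnot(n_genes >= 1, baseline_log2_sd >= 0, replicate_noise >= 0,
            frac_cb_proximal >= 0, frac_cb_proximal <= 1, mapped_total > 0)
  structure(as.list(environment()), class = "expression_model")
}

#' Simulate FPKM and count tables with planted knockdown effects
#'
#' Every condition whose name is not `control_1`/`control_2` is treated as
#' a knockdown and receives `kd_effect` on the CB-proximal genes; replicate
#' values are drawn independently. Counts are derived from FPKM by
#' inverting the FPKM formula at the model's mapped depth.
#'
#' @param model An [expression_model()].
#' @param conditions Character vector of condition names; must contain both
#'   `control_1` and `control_2`.
#' @param n_reps Replicates per condition (default 2).
#' @param seed Integer seed.
#' @return List with `fpkm` and `counts` (genes x samples matrices),
#'   `genes` (data.frame: gene_id, length, cb_proximal),
#'   `samples` (data.frame: sample, condition, replicate, mapped_total).
#' @export
simulate_expression_table <- function(model,
                                      conditions = c("control_1",
                                                     "control_2", "kd"),
                                      n_reps = 2, seed = 1L) {
  stopifnot(inherits(model, "expression_model"))
  if (!all(c("control_1", "control_2") %in% conditions))
    stop("conditions must include both 'control_1' and 'control_2'")
  if (length(conditions) < 2) stop("need at least two conditions")
  withr::local_seed(seed)

  g <- model$n_genes
  len <- round(stats::runif(g, model$gene_length[1], model$gene_length[2]))
  cbp <- stats::runif(g) < model$frac_cb_proximal
  base <- stats::rnorm(g, model$baseline_log2_mean, model$baseline_log2_sd)

  samples <- expand.grid(replicate = seq_len(n_reps),
                         condition = conditions,
                         stringsAsFactors = FALSE)
  samples$sample <- paste0(samples$condition, "_r", samples$replicate)
  samples$mapped_total <- model$mapped_total
  samples <- samples[, c("sample", "condition", "replicate", "mapped_total")]

  fpkm <- sapply(seq_len(nrow(samples)), function(j) {
    mu <- base
    if (!samples$condition[j] %in% c("control_1", "control_2"))
      mu <- mu + ifelse(cbp, model$kd_effect, 0)
    2^(mu + stats::rnorm(g, 0, model$replicate_noise))
  })
  dimnames(fpkm) <- list(sprintf("G%04d", seq_len(g)), samples$sample)
  counts <- round(sweep(fpkm, 1, len / 1e3, "*") * model$mapped_total / 1e6)
  list(fpkm = fpkm, counts = counts,
       genes = data.frame(gene_id = rownames(fpkm), length = len,
                          cb_proximal = cbp),
       samples = samples)
}

#' Describe a synthetic splice-junction experiment
#'
#' A fixed annotated junction set per gene plus Poisson-rate unannotated
#' ("noise") junctions whose per-condition rate can be scaled, emulating
#' elevated splicing noise after nuclear-body disassembly.
#'
#' @param genes GRanges gene annotation (e.g. from
#'   [simulate_gene_annotation()]) with a `gene_id` column.
#' @param annot_per_gene Annotated junctions per gene.
#' @param annot_count_mean Mean read count of a detected annotated junction.
#' @param unannot_rate Expected unannotated junctions per gene per sample.
#' @param rate_multiplier Named numeric vector scaling `unannot_rate` per
#'   condition (default 1 for unnamed conditions).
#' @param unannot_count_mean Mean extra reads above 1 for an unannotated
#'   junction.
#' @return An object of class `junction_model`.
#' @export
junction_model <- function(genes, annot_per_gene = 3, annot_count_mean = 20,
                           unannot_rate = 0.2, rate_multiplier = NULL,
                           unannot_count_mean = 1) {
  stopifnot(methods::is(genes, "GRanges"), length(genes) >= 1,
            annot_per_gene >= 1, unannot_rate >= 0)
  structure(list(genes = genes, annot_per_gene = annot_per_gene,
                 annot_count_mean = annot_count_mean,
                 unannot_rate = unannot_rate,
                 rate_multiplier = rate_multiplier,
                 unannot_count_mean = unannot_count_mean),
            class = "junction_model")
}

# sorted donor < acceptor positions inside a gene
.random_junctions <- function(n, chrom, start, end, strand) {
  pos <- matrix(sample(seq.int(start, end), 2 * n, replace = FALSE), ncol = 2)
  data.frame(chrom = chrom, donor = pmin(pos[, 1], pos[, 2]),
             acceptor = pmax(pos[, 1], pos[, 2]), strand = strand)
}

#' Simulate per-sample junction tables with planted noise junctions
#'
#' The annotated set is drawn once (shared across samples); per sample,
#' each annotated junction receives a Poisson count, and a
#' Poisson(`unannot_rate` x condition multiplier) number of unannotated
#' junctions is drawn at fresh coordinates inside the gene.
#'
#' @param model A [junction_model()].
#' @param conditions Character vector, one condition label per sample
#'   (repeat a label for replicates); at least two distinct groups.
#' @param seed Integer seed.
#' @return List with `junctions` (data.frame: sample, condition, chrom,
#'   donor, acceptor, strand, count, gene_id, truth_annotated) and
#'   `annotation` (data.frame of the annotated set: chrom, donor, acceptor,
#'   strand, gene_id).
#' @export
simulate_junction_table <- function(model,
                                    conditions = c("control", "kd"),
                                    seed = 1L) {
  stopifnot(inherits(model, "junction_model"))
  withr::local_seed(seed)
  genes <- model$genes
  gid <- S4Vectors::mcols(genes)$gene_id
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  gs <- BiocGenerics::start(genes)
  ge <- BiocGenerics::end(genes)
  gstr <- as.character(BiocGenerics::strand(genes))
  gstr[gstr == "*"] <- "+"

  annot <- do.call(rbind, lapply(seq_along(genes), function(i) {
    j <- .random_junctions(model$annot_per_gene, chrom[i], gs[i] + 1,
                           ge[i] - 1, gstr[i])
    j$gene_id <- gid[i]
    j
  }))

  mult <- function(cond) {
    m <- model$rate_multiplier
    if (is.null(m) || is.null(m[cond]) || is.na(m[cond])) 1 else unname(m[cond])
  }
  samples <- make.unique(paste0(conditions, "_s"), sep = "")
  tabs <- lapply(seq_along(conditions), function(s) {
    a <- annot
    a$count <- stats::rpois(nrow(a), model$annot_count_mean)
    a$truth_annotated <- TRUE
    rate <- model$unannot_rate * mult(conditions[s])
    un <- do.call(rbind, lapply(seq_along(genes), function(i) {
      k <- stats::rpois(1, rate)
      if (k == 0) return(NULL)
      j <- .random_junctions(k, chrom[i], gs[i] + 1, ge[i] - 1, gstr[i])
      j$gene_id <- gid[i]
      j$count <- 1 + stats::rpois(k, model$unannot_count_mean)
      j$truth_annotated <- FALSE
      j
    }))
    tab <- rbind(a, un)
    tab$sample <- samples[s]
    tab$condition <- conditions[s]
    tab[, c("sample", "condition", "chrom", "donor", "acceptor", "strand",
            "count", "gene_id", "truth_annotated")]
  })
  list(junctions = do.call(rbind, tabs),
       annotation = annot[, c("chrom", "donor", "acceptor", "strand",
                              "gene_id")])
}

#' Simulate pairwise splicing events with planted inclusion levels
#'
#' Inclusion reads are Binomial(depth, psi) per condition; exclusion reads
#' make up the remainder, so the planted PSI and delta-PSI are recoverable
#' within binomial error.
#'
#' @param n_events Number of events.
#' @param psi_a,psi_b True proportion spliced in per condition.
#' @param depth Total informative reads per event per condition.
#' @param seed Integer seed.
#' @return data.frame: event_id, inc_a, exc_a, inc_b, exc_b.
#' @export
simulate_splicing_events <- function(n_events, psi_a, psi_b, depth = 200,
                                     seed = 1L) {
  stopifnot(n_events >= 1, depth >= 1,
            psi_a >= 0, psi_a <= 1, psi_b >= 0, psi_b <= 1)
  withr::local_seed(seed)
  inc_a <- stats::rbinom(n_events, depth, psi_a)
  inc_b <- stats::rbinom(n_events, depth, psi_b)
  data.frame(event_id = sprintf("E%04d", seq_len(n_events)),
             inc_a = inc_a, exc_a = depth - inc_a,
             inc_b = inc_b, exc_b = depth - inc_b)
}
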