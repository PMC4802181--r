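#' Default configuration for a synthetic end-to-end run
#'
#' Collects every stage parameter and seed in one serializable list. All
#' randomness in [run_pipeline()] derives from `seed` (one sub-seed per
#' stage, so any stage can be replayed in isolation).
#'
#' @param seed Master integer seed.
#' @return A named list (class `run_config`).
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    genome = c(chr1 = 2e6, chr2 = 1e6),
    n_genes = 150,
    bait = c(chrom = "chr1", start = 1e6, end = 1.001e6),
    cis_peaks = list(c(3e5, 3.5e5, 50), c(1.5e6, 1.55e6, 50)),
    trans_peaks = list(c(4e5, 4.5e5, 50)),
    decay_exponent = 1, background_rate = 1, trans_attenuation = 0.01,
    n_reads = 1e5,
    bin_size = 10000, window = 100000, pseudocount = 0.1, threshold = 7,
    extension = 10000, top_fraction = 0.05, neg_distance = 50000,
    n_perm = 100,
    n_cells = 500, p_dep = 0.3, p_indep = 0.1,
    gene_thresh_px = 3, cb_thresh_px = 5, pixel_size_nm = 320,
    n_expr_genes = 500, kd_effect = -2, lfc_threshold = 1,
    expr_pseudocount = 0.01,
    unannot_rate = 0.2, kd_rate_multiplier = 2
  ), class = "run_config")
}

.stage_files <- list(
  simulate = c("genes.bed", "reads_rep1.bed", "reads_rep2.bed",
               "spots.csv", "fpkm.tsv", "expr_genes.tsv",
               "junctions.tsv", "junction_annotation.tsv"),
  fourc = c("profile.bedgraph", "regions.bed"),
  genes = c("positive_genes.tsv", "negative_genes.tsv",
            "enrichment.json"),
  fish = c("fish_frequencies.json"),
  expr = c("expression_calls.tsv"),
  splice = c("splicing_summary.json"))

.need_input <- function(out_dir, file, stage) {
  path <- file.path(out_dir, file)
  if (!file.exists(path))
    stop("stage '", stage, "' is missing its input '", file,
         "'; run the earlier stages first")
  path
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes, in order, the requested stages: `simulate` (all synthetic
#' inputs), `fourc` (bin, pool, smooth, call contact regions), `genes`
#' (4C-positive/negative sets + permutation enrichment), `fish` (spot
#' classification frequencies), `expr` (two-control concordant calls) and
#' `splice` (junction noise summary). Later stages read the files written
#' by earlier ones, so a deleted intermediate produces an explicit
#' missing-input error. Every output file carries the configuration hash;
#' runs with identical configs produce identical artifacts.
#'
#' @param config A [default_run_config()]-style list.
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of stages to run (default: all, in order).
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir,
                         stages = names(.stage_files)) {
  stages <- match.arg(stages, names(.stage_files), several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), config_path, auto_unbox = TRUE,
                       digits = NA)
  hash <- unname(tools::md5sum(config_path))
  tag <- paste0("config=", hash)
  genome <- toy_genome(config$genome)
  log_lines <- c(paste0("# ", tag),
                 paste0("seed=", config$seed))
  written <- list()
  emit <- function(name) file.path(out_dir, name)
  jwrite <- function(x, name) {
    x$config_hash <- hash
    jsonlite::write_json(x, emit(name), auto_unbox = TRUE, digits = NA)
    written[[name]] <<- emit(name)
  }

  run_stage <- function(stage, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_lines <<- c(log_lines, paste0("stage=", stage, " ok"))
    res
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    genes <- simulate_gene_annotation(genome, config$n_genes,
                                      seed = config$seed + 11L)
    write_gene_bed(genes, emit("genes.bed"), comment = tag)
    bait <- GenomicRanges::GRanges(
      config$bait[["chrom"]],
      IRanges::IRanges(as.numeric(config$bait[["start"]]),
                       as.numeric(config$bait[["end"]])))
    mk_peaks <- function(lst, chrom) {
      if (!length(lst)) return(NULL)
      GenomicRanges::GRanges(chrom,
                             IRanges::IRanges(
                               vapply(lst, `[`, 0, 1),
                               vapply(lst, `[`, 0, 2)),
                             factor = vapply(lst, `[`, 0, 3))
    }
    arch <- planted_architecture(
      genome, bait,
      cis_peaks = mk_peaks(config$cis_peaks, config$bait[["chrom"]]),
      trans_peaks = mk_peaks(config$trans_peaks,
                             setdiff(names(config$genome),
                                     config$bait[["chrom"]])[1]),
      decay_exponent = config$decay_exponent,
      background_rate = config$background_rate,
      trans_attenuation = config$trans_attenuation)
    for (rep in 1:2)
      write_bed(simulate_4c_reads(arch, config$n_reads,
                                  seed = config$seed + 20L + rep),
                emit(paste0("reads_rep", rep, ".bed")), comment = tag)
    pop <- cell_population_model(n_cells = config$n_cells,
                                 p_dep = config$p_dep,
                                 p_indep = config$p_indep,
                                 pixel_size = config$pixel_size_nm,
                                 gene_thresh = config$gene_thresh_px,
                                 cb_thresh = config$cb_thresh_px)
    sim <- simulate_cell_spots(pop, seed = config$seed + 31L)
    write_spot_csv(sim$spots, emit("spots.csv"), comment = tag)
    em <- expression_model(n_genes = config$n_expr_genes,
                           kd_effect = config$kd_effect)
    ex <- simulate_expression_table(em, seed = config$seed + 41L)
    write_expression_tsv(ex$fpkm, emit("fpkm.tsv"), comment = tag)
    utils::write.table(ex$genes, emit("expr_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jm <- junction_model(genes,
                         unannot_rate = config$unannot_rate,
                         rate_multiplier = c(
                           kd = config$kd_rate_multiplier))
    js <- simulate_junction_table(jm,
                                  conditions = c("control", "control",
                                                 "kd", "kd"),
                                  seed = config$seed + 51L)
    write_junctions_tsv(js$junctions, emit("junctions.tsv"), comment = tag)
    write_junctions_tsv(js$annotation, emit("junction_annotation.tsv"),
                        comment = tag)
  })

  if ("fourc" %in% stages) run_stage("fourc", function() {
    reads <- lapply(1:2, function(rep)
      read_bed(.need_input(out_dir, paste0("reads_rep", rep, ".bed"),
                           "fourc"), genome))
    tracks <- lapply(reads, bin_reads, genome = genome,
                     bin_size = config$bin_size)
    pooled <- pool_tracks(tracks)
    prof <- smooth_log_profile(pooled, window = config$window,
                               pseudocount = config$pseudocount)
    write_bedgraph(prof, emit("profile.bedgraph"), comment = tag)
    regions <- call_contact_regions(prof, threshold = config$threshold)
    write_bed(regions, emit("regions.bed"), comment = tag)
  })

  if ("genes" %in% stages) run_stage("genes", function() {
    genes <- read_gene_bed(.need_input(out_dir, "genes.bed", "genes"),
                           genome)
    regions <- read_bed(.need_input(out_dir, "regions.bed", "genes"),
                        genome)
    to_df <- function(g) data.frame(
      gene_id = S4Vectors::mcols(g)$gene_id,
      chrom = as.character(GenomeInfoDb::seqnames(g)),
      start = BiocGenerics::start(g), end = BiocGenerics::end(g),
      gene_class = S4Vectors::mcols(g)$gene_class,
      expression = S4Vectors::mcols(g)$expression)
    pos <- define_positive_set(genes, regions, window = config$extension,
                               fraction = config$top_fraction)
    neg <- define_negative_set(genes, regions,
                               distance = config$neg_distance,
                               fraction = config$top_fraction)
    utils::write.table(to_df(pos), emit("positive_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(to_df(neg), emit("negative_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    enr <- permutation_enrichment(regions, genes,
                                  window = config$extension,
                                  n_samples = config$n_perm,
                                  seed = config$seed + 61L)
    jwrite(list(observed = enr$observed,
                null_mean = mean(enr$null_counts),
                null_max = max(enr$null_counts),
                empirical_p = enr$empirical_p,
                n_samples = enr$n_samples, seed = enr$seed),
           "enrichment.json")
  })

  if ("fish" %in% stages) run_stage("fish", function() {
    spots <- read_spot_csv(.need_input(out_dir, "spots.csv", "fish"))
    an <- classify_cells(spots, gene_thresh = config$gene_thresh_px,
                         cb_thresh = config$cb_thresh_px)
    freq <- lapply(c(CB_dependent = "CB_dependent",
                     CB_independent = "CB_independent",
                     any_pair = "any_pair", bridging = "bridging"),
                   function(ev) {
                     f <- interaction_frequency(an, ev)
                     f[c("percent", "se_percent", "n_cells",
                         "n_event_cells")]
                   })
    jwrite(list(frequencies = freq,
                gene_thresh_um = px_to_um(config$gene_thresh_px,
                                          config$pixel_size_nm),
                cb_thresh_um = px_to_um(config$cb_thresh_px,
                                        config$pixel_size_nm)),
           "fish_frequencies.json")
  })

  if ("expr" %in% stages) run_stage("expr", function() {
    fpkm <- read_expression_tsv(.need_input(out_dir, "fpkm.tsv", "expr"))
    cond <- sub("_r[0-9]+$", "", colnames(fpkm))
    lg <- log2_average_replicates(fpkm,
                                  stats::setNames(cond, colnames(fpkm)),
                                  pseudocount = config$expr_pseudocount)
    calls <- concordant_differential_call(lg, kd = "kd",
                                          lfc_threshold =
                                            config$lfc_threshold)
    calls$quartile <- quartile_bins(lg[, "control_1"])
    utils::write.table(calls, emit("expression_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  if ("splice" %in% stages) run_stage("splice", function() {
    jx <- read_junctions_tsv(.need_input(out_dir, "junctions.tsv",
                                         "splice"))
    annot <- read_junctions_tsv(.need_input(out_dir,
                                            "junction_annotation.tsv",
                                            "splice"))
    jx <- classify_annotated(jx, annot)
    un <- jx[!jx$annotated, , drop = FALSE]
    uniq <- unique_to_condition(un)
    summ <- per_gene_unannotated_summary(un)
    jwrite(list(n_junctions = nrow(jx),
                n_unannotated = nrow(un),
                unique_unannotated = lapply(uniq, nrow),
                genes_with_unannotated = summ$n_genes,
                frac_genes_multi = summ$frac_multi),
           "splicing_summary.json")
  })

  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(written)
}
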