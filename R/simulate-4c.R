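#' Describe a planted 4C contact architecture
#'
#' Bundles the bait viewpoint, planted cis/trans contact peaks with their
#' enrichment factors, the distance-decay exponent and the background read
#' density into one object consumed by [simulate_4c_reads()].
#'
#' The generative model is deliberately simple (the field's 4C profiles
#' exhibit distance decay but no canonical parametric form): cis read
#' density is `background_rate * d^(-decay_exponent)` with the bait distance
#' `d` floored at 1 kb to avoid the singularity at the viewpoint, multiplied
#' by the enrichment factor inside planted peaks; trans chromosomes carry a
#' uniform attenuated background, multiplied by the factor inside planted
#' trans peaks.
#'
#' @param genome A `Seqinfo` from [toy_genome()].
#' @param bait GRanges of length 1: the viewpoint.
#' @param cis_peaks,trans_peaks GRanges with a numeric metadata column
#'   `factor` (enrichment >= 1); may be empty.
#' @param decay_exponent Dimensionless decay exponent (>= 0).
#' @param background_rate Relative background density (reads per bp, up to
#'   the overall normalization implied by `n_reads`).
#' @param trans_attenuation Trans background as a fraction of the cis
#'   background (default 0.001, so the bulk of the signal is
#'   intra-chromosomal).
#' @return An object of class `planted_architecture`.
#' @export
planted_architecture <- function(genome, bait, cis_peaks = NULL,
                                 trans_peaks = NULL, decay_exponent = 1,
                                 background_rate = 1,
                                 trans_attenuation = 0.001) {
  stopifnot(methods::is(bait, "GRanges"), length(bait) == 1)
  empty <- GenomicRanges::GRanges(factor = numeric(0))
  if (is.null(cis_peaks)) cis_peaks <- empty
  if (is.null(trans_peaks)) trans_peaks <- empty
  for (p in list(bait, cis_peaks, trans_peaks))
    if (length(p)) .check_within_genome(p, genome, "peak/bait")
  fac <- c(S4Vectors::mcols(cis_peaks)$factor,
           S4Vectors::mcols(trans_peaks)$factor)
  if (length(cis_peaks) + length(trans_peaks) > 0 &&
      (is.null(fac) || length(fac) < length(cis_peaks) + length(trans_peaks)))
    stop("peaks need a numeric 'factor' metadata column")
  if (length(fac) && (any(!is.finite(fac)) || any(fac < 1)))
    stop("enrichment factors must be finite and >= 1")
  bait_chrom <- as.character(GenomeInfoDb::seqnames(bait))
  cis_chrom <- as.character(GenomeInfoDb::seqnames(cis_peaks))
  if (length(cis_peaks) && any(cis_chrom != bait_chrom))
    stop("cis peaks must lie on the bait chromosome")
  if (decay_exponent < 0) stop("decay_exponent must be >= 0")
  if (background_rate <= 0) stop("background_rate must be > 0")
  structure(list(genome = genome, bait = bait, cis_peaks = cis_peaks,
                 trans_peaks = trans_peaks, decay_exponent = decay_exponent,
                 background_rate = background_rate,
                 trans_attenuation = trans_attenuation),
            class = "planted_architecture")
}

#' Simulate mapped 4C reads from a planted architecture
#'
#' Emits exactly `n_reads` mapped read positions by sampling 1 kb genome
#' cells with probability proportional to the architecture's density model,
#' then placing each read uniformly within its cell. Reads are clipped to
#' the chromosome so every record lies within the genome.
#'
#' @param arch A [planted_architecture()].
#' @param n_reads Number of reads to emit (> 0).
#' @param read_length Read length in bp (default 50, the mapped trimmed
#'   length).
#' @param cell_size Internal sampling resolution in bp (default 1000).
#' @param seed Integer seed.
#' @return GRanges of `n_reads` reads (strand sampled uniformly).
#' @export
simulate_4c_reads <- function(arch, n_reads, read_length = 50,
                              cell_size = 1000, seed = 1L) {
  stopifnot(inherits(arch, "planted_architecture"))
  if (length(n_reads) != 1 || is.na(n_reads) || n_reads < 1)
    stop("n_reads must be a positive count")
  sl <- .seqlen(arch$genome)
  if (length(sl) == 0) stop("empty genome")
  withr::local_seed(seed)

  bait_chrom <- as.character(GenomeInfoDb::seqnames(arch$bait))
  bait_mid <- (BiocGenerics::start(arch$bait) +
                 BiocGenerics::end(arch$bait)) / 2

  cells <- lapply(names(sl), function(ch) {
    n_cell <- ceiling(sl[[ch]] / cell_size)
    start <- (seq_len(n_cell) - 1L) * cell_size + 1
    end <- pmin(start + cell_size - 1, sl[[ch]])
    mid <- (start + end) / 2
    w <- rep(arch$background_rate, n_cell)
    if (ch == bait_chrom) {
      d_kb <- pmax(abs(mid - bait_mid) / 1000, 1)  # floored at 1 kb
      w <- w * d_kb^(-arch$decay_exponent)
      pk <- arch$cis_peaks
    } else {
      w <- w * arch$trans_attenuation
      pk <- arch$trans_peaks[
        as.character(GenomeInfoDb::seqnames(arch$trans_peaks)) == ch]
    }
    if (length(pk)) {
      for (i in seq_along(pk)) {
        hit <- mid >= BiocGenerics::start(pk)[i] &
          mid <= BiocGenerics::end(pk)[i]
        w[hit] <- w[hit] * S4Vectors::mcols(pk)$factor[i]
      }
    }
    data.frame(chrom = ch, start = start, end = end,
               w = w * (end - start + 1))
  })
  cells <- do.call(rbind, cells)

  idx <- sample.int(nrow(cells), n_reads, replace = TRUE,
                    prob = cells$w)
  pos <- cells$start[idx] +
    floor(stats::runif(n_reads) * (cells$end[idx] - cells$start[idx] + 1))
  chrom <- cells$chrom[idx]
  start <- pmin(pos, pmax(sl[chrom] - read_length + 1, 1))
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start, width = read_length),
                         strand = sample(c("+", "-"), n_reads, TRUE),
                         seqinfo = arch$genome)
}

#' Simulate barcoded 4C FASTQ reads with known sample assignment
#'
#' Generates raw sequencing reads of the form
#' `barcode + bait primer + random payload`, with constant high base
#' qualities except for an optional planted fraction of low-quality reads,
#' plus the ground-truth per-read sample assignment. Used to exercise
#' [preprocess_reads()].
#'
#' @param n_reads Number of reads.
#' @param barcodes Named character vector, sample name -> barcode sequence.
#' @param bait_primer Bait primer sequence following the barcode.
#' @param read_length Total raw read length (default 101 nt).
#' @param frac_low_quality Fraction of reads given Phred 5 qualities.
#' @param frac_no_barcode Fraction of reads given a junk prefix instead of a
#'   valid barcode.
#' @param seed Integer seed.
#' @return List with `reads` (a [Biostrings::QualityScaledDNAStringSet])
#'   and `assignment` (character vector: sample name or NA for junk reads).
#' @export
simulate_4c_fastq <- function(n_reads, barcodes, bait_primer,
                              read_length = 101, frac_low_quality = 0,
                              frac_no_barcode = 0, seed = 1L) {
  stopifnot(n_reads >= 1, length(barcodes) >= 1, nzchar(bait_primer))
  withr::local_seed(seed)
  samp <- sample(names(barcodes), n_reads, replace = TRUE)
  junk <- stats::runif(n_reads) < frac_no_barcode
  prefix <- ifelse(junk,
                   vapply(nchar(barcodes[samp]), function(k)
                     paste(sample(c("A", "C", "G", "T"), k, TRUE),
                           collapse = ""), ""),
                   unname(barcodes[samp]))
  assignment <- ifelse(junk, NA_character_, samp)
  payload_len <- read_length - nchar(prefix) - nchar(bait_primer)
  if (any(payload_len < 1)) stop("read_length too short for barcode+primer")
  payload <- vapply(payload_len, function(k)
    paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = ""), "")
  seqs <- Biostrings::DNAStringSet(paste0(prefix, bait_primer, payload))
  names(seqs) <- sprintf("read%06d", seq_len(n_reads))
  lowq <- stats::runif(n_reads) < frac_low_quality
  qchar <- ifelse(lowq, "&", "I")  # Phred 5 vs Phred 40
  quals <- Biostrings::PhredQuality(
    vapply(seq_len(n_reads), function(i)
      strrep(qchar[i], read_length), ""))
  reads <- Biostrings::QualityScaledDNAStringSet(seqs, quals)
  list(reads = reads, assignment = assignment, low_quality = lowq)
}
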