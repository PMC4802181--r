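#' Demultiplex, bait-trim and quality-filter raw 4C reads
#'
#' Each read must start with one of the sample barcodes immediately
#' followed by the bait primer; barcode and primer are stripped, the
#' remainder is truncated to `trim_len` nucleotides (default 50, the
#' mapped length), and reads whose mean base quality over the retained
#' bases falls below `min_quality` are rejected. Every rejected read is
#' logged with a reason (`too_short`, `no_barcode`, `no_bait_match`,
#' `low_quality`).
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet] (e.g. from
#'   [read_fastq()] or [simulate_4c_fastq()]).
#' @param barcodes Named character vector, sample name -> barcode. The set
#'   must be prefix-free (no barcode a prefix of another); ambiguous sets
#'   are rejected at configuration time.
#' @param bait_primer Bait primer sequence (non-empty).
#' @param trim_len Retained read length in nt (default 50).
#' @param min_quality Minimum mean Phred quality of the retained bases
#'   (default 20).
#' @return List with `samples` (named list of
#'   `QualityScaledDNAStringSet`, one per sample) and `rejects`
#'   (data.frame: read, reason).
#' @export
preprocess_reads <- function(reads, barcodes, bait_primer, trim_len = 50,
                             min_quality = 20) {
  stopifnot(length(barcodes) >= 1, !is.null(names(barcodes)))
  if (!nzchar(bait_primer)) stop("bait primer must be non-empty")
  bc <- toupper(barcodes)
  for (i in seq_along(bc)) for (j in seq_along(bc))
    if (i != j && startsWith(bc[j], bc[i]))
      stop("ambiguous barcode set: '", bc[i], "' is a prefix of '",
           bc[j], "'")
  primer <- toupper(bait_primer)

  seqs <- as.character(reads)
  quals <- as(Biostrings::quality(reads), "IntegerList")
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))

  out <- lapply(names(bc), function(s) integer(0))
  names(out) <- names(bc)
  keep_start <- integer(length(reads))
  rej <- character(length(reads))

  bclen <- nchar(bc)
  for (i in seq_along(seqs)) {
    hit <- which(vapply(seq_along(bc), function(k)
      startsWith(seqs[i], bc[k]), logical(1)))
    min_len <- (if (length(hit)) bclen[hit[1]] else min(bclen)) +
      nchar(primer)
    if (nchar(seqs[i]) <= min_len) { rej[i] <- "too_short"; next }
    if (!length(hit)) { rej[i] <- "no_barcode"; next }
    offset <- bclen[hit[1]]
    if (substr(seqs[i], offset + 1, offset + nchar(primer)) != primer) {
      rej[i] <- "no_bait_match"; next
    }
    from <- offset + nchar(primer) + 1
    to <- min(from + trim_len - 1, nchar(seqs[i]))
    q <- quals[[i]][from:to]
    if (mean(q) < min_quality) { rej[i] <- "low_quality"; next }
    keep_start[i] <- from
    out[[names(bc)[hit[1]]]] <- c(out[[names(bc)[hit[1]]]], i)
  }

  samples <- lapply(out, function(idx) {
    if (!length(idx))
      return(Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(), Biostrings::PhredQuality(character(0))))
    sub <- Biostrings::subseq(reads[idx], start = keep_start[idx],
                              width = pmin(trim_len,
                                           nchar(seqs[idx]) -
                                             keep_start[idx] + 1))
    sub
  })
  rejected <- which(rej != "")
  list(samples = samples,
       rejects = data.frame(read = ids[rejected], reason = rej[rejected]))
}

#' Bin mapped reads into a fixed-width genomic track
#'
#' Counts, for each non-overlapping bin of `bin_size` bp, the number of
#' reads overlapping the bin. A read spanning a bin boundary increments
#' both bins (overlap counting, not 5'-position counting).
#'
#' @param reads GRanges of mapped reads.
#' @param genome A `Seqinfo` from [toy_genome()].
#' @param bin_size Bin width in bp (default 10000).
#' @return GRanges tiling of the genome with metadata column `count`;
#'   `bin_size` is recorded in `metadata()`.
#' @export
bin_reads <- function(reads, genome, bin_size = 10000) {
  stopifnot(methods::is(reads, "GRanges"), bin_size >= 1)
  .check_within_genome(reads, genome, "read")
  bins <- GenomicRanges::tileGenome(.seqlen(genome), tilewidth = bin_size,
                                    cut.last.tile.in.chrom = TRUE)
  GenomeInfoDb::seqinfo(bins) <- genome
  S4Vectors::mcols(bins)$count <-
    GenomicRanges::countOverlaps(bins, reads, ignore.strand = TRUE)
  S4Vectors::metadata(bins)$bin_size <- bin_size
  bins
}

#' Pool replicate binned tracks by element-wise summation
#'
#' @param ... Two or more binned tracks from [bin_reads()] over the same
#'   genome and bin size (or a single list of them).
#' @return A binned track whose counts are the element-wise sum.
#' @export
pool_tracks <- function(...) {
  tracks <- list(...)
  if (length(tracks) == 1 && is.list(tracks[[1]]) &&
      !methods::is(tracks[[1]], "GRanges"))
    tracks <- tracks[[1]]
  stopifnot(length(tracks) >= 1)
  ref <- tracks[[1]]
  for (t in tracks[-1]) {
    if (length(t) != length(ref) ||
        !identical(S4Vectors::metadata(t)$bin_size,
                   S4Vectors::metadata(ref)$bin_size) ||
        !all(as.character(GenomeInfoDb::seqnames(t)) ==
               as.character(GenomeInfoDb::seqnames(ref))) ||
        !all(BiocGenerics::start(t) == BiocGenerics::start(ref)))
      stop("tracks must share genome and bin size")
    S4Vectors::mcols(ref)$count <- S4Vectors::mcols(ref)$count +
      S4Vectors::mcols(t)$count
  }
  ref
}

#' Running-window smoothing and log2 transform of a binned 4C track
#'
#' Each bin receives the running mean of the counts over all bins whose
#' centres lie within `window / 2` of its own centre (with a 10 kb bin and
#' the default 100 kb window: 11 bins in the chromosome interior), then
#' `pseudocount` is added before converting to the log2 scale. Chromosome
#' ends use the truncated window (the mean over the bins actually
#' available) rather than padding.
#'
#' @param track Binned track from [bin_reads()] (or [pool_tracks()]).
#' @param window Smoothing window in bp (default 100000); must be at least
#'   the bin size.
#' @param pseudocount Added before log2 (default 0.1), so an all-zero
#'   neighbourhood maps to `log2(pseudocount)`.
#' @return GRanges tiling with metadata column `value` (log2 scale);
#'   `bin_size`, `window`, `pseudocount` recorded in `metadata()`.
#' @export
smooth_log_profile <- function(track, window = 100000, pseudocount = 0.1) {
  bin_size <- S4Vectors::metadata(track)$bin_size
  if (is.null(bin_size)) stop("track is missing bin_size metadata")
  if (window < bin_size) stop("window must be >= bin_size")
  h <- floor((window / 2) / bin_size)
  chrom <- as.character(GenomeInfoDb::seqnames(track))
  value <- numeric(length(track))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    x <- S4Vectors::mcols(track)$count[idx]
    n <- length(x)
    cs <- cumsum(c(0, x))
    i <- seq_len(n)
    lo <- pmax(1L, i - h)
    hi <- pmin(n, i + h)
    value[idx] <- log2(pseudocount + (cs[hi + 1] - cs[lo]) / (hi - lo + 1))
  }
  out <- track
  S4Vectors::mcols(out) <- NULL
  S4Vectors::mcols(out)$value <- value
  S4Vectors::metadata(out) <- list(bin_size = bin_size, window = window,
                                   pseudocount = pseudocount)
  out
}

#' Pearson correlation between two smoothed profiles
#'
#' Reported per chromosome and genome-wide. A profile with zero variance
#' on a chromosome yields `NA` for that chromosome (undefined, reported as
#' such rather than silently dropped).
#'
#' @param a,b Smoothed profiles from [smooth_log_profile()] with matching
#'   shape.
#' @return List with `per_chrom` (named numeric) and `overall` (numeric).
#' @export
replicate_correlation <- function(a, b) {
  if (length(a) != length(b) ||
      !all(as.character(GenomeInfoDb::seqnames(a)) ==
             as.character(GenomeInfoDb::seqnames(b))))
    stop("profiles must have matching shape")
  va <- S4Vectors::mcols(a)$value
  vb <- S4Vectors::mcols(b)$value
  chrom <- as.character(GenomeInfoDb::seqnames(a))
  safe_cor <- function(x, y)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
      stats::cor(x, y)
  per <- vapply(unique(chrom), function(ch) {
    i <- chrom == ch
    safe_cor(va[i], vb[i])
  }, numeric(1))
  list(per_chrom = per, overall = safe_cor(va, vb))
}

#' Call contact regions from a smoothed 4C profile
#'
#' Maximal runs of consecutive bins whose smoothed log2 value is strictly
#' greater than `threshold` are emitted as contact regions, each carrying
#' the run's peak value. Adjacent above-threshold bins are merged; the
#' output is disjoint, sorted, and idempotent under re-calling.
#'
#' @param profile Smoothed profile from [smooth_log_profile()].
#' @param threshold Log2 signal threshold (default 7; comparison is
#'   strict `>`).
#' @return GRanges of contact regions with metadata columns `peak_value`
#'   and `threshold`.
#' @export
call_contact_regions <- function(profile, threshold = 7) {
  v <- S4Vectors::mcols(profile)$value
  if (any(!is.finite(v))) stop("profile values must be finite")
  chrom <- as.character(GenomeInfoDb::seqnames(profile))
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    above <- v[idx] > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      bins <- idx[starts[k]:ends[k]]
      out[[length(out) + 1]] <- GenomicRanges::GRanges(
        ch,
        IRanges::IRanges(min(BiocGenerics::start(profile)[bins]),
                         max(BiocGenerics::end(profile)[bins])),
        peak_value = max(v[bins]), threshold = threshold,
        seqinfo = GenomeInfoDb::seqinfo(profile))
    }
  }
  if (!length(out))
    return(GenomicRanges::GRanges(
      peak_value = numeric(0), threshold = numeric(0),
      seqinfo = GenomeInfoDb::seqinfo(profile)))
  BiocGenerics::sort(do.call(c, out), ignore.strand = TRUE)
}
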