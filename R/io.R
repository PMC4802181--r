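## Format readers/writers. Genomic intervals live as GRanges (1-based
## closed) in memory; BED/bedGraph conversion to 0-based half-open happens
## inside rtracklayer at the file boundary. Files written by the pipeline
## may carry leading "# key=value" comment lines (e.g. the config hash);
## all readers skip them.

.strip_comments <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#")
  if (all(keep)) return(path)
  tmp <- tempfile(fileext = paste0(".", tools::file_ext(path)))
  writeLines(lines[keep], tmp)
  tmp
}

.prepend_comment <- function(path, comment) {
  if (is.null(comment)) return(invisible(path))
  lines <- readLines(path)
  writeLines(c(paste0("# ", comment), lines), path)
  invisible(path)
}

#' Read/write mapped reads or regions as BED
#'
#' Thin wrappers around [rtracklayer::import()]/[rtracklayer::export()]
#' (BED is 0-based half-open on disk, 1-based closed in memory). Leading
#' `#` comment lines are skipped on read.
#'
#' @param path File path.
#' @param genome Optional `Seqinfo` to attach (records outside it raise an
#'   error naming the offender).
#' @return GRanges.
#' @export
read_bed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(.strip_comments(path), format = "BED")
  if (!is.null(genome)) {
    .check_within_genome(gr, genome, "BED record")
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  gr
}

#' @rdname read_bed
#' @param gr GRanges to write.
#' @param comment Optional comment (written as a leading `# ` line).
#' @export
write_bed <- function(gr, path, comment = NULL) {
  rtracklayer::export(gr, path, format = "BED")
  .prepend_comment(path, comment)
}

#' Read/write a smoothed or binned track as bedGraph
#'
#' The track's `count`/`value` column is stored in the bedGraph score
#' field.
#'
#' @param track GRanges track from [bin_reads()] or
#'   [smooth_log_profile()].
#' @param path File path.
#' @param comment Optional leading comment line.
#' @export
write_bedgraph <- function(track, path, comment = NULL) {
  gr <- track
  cols <- S4Vectors::mcols(gr)
  score_col <- intersect(c("value", "count", "score"), colnames(cols))[1]
  if (is.na(score_col)) stop("track has no value/count column")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    score = as.numeric(cols[[score_col]]))
  rtracklayer::export(gr, path, format = "bedGraph")
  .prepend_comment(path, comment)
}

#' @rdname write_bedgraph
#' @return `read_bedgraph`: GRanges with a `score` column.
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import(.strip_comments(path), format = "bedGraph")
}

#' Read/write a gene annotation as BED with a gene-class column
#'
#' BED6 (name = gene_id, score = 0) plus a 7th `gene_class` and an 8th
#' `expression` column; coordinates 0-based half-open on disk.
#'
#' @param genes GRanges with gene_id, gene_class, expression.
#' @param path File path.
#' @param comment Optional leading comment line.
#' @export
write_gene_bed <- function(genes, path, comment = NULL) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(genes)),
                   start = BiocGenerics::start(genes) - 1L,
                   end = BiocGenerics::end(genes),
                   name = S4Vectors::mcols(genes)$gene_id,
                   score = 0L,
                   strand = as.character(BiocGenerics::strand(genes)),
                   gene_class = S4Vectors::mcols(genes)$gene_class,
                   expression = S4Vectors::mcols(genes)$expression)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  .prepend_comment(path, comment)
}

#' @rdname write_gene_bed
#' @param genome Optional `Seqinfo` to attach and validate against.
#' @return `read_gene_bed`: GRanges with gene_id, gene_class, expression.
#' @export
read_gene_bed <- function(path, genome = NULL) {
  df <- tryCatch(
    utils::read.table(.strip_comments(path), sep = "\t",
                      col.names = c("chrom", "start", "end", "name",
                                    "score", "strand", "gene_class",
                                    "expression"),
                      colClasses = c("character", "integer", "integer",
                                     "character", "numeric", "character",
                                     "character", "numeric")),
    error = function(e) stop("malformed gene BED '", path, "': ",
                             conditionMessage(e)))
  bad <- which(df$start < 0 | df$end <= df$start)
  if (length(bad))
    stop("invalid coordinates at line ", bad[1], " of ", path)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = df$strand,
                               gene_id = df$name,
                               gene_class = df$gene_class,
                               expression = df$expression)
  if (!is.null(genome)) {
    .check_within_genome(gr, genome, "gene")
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  gr
}

#' Read/write a gene annotation as GTF-lite
#'
#' Only `gene` feature rows with `gene_id` and `gene_class` (and
#' optionally `expression`) attributes are honoured; full GTF grammar is
#' out of scope. GTF coordinates are 1-based inclusive on disk, so a gene
#' printed as `[1, 100]` reads back as the same 1-based closed GRanges
#' (equivalently 0-based half-open `[0, 100)`).
#'
#' @param genes GRanges with gene_id, gene_class, expression.
#' @param path File path.
#' @param comment Optional leading comment line.
#' @export
write_gtf_lite <- function(genes, path, comment = NULL) {
  attrs <- sprintf('gene_id "%s"; gene_class "%s"; expression "%g";',
                   S4Vectors::mcols(genes)$gene_id,
                   S4Vectors::mcols(genes)$gene_class,
                   S4Vectors::mcols(genes)$expression)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(genes)),
                   source = "nbconform", feature = "gene",
                   start = BiocGenerics::start(genes),
                   end = BiocGenerics::end(genes),
                   score = ".",
                   strand = as.character(BiocGenerics::strand(genes)),
                   frame = ".", attributes = attrs)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  .prepend_comment(path, comment)
}

#' @rdname write_gtf_lite
#' @return `read_gtf_lite`: GRanges with gene_id, gene_class, expression.
#' @export
read_gtf_lite <- function(path) {
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9)
  if (length(bad))
    stop("malformed GTF line ", keep[bad[1]], " in ", path,
         ": expected 9 tab-separated fields")
  get_attr <- function(a, key) {
    m <- regmatches(a, regexpr(paste0(key, ' "([^"]*)"'), a))
    if (!length(m)) NA_character_ else sub(paste0(key, ' "([^"]*)"'),
                                           "\\1", m)
  }
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (f[3] != "gene") return(NULL)
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start < 1 || end < start)
      stop("invalid coordinates at GTF line ", keep[i], " in ", path)
    gid <- get_attr(f[9], "gene_id")
    if (is.na(gid))
      stop("missing gene_id attribute at GTF line ", keep[i], " in ", path)
    expr <- get_attr(f[9], "expression")
    data.frame(chrom = f[1], start = start, end = end, strand = f[7],
               gene_id = gid,
               gene_class = get_attr(f[9], "gene_class"),
               expression = if (is.na(expr)) NA_real_ else as.numeric(expr))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) stop("no gene records in ", path)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         strand = df$strand, gene_id = df$gene_id,
                         gene_class = df$gene_class,
                         expression = df$expression)
}

#' Read/write FASTQ with per-record validation
#'
#' Reading validates the 4-line record structure first (an error names
#' the offending record), then parses sequences and qualities with
#' Biostrings.
#'
#' @param path File path.
#' @return `read_fastq`: a [Biostrings::QualityScaledDNAStringSet].
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ '", path, "': truncated record ",
         length(lines) %/% 4 + 1, " (line count not a multiple of 4)")
  rec_start <- seq(1, length(lines), by = 4)
  bad <- which(!startsWith(lines[rec_start], "@") |
                 !startsWith(lines[rec_start + 2], "+"))
  if (length(bad))
    stop("malformed FASTQ '", path, "' at record ", bad[1],
         " (line ", rec_start[bad[1]], ")")
  # Biostrings warns about dropping its own internal metadata columns here
  suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
}

#' @rdname read_fastq
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
}

#' Read/write per-cell spot tables as CSV
#'
#' Columns: cell_id, channel, x_px, y_px, intensity.
#'
#' @param spots data.frame of spots.
#' @param path File path.
#' @param comment Optional leading comment line.
#' @export
write_spot_csv <- function(spots, path, comment = NULL) {
  utils::write.csv(spots, path, row.names = FALSE, quote = FALSE)
  .prepend_comment(path, comment)
}

#' @rdname write_spot_csv
#' @return `read_spot_csv`: validated data.frame.
#' @export
read_spot_csv <- function(path) {
  df <- utils::read.csv(.strip_comments(path))
  need <- c("cell_id", "channel", "x_px", "y_px", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("spot table '", path, "' is missing columns: ",
         paste(miss, collapse = ", "))
  df
}

#' Read/write junction tables as TSV
#'
#' Columns: chrom, donor, acceptor, strand, count plus any extras
#' (sample, condition, gene_id, ...).
#'
#' @param junctions data.frame of junctions.
#' @param path File path.
#' @param comment Optional leading comment line.
#' @export
write_junctions_tsv <- function(junctions, path, comment = NULL) {
  utils::write.table(junctions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .prepend_comment(path, comment)
}

#' @rdname write_junctions_tsv
#' @return `read_junctions_tsv`: validated data.frame.
#' @export
read_junctions_tsv <- function(path) {
  df <- utils::read.delim(.strip_comments(path))
  .check_junctions(df)
  df
}

#' Read/write an expression matrix as TSV (genes in rows)
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path File path.
#' @param comment Optional leading comment line.
#' @export
write_expression_tsv <- function(mat, path, comment = NULL) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .prepend_comment(path, comment)
}

#' @rdname write_expression_tsv
#' @return `read_expression_tsv`: numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(.strip_comments(path), check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
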