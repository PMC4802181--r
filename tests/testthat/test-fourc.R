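test_that("read preprocessing demultiplexes, trims and filters", {
  bc <- c(s1 = "ACGT", s2 = "TGCA")
  fq <- simulate_4c_fastq(200, bc, bait_primer = "GGATCCTT",
                          read_length = 101, seed = 3)
  out <- preprocess_reads(fq$reads, bc, "GGATCCTT")
  # 101-nt read with valid barcode+primer -> retained length 50
  expect_true(all(unlist(lapply(out$samples, BiocGenerics::width)) == 50))
  # planted per-sample assignment recovered exactly
  expect_equal(vapply(out$samples, length, 0L),
               c(s1 = sum(fq$assignment == "s1"),
                 s2 = sum(fq$assignment == "s2")))
  expect_equal(nrow(out$rejects), 0)

  # prefix-ambiguous barcode sets are a configuration error
  expect_error(preprocess_reads(fq$reads, c(a = "AC", b = "ACGT"), "GG"),
               "ambiguous")

  # reads shorter than barcode+primer are logged as too_short
  short <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(c(r1 = "ACGTGGA")),
    Biostrings::PhredQuality("IIIIIII"))
  o2 <- preprocess_reads(short, bc, "GGATCCTT")
  expect_equal(o2$rejects$reason, "too_short")

  # junk prefixes and low-quality reads are rejected with reasons
  fq2 <- simulate_4c_fastq(300, bc, "GGATCCTT", frac_low_quality = 0.2,
                           frac_no_barcode = 0.2, seed = 8)
  o3 <- preprocess_reads(fq2$reads, bc, "GGATCCTT")
  expect_setequal(unique(o3$rejects$reason), c("no_barcode", "low_quality"))
  kept <- sum(vapply(o3$samples, length, 0L))
  expect_equal(kept + nrow(o3$rejects), 300)
  expect_equal(kept, sum(!is.na(fq2$assignment) & !fq2$low_quality))
})

test_that("binning counts overlaps, including boundary-spanning reads", {
  g <- tg2()
  # no reads -> all-zero track
  t0 <- bin_reads(GenomicRanges::GRanges(seqinfo = g), g)
  expect_true(all(S4Vectors::mcols(t0)$count == 0))
  expect_length(t0, 20 + 10)
  # 50-nt read spanning the first bin boundary increments both bins
  r <- GenomicRanges::GRanges("chrA", IRanges::IRanges(9991, 10040))
  t1 <- bin_reads(r, g)
  expect_equal(S4Vectors::mcols(t1)$count[1:3], c(1, 1, 0))
  # a read outside the genome is an error naming the record
  bad <- GenomicRanges::GRanges("chrA", IRanges::IRanges(199990, 200040))
  expect_error(bin_reads(bad, g), "outside the genome")
  expect_error(bin_reads(GenomicRanges::GRanges(
    "chrZ", IRanges::IRanges(1, 50)), g), "chrZ")
})

test_that("binning matches the brute-force overlap oracle", {
  g <- toy_genome(c(chrA = 1e5))
  withr::with_seed(42, {
    for (rep in 1:5) {
      n <- 2000
      start <- sample.int(1e5 - 60, n, replace = TRUE)
      reads <- GenomicRanges::GRanges("chrA",
                                      IRanges::IRanges(start, width = 50))
      got <- S4Vectors::mcols(bin_reads(reads, g, bin_size = 7000))$count
      expect_equal(got, bf_bin_counts(start, start + 49, 1e5, 7000))
    }
  })
})

test_that("pooling is element-wise summation with shape checks", {
  tr <- make_track(list(chrA = c(1, 2, 3), chrB = c(0, 5)))
  zero <- make_track(list(chrA = c(0, 0, 0), chrB = c(0, 0)))
  expect_equal(S4Vectors::mcols(pool_tracks(tr, zero))$count,
               S4Vectors::mcols(tr)$count)
  expect_equal(S4Vectors::mcols(pool_tracks(tr, tr))$count,
               2 * S4Vectors::mcols(tr)$count)
  expect_equal(sum(S4Vectors::mcols(pool_tracks(list(tr, tr, zero)))$count),
               2 * sum(S4Vectors::mcols(tr)$count))
  short <- make_track(list(chrA = c(1, 2)))
  expect_error(pool_tracks(tr, short), "share")
})

test_that("smoothing implements the centred truncated window mean", {
  # constant counts -> log2(0.1 + c) everywhere
  tr <- make_track(list(chrA = rep(4, 30)))
  sm <- smooth_log_profile(tr)
  expect_equal(S4Vectors::mcols(sm)$value, rep(log2(4.1), 30))
  # all-zero track -> every value satisfies 2^v = 0.1
  z <- smooth_log_profile(make_track(list(chrA = rep(0, 20))))
  expect_equal(2^S4Vectors::mcols(z)$value, rep(0.1, 20))
  expect_error(smooth_log_profile(tr, window = 5000), ">=")
})

test_that("smoothing matches the brute-force sliding-mean oracle", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      x <- stats::rpois(60, 3)
      y <- stats::rpois(25, 10)
      tr <- make_track(list(chrA = x, chrB = y))
      sm <- smooth_log_profile(tr)
      expect_equal(S4Vectors::mcols(sm)$value,
                   c(bf_smooth(x, 5, 0.1), bf_smooth(y, 5, 0.1)))
    }
  })
})

test_that("smoothing is monotone in the counts", {
  withr::with_seed(8, {
    x <- stats::rpois(40, 2)
    base <- S4Vectors::mcols(smooth_log_profile(
      make_track(list(chrA = x))))$value
    x2 <- x
    x2[17] <- x2[17] + 5
    up <- S4Vectors::mcols(smooth_log_profile(
      make_track(list(chrA = x2))))$value
    expect_true(all(up >= base))
  })
})

test_that("replicate correlation handles self, anti and degenerate cases", {
  p <- make_profile(list(chrA = c(1, 3, 2, 5), chrB = c(2, 2, 4)))
  rc <- replicate_correlation(p, p)
  expect_equal(unname(rc$overall), 1)
  anti <- p
  S4Vectors::mcols(anti)$value <- -S4Vectors::mcols(p)$value + 10
  expect_equal(unname(replicate_correlation(p, anti)$overall), -1)
  flat <- p
  S4Vectors::mcols(flat)$value <- rep(1, length(p))
  expect_true(is.na(replicate_correlation(p, flat)$overall))
})

test_that("seeded replicates of one architecture are highly correlated", {
  g <- toy_genome(c(chr1 = 2e6))
  bait <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e6, 1.001e6))
  pk <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(3e5, 1.5e6),
                                                c(3.5e5, 1.55e6)),
                               factor = c(50, 50))
  arch <- planted_architecture(g, bait, cis_peaks = pk)
  prof <- lapply(1:2, function(s)
    smooth_log_profile(bin_reads(simulate_4c_reads(arch, 1e5, seed = s),
                                 g)))
  expect_gt(replicate_correlation(prof[[1]], prof[[2]])$overall, 0.9)
})

test_that("contact-region calling finds maximal strict-threshold runs", {
  p <- make_profile(list(chrA = c(6.9, 7.2, 7.5, 6.0)))
  reg <- call_contact_regions(p, threshold = 7)
  expect_length(reg, 1)
  expect_equal(BiocGenerics::start(reg), 10001)
  expect_equal(BiocGenerics::end(reg), 30000)
  expect_equal(S4Vectors::mcols(reg)$peak_value, 7.5)
  # all sub-threshold (boundary value 7 is NOT above threshold) -> empty
  expect_length(call_contact_regions(
    make_profile(list(chrA = c(7, 7, 6)))), 0)
  # disjoint, sorted, idempotent
  p2 <- make_profile(list(chrA = c(8, 6, 8, 8, 6, 9), chrB = c(9, 6)))
  r2 <- call_contact_regions(p2)
  expect_length(r2, 4)
  expect_true(all(BiocGenerics::width(GenomicRanges::reduce(r2)) ==
                    BiocGenerics::width(r2)))
  again <- call_contact_regions(p2)
  expect_identical(as.data.frame(r2), as.data.frame(again))
})

test_that("binned counts conserve reads up to boundary double-counting", {
  g <- toy_genome(c(chrA = 1e5))
  withr::with_seed(12, {
    start <- sample.int(1e5 - 60, 500, replace = TRUE)
    reads <- GenomicRanges::GRanges("chrA",
                                    IRanges::IRanges(start, width = 50))
    tr <- bin_reads(reads, g)
    expect_gte(sum(S4Vectors::mcols(tr)$count), 500)
    # interior reads only: exact conservation
    inner <- GenomicRanges::GRanges("chrA",
                                    IRanges::IRanges(c(100, 12000),
                                                     width = 50))
    expect_equal(sum(S4Vectors::mcols(bin_reads(inner, g))$count), 2)
  })
})
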