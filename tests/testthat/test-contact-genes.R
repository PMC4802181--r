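test_that("region extension clips, merges and reduces to identity at 0", {
  g <- toy_genome(c(chr1 = 1e6))
  r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100001, 110000),
                              seqinfo = g)
  e0 <- extend_regions(r, 0)
  expect_equal(BiocGenerics::start(e0), 100001)
  expect_equal(BiocGenerics::end(e0), 110000)
  # 0-based [100000,110000) grown by 10 kb -> [90000,120000)
  e <- extend_regions(r, 10000)
  expect_equal(BiocGenerics::start(e) - 1, 90000)
  expect_equal(BiocGenerics::end(e), 120000)
  # two regions 15 kb apart merge under a 10 kb extension
  r2 <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(100001, 125001),
                                                c(110000, 130000)),
                               seqinfo = g)
  expect_length(extend_regions(r2, 10000), 1)
  expect_length(extend_regions(r2, 2000), 2)
})

test_that("extension/merge matches a brute-force oracle on random inputs", {
  g <- toy_genome(c(chr1 = 1e6))
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(2:8, 1)
      s <- sort(sample.int(9e5, n))
      e <- s + sample.int(3e4, n)
      w <- sample(c(0, 5000, 10000, 25000), 1)
      got <- extend_regions(GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(s, e), seqinfo = g), w)
      want <- bf_merge(pmax(s - w, 1), pmin(e + w, 1e6))
      expect_equal(BiocGenerics::start(got), want[, 1])
      expect_equal(BiocGenerics::end(got), want[, 2])
    }
  })
})

test_that("midpoint intersection follows the floor-midpoint rule", {
  mk <- function(s, e) GenomicRanges::GRanges("chr1",
                                              IRanges::IRanges(s, e))
  gene <- mk(1, 10000)  # 0-based [0,10000), midpoint 5000 (0-based)
  expect_length(intersect_genes_midpoint(gene, mk(4001, 6000)), 1)
  expect_length(intersect_genes_midpoint(gene, mk(6001, 8000)), 0)
  # random instances vs point-in-interval oracle
  withr::with_seed(32, {
    for (rep in 1:20) {
      gs <- sample.int(9e5, 30)
      ge <- gs + sample.int(2e4, 30)
      rs <- sort(sample.int(9e5, 5))
      re <- rs + sample.int(5e4, 5)
      genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(gs, ge))
      regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(rs, re))
      got <- length(intersect_genes_midpoint(genes, regions))
      mid1 <- (gs - 1 + ge) %/% 2 + 1
      expect_equal(got, sum(bf_point_in(mid1, rs, re)))
    }
  })
})

test_that("top-fraction expression filter uses nearest rank, keeping ties", {
  g <- toy_genome(c(chr1 = 1e7))
  mk_genes <- function(expr) {
    n <- length(expr)
    GenomicRanges::GRanges("chr1",
                           IRanges::IRanges(seq(1, by = 20000,
                                                length.out = n),
                                            width = 10000),
                           gene_id = as.character(seq_len(n)),
                           gene_class = "coding", expression = expr,
                           seqinfo = g)
  }
  genes <- mk_genes(sample(1:100))
  top <- select_expressed_top_fraction(genes, 0.05)
  expect_length(top, 5)
  expect_setequal(S4Vectors::mcols(top)$expression, 96:100)
  # all equal -> everything passes at the threshold
  expect_length(select_expressed_top_fraction(mk_genes(rep(7, 40))), 40)
  # sort-and-slice oracle on random draws
  withr::with_seed(33, {
    for (rep in 1:10) {
      expr <- stats::rlnorm(60)
      got <- S4Vectors::mcols(
        select_expressed_top_fraction(mk_genes(expr), 0.1))$expression
      expect_setequal(got, sort(expr, decreasing = TRUE)[1:6])
    }
  })
  expect_error(select_expressed_top_fraction(mk_genes(1)[0]), "empty")
})

test_that("negative set keeps only distant top-expressed genes", {
  g <- toy_genome(c(chr1 = 1e6))
  genes <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(100001, 350001, 165001), width = 10000),
    gene_id = c("near", "far", "overlap"), gene_class = "coding",
    expression = c(10, 10, 10), seqinfo = g)
  regions <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(160001, 170000),
                                    seqinfo = g)
  neg <- define_negative_set(genes, regions, distance = 50000,
                             fraction = 1)
  # 60 kb away is eligible, 50 kb exactly is not kept (strict >), overlap
  # is excluded outright
  expect_setequal(S4Vectors::mcols(neg)$gene_id, c("far"))
  pos <- define_positive_set(genes, regions, window = 10000, fraction = 1)
  expect_setequal(S4Vectors::mcols(pos)$gene_id, c("overlap"))
  # positive and negative sets are disjoint by construction
  expect_length(intersect(S4Vectors::mcols(pos)$gene_id,
                          S4Vectors::mcols(neg)$gene_id), 0)
})

test_that("enlarging the window never shrinks the intersected set", {
  g <- toy_genome(c(chr1 = 2e6))
  withr::with_seed(34, {
    genes <- simulate_gene_annotation(g, 100, seed = 5)
    regions <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(c(2e5, 9e5), c(3e5, 1e6)), seqinfo = g)
    sizes <- vapply(c(0, 10000, 25000, 50000), function(w)
      length(intersect_genes_midpoint(genes, extend_regions(regions, w))),
      0L)
    expect_true(all(diff(sizes) >= 0))
  })
})

test_that("permutation enrichment p-values behave at the extremes", {
  g <- toy_genome(c(chr1 = 1e6))
  # no target gene anywhere near: observed 0 <= every null -> p = 1
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(1, 1000),
                                  gene_id = "g", gene_class = "coding",
                                  expression = 1, seqinfo = g)
  regions <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(5e5, 51e4),
                                    seqinfo = g)
  enr <- permutation_enrichment(regions, genes, n_samples = 50, seed = 1)
  expect_equal(enr$empirical_p, 1)
  expect_length(enr$null_counts, 50)
  # minimum attainable p is 1/(n+1), never zero
  clustered <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(500001, 509001, by = 1000), width = 500),
    gene_id = letters[1:10], gene_class = "snRNA",
    expression = 1, seqinfo = g)
  enr2 <- permutation_enrichment(regions, clustered, n_samples = 100,
                                 seed = 2)
  expect_gte(enr2$empirical_p, 1 / 101)
  expect_lte(enr2$empirical_p, 1)
})

test_that("planted small-RNA clustering inside peaks is detected", {
  g <- toy_genome(c(chr1 = 2e6))
  # 12 snRNA genes packed into the two contact regions, background coding
  withr::with_seed(35, {
    sn <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(c(seq(300001, 345001, by = 8000),
                                 seq(1500001, 1545001, by = 8000)),
                               width = 2000),
      gene_id = paste0("sn", 1:12), gene_class = "snRNA", expression = 100)
    bg <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(sample.int(1.9e6, 100), width = 2000),
      gene_id = paste0("c", 1:100), gene_class = "coding", expression = 1)
    genes <- c(sn, bg)
    GenomeInfoDb::seqinfo(genes) <- g
    regions <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(c(300001, 1500001), c(350000, 1550000)),
      seqinfo = g)
    enr <- permutation_enrichment(regions, genes, n_samples = 100,
                                  seed = 3)
    expect_lt(enr$empirical_p, 0.01 + 1e-9)
  })
})
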