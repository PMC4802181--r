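# nbconform

Nuclear body–genome conformation analysis in R.

Cajal bodies (CBs) — coilin-marked nuclear bodies central to
spliceosomal snRNP maturation — sit non-randomly in the nucleus.
`nbconform` implements the quantitative pipeline for asking whether
specific loci (snRNA/snoRNA/scaRNA arrays, histone clusters) are drawn
into CB proximity and what CB loss does to their expression and to
splicing fidelity:

* **4C-seq contact profiling** — demultiplex/trim raw reads, count
  mapped reads into 10 kb bins, smooth with a running 100 kb window
  (`log2(0.1 + mean)`), and call contact regions where the smoothed
  log2 signal exceeds 7.
* **Contact-gene sets and permutation enrichment** — extend regions by
  ±10/25/50 kb, select genes by the midpoint rule and a top-5%
  expression filter, build a distant 4C-negative control set, and test
  class enrichment against 100 random interval samples of matching
  size, with the add-one empirical P value
  `(1 + #{null ≥ obs}) / (1 + n)`.
* **High-content FISH co-localization** — nuclear segmentation, spot
  detection at the brightest pixel, per-RNU1-spot minimum distances,
  and event classification: *CB-dependent* (gene–gene ≤ 3 px ≈ 0.96 µm
  **and** gene–CB ≤ 5 px ≈ 1.6 µm at 320 nm/px), *CB-independent*
  (gene–gene ≤ 3 px, gene–CB > 5 px), plus an orthogonal *bridging*
  flag; frequencies are the percentage of eligible cells with ≥ 1
  event.
* **Geometric association null** — for a body placed uniformly in the
  projected nuclear disc, `P = min(1, (CTrad + Δ)² / NUCrad²)`, with a
  Monte-Carlo placement oracle.
* **Expression and splicing noise** — FPKM, mean-of-log2 replicate
  averaging, a two-control concordant differential call, quartile
  binning, 2^−ΔΔCt fold changes, exact-match junction annotation,
  condition-unique junction sets, per-gene noise summaries,
  depth/FPKM normalization metrics, PSI/ΔPSI, and Fisher's exact test.
* **Synthetic-data generators** — seeded simulators for every input
  (4C reads with distance decay and planted peaks, cell populations
  with planted pairing rates, log-normal expression with planted
  knockdowns, junction tables with planted noise rates), so each stage
  has recoverable ground truth.

## Worked example

Simulate a two-chromosome genome with two factor-50 contact peaks
planted around an *RNU1*-like bait, profile it, and test enrichment of
small-RNA genes near the called regions:

```r
library(nbconform)

genome <- toy_genome(c(chr1 = 2e6, chr2 = 1e6))
genes  <- simulate_gene_annotation(genome, 150, seed = 3)
bait   <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e6, 1.001e6))
peaks  <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(c(3e5, 1.5e6), c(3.5e5, 1.55e6)),
            factor = c(50, 50))
arch   <- planted_architecture(genome, bait, cis_peaks = peaks)

reads   <- simulate_4c_reads(arch, 1e5, seed = 7)
profile <- smooth_log_profile(bin_reads(reads, genome))
regions <- call_contact_regions(profile, threshold = 7)
as.data.frame(regions)
#>   seqnames   start     end  width strand peak_value threshold
#> 1     chr1  250001  400000 150000      *   10.43027         7
#> 2     chr1  700001 1320000 620000      *   11.84285         7
#> 3     chr1 1450001 1600000 150000      *   10.78769         7
```

Both planted peaks are recovered (the middle region is the bait's own
proximity zone, where 4C signal is always high). The FISH track
recovers a planted 30% CB-dependent pairing rate:

```r
pop <- cell_population_model(n_cells = 2000, p_dep = 0.3, p_indep = 0.1)
sim <- simulate_cell_spots(pop, seed = 5)
f   <- interaction_frequency(classify_cells(sim$spots), "CB_dependent")
f$percent
#> [1] 28.9
f$se_percent
#> [1] 1.013605
```

28.9% with a binomial standard error of 1.0 — within sampling error of
the planted 30%. `run_pipeline(default_run_config(seed = 1), "out/")`
wires all stages into one deterministic artifact directory.

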