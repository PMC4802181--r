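---
title: "Methods: models, parameters and design choices in nbconform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in nbconform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbconform)
```

## What this package models

Cajal bodies (CBs) are membrane-less nuclear bodies involved in
spliceosomal snRNP maturation. A recurring question in nuclear
organization is whether such bodies sit at random with respect to the
genome, or whether specific loci — snRNA/snoRNA/scaRNA arrays, histone
gene clusters — are drawn into their proximity, with consequences for
expression and splicing fidelity when the body is disassembled.
`nbconform` implements the quantitative machinery for that question as
five analysis tracks, each of which can be exercised end-to-end on
seeded synthetic data with planted ground truth:

1. **4C-seq contact profiling** — from raw barcoded reads to called
   contact regions of a bait locus (e.g. an *RNU1* snRNA array).
2. **Contact-gene sets and permutation enrichment** — which gene
   classes cluster near the contact regions more than chance allows.
3. **High-content FISH co-localization** — per-cell spot tables,
   minimum pairwise distances, and the CB-dependent / CB-independent /
   bridging classification of gene-pairing events.
4. **A geometric association null** — the probability that a body
   placed at random in the projected nucleus would sit near a
   chromosome territory anyway.
5. **Expression and splicing-noise summaries** — FPKM, a two-control
   concordant differential call, quartile binning, 2^-ddCt fold
   changes, and junction-level splicing-noise metrics.

## The 4C track

Mapped reads are counted into non-overlapping **10 kb bins** by
*overlap*: a read spanning a bin boundary increments both bins. The
prose description of binned coverage ("reads overlapping each bin") is
taken literally; the alternative 5'-position counting would conserve
read totals exactly but is not what the wording says. The modest
double-counting at boundaries is accepted and tested.

Smoothing assigns to each bin the **running mean over all bins whose
centres lie within ±50 kb** of its centre — 11 bins of 10 kb in the
chromosome interior. A "100 kb window" is genuinely ambiguous between
10 and 11 bins; we fixed the centred, odd-width reading (it is
symmetric and centre-assigned) and left `window` a parameter.
Chromosome ends use the *truncated* window (the mean over the bins
actually present) rather than zero-padding, which would invent signal
where there is none. A pseudocount of **0.1** is added before log2, so
an all-zero neighbourhood maps exactly to `log2(0.1)`; this identity is
asserted in the tests. Contact regions are maximal runs of bins with
smoothed value **strictly greater than 7** log2 units; strictness
matches the defining inequality (">7"), and the region set is disjoint,
sorted and idempotent under re-calling.

Read preprocessing demultiplexes on a prefix-free barcode set, requires
the bait primer immediately after the barcode, truncates the remainder
to **50 nt** (the mapped length), and applies a mean-Phred >= Q20 filter
(the quality criterion is otherwise unspecified upstream; Q20 is the
conventional default and is configurable). Every rejected read is
logged with a machine-readable reason.

## Contact genes and the permutation null

Contact regions are extended by ±10/25/50 kb and merged; a gene belongs
to a region iff its **midpoint** falls inside the extended interval.
Two different selection rules circulate for this step — a 50%-overlap
rule and a midpoint rule — and they disagree for long genes on region
edges; the midpoint rule is implemented as primary because it is the
one stated in prose, and it is self-consistent (monotone in the
extension window). The 4C-positive set additionally requires expression
in the **top 5%** of all genes (nearest-rank threshold, ties kept
inclusively so the result never depends on an arbitrary tiebreak); the
4C-negative control set takes top-5% genes lying entirely **more than
50 kb** from every contact region. Positive and negative sets are
disjoint by construction.

Enrichment of gene classes (snRNA, snoRNA, scaRNA, histone) near
contact regions is tested by **100 random samples of matching size**:
each null sample redraws the regions as random non-overlapping
intervals of identical count, length and chromosome. The empirical P
value uses the add-one correction `(1 + #{null >= obs}) / (1 + n)`, so
it is never zero and its minimum is `1/(n+1)`. The calibration suite
verifies that under uniformly placed target genes the test rejects at
close to its nominal 5% level; the +1 correction and the discreteness
of the count statistic make it mildly conservative (measured ~4% at the
calibration problem size), which is the expected direction of error for
a permutation test.

## FISH co-localization

Spot tables carry continuous centre coordinates; rounding to integer
pixels happens only when images are rendered, so the classifier can be
tested at sub-pixel boundary cases. For each *RNU1* spot in an eligible
cell (>= 1 spot in each of the RNU1, VGOI and CB channels), minimum
Euclidean distances are computed per RNU1 spot; the CB-to-VGOI distance
used for the bridging flag is the one belonging to **the CB that
realizes the RNU1-CB minimum**, not to an arbitrary CB — the any-CB
variant can be obtained by reclassifying with the CB channel
relabelled. Thresholds: gene-gene **<= 3 px (0.96 µm)** and gene-CB
**<= 5 px (1.6 µm)** at 320 nm/px; inclusion bounds are `<=`, the
CB-distal condition is strict `>`. For any distance pair exactly one of
{CB_dependent, CB_independent, none} applies; bridging is an orthogonal
flag. Interaction frequencies are the percentage of eligible cells with
at least one qualifying event; ineligible cells enter neither numerator
nor denominator.

Nuclear segmentation uses a global Otsu threshold, hole filling,
connected components, a minimum-area filter, and exclusion of
border-touching nuclei. The upstream description is only "a custom
image analysis script", so the contract pinned by the tests is
behavioural: disc-like nuclei are recovered, border nuclei are flagged
and excluded, a blank field yields zero nuclei without error. Spot
detection scans nucleus pixels in decreasing intensity (ties broken by
smallest (y, x)) and accepts a pixel as a spot centre — its brightest
pixel — unless it falls within the minimum separation of an accepted
centre.

## The geometric null

The theoretical random body-territory association frequency is modelled
on the 2D projection: nuclear and territory areas are reduced to
equivalent-disc radii (`r = sqrt(area/pi)`), and a body centre uniform
in the nuclear disc is "associated" when its edge-edge distance to the
territory is at most a threshold delta. Under the concentric model this
is the area ratio

$$P = \min\left(1,\ \frac{(\mathrm{CTrad} + \Delta)^2}{\mathrm{NUCrad}^2}\right),$$

clamped to [0, 1], scale-invariant, and monotone in both delta and the
territory radius. The source material prints only the variable
definitions, not the formula itself nor the measured radii, so the
concentric area-ratio model is adopted as the documented default and a
random-placement variant (territory centre uniform subject to
containment) is available behind a flag; the two are compared against a
10^6-draw Monte-Carlo oracle in the acceptance suite. Because the
inputs behind the published 23.5% value are not printed, that number is
not a reproduction target.

## Expression and splicing

FPKM is `count / ((length/10^3) * (total/10^6))`. Condition-level
expression is the mean of replicate `log2(FPKM + 0.01)` values; the
log2 pseudocount is a package choice (the 0.1 pseudocount above belongs
to the 4C profiles, not to FPKM) and is recorded in the output
metadata. The differential call is deliberately primitive, because that
is the procedure being modelled: a gene is *decreased* iff the
knockdown sits at least `lfc_threshold` log2 units below **both** an
untreated control and an siRNA control, *increased* symmetrically,
otherwise *unchanged*. No fold-change threshold is printed upstream;
the default of 1 log2 unit (two-fold) is exposed as a parameter.
Dispersion-modelling differential machinery (DESeq-style) is
intentionally out of scope — the concordance rule *is* the method here.
Quartile labels (Q1-Q4) use nearest-rank cutoffs with values equal to a
cutoff assigned upward, so a constant vector is all Q4.

Junction annotation status is an exact match on (chrom, donor,
acceptor, strand). "Detected" means count >= 1 by default (the
detection threshold is exposed because uniqueness counts are sensitive
to it), and a junction is unique to a condition group when any member
sample detects it and no sample of any other group does; a stricter
all-members variant is a flag. Junctions map to genes by full
containment of both splice sites; junctions inside no gene are reported
as `intergenic`, inside several overlapping genes as `ambiguous`. The
four depth/expression normalization metrics are computed exactly as
their defining ratios, with undefined denominators flagged rather than
silently zeroed. PSI is `inc/(inc+exc)`, undefined at 0/0, and the
two-sided Fisher test uses the probability-mass convention (sum of
hypergeometric probabilities no larger than the observed table's) via
`stats::fisher.test`, cross-checked in the tests against exhaustive
enumeration.

## The synthetic-data generators

No distributional forms are given for any of the modelled data, so
every generative choice here is an implementer's choice, documented as
such:

* **4C reads.** Cis density `background * d^(-decay)` with the bait
  distance floored at 1 kb (the profile exhibits decay but no
  parametric form is claimed; the floor avoids the viewpoint
  singularity), multiplied by the enrichment factor inside planted
  peaks; trans chromosomes carry a uniform background attenuated by
  10^-3 so that the bulk of the signal is intra-chromosomal, as in real
  4C profiles. Reads are sampled cell-by-cell at 1 kb resolution, and
  exactly `n_reads` are emitted.
* **Cell populations.** Nuclear radii are truncated-normal (default
  40 ± 4 px); CBs per cell follow a small count distribution peaked at
  2-3, as high-content imaging of aneuploid cells shows; allele counts
  per gene default to 2-4. A cell carries a planted CB-dependent
  triplet with probability `p_dep` and a planted CB-distal pair with
  probability `p_indep`; all *non-planted* spots are placed with
  exclusion margins (0.5 px beyond the thresholds) so that no
  accidental pair events arise and the planted rates are exact binomial
  ground truth. This is the key idealization: real images contain
  chance co-localizations, so a measured frequency on real data mixes
  true pairing with a proximity background, and passing the recovery
  tests demonstrates correctness of the bookkeeping, not freedom from
  that background.
* **Expression.** log2-FPKM baselines are normal with sd 4 (a wide
  dynamic range emulating small-RNA expression spanning many orders of
  magnitude), knockdown effects (default -2 log2) apply only to genes
  flagged CB-proximal, and replicates add independent N(0, 0.25)
  noise.
* **Junctions.** A fixed annotated set per gene plus
  Poisson-distributed unannotated junctions whose rate can be scaled
  per condition (default doubling under knockdown), all coordinates
  contained in their gene.
* **Splicing events.** Inclusion reads are Binomial(depth, PSI), so a
  planted delta-PSI is recoverable within binomial error.

Each generator consumes one explicit seed (`withr::local_seed`, so the
caller's RNG state is never disturbed) and is bitwise deterministic
under it. What the generators do **not** emulate: realistic sequence
content or error models, restriction-fragment structure, true 3D image
stacks, chance spot proximity (above), and genome-scale annotation
sizes.

## Problem sizes, tolerances, numerical corners

The acceptance suite runs at desk scale, chosen so every check is
statistically decisive: 10^5 reads against factor-50 peaks for peak
recall (the smoothed log2 threshold of 7 equals ~128 reads per 10 kb
bin, which planted peaks exceed by an order of magnitude); 2,000 cells
for pairing-rate recovery within 3 binomial standard errors; 1,000
null simulations x 100 permutations for calibration; 10^6 Monte-Carlo
draws per point on a 3x3 geometry grid. Degenerate inputs are handled
explicitly rather than silently: zero-variance profiles give NA
correlations, 0/0 PSI and all-zero Fisher margins are undefined and
reported, a blank image yields zero nuclei, zero eligible cells yield
an NA frequency, and negative or zero denominators in the junction
metrics raise flags.

Headline quantities from the motivating biology that derive from real
HeLa/primary-cell sequencing and imaging (observed association
percentages, genome-wide differential and junction counts, published
correlations) are not reproduction targets of the synthetic pipeline;
the pipeline reproduces *procedures*, and its tests verify those
procedures against independent oracles and planted truth.

## A word on interfaces

All interval data live as `GRanges` (1-based, closed) in memory; BED
and bedGraph conversion to 0-based half-open coordinates happens only
at the file boundary, inside `rtracklayer`. GTF-lite is 1-based
inclusive on disk, honouring only gene-level records with `gene_id` and
`gene_class` attributes. Strand is carried through all formats but
ignored by distance and overlap computations, which are strand-agnostic
here. The package is function-first: `run_pipeline()` wires the stages
into a reproducible artifact directory (every output carries the config
hash; identical configs give identical bytes), and there is no shell
executable — R scripts over the exported functions are the intended
automation surface.
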