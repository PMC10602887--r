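---
title: "Methods: enhancer chromatin dynamics from coverage tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer chromatin dynamics from coverage tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerdyn)
```

This vignette is the package's account of its methods: what each stage
computes, the assumptions behind it, the defaults and why they were
chosen, and what the synthetic-data tests do and do not demonstrate.

## Coordinate and data model

Every interval in the package is 0-based half-open (`[start, end)`), the
BED convention, including gene models read from GTF (converted on read
from 1-based inclusive). A single internal convention removes the class of
off-by-one errors that arise when BED, GTF and GRanges conventions mix;
conversion to 1-based closed coordinates happens only inside the bridges
to GenomicRanges machinery. Chromosome names are matched as exact strings
— silent "chr" aliasing hides data errors.

Two conventions deserve explicit statement because reasonable tools
disagree on them:

- The **center** of an interval is `start + floor(width / 2)`, so
  even-width peaks have a deterministic anchor.
- The **distance from a point to an interval** is 0 inside the interval
  and otherwise the distance to the nearest *covered* base,
  `min(|p - start|, |p - (end - 1)|)`. This differs by one from tools that
  measure gaps between intervals; the package applies its convention
  consistently in linking and documents it here because nearest-feature
  medians depend on it.

Coverage tracks hold dense per-base signal per chromosome with a library
size. Depth normalization is counts-per-million style
(`values * 1e6 / library_size`). CPM is a pure rescaling — every
downstream ratio and profile shape is unaffected by the choice of unit —
which is why the package does not attempt spike-in or bin-level scaling;
those require information a coverage track does not carry.

## Anchored profile matrices

`extract_matrix()` takes a window of `flank_bp` on each side of every
anchor center, splits it into `bin_width`-bp bins, and stores the
arithmetic mean of the per-base signal per bin. Two decisions matter:

- **Bins that run off a chromosome end are masked, not zero-filled.**
  Zero-filling would drag aggregate profiles toward zero exactly at the
  edges, which is a systematic bias, not noise. Masked cells are excluded
  from aggregation, and the per-bin count `n` is reported so edge
  attrition is visible.
- **Minus-strand anchors are reversed** so column order is always 5' to
  3'; an unstranded anchor set is simply left in genomic orientation.

The defaults (`flank_bp = 2000`, `bin_width = 10`) give 400 bins, enough
to resolve a nucleosome-scale peak while keeping matrices small; both are
plain arguments, and figure-scale choices belong to the caller.

## Geometric-mean aggregation

Region sets in this design span orders of magnitude in signal; a single
amplified locus can dominate an arithmetic-mean profile. Profiles are
therefore aggregated per bin as a pseudocounted geometric mean:

$$\mathrm{GM}_j = \exp\!\Big(\tfrac{1}{n_j}\sum_i \ln(x_{ij} + c)\Big) - c$$

Coverage contains exact zeros, so a strictly positive pseudocount $c$ is
required; it is applied symmetrically (added before the log, subtracted
after) so that all-zero bins aggregate to exactly zero rather than to a
pseudocount artifact. The default $c = 1$ normalized unit is of the order
of the background coverage in typical tracks; any strictly positive value
preserves the robustness property (the suite asserts that with one region
scaled by 10–1000x the GM stays closer to the bulk value than the
arithmetic mean in every case), and as $c \to 0$ on positive data the GM
becomes exactly scale-equivariant. The choice of $c$ does shift absolute
profile heights, which is one reason the package reports comparisons as
ratios and enrichments rather than raw heights.

## Metagene profiles

`metagene_matrix()` builds rows of fixed 1 kb flanks at native resolution
around a body rescaled to `body_bins = 100` bins. Only the body is scaled;
flanks keep their bp meaning, so promoter-proximal features stay aligned
across genes of different lengths. Body bins use **fractional
apportionment**: bin boundaries fall at real-valued positions
`start + length * k / body_bins`, and each base contributes to a bin in
proportion to its overlap. Nearest-bin assignment would make genes shorter
than `body_bins` bases ill-defined; apportionment keeps them well-defined
(with a logged warning) and makes constant coverage yield exactly constant
profiles for any gene length — an invariance the suite checks for 1 kb
against 100 kb genes.

## Regulated-gene sets

`filter_de()` consumes DESeq2-style tables and applies
`|log2FC| >= log2(fold_threshold)` with `padj < alpha` (defaults 2-fold,
0.05). The fold bound is inclusive and the p bound strict — "at least
2-fold" reads naturally as inclusive, and `padj < 0.05` as strict; both
are arguments, so the opposite reading costs one call. Records with
missing adjusted p-values (the independent-filtering artifact of upstream
tools) are excluded with a logged count rather than treated as
significant or as zero. The package never fits the DE model itself; it is
a consumer of result tables.

## Enhancer linking

Enhancers are H3K4me1 peaks; AR-positivity is overlap (>= 1 bp by
default) with an AR peak set. Each regulated gene is linked to the
eligible enhancer minimizing the TSS-to-interval distance. The TSS was
chosen as the gene anchor because it is the conventional anchor for
enhancer-gene assignment and is well-defined for every stranded gene;
gene-body distance would make the measure depend on gene length. Linking
is restricted to the gene's chromosome (cross-chromosome "distance" has
no meaning here), unlinkable genes are counted rather than fatal, and
ties break deterministically by smaller enhancer start, then smaller id
— determinism matters because downstream medians are reported. One
enhancer may serve many genes; nothing in the design implies exclusivity.

## Super-enhancer calling

The caller follows the rank-ordering recipe: stitch peaks whose gaps are
at most 12,500 bp, optionally dropping peaks fully inside TSS ± 2,500 bp;
score each stitched region by total normalized coverage (minus an
optional control, floored at zero); sort ascending, rescale rank and
signal each to [0, 1], and cut where the curve's tangent has slope 1.
On the discrete curve that point is found by minimizing
`rescaled_signal - rescaled_rank`, with the latest rank winning ties;
regions with signal strictly above the cutoff signal are super-enhancers,
so ties at the cutoff are not called. The stitch distance and TSS window
are the protocol's published conventions, kept as arguments; TSS
exclusion is off by default since the appropriate choice depends on
whether promoters were removed upstream. Degenerate inputs — fewer than
three regions or a flat signal — yield zero calls with a warning instead
of an arbitrary cutoff. The analytic check in the suite plants signals
whose rescaled curve is exactly $y = x^2$, for which the slope-1 tangent
sits at $x = 0.5$, i.e. a rescaled-signal cutoff of 0.25.

## Paired accessibility testing

`paired_t_test()` is the two-sided paired Student t-test on aligned
per-region totals, `t = mean(d) / (sd(d)/sqrt(n))` with `df = n - 1`,
delegated to `stats::t.test()`. Zero-variance differences are handled
explicitly: identical inputs give `t = 0, p = 1`; constant non-zero
differences raise an error rather than reporting `p = 0`, because that
pattern indicates a degenerate (usually synthetic) input, not infinite
evidence. Multiple testing uses the Bonferroni per-test threshold
`alpha / m` with `m` an explicit argument — the package does not guess
the number of tests a study performed. Direction is deliberately not
inferred from the test; it is read from the profiles.

## The synthetic-data generator

The generator exists so that every stage has a planted truth to recover.
It emulates the statistical structure the analysis assumes, at desk
scale:

- a genome of two 1 Mb chromosomes; 80 non-overlapping genes of 3–9 kb;
  150 intergenic enhancers of 0.4–1.2 kb with 500 bp clearance between
  features;
- AR peaks (200–400 bp) planted inside 40% of enhancers, never touching
  the others, so AR-positive classification has an exact truth;
- one cluster of 6 enhancers within stitching range carrying a 5x
  amplitude multiplier — the planted super-enhancer;
- per-base coverage drawn as Poisson around
  `lambda + sum A * exp(-(x - center)^2 / (2 w^2))`, with background
  `lambda = 0.5` reads/bp (total depth `lambda * L = 1e6`), Gaussian peak
  width 150 bp at enhancers and 100 bp at TSSs;
- DE tables with exact planted counts (default 40 up, 30 down):
  planted genes draw `|log2FC| >= 1` and `padj < 0.05`, nulls draw
  `padj` uniform on (0.05, 1] with a 5% missing-padj fraction;
- an amplitude table per (mark, timepoint, genotype) encoding the
  qualitative dynamics of the study design: a parental AR spike at 4 h
  that persists, gradual H3K27Ac and H3.3S31Ph accumulation, an H3.3 dip
  at 4 h with late restoration; AR knockout zeroing the AR/BRD4/
  acetylation response; Daxx knockout with a transient 4 h overshoot;
  HIRA knockout scaling the H3.3 axis to 0.3 of parental and converting
  AR/BRD4 binding into a 4 h spike with 12/24 h decay.

All randomness flows from one master seed through named substreams
(annotation, each coverage track, each DE table), so any single output is
reproducible in isolation and a full dataset write is byte-identical
across runs.

Poisson noise was chosen over negative binomial because the simulated
tracks model a single library, not biological replicates; overdispersion
is a config extension point, not a default. What the generator does *not*
emulate — mappability and GC bias, fragment-size effects, replicate
variability, peak-shape asymmetry, background autocorrelation — bounds
what green tests mean: they demonstrate that the implementation computes
its estimators correctly and recovers planted parameters under the stated
noise model, not that the biological conclusions of any particular study
re-derive from raw data.

## Measuring amplitude ratios between genotypes

One subtlety is worth recording. Per-track CPM puts tracks on different
absolute scales whenever their library sizes differ — and a genotype that
genuinely loses signal (HIRA KO loses H3.3) has a smaller library, so CPM
partially *reinflates* the lost signal. A ratio of raw profile heights
across genotypes therefore confounds the planted amplitude ratio with the
library-size ratio. The package's measurement, used by
`scripts/acceptance.R` and the end-to-end tests, is the ratio of
**background-subtracted center heights on a common depth scale** (both
tracks normalized by the same library size): background cancels
additively, the common scale cancels in the ratio, and the planted
HIRA-KO H3.3 amplitude ratio of 0.3 is recovered to within a few
hundredths. `profile_enrichment()` provides the related scale-free
fold-enrichment summary `(center - background) / background`, with
background taken as the median of the outermost 20% of bins on each side.

## Problem sizes in the test suite

The suite runs oracle comparisons at sizes where brute force is exact and
fast: 100 random track/anchor instances for the profile engine, 100
random gene-enhancer instances (up to 500 genes x 200 enhancers) for
linking, 500-peak stitching instances, 10,000 null simulations for
type-I calibration, and 100 generator seeds for super-enhancer recovery
on a sparse 1 Mb genome — sparse because stitched regions only stay
distinct when inter-enhancer spacing exceeds the 12.5 kb stitch distance,
which is the regime the recovery claim is about. The end-to-end recovery
test uses the generator defaults above.

## Known limitations

- bedGraph tracks are materialized densely per chromosome; the intended
  scale is simulated or region-restricted data (megabases), not whole
  mammalian genomes.
- bedGraph is the canonical track format (text, diff-able, sufficient at
  this scale); bigWig is read through rtracklayer but never written.
- The paired test assumes approximately normal per-region differences;
  with heavy-tailed totals a rank-based alternative would be more
  defensible, but is out of scope because the analysis this package
  mirrors used the t-test.
- The metagene flank/body geometry assumes genes are at least a few bins
  long; single-digit-bp "genes" are handled but scientifically
  meaningless.
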