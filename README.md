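# enhancerdyn

Enhancer-centric analysis of chromatin dynamics from sequencing coverage
tracks. The package implements the computational core of a common
prostate-cancer epigenomics design: cells carrying knockouts of the
histone-H3.3 chaperone machinery (HIRA, Daxx) or of the androgen receptor
(AR) are profiled by ChIP-seq (H3.3, H3K27Ac, H3K4me1, H3.3S31Ph, AR,
BRD4), ATAC-seq and RNA-seq over an androgen induction time course
(0/4/12/24 h), and the question is how enhancer chromatin and AR binding
change across genotypes and time.

It is aimed at analysts who already have normalized coverage tracks
(bedGraph), peak calls (BED) and differential-expression tables
(DESeq2-style TSV) and need the downstream, figure-generating layer:

- **Geometric-mean metaplots.** For a signal over a region set, coverage is
  extracted in bins around each anchor and aggregated per bin as
  `GM_j = exp(mean(log(x_ij + c))) - c` with pseudocount `c`, so a handful
  of extreme regions cannot dominate the profile the way an arithmetic mean
  lets them.
- **Metagene profiles.** Gene bodies are rescaled to a common number of
  bins by fractional apportionment, with fixed 1 kb flanks binned at native
  resolution, anchored on strand-aware TSS/TES.
- **Regulated-gene sets.** Genes at least 2-fold changed with adjusted
  p < 0.05 (both thresholds configurable), plus Venn-style disjoint
  overlap cells across contrasts.
- **AR-positive enhancer linking.** Enhancers are H3K4me1 peaks; an
  enhancer is AR-positive when it overlaps an AR peak; each regulated gene
  is linked to the nearest AR-positive enhancer by TSS distance, with
  median-distance summaries.
- **Super-enhancer calling.** Rank-ordering of stitched enhancer regions
  (12.5 kb stitch distance): regions are sorted by total signal, rank and
  signal are rescaled to [0, 1], and the cutoff is the point where the
  curve's tangent has slope 1; regions above it are super-enhancers.
- **Paired accessibility tests.** A paired-sample Student t-test on
  aligned per-region ATAC totals between two cell lines, judged at a
  Bonferroni per-test threshold `alpha / m`.
- **Synthetic data generator.** A seed-driven simulator plants Gaussian
  enrichment amplitudes per (mark, timepoint, genotype) over Poisson
  background, regulated genes, AR-positive enhancers and one clustered
  super-enhancer, so the whole pipeline is testable without sequencing
  data.

All interval coordinates are 0-based half-open (BED convention)
throughout.

## Worked example

Simulate a small two-genotype dataset and compare H3.3 at enhancers in
parental versus HIRA-knockout cells under androgen deprivation:

```r
library(enhancerdyn)

config <- simulation_config(seed = 7, marks = c("H3.3", "H3K27Ac"),
                            genotypes = c("parental", "HIRA_KO"))
truth <- simulate_annotation(config)

prof <- lapply(c(parental = "parental", HIRA_KO = "HIRA_KO"), function(g) {
  track <- normalize_depth(simulate_coverage(truth, "H3.3", 0, g))
  geometric_profile(extract_matrix(track, truth$enhancers,
                                   flank_bp = 2000, bin_width = 10))
})
long <- overlay_profiles(prof)
subset(long, bin_offset %in% c(-2000, -10, 0),
       c(condition, bin_offset, gm, n))
#>     condition bin_offset        gm   n
#> 1    parental      -2000 0.4568851 150
#> 200  parental        -10 5.4916327 150
#> 201  parental          0 5.5779927 150
#> 401   HIRA_KO      -2000 0.5097657 150
#> 600  HIRA_KO         -10 2.5088667 150
#> 601  HIRA_KO           0 2.5204633 150
```

The geometric-mean profile rises from background (~0.5 CPM at -2 kb) to a
peak at the enhancer center, and the HIRA-KO peak sits far below the
parental one — the simulated analogue of reduced H3.3 incorporation when
its chaperone is lost. Calling super-enhancers on H3K27Ac at 4 h:

```r
k27 <- normalize_depth(simulate_coverage(truth, "H3K27Ac", 4, "parental"))
ranked <- rank_and_cut(score_regions(stitch_peaks(truth$enhancers), k27))
attr(ranked, "cutoff")
#> $cutoff_signal
#> [1] 16875.07
#> $cutoff_rescaled
#> [1] 0.3697266
#> $n_super
#> [1] 4
#> $n_total
#> [1] 65
```

The 150 enhancers stitch into 65 regions; 4 exceed the tangent cutoff, and
the top-ranked one is the planted cluster. `run_pipeline()` chains all
stages from a single YAML/JSON config and writes per-stage artifacts plus
a hash manifest; `inst/scripts/enhancerdyn.R` is a command-line wrapper
over it.

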