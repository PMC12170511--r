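# hexniche

Spatial immune-niche analysis for spot-based spatial transcriptomics
(10x Visium) of liver cancer.

## The problem

In a Visium section of hepatocellular carcinoma (HCC), some 55 µm spots are
dominated by infiltrating immune cells. The cells most directly exposed to
those immune cells sit in the spots that *touch* them on the hexagonal
capture lattice. hexniche is for analysts who want to quantify that contact
effect — and how sequencing depth changes it — with every step reproducible
from first principles:

* **Immune-spot calling.** Each spot is scored as the mean log-normalized
  expression (`ln(1 + 10⁴·count/total)`) over a 23-gene immune marker panel
  (Kupffer: *CD68, CD163, LYZ, C1QA, AIF1*; T: *CD3D, CD2, IL7R, TRBC2,
  CD69*; B/plasma: *IGKC, JCHAIN, CD79A, CD27, CD74*; NK/other: *CD4, CD8A,
  ITGAM, NKG7, KLRD1, PRF1, CD7, TRDC*). Spots with score > 0.9 are immune
  cell-enriched.
* **Niche classification.** On the Visium lattice (array row and column
  share parity) the six contact neighbours of `(r, c)` lie at offsets
  `(0, ±2)`, `(±1, ±1)`. Non-immune spots touching an immune spot are
  `adjacent`; the rest are `away`. The three labels partition the tissue.
* **Differential expression.** Mann–Whitney rank-sum tests (tie-corrected
  normal approximation, 0.5 continuity correction) on three contrasts —
  tumor adjacent vs away, benign adjacent vs away, tumor-adjacent vs
  benign-adjacent — with Benjamini–Hochberg correction, log2 fold changes on
  de-logged means, and the conventional filters (min 10% detection,
  |log2FC| ≥ 0.25, q < 0.05).
* **Depth comparison.** Binomial thinning emulates standard-depth
  sequencing from deep counts (entry-wise dominated, detection sets nested
  by construction); per-gene detection deltas and a two-sample
  Kolmogorov–Smirnov test summarize the depth effect.
* **Composition testing.** Centered-log-ratio transform plus a
  permutational multivariate ANOVA (sequential sums of squares on the
  Gower-centered distance matrix, raw-observation permutation) for crossed
  factors such as depth regime × tissue region.
* **Ground-truthed simulation.** A negative-binomial generator plants known
  immune spots, contiguous tumor subclones and adjacency-response genes on
  a two-slide hex grid, so recall, false-positive rate, DE sensitivity,
  false-discovery proportion and null calibration are measured, not assumed.

The central container is `SpotExperiment`, a `SummarizedExperiment` whose
`colData` carries the spatial substrate (slide, array coordinates,
in-tissue flag, tumor/benign region) with lattice conventions enforced by
the validity method.

## Worked example

```r
library(hexniche)

cfg <- pipelineConfig(
  simulate = syntheticConfig(seed = 1, n_rows = 24, n_cols = 24,
                             n_genes = 1000, n_response_genes_tumor = 60,
                             n_response_genes_benign = 20),
  hvg_n = 1000, output_dir = "demo_run", seed = 1)
report <- runPipeline(cfg)
```

The run writes niche labels, DE tables, the detection comparison and a JSON
report under `demo_run/`, with this summary (`demo_run/report.txt`):

```
spots analyzed: 1152 | immune 50 / adjacent 240 / away 862 (deep)
immune spots at standard depth: 0
DE tumor_adjacent_vs_away: 59 significant (deep) vs 2 (standard)
DE benign_adjacent_vs_away: 18 significant (deep) vs 0 (standard)
DE tumor_adjacent_vs_benign_adjacent: 89 significant (deep) vs 1 (standard)
genes with higher detection at deep depth: 998 of 1000 (99.8%)
PERMANOVA: A p=0.001, B p=0.001, A:B p=0.104
```

Reading it: of 1,152 tissue spots, 50 were called immune cell-enriched and
240 touch one of them. The tumor stratum responds to immune contact much
more broadly than the benign stratum (59 vs 18 significant genes; the
planted ratio is 3:1), and 35-fold thinning collapses both the immune calls
and the DE yield — the depth effect the pipeline is designed to expose.
The PERMANOVA recovers the planted depth and region effects on macrophage
composition (p = 0.001 each) and finds no interaction (p = 0.104). Against
the generator's ground truth this run recalls 94.3% of planted immune spots
with no false positives, and the tumor contrast recovers 98.3% of planted
response genes with a false-discovery proportion of 0.

A thin CLI wrapper is included for shell use:

```sh
Rscript inst/scripts/run_pipeline.R \
  --config inst/extdata/example_pipeline.yaml --seed 1 --out demo_run
```

## Documentation

The methods vignette (`vignettes/hexniche-methods.Rmd`) describes the
niche model and its assumptions, the normalization substitution behind the
0.9 threshold, the statistics and their numerical edge cases, what the
synthetic generator does and does not emulate, and known limitations.
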