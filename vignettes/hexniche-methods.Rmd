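---
title: "Methods: spatial immune niche analysis with hexniche"
author: "hexniche authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial immune niche analysis with hexniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Spot-based spatial transcriptomics (10x Visium) measures expression in 55 µm
capture spots arranged on a hexagonal lattice, each holding a handful of
cells. In a tumor section, some spots are dominated by infiltrating immune
cells; the cells in the spots that *touch* those immune-enriched spots are
the ones most directly exposed to immune signalling. hexniche implements the
resulting three-class spatial analysis for hepatocellular carcinoma (HCC)
sections with an adjacent benign-liver region:

1. call **immune cell-enriched spots** from a marker panel score;
2. classify every other spot as **adjacent** (touching an immune spot on the
   hex lattice) or **away**;
3. compare expression between adjacent and away spots, separately within the
   tumor and benign strata, and between the two strata's adjacent spots;
4. quantify how sequencing depth changes the picture (gene detection,
   immune-spot calls, differential-expression yield);
5. test whether factors such as depth regime and tissue region shift immune
   cell-type *composition*, using a centered-log-ratio (CLR) PERMANOVA.

Everything runs against a synthetic-data generator with known ground truth,
so each stage's operating characteristics (recall, false-positive rate,
sensitivity, false-discovery proportion, null calibration) are measured
rather than assumed.

# Spatial substrate and niche model

Spots live at integer array coordinates `(r, c)` where row and column share
parity (the Visium convention: odd rows are offset by one column unit). The
six contact neighbours of `(r, c)` are at offsets `(0, ±2)`, `(+1, ±1)` and
`(−1, ±1)` on the same slide. "Adjacent to immune cells" is formalized as
this 6-neighbourhood; no second ring is considered.

The immune score of a spot is the arithmetic mean of log-normalized
expression over the marker panel union (23 genes by default: Kupffer-cell,
T-cell, B/plasma and NK/other lineages). A spot is called immune
cell-enriched when its score is **strictly** greater than the threshold
(default 0.9). Two design points deserve emphasis:

* Panel genes absent from the matrix shrink the averaging denominator
  instead of contributing zeros, so a probe set lacking one symbol is not
  penalized; a coverage floor (default 50% of the panel) guards against
  degenerate panels. Whether to average over the panel union or per lineage
  first is genuinely open; hexniche uses the flat union mean.
* Immune precedence: an immune spot adjacent to another immune spot stays
  `immune` — the three classes are exclusive and exhaustive, and the suite
  asserts that partition on every input.

# Normalization and the 0.9 threshold

Counts are normalized as `ln(1 + 10^4 * count / spot_total)` (log-CP10K).
This is a deliberate substitution: regularized negative-binomial approaches
(SCT and relatives) are excellent defaults interactively but introduce
fitted, version-dependent parameters; log-CP10K makes every downstream
number reproducible from first principles. The score threshold of 0.9 is
interpreted on this log scale and is a configuration parameter
(`NicheConfig$score_threshold`), not a constant — on data normalized
differently the appropriate value may differ. The synthetic generator
calibrates marker abundances on the same scale, so threshold and generator
are mutually consistent by construction.

Highly variable genes are ranked by binned standardized dispersion: per gene
the mean and dispersion (variance/mean) of de-logged normalized values are
computed, genes are split into 20 equal-occupancy mean bins, and dispersion
is z-scored within each bin. Tie-breaks are fully specified (zero-dispersion
genes last; z snapped to 10 significant digits; remaining ties by gene
symbol) so the ranking is deterministic and matched by an independent dense
oracle in the tests.

# Differential expression

Each contrast is a two-group comparison of log-normalized values with the
Mann–Whitney rank-sum test (average ranks for ties; normal approximation
with tie-corrected variance and 0.5 continuity correction), Benjamini–
Hochberg adjustment over tested genes, and a log2 fold change computed on
de-logged group means stabilized by a pseudocount. Genes detected in fewer
than `min_pct` (default 10%) of spots in both groups are excluded before
testing. A gene is significant when `q < 0.05`, `|log2FC| ≥ 0.25` and the
detection filter passes — the conventional single-cell defaults, all
exposed in `deConfig()`.

The normal approximation is used at every sample size; the exact
permutation distribution exists only as a test oracle. Exhaustive
enumeration over every attainable statistic at group sizes up to 8 shows
the approximation within 0.05 of the exact two-sided p for tie-free data;
under *heavy* ties in tiny samples (many duplicated values at n = 3) the
discrepancy can reach ~0.19, which is immaterial at the hundreds of spots
per group where the test is actually applied, but is bounded explicitly in
the suite.

The three canonical contrasts exclude immune spots from every group:
tumor-adjacent vs tumor-away, benign-adjacent vs benign-away, and
tumor-adjacent vs benign-adjacent. "Integrating" differentially expressed
genes with the top-3000 HVG list is implemented as set intersection (the
restrictive reading); union is available via `screenWithHVG(mode =
"union")`.

# Depth comparison

Standard-depth data are emulated by binomial thinning: each count is
replaced by a Binomial(count, rate) draw, which preserves relative
abundances exactly (a Poisson gene stays Poisson at the scaled mean — the
suite checks the moments) and guarantees the thinned matrix is entry-wise
dominated by the original, making detection sets nested by construction.
This attributes depth effects to depth alone, unlike comparing two
physically distinct sequencing runs; both uses share the same comparison
operations.

Two summaries are reported because the underlying question — "did deeper
sequencing detect more?" — admits two readings: the per-gene count of
strictly increased detection fractions, and a global two-sample
Kolmogorov–Smirnov test on the two per-gene detection-rate distributions
(exact supremum over pooled ECDF points; asymptotic p with effective sample
size `n_a n_b / (n_a + n_b)`). Neither is presented as the other's
substitute.

In the pipeline, the thinned run re-calls immune spots from the thinned
scores (for the immune-count depth effect) but runs its DE contrasts on the
niche labels called from the *deep* data. This keeps the two depth regimes
comparing identical spot groups, so differences in significant-gene counts
reflect the counts alone rather than a reshuffled spatial classification.
At the default 35-fold thinning the standard-depth immune score collapses
for most spots (few immune calls survive), which is itself the depth effect
the comparison is designed to expose.

# Composition testing

Cell-type composition tables (one row per observation on the simplex) are
CLR-transformed: zeros are replaced by `epsilon` (default 1e-6) with row
re-closure — simple multiplicative replacement — then each row of logs is
centered by its mean. The PERMANOVA partitions the total sum of squares of
the Euclidean distance matrix sequentially (Type I) into factor A, factor
B, interaction and residual via trace forms on the Gower-centered
inner-product matrix; pseudo-F uses the full-model residual; p-values come
from permuting raw observations, `(1 + #{F* ≥ F}) / (n_perm + 1)`. Whether
to permute raw observations or reduced-model residuals is open in general;
raw-observation permutation matches the most common practice and is the
package's choice. The one-way pseudo-F equals the classical centroid
trace-ratio (asserted to 1e-8), and the two-way partition is cross-checked
against an independent implementation in the test suite.

# The synthetic generator

The generator emulates the structure of a two-slide Visium HCC case and is
the package's measurement instrument, not a demo. Its defaults are the
study conditions:

| parameter | default | what it encodes |
|---|---|---|
| grid | 2 slides × 56 × 56 | 6,272 spots, within 1% of the motivating case (6,320) |
| benign band | 30% of slide-1 rows | contiguous benign region on one slide only |
| subclones | 15 patches | contiguous tumor expression programs, grown on the lattice |
| immune fraction | 0.046 | 289 planted immune spots at the default grid |
| benign bias | 4× | immune spots enriched within 2 hex steps of the benign region |
| marker target | 1.2 log-CP10K | immune-spot marker mean, above the 0.9 threshold |
| response genes | 200 tumor / 67 benign | ~3:1 broader tumor response, planted at log2FC = 1 (signed) |
| overdispersion | 0.1 | negative-binomial size 10, typical UMI overdispersion |
| depth | 20,000 vs 20,000/35 | deep vs standard mean counts/spot; the ~35:1 ratio of ~700K vs ~20K reads/spot scaled down for desk-scale runtime |

Counts are negative binomial around `library_size × relative_abundance`
with lognormal library sizes (sdlog 0.35) — the standard overdispersed
model for UMI data. Marker and response genes are held at *calibrated
absolute* relative abundances (e.g. the immune-spot marker abundance is
`(e^1.2 − 1)/10^4`), so their expected log-normalized expression lands at
the configured scale irrespective of the other genes; the remaining genes
share the residual probability mass according to lognormal baseline weights
modulated by their patch's expression program. Response effects apply only
in non-immune spots hex-adjacent to an immune spot, and only in the
matching stratum (tumor-response genes in tumor spots, benign in benign).
All randomness flows from one integer seed through fixed-offset stage
seeds; the expression *structure* (baselines, programs, planted sets) is
drawn once and shared by both depth regimes, mirroring one library
sequenced twice.

What the generator does **not** emulate: histology, segmentation error,
doublets, probe chemistry, spatial autocorrelation beyond the subclone
patches, batch effects between slides, and the deconvolution step that
produces real composition tables (compositions with planted factor effects
are simulated directly as Dirichlet draws). Passing tests therefore show
the pipeline recovers what it is pointed at under a faithful noise model —
they do not certify performance on tissue artifacts the generator omits.

# Numerical choices and degenerate inputs

* Natural log, pseudocount 1, scale factor 10^4 — stated because nothing
  forces them; all exposed.
* Strict inequalities where a published description says "higher than":
  score > 0.9; detection "increase" means delta > 0.
* An in-tissue spot with zero total count is an error naming the spot; an
  all-tie rank-sum test returns p = 1; empty contrast groups fail, naming
  the contrast, and the benign contrasts degrade gracefully when a dataset
  has no benign region.
* BH p-values are validated into (0, 1]; q is capped at 1 and monotone.
* KS uses the exact pooled-ECDF supremum, never a grid approximation.
* PERMANOVA requires ≥2 levels per factor, ≥2 observations per design cell
  and no empty cells (confounding is an error, not a warning).

# Problem sizes in the test suite

Unit tests run on toy fixtures (grids up to 16 × 16, ≤ 400 genes) in
seconds. The end-to-end validation uses the full default configuration —
6,272 spots × 5,000 genes — across 10 seeds for the depth study (the first
5 of which supply the parameter-recovery averages), 10 small-scale
effect-free datasets for false-discovery calibration, and 200 null
composition datasets for PERMANOVA p-value uniformity. The complete suite
runs in a few minutes on one CPU.

# Known limitations

* Log-CP10K, not a variance-stabilizing fit: very low-depth spots have
  coarse, heavy-tailed normalized values (visible in the thinned regime).
* The rank-sum normal approximation is inaccurate for heavily tied tiny
  groups (n ≈ 3); the package refuses groups below 3 but does not switch to
  an exact test.
* "Contact" is first-ring only; biological influence plausibly extends
  further and a configurable ring is future work.
* PERMANOVA assumes exchangeability of observations under the null;
  spatially autocorrelated compositions would need restricted permutations.
* Gene identity is by symbol; collision handling is suffix-based
  disambiguation, adequate for simulation and standard feature tables but
  not a general identifier model.
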