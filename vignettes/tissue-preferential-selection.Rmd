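---
title: "Identifying and characterizing tissue-preferential genes with TissuePref"
author: "TissuePref authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and characterizing tissue-preferential genes with TissuePref}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TissuePref)
```

## The analysis problem

Root hairs are tip-growing extensions of root epidermal cells that take up
water and nutrients and mediate interactions with soil microbes. Because
they are a minute fraction of root mass, genes that drive their development
are invisible to whole-root profiling: they must be found by contrasting a
root hair-enriched expression profile against a multi-tissue compendium.
`TissuePref` implements that contrast as a reusable pipeline for any
target/reference tissue pair on log2-intensity microarray-style data, and
adds the standard downstream characterization steps: annotation-term
over-representation, promoter cis-element scanning, coexpression refinement
of protein-protein interaction (PPI) networks, and cross-species
conservation of preferential expression.

The package ships a synthetic-data generator with planted ground truth, so
every stage is testable end to end without external accessions.

## The selection chain

`selectPreferential()` chains five stages over a genes x samples
[`TissueExpression`] object, recording per-stage provenance:

1. **Quantile normalization** (`quantileNormalize()`, optional, default on):
   every sample column is forced onto the common per-rank mean
   distribution, ties averaged (via `limma`). Appropriate for single-channel
   arrays hybridized in one series.
2. **Replicate averaging** (`collapseReplicates()`): arithmetic mean per
   tissue, in log2 units.
3. **Expression filter** (`filterExpressed()`): keep genes whose *maximum*
   over collapsed tissue values is strictly above the threshold (default 8
   log2 units). The max-over-tissues reading is the most permissive one: a
   gene expressed in any single tissue survives to be clustered.
4. **K-means clustering** (`clusterExpression()`) with selection of the
   target-preferential cluster (`selectPreferentialCluster()`): Lloyd's
   algorithm over Euclidean distance, K-means++ initialization, 10 restarts
   keeping the best inertia, fixed seed, defaults to 12 clusters. The
   pipeline clusters **z-scored gene profiles** (each gene row centered and
   scaled): once genes span a realistic dynamic range, raw Euclidean
   K-means groups them by overall level rather than by tissue pattern, and
   it is the pattern that defines preferential expression. The chosen
   cluster maximizes the centroid contrast
   `centroid[target] - max(centroid[other tissues])`; ties resolve to the
   lowest cluster index. (`clusterExpression()` itself defaults to raw
   values; the pipeline passes `standardize = TRUE`.)
5. **Cross-tissue elimination** (`dropCrossTissueHigh()`): a gene is kept
   only if its target value exceeds the best tissue other than target and
   reference by a margin (default 1 log2 unit, mirroring the 2-fold logic
   of the final rule), followed by the **fold-change rule**
   (`foldChangeFilter()`): target minus reference at least `log2(2)`
   ("at least two-fold" read inclusively).

All tunable values live in `selectionParams()`. The thresholds are in log2
units; `foldMin` is a linear fold.

```{r example}
sim <- simulateCompendium(600, c("root_hair", "root", "leaf", "stem",
                                 "seed", "flower"),
                          replicates = 3, nPreferential = 40,
                          effectLog2 = 2, seed = 42)
res <- selectPreferential(sim$expr, selectionParams(nClusters = 8,
                                                    seed = 42))
stageSummary(res)
length(intersect(selectedGenes(res), plantedGenes(sim$truth)))
```

## Repeat-based term enrichment

Annotation over-representation is computed over *annotation repeats*
(gene-term assignments), not genes: with `m` repeats of a term genome-wide,
`Q` repeats across the queried genes and `G` repeats genome-wide, the
expected count is `E = m * Q / G`, fold enrichment is `k / E` for `k`
observed repeats, and the p-value is the upper tail of
Hypergeometric(population `G`, successes `m`, draws `Q`). The repeat-based
population is the parameterization that the published expected/fold values
for the rice root-hair query (`Q = 422`, `G = 39571`) pin down numerically;
a gene-based variant is available via
`termEnrichment(..., countUnits = "genes")`. Terms are selected at raw
`p <= 0.05` and `fold >= 2`, both inclusive; no multiple-testing correction
is applied (the report column is named `p_raw` and the file writer labels
it "raw hypergeometric p"). Fold is always computed from the unrounded
expectation; display rounding (2 decimals, half away from zero) happens
only in `writeEnrichmentTable()`.

```{r enrichment}
roundHalfUp(expectedCount(9, 422, 39571), 2)        # oxygen-transport row
roundHalfUp(foldEnrichment(3, expectedCount(9, 422, 39571)), 2)
hypergeomPValue(3, 9, 422, 39571)
```

## Promoter motif scanning

`scanPromoter()` slides a motif and its reverse complement across every
offset of a promoter window (0 = farthest-upstream base; the report adds
`distance_to_tss = L - offset - w`). Two motif representations are
supported:

* **IUPAC consensus** with up to `maxMismatches` mismatches. An `N` in the
  promoter never matches - it always counts as a mismatch.
* **Position probability matrix**, scored as log2 odds against a uniform
  background (pseudocount 1e-4); windows scoring at least `scoreFraction`
  (default 0.85) of the maximum attainable score are reported. The
  fraction-of-maximum rule is deliberate: it makes the threshold
  independent of motif length and of the score minimum, unlike min/max
  interpolation.

All overlapping occurrences are reported; de-duplication is the caller's
choice. The root hair-specific cis-element (RHE, a 16-17-nt element) is
*not* hard-coded: motifs are inputs (`readMotif()` accepts a one-line IUPAC
file or a minimal MEME-style probability block), since the element's
sequence is defined by prior literature, not by this package.

## Network refinement and conservation

`refineNetwork()` correlates the two endpoints of every PPI edge across
the *collapsed tissue columns* (correlation across anatomy, not across
replicates) and keeps edges with Pearson correlation strictly greater
than the threshold (default 0.5). Edges with an endpoint missing from the
matrix, or with a zero-variance profile, are dropped and counted, never
retained. The node set is exactly the endpoints of retained edges, split
into seed genes (the preferential set) and interactors.

`conservationStats()` consumes an oriented ortholog pair table and reports,
for each species' preferential set, how many genes appear in at least one
pair and how many have at least one partner inside the other species'
set. Many-to-many orthology counts each gene once. Percentages are
displayed half-up at one decimal.

## What the synthetic data emulate - and what they do not

`simulateCompendium()` models the log2 intensity of gene *g* in tissue *t*
as `level_g + wobble_gt`, plus replicate noise:

* `level_g ~ N(baselineMean = 10, geneLevelSd^2 = 1.5^2)` - the
  gene-to-gene dynamic range. A wide per-gene spread matters: quantile
  normalization maps values through ranks, and on a compendium whose genes
  all sit at the same level a +2 effect saturates the top ranks and is
  truncated. Real compendia span many log2 units; 1.5 reproduces that
  qualitatively.
* `wobble_gt ~ N(0, baselineSd^2 = 0.3^2)` - the tissue-to-tissue
  fluctuation of a *non-preferential* gene, set on the scale of replicate
  noise (0.3). This is a definitional choice: a background gene whose
  tissue spread rivals the 1-log2 cross-tissue margin would itself be
  tissue-preferential, which is exactly what background genes must not be.
* Planted genes sit flat at their own `level_g` in every tissue and add
  `effectLog2` (default 2) in the target tissue only.

Determinism: every generator draws from a seed derived from the master
seed through a stable string label (`substreamSeed()`), so adding one
generator to a bundle never perturbs another, and all outputs are
bit-reproducible given the seed.

Known limitations, stated plainly: the generator draws i.i.d. Gaussian
noise with no probe effects, no dye/array batch structure, no correlated
gene modules beyond the planted set, and no mean-variance trend; promoters
are uniform A/C/G/T with exact planted motif copies. At `effectLog2 = 0`
planted genes keep their flat profile, so they are slightly *less*
tissue-variable than background genes - the null check in the test suite
therefore asks for absence of planted-gene *enrichment* among selected
genes, which this construction cannot bias upward. Passing tests on these
data show the pipeline's logic is correct under its stated model; they do
not certify performance on real arrays, where normalization choices and
correlated noise dominate.

Problem sizes in the shipped tests and acceptance script (2000 genes, 10
tissues, 3 replicates, 100 planted genes, 20 seeds) were chosen as the
smallest sizes at which the selection chain's operating characteristics
stabilize; larger compendia only sharpen them.

## Numerical conventions

* Coordinates are 0-based half-open internally; GFF3's 1-based inclusive
  convention is converted at the boundary (`extractPromoters()`).
* Promoter position 0 is the farthest-upstream base of the window.
* Cluster indices are 1-based (R convention); ties in cluster selection go
  to the lowest index.
* Report columns round half away from zero (`roundHalfUp()`), matching the
  convention of the printed reference tables; computation is always at
  full precision.
* K-means restarts that empty a cluster are discarded and retried on the
  next substream; the best inertia among successful restarts wins.
* `fold = k / expected` returns `Inf` for `k > 0` with zero expectation
  and `NaN` for `0 / 0`; both sentinels are excluded by `enrichSelect()`
  only via the p/fold thresholds, never silently.

## Orchestration

`runPipeline()` drives the whole analysis from one YAML (or list) config:
selection always; enrichment, motif scanning, network refinement and
conservation whenever the corresponding inputs are named. Unknown config
keys are rejected by name, inputs are checked before any stage runs, and
every output file is listed in `manifest.tsv` with an MD5 hash - a second
run with the same config reproduces identical hashes. With a
`simulateBundle()` truth file in the config, the manifest also records the
selected set's F1 against the planted genes.
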