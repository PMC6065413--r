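---
title: "Methods: associating mutational profiles with normal-tissue features"
author: "tissueMutAssoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: associating mutational profiles with normal-tissue features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model implemented by
`tissueMutAssoc`, the choices made where the design was genuinely open,
and the limits of what the synthetic benchmark can show.

## The data model

The pipeline operates on gene-level tables:

- a **mutation catalog** (MAF-dialect records: gene, sample, cancer type,
  variant classification), reduced to a `FrequencyMatrix` of per-gene,
  per-cancer-type mutation frequencies — the fraction of cohort samples
  carrying at least one qualifying mutation. For protein-coding genes only
  non-silent variant classes qualify (the standard MAF non-silent set,
  configurable); for non-coding genes every record counts. A sample counts
  at most once per gene and cancer type; genes without records in a cohort
  get frequency 0, not missing.
- an **expression matrix** (FPKM, genes × tissues), z-normalized before
  feature computation. The normalization axis is not dictated by the data
  model; per-gene-across-tissues is the default because the association
  test compares a gene's values across tissues, and per-tissue
  normalization is available as an option (`zNormalize(..., axis =
  "tissue")`).
- a **chromatin-state table**, either 25-state label strings per epigenome
  or pre-binarized ON/OFF calls per tissue. The four transcription-
  associated states map to EpiON; replicate epigenomes for one tissue are
  aggregated by strict majority (ON only if strictly more than half of the
  replicates are ON), and expression replicates would be averaged upstream.
- **pathways** (GMT membership, optionally directed edge lists) and an
  undirected simple **PPI network**.

## Features and activity scores

Chromatin accessibility enters the cross-tissue test only for genes whose
state varies across tissues (EpiDIFF); constitutively ON/OFF genes carry no
cross-tissue information and are excluded (with accounting).

The three expression-derived features are **activity scores**: the
upper-tail probability *p* of the observed mean expression of a gene set
(the gene itself; its first-degree pathway neighbors; its PPI partners)
among `nNull` uniformly drawn same-size gene sets, reported as −log *p*.
Numerical choices:

- *Pseudocount*: *p* = (1 + *s*)/(1 + *n*<sub>null</sub>), so *p* ∈ (0, 1]
  and the score is bounded by log(*n*<sub>null</sub> + 1). The raw
  fraction can be zero, which would make the score infinite.
- *Singleton sets* use the exact null (the full expression vector) instead
  of sampling; small universes can request exhaustive enumeration
  (`exhaustive = TRUE`), and the sampled null converges to it within
  Monte-Carlo error (property-tested).
- Null sets are drawn without replacement from all genes with expression in
  the tissue; the target's own neighbors are *not* excluded, matching the
  plain reading of "randomly drawn gene sets". Draws are independent per
  (feature, tissue, set size); whether draws should be shared across
  tissues is unknowable from the data model, and independent draws are the
  conservative choice.
- When a gene maps to several pathways, the feature takes the *minimum*
  p-value over mapped pathways (the strongest pathway). When a pathway has
  no directed edges, the neighbor set falls back to all other members
  behind an explicit flag (`membershipFallback`), since GMT files carry no
  topology.

The **control feature** is the mean expression of 5 genes sampled without
replacement from a gene's pooled distance-3-to-7 PPI neighbors — remote
enough to carry only background signal; genes with a pool smaller than 5
are excluded. The same 5 genes are used across all tissues within one
realization; repeated realizations use fresh seeds.

## The association test

For each gene, tissues are sorted by mutation frequency ascending and
split at the largest successive gap (ties: the lowest boundary index,
which is deterministic and, for discrete frequency data where gap ties are
common, yields the larger high group and hence better permutation
resolution). The statistic is the difference of median feature values,
group 2 (high) minus group 1 (low). For the chromatin feature the grouping
is the gene's EpiON/EpiOFF tissue states and the statistic is the median
*mutation-frequency* difference.

The null permutes mutation frequencies over tissues. Because the gap split
depends only on the *sorted* frequencies, permuting frequencies and
re-deriving the split is exactly equivalent to fixing the empirical group
sizes and assigning tissues to groups at random; the package uses this
faster form, and a test verifies the equivalence by exhaustive enumeration
at 5 tissues. The p-value is two-sided on |statistic| with the pseudocount
form: a one-sided reading cannot produce the negative associations the
method is designed to report, so the direction (sign of the statistic at
significance) is reported separately. For the chromatin feature the
frequency-permutation null is used (label permutation is available as an
option; at fixed group sizes the two are identical in distribution).

Group sizes down to 1 are allowed — a differentially mutated gene is often
highly mutated in very few tissues — but see *Resolution limits* below.
Permutation streams are seeded per (gene, feature) by a counter-based hash
of the master seed, so results do not depend on iteration order.

The **permutation FDR** for a feature permutes each gene's frequency
labels `nLabelPerm` times, re-runs the test, and reports
#significant(permuted) / (#significant(empirical) × `nLabelPerm`). Since a
label permutation leaves the sorted frequencies (hence group sizes and the
null) unchanged, each permuted statistic is a fresh draw from the same
null, which the implementation exploits by reusing one null sample per
gene.

## Enrichment random walks

Genes are ranked by ascending association p-value (ties broken
lexicographically by symbol, so rankings are reproducible across runs).
The observed walk counts gene-set members among the top-*x* ranks; the
uninformative expectation is the hypergeometric mean *xK*/*N* (the
implementation computes the explicit expectation sum on request and the
closed form on hot paths; they agree to 1e−9 by the hypergeometric mean
identity). Curves are normalized by their terminal value, treated as CDFs
of rank-valued variables, and compared with a closed-form Mann–Whitney
statistic θ = P(X<sub>obs</sub> < X<sub>ref</sub>) + ½P(=). The univariate
null re-walks with membership permuted over ranks; p is the pseudocount
fraction of permuted θ at least as large as the empirical θ (one-sided
toward positive deviation). Both observed-vs-expected (default) and
observed-vs-permuted references are supported.

For two features the **joint walk** counts members in the union of the two
top-*x* lists (each member enters at the smaller of its two ranks). The
**conditional walk** F2|F1 is the expected union count when F2 is a
uniformly random ranking: the first list's member trace *k*(*n*) plus a
double hypergeometric expectation over the number of new genes and new
members, which collapses to *k*(*n*) + (*K* − *k*(*n*)) *n*/*N*. Both the
literal double sum and the closed form are implemented and agree exactly.
The conditional curve includes the F1 baseline *k*(*n*) because it is
compared against the joint walk, which also counts F1's contribution;
the bare "extra members" expectation alone would not be on the same scale.

The bivariate null keeps F1's observed ranking and membership fixed and
replaces F2 by a uniformly random ranking (reciprocally for the F1|F2
comparison). A membership-permutation null — natural in the univariate
case — is *not* appropriate here: it destroys both features'
informativeness and inverts the test's semantics (an exact copy of an
informative F1 would come out "significant"). With the random-ranking
null, a copy classifies as "neither/overlapped", two independent
informative features as "both indispensable", and an uninformative F2 as
"F1 superior" (scenario-tested at 50 replicates each).

Universes are harmonized before any bivariate run: the shared universe is
the genes scored by both features, and K is recomputed within it, because
feature universes genuinely differ (pathway membership, PPI coverage,
EpiDIFF status).

## The synthetic benchmark

`syntheticConfig()` / `generateBundle()` produce complete input bundles
with known ground truth. Defaults define the study conditions:

- 12 tissue types (within the regime of a dozen-to-twenty cancer types the
  pipeline targets), cohorts of 100 patients, background mutation
  probability 0.02 per gene and tissue, realized as binomial draws so
  frequencies have realistic granularity and integral patient counts;
- planted associated genes (8% of genes per feature, disjoint blocks) get
  1–3 high-mutation tissues with the frequency elevated by a gap of 0.3;
  25% of planted genes have negative direction, mirroring the
  positive-association bias the method reports on real data;
- the feature shift is 3 SD of the expression noise, applied to the gene
  itself (expression feature), to dedicated carrier genes in a planted
  pathway, or to the gene's PPI partners — so for the network features the
  *neighbors*, not the gene, carry the signal. Only non-focal genes
  receive neighbor shifts, keeping each planted signal clean; PPI focal
  genes are chosen among genes with at least 2 eligible partners so the
  planting is never vacuous;
- chromatin-planted genes are EpiDIFF with ON states aligned (or
  anti-aligned) to the high group; the background mixes EpiAllON (40%),
  EpiAllOFF (20%) and random EpiDIFF (30%) genes;
- the network is preferential-attachment by default (heavy-tailed degrees,
  non-trivial distance-3–7 pools), mean degree 4;
- the planted cancer-gene set is drawn with probability 0.6 for
  pathway-associated genes and 0.05 otherwise, so cancer genes concentrate
  among pathway-associated genes.

What the generator does **not** emulate: correlated co-expression and
co-mutation among neighboring genes, mutational signatures, copy-number
events, and tissue-specific expression baselines. Passing recovery tests
therefore shows the machinery detects the planted regime at the stated
effect sizes — not that real data carry such signals.

## Resolution limits and calibration

Two intrinsic properties of the discrete permutation null matter when
interpreting results:

- **Resolution floor.** With group sizes (m, T−m) there are only C(T, m)
  distinct assignments, so the attainable p floor is about 1/C(T, m). At
  T = 12 a single-tissue high group cannot reach p < 0.03 under any
  feature; planted genes with one high tissue are undetectable *by
  design*, which caps overall detection in the recovery study (the
  acceptance suite asserts the nominal targets and reports the measured
  rates honestly).
- **Conservative null p-values.** Null genes frequently land on m = 1
  splits (binomial background counts often isolate the top value), whose
  p atoms start near 1/12; the marginal null p distribution is therefore
  stochastically above uniform below ~0.08, the measured type-I error at
  α = 0.03 falls below the nominal level, and a KS uniformity check
  rejects. The test never overclaims — it is conservative — and the
  permutation FDR, whose numerator and denominator are equally affected,
  still centers near 1 on null data.

The activity-score transform (−log of an upper-tail p) amplifies
up-shifts and compresses down-shifts toward its floor at 0, so
negative-direction associations are detected with lower power than
positive ones — consistent with the strong positive bias the method
exhibits on real data.

Problem sizes used by the test suite and the acceptance script (chosen to
estimate each quantity with useful Monte-Carlo precision): 2000 genes ×
2000 permutations for null calibration, 500 planted genes × 2000
permutations for recovery, 5000 replicates for the conditional-walk
oracle, 50 replicates per bivariate scenario, and the quick-profile
defaults `nPerm = nNull = 1e4` in `runConfig()` (the paper-scale profile
`paperScale = TRUE` raises all permutation counts to 1e5; pseudocount
p-values keep quick-profile results conservative).

## Interfaces

All functionality is exposed as documented R functions over S4 containers;
`runPipeline()` orchestrates the full analysis from a `runConfig()` (or a
YAML file via `readRunConfig()`) and writes per-feature association TSVs,
a summary table, walk-curve TSVs, a bivariate outcome table and a JSON
manifest sufficient to re-run the identical analysis. Within-tissue
comparisons (`splitGenes()`, `ksPermutationTest()`,
`subsampleRobustness()`, `exportGroupHistogram()`) export histogram data
for distribution panels; bins never feed the statistics.
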