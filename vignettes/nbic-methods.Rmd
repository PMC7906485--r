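---
title: "Exhaustive N-way biclustering of loading matrices: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive N-way biclustering of loading matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NBiC)
```

## The problem

Source-based morphometry decomposes a set of gray-matter maps by ICA into
spatial components and a subjects × components *loading matrix*: each entry
says how strongly one subject expresses one spatial pattern. Clinically
heterogeneous disorders such as schizophrenia motivate searching that matrix
for *biclusters* — subgroups of subjects that are homogeneously expressed
across subgroups of features — rather than clustering subjects over all
features at once. Symptom-scale scores (e.g. the three PANSS summary scores)
can be appended as extra feature columns, so that a bicluster may mix
imaging components and symptoms; biclusters whose feature set contains all
symptom columns are labelled SYMBiCs.

This package implements that search as a deterministic, exhaustive
procedure over feature subsets, plus the surrounding apparatus: column
sorting rules, overlap-based validation, stability frequencies, coherence
and recovery metrics, seeded synthetic fixtures with planted biclusters,
and a bicluster–symptom correlation stage.

## The procedure

1. **Sorting.** Each feature column is reduced to a *sorted component*
   (SCOMP): the subset of subjects whose loading on that feature is extreme
   under one of four mean-based rules (`sortComponent()`):
   method 1 keeps loadings beyond the positive-entry mean or beyond the
   negative-entry mean; method 2 keeps the upper quartile of the positive
   loadings and the lower quartile of the negative ones; method 3 keeps
   |loading| ≥ |column mean|; method 4 keeps loadings ≥ the column mean
   when that mean is nonnegative, and loadings < the mean otherwise.
   Method 4 is the default.

2. **Search.** Every feature subset with at least `K` members is enumerated
   by depth-first prefix extension; the subject sets of its SCOMPs are
   intersected exactly; intersections with at least `N` subjects become
   candidate biclusters. Because set intersection is order-independent, the
   *set* of candidates is identical for every feature ordering — the
   package therefore enumerates candidates once (with pruning: a prefix
   whose intersection is already below `N` cannot produce a qualifying
   superset) and replays them per permutation in that permutation's
   depth-first discovery order.

3. **Validation.** Within one permutation, a candidate is kept only if its
   dice (F1) similarity to every previously kept candidate stays below
   `fTH1 = O/100`; the F1 between two biclusters counts shared matrix
   cells, which factorises as (shared subjects) × (shared features).
   Across permutations, each temporary list folds into the final list:
   a bicluster whose best F1 against the final list reaches
   `fTH2 = OE/100` increments that incumbent's frequency (the incumbent's
   membership is kept; earliest entry wins ties), otherwise it is appended
   with frequency 1. The final stability filter keeps biclusters with
   frequency ≥ `minFrequency`.

The frequency semantics follow the merge rule literally: every accepted
temporary bicluster either increments exactly one incumbent or is appended,
so the final frequencies always sum to the number of accepted temporary
biclusters, and the final list is pairwise below `fTH2` by induction on
insertions. A per-permutation cap on increments was considered and
rejected: in the rare non-transitive case (two mutually dissimilar
biclusters both similar to one incumbent) any cap must either drop a
temporary bicluster or append an `fTH2`-similar one, breaking one of those
two invariants.

## Parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `N` | minimum subjects per bicluster | 35 | small enough to find subgroups, large enough for stable post-hoc correlations |
| `K` | minimum features per bicluster | 3 | pairs (K = 2) produce many weakly informative biclusters |
| `O` | allowed overlap % within a permutation | 35 | `fTH1 = O/100` is the minimum threshold implied by the size gates |
| `OE` | allowed overlap % across permutations | `O` | separate cross-permutation control when desired |
| `M` | sorting rule | 4 | recovers planted blocks exactly on the 40 × 10 fixture |
| `permutations` | feature-order budget | 720 | all m! orders are replayed when m ≤ 6; above that a seeded uniform sample, headed by the identity order |
| `minFrequency` | stability filter | 2 | a bicluster seen under a single ordering is not "stable" |
| `zscore` | z-score columns before sorting | auto | on when symptom columns are present: the sorting rules compare to column means, which are scale-dependent, and questionnaire scores live on a different scale from ICA loadings |

The full factorial of feature orders is infeasible beyond m ≈ 6 (10! ≈ 3.6
million). Because candidates are memoized, permutations differ only in the
local-validation order and in which incumbent enters the final list first —
exactly the order sensitivity the permutation step is meant to average out —
so a few hundred sampled orders suffice to stabilise frequencies; the
sampling is uniform without replacement and fully determined by `seed`.

## Synthetic data

`generateBaseMatrix()` draws each column from a normal distribution with a
per-column mean sampled uniformly in (0, 0.3) and SD 0.3, clipped to
[−1, 1] — bounded, column-shifted values resembling ICA loadings, with
roughly a quarter to a half of entries negative. Truncation is by clipping
rather than rejection, which leaves small point masses at ±1 that are
irrelevant at these parameter values.

`embedBiclusters()` plants a bicluster by redrawing its cells uniformly in
[0.8, 1.0], then runs one repair pass: any planted cell below the
post-embedding positive-entry mean of its column plus a 0.05 margin is
redrawn in [mean + 0.05, 1], and the guarantee is re-verified afterwards
(the verification uses the post-embedding mean, the stricter reading).
One pass suffices because planted cells near 1 dominate the positive mean.
The nonnegative background column means are load-bearing here: the
guarantee that planted cells pass the mean-based selection rules is only
achievable when the planted column's overall mean stays nonnegative —
under a negative mean the positive-or-negative rule selects extreme
*negatives*, and no raised cell can qualify. Since only planted cells may
be modified, the generator default keeps background column means
nonnegative; both the mean range and the SD are arguments.

Two fixed designs ship with the package: a 400 × 10 matrix with four
planted blocks of 38, 35, 37 and 40 subjects over three components each
(blocks share some subjects and components), and a 40 × 10 matrix with
three disjoint 13-subject blocks over disjoint component triples.
`generateSymptomCoupled()` appends symptom columns: each score is a scaled
block-membership indicator plus Gaussian noise with population correlation
≈ `coupling`, mapped to a 7–49 questionnaire-like range (continuous, not
integer-rounded; the rounding error is negligible against the noise SD).

What these fixtures do *not* emulate: site effects, loading correlations
between components (columns are independent), heavy tails, missing scores,
and diagnosis structure. Passing recovery tests therefore demonstrates the
search mechanics, not robustness to real multi-site MRI data.

## Evaluation metrics

`msr()` is the classical mean square residue — the mean squared additive
residual `a_ij − rowmean_i − colmean_j + grandmean` — zero for constant or
additive submatrices, invariant to row/column constant shifts.

`consensusScore()` compares two bicluster sets: it builds the pairwise F1
matrix, solves the maximum-weight one-to-one assignment (via bipartite
matching), and divides by the larger set's cardinality, so it is 1 exactly
for identical sets and penalises both missed and surplus biclusters. An
optional variant (`mergeSensitivity`) first unions estimated biclusters
that are cell-sensitive to the same reference bicluster into a combined
set; the merge threshold has no canonical value, so the variant is off by
default.

A caveat worth stating plainly: because the score divides by the larger
set's size, a sorting rule that extracts few, clean biclusters can outscore
a rule that recovers every planted block but also reports many candidate
subgroups. On the 400 × 10 fixture the mean-threshold rules keep ~40–50% of
subjects per column, so at N = 35 many feature triples meet the subject
gate by chance and the final list holds dozens of mutually dissimilar
biclusters; the quartile rule keeps ~25% and extracts only the planted
blocks, attaining the highest consensus score in every probed seed. The
acceptance suite records this as a failing expectation rather than
adjusting the metric or the fixture.

## Numerical and degenerate-input choices

* Quartiles use the linear-interpolation definition (`quantile` type 7);
  zero loadings belong to neither sign subsample in methods 1–2.
* An all-zero column selects every subject under methods 3–4 (|mean| = 0
  with closed inequalities) and none under methods 1–2.
* Boundary similarities use ≥: a candidate exactly at `fTH1`/`fTH2` counts
  as "too similar" (the thresholds are minima).
* Ties in the global update resolve to the earliest final-list entry; the
  stability filter orders by frequency, then size, then insertion —
  everything is deterministic given the seed.
* The depth-first order of a candidate under a permutation is the
  lexicographic order of its sorted position sequence, encoded as a
  base-(m+2) fraction for a single numeric sort (exact for m ≤ 14; string
  keys beyond).
* Association rows with fewer than 3 usable subjects or zero variance are
  flagged not-computable rather than returning NaN; FDR adjustment is
  Benjamini–Hochberg, per symptom by default (`fdrFamily = "global"`
  pools all tests).
* The bicluster–symptom correlate is the subject-wise mean loading over the
  bicluster's imaging features, correlated within the bicluster's subjects
  by default. `allSubjects = TRUE` correlates over the whole cohort
  instead, which is the reading with power against membership-coupled
  scores — within a bicluster its own membership indicator is constant, so
  indicator-coupled signals are invisible to the within-subgroup reading.

## Problem sizes used by the shipped checks

The test suite replays the two fixed designs at their native sizes
(400 × 10 and 40 × 10), with 200 sampled permutations over 20 seeds for the
recovery check, 120 permutations over 10 seeds for the sorting-rule
comparison, and 100 seeded null runs for the association false-positive
control; brute-force oracles (power-set enumeration, cell-level dice,
exhaustive assignment) run at m ≤ 5, 15 subjects × 8 features, and set
sizes ≤ 4, where exhaustion is exact.

## Known limitations

* Exhaustive subset enumeration is exponential in the feature count; the
  method is meant for a curated set of components (m ≈ 10–30 with pruning),
  not whole decompositions at large m with permissive size gates.
* The stability filter is a frequency heuristic; no null model for
  bicluster existence is provided, and significance claims attach only to
  the symptom correlations, not to the biclusters themselves.
* Merging keeps the incumbent's membership, so the reported subject set of
  a frequently rediscovered bicluster is the first-discovered variant.
* Real loading matrices should be complete: missing values are rejected,
  not imputed.
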