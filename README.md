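# NBiC

Exhaustive N-way biclustering of subject-by-feature loading matrices.

## What problem this solves

Source-based morphometry (ICA of gray-matter maps) summarises a structural
MRI cohort as a subjects × components **loading matrix** `L`: entry
`L[i, j]` is how strongly subject *i* expresses spatial component *j*.
Heterogeneous disorders such as schizophrenia motivate looking for
**biclusters** — subgroups of subjects homogeneously expressed across
subgroups of features — instead of clustering subjects over all features at
once. Symptom-scale scores (e.g. PANSS positive/negative/general) can be
appended as extra columns so a bicluster may mix imaging components and
symptoms; a bicluster containing all symptom columns is a **SYMBiC**.

The package is for researchers holding such a loading matrix (the ICA step
is upstream and out of scope) who want a deterministic, exhaustive,
parameter-transparent subtyping search with built-in evaluation.

## The method

For each feature column a *sorted component* (SCOMP) is extracted — the
subjects whose loading is extreme under one of four mean-based rules (the
default keeps `x ≥ mean(x)` when the column mean is nonnegative, else
`x < mean(x)`). Every feature subset with `|F| ≥ K` is enumerated
depth-first; the exact intersection of its SCOMPs with `|S| ≥ N` subjects
becomes a candidate bicluster. Candidates are de-duplicated with the dice
(F1) index over matrix cells,

    F1(A, B) = 2 |A ∩ B| / (|A| + |B|),   |A ∩ B| = S_shared × F_shared,

within a feature ordering at threshold `fTH1 = O/100` and across orderings
at `fTH2 = OE/100`; re-discoveries across orderings accumulate a stability
frequency, and the final report keeps biclusters with frequency ≥
`minFrequency`. Evaluation helpers include the mean square residue (MSR,
coherence), an assignment-based consensus score between bicluster sets,
per-truth recovery reports, seeded generators with planted biclusters, and
a bicluster–symptom Pearson correlation stage with Benjamini–Hochberg FDR
control (`|r| ≥ 0.4`, adjusted `p ≤ 0.05` by default).

## Worked example

The packaged 40 × 10 demonstration fixture plants three disjoint 13-subject
biclusters; the search recovers them:

```r
library(NBiC)
fx  <- sim2Fixture(seed = 1)
res <- runNBiC(fx$matrix, NBicParam(N = 11, K = 3, O = 35,
                                    permutations = 200, seed = 1))
res
#> BiclusterSet of 3 biclusters
#>  id features nSubjects nFeatures size frequency
#>   1 C1,C3,C8        14         3   42       200
#>   2 C2,C4,C5        14         3   42       200
#>   3 C6,C7,C9        13         3   39       200

recoveryReport(res, fx$truth)
#>   truth   bestF1 match
#> 1     1 0.962963     1
#> 2     2 0.962963     2
#> 3     3 1.000000     3

consensusScore(res, fx$truth)
#> [1] 0.9753086

msr(biclusterValues(fx$matrix, res[[2]]))
#> [1] 0.001981637
```

Each reported bicluster names its feature columns and subject count and was
rediscovered in all 200 feature orderings (`frequency`). The recovery table
gives, per planted block, the best dice similarity achieved by any reported
bicluster — two blocks are matched up to one extra intersecting subject
(F1 = 0.96), one exactly. The consensus score condenses the whole
comparison to 0.98 (1 means identical sets), and the near-zero mean square
residue says the recovered submatrix is internally coherent.

From a shell, the same run is:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/nbic.R", package = "NBiC"))')" \
    --demo sim2 --permutations 200 --seed 1 --out out/
```

which writes `biclusters.tsv`, `biclusters.json` (full membership),
`run.log`, and — when symptom scores are supplied via `--symptoms` or
symptom columns are flagged with `--symptom-cols` — `associations.tsv`
mirroring the per-symptom r / p / adjusted-p layout.

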