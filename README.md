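# groupRF

Group-level Random Forests importance scores with permutation-based
statistical calibration, for settings where features come in predefined
disjoint groups — the motivating case being voxel-level brain images (e.g.
FDG-PET) whose voxels are grouped into anatomical atlas regions, and where
the question is *which regions* carry information about a binary clinical
outcome, not which individual voxels.

## The problem

Random Forests handle p ≫ n data well and provide per-feature importance
scores, but those scores have no absolute scale: a threshold separating
"relevant" from "irrelevant" groups cannot be read off the ranking itself.
groupRF implements a group-importance pipeline plus four permutation
procedures that convert ranks into interpretable error estimates.

**Importance.** Each tree T contributes, for feature x_i,

    I(x_i, T) = Σ_{nodes N split on x_i} (n(N) / n) · ΔI(N),

with Gini impurity I(N) = 1 − p₀² − p₁² and
ΔI(N) = I(N) − (n_l/n_N) I(N_l) − (n_r/n_N) I(N_r).
The forest score is the unweighted mean over trees (not normalised). Group
scores are the sum, average or maximum of member-feature scores
(`I_sum`, `I_avg`, `I_max`); groups are ranked by descending score.

**Statistical scores.** With s_1 ≥ … ≥ s_G the observed group scores in rank
order, and P permutation repetitions in which the groups ranked i..G are made
irrelevant by one shared row permutation and the forest refitted:

* **CER_i = P( max_{k=i..G} s_k^p ≥ s_i )** — conditional error rate, an
  FWER estimate at rank i;
* **CER^r_i** — fraction of repetitions in which the rank-i group keeps a
  rank ≤ i among all permuted scores;
* **eFDR_i = E[ V_i / (V_i + i − 1) ]** — permutation FDR estimate, where
  V_i is the largest m such that the m best permuted tail scores dominate
  s_i..s_{i+m−1} element-wise (0/0 := 0);
* **mProbes** — fraction of repetitions in which any shuffled "probe" copy
  of a group outranks the real group after refitting on the augmented matrix.

Selection takes the longest prefix of ranks with score < α (default
α = 0.05, `first_crossing`; a `max_rank` variant is available). Evaluation
stops at the first rank at or above α unless a full curve is requested.

## Worked example

```r
library(groupRF)

b <- syntheticBenchmark(n = 100, p = 120, g = 12, nRelevant = 3, seed = 7)
b
#> SyntheticBenchmark: n = 100 , p = 120 , g = 12 , relevant groups: G6, G8, G12
#> 1 label(s) flipped

tab <- runRank(b@x, b@y, b@partition, aggregation = "avg", trees = 300, seed = 7)
head(as.data.frame(tab), 5)
#>   group_id size       score rank aggregation
#> 1       G8    5 0.030692924    1         avg
#> 2       G1    8 0.005193364    2         avg
#> 3       G2    7 0.004311119    3         avg
#> 4       G9    2 0.003796396    4         avg
#> 5      G12   17 0.003389912    5         avg

res <- groupSelect(b@x, b@y, b@partition, methods = "cer", nPerm = 100,
                   trees = 300, seed = 7)
res
#> SelectionResult [cer], alpha = 0.05, rule = first_crossing
#> selected 1 group(s): G8
#> ranks evaluated: 2 of 12

sort(b@relevantGroups)
#> [1] "G12" "G6"  "G8"

assessSelection(selectedGroups(res), groupRanking(res@table), b@relevantGroups)
#>   precision    recall      aupr      rec1 prec1 n_selected n_relevant_selected
#> 1         1 0.3333333 0.5916667 0.3333333   0.5          1                   1
```

The conservative behaviour is by design: CER controls the family-wise error,
so with n = 100 samples it selects only the strongest group and makes no
false discovery (precision 1).

For imaging data, build the partition from a NIfTI atlas and mask with
`partitionFromAtlas("atlas.nii.gz", "mask.nii.gz")`; the feature order is the
column-major (first-axis-fastest) order of in-mask voxels and must match the
data matrix. A command-line front end with `generate` / `rank` / `select` /
`evaluate` / `benchmark` subcommands is installed at
`system.file("scripts", "grouprf", package = "groupRF")`.

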