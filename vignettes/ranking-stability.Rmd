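---
title: "Feature-ranking stability and predictive power in case-control risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-ranking stability and predictive power in case-control risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankstab)
```

## The problem

In epidemiological risk prediction — here, breast-cancer risk from
environmental exposures, SNP genotypes and clinical covariates — the signal
is weak: even with every feature, cross-validated AUC values sit around
0.55–0.62. In this regime two questions must be answered *together*:

1. **Which features does a ranking algorithm call relevant?** A ranking
   `r` assigns each of the `p` features a rank in `1..p` (1 = most
   relevant); a top-k *selection* `s` keeps the k best-ranked ones.
2. **Can that answer be trusted?** If rerunning the ranker on a slightly
   perturbed sample reshuffles the list, the "most relevant features" are
   an artifact of the sample, not of the disease.

`rankstab` implements both halves: six rankers of three families (filter:
ReliefF, point-biserial Pearson; wrapper: AUC-guided backward elimination
around a linear SVM or logistic regression; embedded: SVM-RFE, random
forest), a K-run subsampling protocol, stability metrics, and
cross-validated AUC evaluation over nested top-k subsets for five
classifier families.

## The stability model

The ranker is run `K` times (default 7), each time on a random 70% row
subsample. The K rankings form a `p × K` rank matrix `A`. Stability is the
averaged pairwise similarity

$$S(A) = \frac{2}{K(K-1)} \sum_{i<j} SM(r_i, r_j),$$

with `SM` one of:

* **Spearman rank correlation** on full rankings,
  $SR(r,r') = 1 - 6\sum_i (r_i - r'_i)^2 / \{p(p^2-1)\}$ — 1 for identical
  lists, −1 for exact reversals;
* **Jaccard index** on top-k selections, $|s \wedge s'| / |s \vee s'|$,
  tabulated over a grid of k (default decades plus `p`) and summarised by
  the grand mean over all `k = 1..p`. At `k = p` the index is identically
  1 — a useful boundary check that the whole protocol preserves.

We deliberately implement the Jaccard index as intersection-over-union:
the common verbal description "features appearing in only one list" would
define a *distance*, and it contradicts the boundary value of 1 at
`k = p` that the index must produce.

For a view beyond a single scalar, all rankings from all rankers are
embedded in the plane by metric MDS on the dissimilarity
`d = 1 − SR` (range `[0, 2]`). We fit by SMACOF stress majorization with
normalized stress $\sum_{i<j}(d_{ij}-\hat d_{ij})^2 / \sum_{i<j} d_{ij}^2$,
4 seeded random restarts, convergence at a relative stress change below
1e-6 or 300 iterations. Stress is non-increasing across Guttman updates by
construction. Two numerical corner cases are handled explicitly: exactly
duplicated rankings are initialised at the same position (their updates
then coincide forever, so they remain exactly collapsed), and an
all-identical input collapses to a single point with stress 0, flagged
`degenerate` rather than failed.

## The rankers and their knobs

| ranker | score | key defaults |
|---|---|---|
| `rank_pearson` | absolute point-biserial correlation with the 0/1 label | zero-variance features score 0 |
| `rank_relief` | ReliefF weight (nearest hits vs misses) | `n_neighbors = 10`, all instances as anchors |
| `rank_svm_rfe` | reverse elimination order by squared SVM weight | linear kernel, `C = 1`, `step = 1` |
| `rank_rf` | mean Gini impurity decrease | 500 trees, seeded |
| `rank_wrapper` | reverse elimination order by cross-validated AUC | backward, 7 folds, `max_fits` budget |

Conventions shared by all rankers: rank 1 is best; ties break by ascending
feature position (deterministic and order-stable); every output is a
permutation of `1..p` (asserted in tests). Pearson and SVM-RFE standardize
internally, so they are invariant to affine rescaling of any feature.
Column-order invariance holds exactly for the deterministic rankers
(Pearson, ReliefF, SVM-RFE); for the random forest it holds only in
distribution, because the per-split feature subsampling consumes RNG by
column position.

ReliefF uses a range-normalized Manhattan distance over all features. For
0/1 features this is exactly the 0/1 mismatch contribution; genotypes
enter on the additive 0/1/2 scale, which treats a heterozygote as halfway
between the homozygotes — the standard additive-coding view.

SVM-RFE's `step` may be a count or a fraction of the surviving set.
One-at-a-time elimination (`step = 1`) is the default; protocol-scale runs
in this package (K = 7 on 1305 × 124 subsamples) use `step = 0.5`, the
halving schedule long recommended for wide tables, which cuts the cost per
run from `p` SVM fits to about `log2(p)` while preserving the batch-level
ordering (features removed together are ranked by their within-batch
importance).

The wrapper's exhaustive greedy search costs `O(p²)` cross-validated
fits. A `max_fits` budget (default 5000 fold-level fits) caps this;
beyond it the elimination continues on the smallest absolute coefficient
of one fit per round, and the result is flagged. This mirrors how such
wrappers are run in practice on wide tables, and the instability the
protocol reveals for wrappers is visible either way.

Aggregation across the K runs uses the per-feature **mean** rank by
default; the menopausal-partition reports use the **median**, which
resists the extreme rank excursions single unstable runs produce. The raw
aggregate is exposed as the "median rank position" column of the partition
reports.

## Predictive power

`crossval_auc` estimates AUC by stratified 7-fold cross-validation
(stratification keeps the case/control ratio of every fold within one
sample; the protocol description leaves the fold scheme open and
stratification is the standard choice at this class balance). All
preprocessing is fitted on the training folds only — including the
z-scoring used by the logistic, kNN, SVM and MLP classifiers — so no
information from held-out rows reaches the model. A canary test plants a
feature that equals the label on one fold's rows only and checks that the
pipeline cannot exploit it. Tree-based boosting skips standardization
(scale-invariant).

Classifier defaults: logistic regression with ridge penalty `C = 1`
(`lambda = 1/(C·n)`, cap 1000 iterations; `glmnet`, plain `glm` for a
single feature), kNN with `k = 21` on standardized inputs, RBF-kernel SVM
(`C = 1`, kernel width `1/(p · pooled variance)`, SMO training via
libsvm), AdaBoost-SAMME over depth-1 stumps (learning rate 1, up to 500
estimators — for two classes SAMME reduces to discrete AdaBoost), and a
single-hidden-layer perceptron with 200 logistic-sigmoid units and an
iteration cap of 5000. The MLP is trained by `nnet`'s BFGS optimizer — the
architecture follows the study configuration, while the optimizer is the
one the installed single-hidden-layer implementation provides.

`performance_vs_cardinality` traces AUC over nested top-k subsets of one
aggregated ranking under identical fold seeds, so the `k = p` point equals
the full-set baseline bit for bit. The ranking is computed once on the
full table (matching the aggregate-then-evaluate protocol); because the
same rows inform both the ranking and the CV folds, top-k points carry a
selection-bias optimism — an acknowledged property of this design, which
is why the package also reports the stability side.

## The synthetic cohort

No cohort data are distributable, so `generate_dataset` emulates the
*structure* the analysis needs: 1865 individuals (946 controls, 919
cases), 124 features — 50 environmental exposures drawn from equicorrelated
Gaussian blocks of 10 (within-block correlation 0.3, then standardized),
64 SNPs in Hardy-Weinberg proportions with minor-allele frequency uniform
on (0.05, 0.5), and 10 mixed covariates (age, a menopausal indicator,
family history, ...). Disease follows a weak logistic model
`logit P(case|x) = β0 + Σ βj xj` (continuous features z-scored, genotypes
per allele count); a pool of 20× the target size is simulated and exact
case/control margins are then subsampled, since a logistic model cannot
hit margins directly. The menopausal indicator is assigned exactly within
each class stratum — to the oldest individuals, inducing a realistic
age–menopause dependence — so the pre/post partitions (1233 = 569 + 664
and 632 = 350 + 282, each with 123 features after the indicator is
removed) are deterministic fixtures.

The default effect sizes (eight small effects spread over the three
blocks) were calibrated once, by simulation, to land the full-set
logistic CV AUC near 0.58–0.62 — inside the weak-signal regime the method
is designed for — and verified to give AUC ≈ 0.50 with all effects
zeroed. The parameter-recovery scenario (`planted_config`) plants five
effects of 1.0 log-odds per standard deviation on unit-variance carriers
(four environmental features in distinct correlation blocks, plus age).
Unit-variance carriers are the right benchmark substrate: a per-allele
effect on a genotype gives a marginal effect size that depends on the
randomly drawn allele frequency, and impurity-based forest importance is
additionally biased against low-cardinality, low-variance predictors —
a recovery check should control the marginal signal it asks rankers to
find, not confound it with carrier encoding.

What the generator does *not* model: real dietary distributions, linkage
disequilibrium between SNPs, gene–environment interaction. Passing tests
therefore demonstrate that the machinery is correct and calibrated on
data with this covariance and signal structure, not that any particular
ranking of real risk factors is right.

## Seeds and determinism

All randomness flows from one master seed through
`derive_seed(master, stage, index)` — a deterministic hash of the stage
label combined linearly with the seed and run index, reduced modulo
2³¹ − 1. Run j of a protocol uses `derive_seed(seed, "protocol_<method>",
j)`; `run_study` derives one sub-seed per stage. Identical configs and
seeds reproduce every output byte for byte (tested), and the run manifest
records the derived seeds and per-file checksums.

## Problem sizes used in the tests

Cohort-scale checks (planted-feature recovery, null calibration, the
pruning effect) run at the full synthetic geometry — M = 1865, p = 124,
K = 7, 7 folds — over 5–10 master seeds, with SVM-RFE on the halving
schedule. Unit and property tests use reduced geometries (M = 60–500,
p = 3–30, K = 2–3) chosen so each property is still informative: e.g.
wrapper instability needs p > 10, ReliefF's brute-force oracle needs
M = 4 for exhaustive neighbour enumeration. The end-to-end `run_study`
test uses M = 180, p = 26, K = 3 with two rankers and two classifiers.

## Known limitations

* The wrapper rankers are exact only up to their fit budget; beyond it
  the coefficient-based fallback is a different (cheaper) search.
* Aggregation operates on ranks, not on raw scores; rankers whose scores
  carry calibrated meaning lose that information (by design — rank
  aggregation is what the protocol specifies).
* The MDS embedding is a local optimum of a non-convex stress; restarts
  mitigate but do not eliminate this.
* AUC curves reuse the full-table ranking (selection bias noted above);
  a fully nested per-fold re-ranking is a straightforward extension.
* The Jaccard curve's grand mean is computed over all `k = 1..p`, which
  weights small and large cardinalities equally.
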