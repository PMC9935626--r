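---
title: "Joint and individual variation for cross-cohort translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint and individual variation for cross-cohort translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jdr)
```

## The problem

Cell lines and mouse models are indispensable in cancer genomics, but part
of their expression variation is specific to the model system: culture
artifacts, missing microenvironment, species differences. A drug-response
model trained naively on model-system expression can load on exactly that
cohort-specific variation and fail on patients. `jdr` addresses this by
horizontally integrating two expression cohorts across their shared gene
axis and splitting each cohort's variation into a *joint* part (structure
shared with the partner cohort), an *individual* part (structure specific
to that cohort), and *residual* noise:

$$X_k = J_k + I_k + E_k, \qquad k \in \{A, B\}.$$

Models and biomarkers built on $J$ use only variation that demonstrably
exists in both cohorts, which is the variation one can hope to translate.

## The decomposition

Both blocks are samples × genes, upper-quartile normalized, log2
transformed, restricted to a common gene list and gene-mean-centered
(`upper_quartile_log_normalize()`, `intersect_and_align()`,
`mean_center_genes()`; mouse symbols are first mapped to human homologs
with `parse_homolog_map()` / `apply_homolog_map()`).

1. **Initial truncated SVD.** Each block is reduced to rank $r_k$:
   $X_k \approx U_k D_k V_k^\top$. The columns of $V_k$ are metagenes over
   the shared gene axis. $r_k$ caps how much structure can enter the
   comparison; everything beyond it is treated as noise.
2. **Principal-angle analysis.** The metagene matrices are stacked,
   $M = [V_1^\top; V_2^\top]$, and $M = U_M D_M V_M^\top$. Each singular
   value $\sigma_{M,i}$ gives a principal angle between the two metagene
   subspaces, $\phi_i = \arccos(\sigma_{M,i}^2 - 1)$ (arguments clamped to
   $[-1, 1]$; angles reported in degrees, ascending).
3. **Joint rank.** An angle is called joint when it is smaller than random
   subspaces of the same dimensions typically achieve:
   `random_angle_cutoff()` draws pairs of uniformly random subspaces,
   records each pair's smallest principal angle, and returns the 5th
   percentile of that distribution (1000 draws by default; both the
   percentile and the number of draws are configurable, and a cutoff
   computed externally — e.g. a Wedin-bound refinement — can be injected
   through `ajive_config(angle_cutoff=)`).
4. **Reprojection.** The joint gene-space basis $W$ is the top
   joint-rank right singular vectors of $M$ (they live in gene space),
   re-orthonormalized. With $P_J = W W^\top$:
   $J_k = X_k P_J$, $I_k = \hat X_k (\mathrm{Id} - P_J)$ with $\hat X_k$
   the rank-$r_k$ approximation, and $E_k = X_k - J_k - I_k$.

This construction makes the three components exactly Frobenius-orthogonal
($P_J(\mathrm{Id}-P_J) = 0$ and the truncated-SVD residual is orthogonal to
$\hat X_k$), so $\|X\|^2 = \|J\|^2 + \|I\|^2 + \|E\|^2$ holds to machine
precision — the conservation property the test suite asserts. Whether the
stacked joint projections should be re-decomposed once more before
reprojection is a genuinely open design point among JIVE variants; the
direct projector construction was chosen for its exact additivity.

Only two blocks are supported: every analysis this workflow targets is
pairwise, and angle thresholds for more blocks would need new calibration.
Singular-vector signs follow a fixed convention (largest-magnitude entry
positive), making results bit-reproducible; the random-angle draw orders
the two ranks internally so that swapping the block order changes nothing.

## Choosing the initial rank

`half_split_curve()` implements a self-splitting bootstrap: the block's
samples are divided into two random halves, the halves are integrated with
each other at each candidate rank, and the percent of pooled sum of squares
labelled joint and individual is recorded over (by default) 10 repetitions.
Genuine signal directions recur in both halves and register as joint;
ranks past the signal add half-specific noise directions that register as
individual. `select_rank()` takes the rank maximizing
mean(% joint) − mean(% individual), smaller rank on ties — a deliberate
sharpening of the qualitative "maximize joint while minimizing individual"
rule; the full curve is returned so an elbow can be picked by eye instead.
Percentages are pooled across the two halves by total sum of squares
(averaging per half first differs only in the third decimal on the scales
tested, but pooling is the variant with an exact conservation identity).

## Per-sample and per-gene summaries

`sample_variation_profile()` reports, per sample, the percent of its sum of
squares in $J$ and $I$; residual percent is defined as everything not
explained by joint or individual structure, i.e. the remainder to 100.
The joint/individual ratio ranks how well each sample is represented by
the partner cohort. `gene_set_partition()` sums per-gene variances of a
signature inside $O$, $J$ and $I$ to show where a signature's variation
lives (population variances, denominator $n$).

The per-gene **joint statistic** is
$\log\left(\max(\sigma^2_{J,g}, s) / \max(\sigma^2_{I,g}, s)\right)$
(natural log; the base only rescales thresholds). The floor $s$ (default
0.5, chosen for log2 expression scales) zeroes the statistic for genes with
negligible variance on both sides; a `strict_floor` mode zeroes it whenever
*either* variance is at the floor, for users who read the rule that way.
Significance uses a permutation null: per iteration the joint and
individual rows are pooled and re-split (one shared row permutation of the
stacked matrix per iteration — the SAM convention, preserving gene-gene
correlation; each gene's marginal null is the same as for independent
shuffles). Two-tailed p-values carry +1 smoothing. FDR cutoffs are
SAM-style: median permutation count beyond the cutoff over observed count
beyond it, computed independently per tail because the statistic is signed
and each cohort gets its own thresholds. A gene significant in both blocks
is *fully joint* (translatable); in one, *unidirectionally* joint; in
neither, not joint (`classify_translatability()`).

## Translation models

`fit_elastic_net_response()` reproduces the modeling protocol:
penalty-strength values from the elastic-net path at each mixing ratio
(0.1, 0.5, 0.7, 0.9, 0.95, 1 by default, 100 values each, computed per
ratio since paths differ across ratios), exhaustive grid search over 20
random 67/33 train/test iterations (optionally stratified, e.g. by tissue),
winner by best mean held-out $R^2$, ties toward the stronger penalty, final
refit on all samples. The classifier variant swaps in a binomial likelihood
and scores held-out ROC-AUC, since $R^2$ is undefined for classification.
`predict_and_roc()` applies a model to an external cohort and computes the
ROC by threshold sweep; tied scores collapse to one operating point so the
trapezoid AUC equals the Mann–Whitney statistic with ties counted ½.
`bootstrap_auc_comparison()` compares two models by resampling the
evaluation cohort; exact zero AUC differences count one half, so identical
models give p = 0.5. Signature utilities (`signature_score()`,
`compare_signature_groups()`, `drug_response_correlation()`) cover
median-expression scoring, pooled t-tests (Welch behind a flag) and
tie-corrected Spearman associations; repeated response measurements per
sample collapse by median by default (mean available — both conventions
appear in practice).

## What the generator emulates

`simulate_joint_blocks()` plants the structure the decomposition assumes:
a shared orthonormal gene-space basis carrying i.i.d. normal scores in both
blocks, block-specific bases with disjoint gene support (hence exactly
orthogonal), isotropic Gaussian noise, and gene classes (defaults: 10%
joint, 10% per-block individual, rest null). It works on the
post-normalization log scale; it does **not** emulate count-level noise,
library-size effects, correlated gene modules within the null set, or
batch structure — so green tests show the machinery is correct and
calibrated under its own model, not that any particular real pairing will
decompose cleanly. `simulate_response()` makes outcomes linear in joint
metagene scores (logistic transform for binary labels).
`simulate_translation_scenario()` additionally correlates a training-block
individual direction with the response and anti-correlates it in an
external cohort — the adversarial situation in which training on $O$ is
misled by cohort-specific variation while training on $J$ transfers.

**Signal-to-noise convention.** Where test conditions say SNR, the package
means the spiked-model ratio of the leading signal singular value to the
noise operator norm: $\mathrm{SNR} = \sigma_{\text{sig}}\sqrt{n} /
(\sigma_{\text{noise}}(\sqrt{n} + \sqrt{g}))$. This is the scale on which
subspace recovery is well-posed; at SNR 4 the planted joint basis is
recovered to within a few degrees. Joint-statistic simulations use a larger
score scale (signal sd 30 at 2000 genes) because the statistic's floor
$s = 0.5$ is absolute: per-gene signal variances
($\approx$ signal\_sd$^2 \cdot$ rank / class size) must clear the floor,
which a chi-square tail bound guarantees at that scale.

## Numerical choices and test scales

- All arccos arguments clamped to $[-1, 1]$; angles in degrees.
- Population variances (denominator $n$) throughout the statistic; the
  choice cancels in the ratio except in the floored regime.
- Requested SVD ranks above the numerical rank warn and truncate.
- Rank-selection ties break toward the smaller rank; hyperparameter ties
  toward the stronger penalty; homolog collisions keep the higher-variance
  gene; one-to-many homologs keep the first human symbol in file order.
- The unexpressed-gene filter defaults to the strictest reading (drop a
  gene all-zero in any one block); the lenient reading and no filtering are
  flags.
- Validation problem sizes: rank recovery at 80 samples × 150 genes (50
  replicates per planted rank), rank selection at 200 × 100 (20
  replicates), statistic calibration/power at 100 × 2000 with 1000
  permutations, translation modeling at 100 × 200 with a 150-sample
  external cohort (25 replicates). These sizes were chosen so each property
  is measured with comfortable sampling margin while the whole suite stays
  quick on a laptop.

## Known limitations

- Two blocks only; no nonlinear (kernel) integration.
- The angle cutoff uses the random-subspace percentile rule, not the Wedin
  bound (injectable externally).
- Permutation FDR estimates are noisy at small permutation counts; the
  median-count SAM form is used (the mean-count variant of the same
  estimator differs slightly).
- The generator's isotropic null is favourable to calibration; heavy gene-
  gene correlation in real nulls widens the statistic's null distribution,
  which the per-dataset FDR thresholds absorb only partly.
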