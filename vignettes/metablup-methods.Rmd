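---
title: "Partitioning and predicting phenotypes from host genomes and rumen metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning and predicting phenotypes from host genomes and rumen metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metablup)
```

## The model

`metablup` fits univariate animal models of the form

$$ y = X\beta + Zu + Wm + To + e $$

where $y$ is a feed-efficiency phenotype over $n$ animals, $X\beta$ collects
fixed effects (intercept, management group, breed fractions, expected
heterozygosity), and the random effects are distributed

$$ u \sim N(0, G_T\,\sigma^2_u), \quad m \sim N(0, M_T\,\sigma^2_m), \quad
   o \sim N(0, J_T\,\sigma^2_o), \quad e \sim N(0, I\,\sigma^2_e). $$

$G_T$, $M_T$, $J_T$ are *tuned* (ridge-stabilised) genomic, metagenomic and
interaction relationship matrices. Model complexities range from a single
random effect (genomic-only or metagenomic-only) through joint
(genomic + metagenomic) to interaction models; the interaction effect is
only ever fitted alongside both main effects. With two MRM construction
methods and three adjustments this gives 19 models per trait.

Reported ratios all share the same denominator, the sum of **all** variance
components in the model (including the residual): $h^2 = \sigma^2_u/\Sigma$,
$m^2 = \sigma^2_m/\Sigma$, $i_a^2 = (\sigma^2_u+\sigma^2_m)/\Sigma$,
$i_i^2 = (\sigma^2_u+\sigma^2_m+\sigma^2_o)/\Sigma$. Standard errors of
ratios use the first-order delta method on the inverse average-information
matrix.

## Kernels

**GRM.** VanRaden's first method: $G = (Q-P)(Q-P)'/(2\sum_i p_i(1-p_i))$
with $p_i$ the observed alternate-allele frequency and the columns of $P$
equal to $2p_i$. Because frequencies come from the data, rows of $G$ sum to
zero exactly — a property the tests assert to $10^{-10}$.

**Log relative abundance.** ORF read counts $R$ are transformed as
$S_{ij} = \log_{10}\!\big((R_{ij}+1)/\sum_j (R_{ij}+1)\big)$. The unit
pseudocount keeps zeros finite; the row normalisation absorbs uneven
sequencing depth, which the generator deliberately injects (log-normal
library sizes).

**MRMs.** Method 1 mirrors the GRM on the Gaussian scale:
$M_1 = (S-N)D(S-N)'/\sum_j \mathrm{var}(s_j)$. Method 2 standardises each
ORF column to $C$ and takes $M_2 = CDC'/m$. $D$ carries optional per-ORF
weights. Two conventions were left open by the construction and fixed here:

* **Variance convention.** `var(·)` is the sample ($n-1$) variance
  throughout. This makes $\mathrm{trace}(M_1) = \mathrm{trace}(M_2) = n-1$
  an exact, testable identity, and makes $M_1 = M_2$ exactly whenever all
  ORF variances are equal (both identities are in the test suite).
* **Weight clamping.** Weighted kernels use $1 - h^2_{ORF}$; estimates are
  clamped to $[0,1]$ first, so a failed or boundary per-ORF fit contributes
  weight 1 (i.e. no down-weighting) rather than an out-of-range value.

**Data-driven (multi-population) MRMs.** Animals are clustered on the first
4 principal components of $S$ with k-means (k = 2 by default, 25 restarts,
fixed seed — the cluster count is a configuration parameter here, not an
internally optimised quantity). Centring and scaling are then per cluster;
method-1 cross-cluster blocks are divided by the geometric mean of the two
clusters' variance sums, exactly as the block formula prints, with no
re-centring across clusters. A single cluster reduces both methods to their
single-population forms exactly (tested). Weighted × data-driven is
deliberately not offered: the design crosses each method with one
adjustment at a time, giving six MRMs.

**Interaction kernels.** $J = G \circ M$ (Hadamard), formed from *untuned*
factors — the function refuses tuned inputs — then tuned itself. The Schur
product theorem guarantees PSD inputs give a PSD product.

**Tuning.** Every kernel used in a model gets $+0.001\,I$ exactly once;
double tuning is an error, because the ridge is part of the model
definition, not a repeatable numerical patch.

## REML

Variance components maximise the restricted likelihood
$\ell_R = -\tfrac12[\log|V| + \log|X'V^{-1}X| + y'Py]$ by
average-information updates. Numerical choices that matter:

* **Boundary handling.** Components are constrained non-negative with an
  active-set/KKT scheme: a component whose gradient points outward at the
  boundary is pinned (kernel components at 0; the residual at a $10^{-8}
  \cdot \mathrm{var}(y)$ floor, where the tuned kernels keep $V$ positive
  definite) and released only when its gradient points inward with a
  non-trivial expected gain. Pinned components are flagged as boundary
  cases in the output.
* **EM fallback.** When the (clamped) AI step fails to increase the
  likelihood under step halving, an EM step — always an ascent direction —
  is tried before declaring a boundary optimum.
* **Multiple starts.** The restricted likelihood can be multimodal when
  several competing kernels explain few records, so each fit runs from an
  equal-split start plus one start skewed towards each component, keeping
  the best likelihood. On small two-kernel instances the resulting optimum
  matches a dense ratio grid plus direct optimiser to well below $10^{-4}$
  log-likelihood units (tested on 10 instances; stress-checked on 60).
* **Convergence.** Relative log-likelihood change below $10^{-8}$ and
  component changes below $10^{-6}$, *plus* a negligible expected Newton
  gain on the active set — the last condition guards against the slow-crawl
  false convergence EM steps exhibit near a boundary. Maximum 200
  iterations per start; non-convergence is reported, not raised, so
  cross-validation can omit those folds the way summaries expect.
* **AIC** is $-2\ell_R + 2\,(\text{number of variance components})$,
  boundary components included in the count. Absolute AIC values are
  convention-dependent (likelihood constant, boundary counting), so only
  orderings on the same data are meaningful; the tests assert the ordering
  is invariant to phenotype rescaling.
* **Ridge degeneracy.** With a single kernel numerically proportional to
  the identity only $\sigma^2_u + \sigma^2_e$ is identifiable; the fit
  warns and flags this instead of returning an arbitrary split.

**Per-ORF heritabilities** (for the weighted adjustment) reuse one
eigendecomposition of $G_T$ across all ORFs and profile the total variance,
leaving a 1-D search over $h^2 \in [0, 0.999)$ per ORF — exact for the
single-kernel model and orders of magnitude faster than a general REML per
column. Constant or unfittable columns get $h^2 = 0$ (weight 1) with a
warning.

## Prediction and validation

Kernels are built once on all animals and shared across folds (the
conventional treatment of relationship matrices in cross-validation; a
strict per-fold rebuild is a config option away from the same functions).
Variance components are re-estimated per fold on training records only;
test animals' solutions come from the mixed-model equations through their
kernel rows, which equals the conditional-expectation formula
$K_{test,train}V_{train}^{-1}(y - X\hat\beta)$ (asserted on small
instances).

Adjusted phenotypes are $y_{adj} = y - X\hat\beta$. Which fit supplies
$\hat\beta$ is genuinely open; the default is the full-data fit of the same
model, because LODO leaves the held-out diet's management groups
unestimable from training (management groups concatenate diet). A
training-only option exists for the fourfold scheme and fails loudly in
the unestimable case. Accuracy = Pearson correlation of $y_{adj}$ with TAM
(sum of solutions) and each component solution; RMSE; dispersion = OLS
slope (with intercept) of $y_{adj}$ on TAM. A degenerate predictor — a
component pinned at zero makes all its solutions zero — is scored accuracy
0 and `NA` dispersion: it carries no ranking information, and leaving it
`NA` would silently drop exactly the folds where a model failed.
Non-converged folds are excluded from medians and counted.

## The synthetic-data generator

The generator emulates the study's structure so every stage is testable
without the (non-public) real data: 717 animals by default, in 16
management groups nested in 4 diets of 2 diet types, with sex tied to diet
type; HWE genotypes with allele frequencies uniform on [0.05, 0.5];
18 Dirichlet breed fractions and a bounded heterozygosity covariate;
log-normal library sizes around 2×10⁷ reads. SNP and ORF counts default to
5,000 and 2,000 — enough for the kernels to behave like their full-scale
counterparts while a complete study runs in minutes; tests and the
acceptance script state the sizes they use per experiment.

Per-ORF heritabilities are drawn from Beta(0.605, 8.038), solved
numerically so the mean is 0.07 and the median 0.04; this puts ~75% of
draws below 0.10 (slightly more than the 69% summary the targets derive
from — the mean/median pair was prioritised). A configurable fraction of
ORFs (default 50%) receives a diet-type shift of `diet_shift_sd` (default
1.0) log10 units, which makes PCA + k-means recover diet types essentially
perfectly — the property the data-driven adjustment relies on.

The phenotype is $y = X\beta + u + m + o + e$ with every component stored
as ground truth. $u$ and $o$ are drawn from $N(0, \sigma^2 K)$ with $K$ the
GRM and the Hadamard kernel built from the simulated data; $m$ is a random
weighted sum of centred log-abundance columns with a deterministic
trace-based scale, so that $\mathrm{cov}(m) \propto M_1$ with coefficient
exactly the target $m^2$ — the construction under which REML recovery of
the target is a well-posed check. One consequence is deliberate: because
the MRM has a dominant diet axis, the *realised* variance of a single $m$
draw keeps an $O(1)$ fluctuation (a $\chi^2_1$ loading on that axis) that
does not shrink with $n$. The realised genomic and residual fractions do
converge; the metagenomic fraction is unbiased at the target, and the
tests check exactly those two statements rather than a blanket convergence
claim. Conditioning the draw to hit the target variance exactly, or
restricting it to the identifiable space, was tried and rejected: both
break the proportionality between the effect's covariance and the fitted
kernel and visibly bias $\hat m^2$.

ORFs are conditionally independent given diet and genetics — real rumen
communities have correlation structure (co-abundant gene clusters,
cross-feeding) the generator does not emulate, so passing tests speak to
the estimator's behaviour under the assumed model, not to robustness
against ecological covariance. Other simplifications: no pedigree, no
read-level sequence simulation, management-group effects are plain wide
normals.

## Filters

Record/feature filters mirror the study's rules and are single-pass
(statistics computed once, no iteration — applying a filter twice equals
applying it once):

* genotypes: MAF strictly greater than 0.05 (frequencies from non-missing
  calls), then mean-dosage imputation of missing calls;
* ORFs: removed only when prevalence < 10% **and** maximum within-sample
  relative abundance < 0.01% — surviving either criterion keeps the ORF;
  the opposite (OR) reading of the rule is available behind a flag;
* animals: removed when any listed trait lies more than 3 SDs from its
  within-diet mean. Note that in a group of $g$ animals the largest
  attainable sample z-score is $(g-1)/\sqrt{g}$, so small groups cannot
  produce 3-SD outliers — the tests verify the rule against direct
  computation rather than against a fixed removal count.

## Problem sizes

The test suite simulates at n = 120–600 animals with 10²–10³ markers and
ORFs, and the acceptance script's recovery experiment uses n = 600,
m = 1,000 ORFs, 2,000 SNPs over 20 seeds — sizes chosen so the full suite
and script each run in a couple of minutes on one CPU while keeping the
REML problems statistically non-trivial (reported SEs around 0.05–0.10 on
the variance ratios, as at full scale).

## Known limitations

* No multivariate/bivariate models (a natural extension for the two-cluster
  setting), no Bayesian samplers, no pedigree A-matrix.
* No sparse or low-rank kernel approximations; everything is dense, which
  is comfortable to a few thousand animals.
* The weighted adjustment treats per-ORF heritabilities as known without
  error, as the estimates it imitates were.
* AIC values are comparable only within a run (see above).
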