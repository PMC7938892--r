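---
title: "Benchmarking SNP feature-selection stability for genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking SNP feature-selection stability for genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In genomic prediction of quantitative traits such as residual feed intake
(RFI) in growing pigs, the number of SNP markers (tens of thousands) far
exceeds the number of phenotyped animals (a few thousand). Feature
selection (FS) — choosing a subset of SNPs as predictors — reduces
computation, prevents overfitting, and is the basis for designing
low-density genotyping chips. But a selector is only useful for chip design
if it is *stable*: retraining on a slightly different sample should select
largely the same markers. `fsstab` provides the full benchmarking pipeline:
phenotype pre-adjustment, genotype quality control, five filter selectors,
embedded (penalized-regression) selection, six learners, nested
cross-validation, and chance-corrected stability estimation — plus a
synthetic data generator so everything can be exercised without proprietary
animal-breeding data.

## Phenotype pre-adjustment

The prediction target is adjusted RFI, built in three steps from component
traits:

1. **Metabolic weight.** `compute_metabolic_weight()` returns
   $\mathrm{MW} = ((W_\mathrm{start}+W_\mathrm{end})/2)^{0.75}$, mean test
   weight at the 3/4 allometric exponent. Units follow the inputs (kg by
   default); a `scale` factor is provided because field data sometimes
   record weights in kg while MW is quoted in g.
2. **Multivariate outlier screening.** Within each farm-by-batch
   contemporary group, records whose squared Mahalanobis distance from the
   group centre on (ADG, DFI, BFT, MW) exceeds 12 are removed. The
   classical (non-robust) mean/covariance is used; only the threshold, not
   a robust variant, is part of the procedure being reproduced.
3. **RFI and environmental adjustment.** RFI is the OLS residual of DFI on
   ADG, BFT and MW; `adjust_rfi()` then removes FarmBatch, age-at-start and
   test-length effects by a second OLS fit and keeps its residuals.
   Intercepts are included in both models (the residuals then sum to zero,
   which is what "adjusted" requires); FarmBatch levels with fewer than 10
   records are dropped rather than pooled. The output is orthogonal to the
   design by construction and re-adjusting is a no-op.

## Genotype quality control

`qc_genotypes()` applies, in fixed order: SNP call-rate (< 0.90) and MAF
(< 0.05) removal, sample call-rate (< 0.90) removal, mean imputation
(missing calls get the rounded per-SNP mean), near-zero-variance removal
(constant SNPs, or most-common/second-most-common frequency ratio above
95/5 with under 10% distinct values), and greedy correlation pruning at
|r| > 0.8 (the SNP with the larger mean absolute correlation goes first;
ties resolve by column order). The last two stages delegate to
`caret::nearZeroVar()` and `caret::findCorrelation(exact = TRUE)`, the
utilities whose semantics these rules follow. The pipeline is idempotent
and reports SNP/sample counts after every stage.

## Filter methods

All five filters return a `filter_score` table (snp_id, score, rank) and
are pure functions of the training fold and a seed:

- **spearcor** — absolute Spearman correlation of each SNP with the
  target. The absolute value is used (relevance should not depend on
  allele coding); this is a deliberate choice where the procedure could be
  read as signed ranking.
- **univ.dtree** — a small regression tree per SNP; score is minus the
  repeated-CV MSE (5-fold × 2 repeats, depth 3 by default — the resampling
  scheme is a package choice, fixed by configuration).
- **mrmr** — greedy maximum-relevance-minimum-redundancy on mutual
  information. MI is estimated by the Gaussian closed form
  $-\tfrac12\log(1-\rho^2)$ from the Pearson correlation; a discretized
  plug-in estimator (`mi_plugin()`) is available as an option and serves as
  the independent cross-check in the tests. A candidate perfectly
  correlated with an already-selected SNP has infinite redundancy and is
  chosen only when nothing else remains. For selected SNPs the score is the
  reverse selection order; with `k = p` this yields a full ranking.
- **cforest** — conditional permutation importance from a random forest
  (fitted with **ranger**; 100 trees, `mtry = p/3` by default). Each
  SNP's values are permuted *within strata defined by the observed values
  of the predictors correlated with it* (|r| > 0.2, the two strongest;
  genotypes take at most three values, so strata are value combinations),
  and the score is the mean increase in per-tree out-of-bag squared error,
  averaged over a few seeded permutations. Conditioning on correlated
  predictors' values rather than on each tree's own split-point partition
  is a simplification of the original conditional-importance construction;
  it preserves the property that matters here — a spuriously correlated
  SNP is not credited for its neighbours' signal — and an unused SNP
  scores exactly 0. Results are sensitive to the forest hyper-parameters,
  which are unreported in the original study; treat cforest rankings as
  indicative.
- **random** — uniform selection without replacement; the chance-level
  benchmark every stability estimate is judged against.

## Learners

- **Penalized regression** (`fit_penalized_regression()`): the elastic-net
  objective via **glmnet** coordinate descent, `alpha` grid 0, 0.1, …, 1
  (0 = ridge, 1 = LASSO), `lambda` by inner-CV with ties broken toward
  stronger regularization. Nonzero coefficients are the embedded
  selection. At a fixed `lambda`, glmnet's internal response
  standardization means the ridge solution equals
  $(X'X + \lambda' I)^{-1}X'y$ with $\lambda' = N\lambda/\mathrm{sd}_N(y)$
  — documented because the package's tests verify this closed form.
- **SVM** (`fit_svm_rbf()`): ε-insensitive RBF regression via **e1071**;
  grids C ∈ {0.001, 0.1, 1, 5, 10}, γ ∈ {0.005, 0.05, 0.5, 5}; ε fixed at
  0.1 (unreported in the original study). A configurable feature cap
  (default 2000) refuses dense kernel fits on very wide inputs.
- **Gradient boosting** (`fit_gradient_boosting()`): least-squares boosted
  trees via **xgboost** with leaf L2 regularization disabled
  (`lambda = 0`) so a single unit-rate stump reproduces the classic
  gradient-boosting machine exactly; grids depth {10, 12, 15, 17}, rate
  {0.01, 0.02}, trees {500, 1000, 3000}. The validation-error curve of one
  run at the largest tree count scores every candidate tree count; ties go
  to the smaller model.
- **GBLUP** (`fit_gblup_gibbs()`): $y = 1\mu + u + \varepsilon$,
  $u \sim N(0, G\sigma_u^2)$ with the genomic relationship matrix
  $G = (M-E)(M-E)'/(2\sum_j q_j(1-q_j))$ from `compute_grm()` (allele
  frequencies computed from the data). A Gibbs sampler works in the
  eigenbasis of $G$ (one decomposition up front; each sweep is then
  linear-time in animals), with scaled inverse-χ² variance priors in the
  improper flat limit (df = −2, scale = 0) and a tiny variance floor for
  degenerate inputs. Desk-scale defaults are 25,000 iterations / 2,500
  burn-in / thinning 10; long-chain settings (250,000 / 25,000 / 10) are a
  function argument away. Effective sample sizes are estimated from the
  autocorrelation function and a warning is raised when they fall below a
  floor. Held-out animals are predicted by the conditional expectation
  $\hat u_{new} = G_{new,train} G_{train}^{-1}\hat u$.

## Nested cross-validation

`run_experiment()` implements an outer 10-fold / inner 6-fold nested CV:
for each outer fold, features are standardized on the training animals
only, filters are scored on the training fold, top-k subsets selected,
hyper-parameters tuned on the shared inner folds, the model refitted on the
whole outer-training set and the held-out animals predicted. Accuracy is
the per-fold Spearman correlation, summarized by median and IQR (type-7
quantiles — the interpolation convention is a documented choice). One
`cv_split` object is shared by every (filter, size, learner) configuration;
folds are simple random, unstratified, with sizes differing by at most one.
A poisoning test in the suite verifies that perturbing held-out phenotypes
leaves every fitted artifact bit-identical — nothing outside the training
fold reaches a model. Failing configurations (e.g. kernel learners above
the feature cap) are recorded and skipped, not fatal.

## Stability estimation

For a system $S = \{S_1,\dots,S_n\}$ of SNP subsets from $n$ training
folds over $p$ features, `nog_stability()` computes the chance-corrected
estimator

$$\hat\Phi(S) = 1 - \frac{\tfrac1p\sum_i \sigma^2_{f_i}}
  {\tfrac{\bar d}{p}\bigl(1-\tfrac{\bar d}{p}\bigr)},\qquad
  \sigma^2_{f_i} = \tfrac{n}{n-1}\hat p_{f_i}(1-\hat p_{f_i}),$$

with $\hat p_{f_i}$ the selection frequency of feature $i$ and $\bar d$
the mean subset size. It allows unequal subset sizes (needed for embedded
selectors), decreases in the per-feature variances, is bounded above by 1,
attains 1 only for identical subsets, and has expectation 0 under random
selection — properties the test suite asserts on simulated systems against
a brute-force frequency-matrix oracle. `nog_confidence_interval()` uses
the asymptotic-normal interval with the variance estimated from per-subset
influence terms ($\hat\sigma^2 = \tfrac{4}{n^2}\sum_j(\phi_j-\bar\phi)^2$);
the original study prints no interval formula, so this choice is validated
by a coverage simulation (intervals for random systems cover 0 at the
nominal rate) rather than asserted as a reproduction.
`subset_descriptives()` reports NSNPs, the proportion of distinct features
(PDF), and the median/IQR of subset sizes; `expected_random_pdf()` gives
the analytic expectation $p(1-((p-d)/p)^n)/(nd)$ used as the oracle for
chance-level PDF. `score_stability()` measures mean pairwise Pearson and
Spearman correlations between per-fold score vectors (average ranks on
ties).

## The synthetic data generator

`simulate_genotypes()` draws per-SNP MAFs uniformly from `maf_range` and
induces block LD with a latent Gaussian haplotype model: within each
non-overlapping block, two AR(1)-correlated latent vectors per animal are
thresholded at MAF-matched quantiles. With `ld_rho = 0` genotypes are
Binomial(2, maf) and in Hardy–Weinberg proportions by construction. The
stored code counts major alleles, so 0 is the minor-allele homozygote.
`simulate_phenotypes()` builds component traits at magnitudes typical of a
growing-pig feed test (ADG ≈ 900 ± 90 g/day, BFT ≈ 12 ± 2 mm, test
weights ≈ 31 → 130 kg) and composes daily feed intake from them plus an
RFI signal: an additive genetic value over `n_qtl` causal SNPs
(Normal(0, 1) effects rescaled so the realized genetic variance is exactly
$h^2\sigma^2_{RFI}$ — no heritability drift at small N), environmental
noise, FarmBatch effects, and age/length slopes. Optional epistasis adds
product terms of standardized genotypes (off by default; used only to
differentiate non-parametric learners). Defaults mirror the reference
study design: 5,708 animals, 9,523 SNPs, 46 FarmBatch levels each with at
least 10 records, MAF ≥ 0.05; quantities the study does not report
($h^2 = 0.3$, 100 QTL, block size 10 with latent ρ = 0.3, RFI SD 150
g/day, batch SD 50 g/day) were fixed once at values a breeder would call
realistic.

What the generator does *not* emulate: real pig genome maps and
recombination-driven long-range LD, pedigree/family structure (and hence
Mendelian-inconsistency checks, which are out of scope), genotyping-error
patterns, selection in the historical population, and
genotype-by-environment interaction. Passing tests therefore demonstrate
correctness of the statistical machinery under the assumed generative
model, not that any particular filter will be stable on a specific real
dataset.

A note on the causal-recovery property test: with Normal(0, 1) effect
draws the number of *detectable* QTL is itself random — a draw routinely
leaves a handful of QTL with negligible variance share that no method can
find. The acceptance suite therefore checks the per-dataset recovery
envelope over five replicate simulations and requires it in the majority,
while the stability gap between spearcor and random selection is asserted
in every replicate.

## Numerical choices and problem sizes

- Tie-breaks are deterministic everywhere: top-k selection and mRMR by SNP
  index, correlation pruning by column order, hyper-parameter ties toward
  stronger regularization / smaller models.
- Constant SNPs score 0 (with a warning) in spearcor; constant score
  vectors are excluded from score-stability pairs.
- The Gibbs sampler floors variances at 1e-10 so degenerate (constant)
  phenotypes stay finite; G's eigenvalues get a 1e-8 jitter.
- The test suite and acceptance checks run at reduced scales chosen to
  exercise every code path briskly: simulations of 150–2,000 animals and
  30–1,000 SNPs, forests of 40–100 trees, Gibbs chains of 4,000–20,000
  iterations, and 10-fold outer / 3–6-fold inner CV. These sizes are the
  package's own testing choices; production analyses should use the
  defaults (or larger).

## Limitations

- The mRMR Gaussian-MI approximation is exact only for jointly Gaussian
  pairs; genotypes are ternary, so it is a monotone surrogate of the true
  MI — adequate for ranking, not for MI estimation per se.
- cforest importances depend on unreported forest hyper-parameters; the
  defaults here are sensible, not canonical.
- The GBLUP feature set is configurable (the study's own account differs
  between its pre- and post-edition SNP sets); `run_experiment()` uses the
  QC'd matrix it is given.
- The confidence-interval construction for stability is asymptotic in the
  number of subsets; with the usual n = 10 it is serviceable but not
  exact, as the coverage simulation shows.
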