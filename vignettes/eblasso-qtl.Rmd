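---
title: "Empirical Bayesian LASSO logistic regression for binary-trait QTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical Bayesian LASSO logistic regression for binary-trait QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebqtl)
```

## The problem and the model

Complex binary traits (disease status, survival of a stress challenge,
fast/slow phenotypes) in experimental crosses are typically influenced by
many quantitative trait loci (QTLs), possibly interacting in pairs. With
`m` genotyped markers the multiple-QTL logistic model is

$$\mathrm{logit}(p_i) \;=\; \beta_0 + \sum_{j=1}^m \beta_j x_{ij}
  + \sum_{j<j'} \beta_{jj'}\, x_{ij} x_{ij'},$$

where `x_ij` is the Cockerham additive code of the genotype (1, 0, −1 for
the three F2 classes; ±0.5 for a backcross) and an epistatic effect is the
product of its two parent columns. The number of candidate effects,
`k = 1 + m + m(m−1)/2`, dwarfs the sample size — for `m = 481` markers
there are 115,922 candidates — so the model is only identifiable under a
sparsity assumption: almost every coefficient is zero.

`ebqtl` implements two empirical-Bayes ("EBLASSO") estimators of this
model. Each coefficient gets a zero-mean normal prior with its own
variance, $\beta_j \sim N(0, \sigma_j^2)$, and the variances get a
shrinkage hyperprior:

* **NE** (normal–exponential): $\sigma_j^2 \sim \mathrm{Exp}(\lambda)$.
  Marginally the coefficient prior is double-exponential, so this is a
  Bayesian analogue of the LASSO with one tuning rate `lambda`.
* **NEG** (normal–exponential–gamma): additionally
  $\lambda \sim \mathrm{Gamma}(a, b)$, giving
  $p(\sigma^2) = (a/b)(\sigma^2/b + 1)^{-(a+1)}$ — heavier tails, two
  tuning constants, and (for `a` near 0) markedly less bias on large
  effects. Any `a > −1.5`, `b > 0` is admissible.
* **uniform**: a flat prior on the variances, the `lambda = 0` limit of
  NE; this is the relevance-vector-machine-like estimator, provided mainly
  as a baseline because it under-shrinks when `k` is large.

Variances estimated at zero (infinite precision `alpha = 1/sigma^2`)
remove their effect from the model; the handful of effects with finite
`alpha` are reported with Wald statistics.

## How the fit works

`eb_fit()` alternates two steps until convergence:

1. **Laplace step.** For the current precisions, the logistic posterior
   mode `beta_MAP` is found by Newton–Raphson with step halving, giving
   the Gaussian approximation with covariance
   $\Sigma = (X^T B X + A)^{-1}$, `B = diag(p(1−p))`. The step also
   produces the pseudo-response
   $\hat y = X\beta_{MAP} + B^{-1}(y − p_{MAP})$, which turns the problem
   into a weighted linear model $\hat y = X\beta + \varepsilon$,
   $\varepsilon \sim N(0, B^{-1})$, whose exact Gaussian posterior matches
   the Laplace approximation.

2. **Greedy variance updates.** On that linear model, each candidate
   column carries a sparsity factor $s = x^T C_{-}^{-1} x$ and quality
   factor $q = x^T C_{-}^{-1} \hat y$ (with `C` the model covariance of
   the pseudo-response built from the included effects, applied through
   the Woodbury identity). The per-coordinate marginal posterior of
   `alpha` has a closed-form maximizer under the NE prior — include the
   effect iff $q^2 - s > 2\lambda$, with
   $\alpha^* = s[(s+4\lambda) + \sqrt{s^2 + 8\lambda q^2}]\,/\,
   [2(q^2 - s - 2\lambda)]$ — and a one-dimensional maximizer under NEG
   found by a log-scale grid plus golden-section refinement (validated in
   the tests against an independent grid/`optimize` oracle; a closed form
   exists for the predecessor linear-model algorithm but is not needed at
   this cost). The engine repeatedly applies whichever action — add,
   delete or re-estimate a precision — most increases the marginal
   posterior, until none improves it.

Convergence requires all three of: no effect added or deleted in the last
pass, penalized log-likelihood change below `tol_loglik` (default 1e-4),
and total precision movement `sum |delta log alpha|` below `tol_alpha`
(default 1e-3), with a cap of `maxit_outer = 200` outer iterations
(a warning flags the rare non-converged fit, which still returns its last
iterate).

### Design choices that were genuinely open

* **Column scale of the shrinkage prior.** The variance updates operate on
  candidate columns scaled to unit Euclidean norm; estimates are mapped
  back to the raw genotype coding for reporting. This is what makes the
  method's hyperparameter scale coherent: the rule that
  $\lambda_{max} = 1.5\,\max_j |x_j^T(y - \bar y)|$ retains a single
  effect holds on this scale (and demonstrably not on the raw ±1 coding,
  where `q² − s` for strong markers exceeds `2·lambda_max` a hundredfold),
  and useful `lambda` values land in the 0.01–1 range regardless of sample
  size or coding. The package therefore treats unit-norm scaling as part
  of the estimator, not an option.
* **Action order.** Actions are applied best-improvement-first (ties to
  the lowest column index) rather than sweeping columns in a fixed order;
  this makes the trajectory independent of column ordering and each
  accepted action carries an exactly computed, strictly positive gain, so
  the marginal posterior is non-decreasing — a property the test suite
  checks against dense linear algebra. For the 1e5-column epistatic
  expansion, additions are proposed from a cached full sweep and verified
  exactly against the current model before acceptance; a pass may only
  conclude after a fresh sweep finds no improving addition. The full
  design matrix is never materialized: a sweep is a handful of `m x m`
  cross-products with the marker matrix.
* **Intercept.** The intercept always has a flat prior and is updated only
  inside the Laplace step; the variance machinery sees effect columns
  only (an empty model has `C = B^{-1}` exactly).
* **Oscillation.** Occasionally a borderline effect is added by the
  variance updates and deleted again after the next Laplace refresh, ad
  infinitum (the two steps optimize slightly different surfaces). A cycle
  guard detects a structurally changed active set revisiting an earlier
  configuration for the third time, stops, and returns the iterate with
  the best penalized log-likelihood, flagged by a warning and
  `converged = FALSE`.
* **Separation.** Fitted probabilities are clipped to
  `[1e-10, 1 − 1e-10]` before `B` is inverted, so quasi-separated fits
  degrade gracefully instead of producing infinite pseudo-responses.
* **Degrees of freedom.** Wald p-values use Student t with
  `n − k_m − 1` degrees of freedom by default; `eb_control(df = "one")`
  reproduces the heavy-tailed 1-df convention some hierarchical GLM
  packages use. With `n` in the hundreds the default is essentially a
  normal reference.
* **Missing genotypes.** `impute_missing()` drops individuals with more
  than 10% missing calls, then fills each remaining gap with the nearest
  non-missing flanking marker on the same chromosome (ties between
  disagreeing flanks resolve to the expected code 0). At the few-percent
  missingness typical of cross data this nearest-flank rule is essentially
  equivalent to more elaborate expectation-based imputation because
  adjacent markers are highly correlated.

## Hyperparameter selection

`cv_loglik()` scores one prior setting by ten-fold cross-validation:
folds are class-stratified and fixed once per seed, and the score is the
**per-observation** held-out Bernoulli log-likelihood (so 0 is a perfect
predictor and −log 2 ≈ −0.693 a coin flip; typical good settings on the
simulated designs score near −0.36, which is only consistent with a
per-sample average, hence the convention).

`tune_ne()` scans `lambda` in two stages — a log-spaced descent (step
0.35) from `lambda_max` to 0.001, then ten values in a length-0.01
interval around the stage-1 winner. `tune_neg()` uses three steps:
diagonal `a = b` in {0.001, 0.01, 0.1, 1}; then `a` over
{−0.5 … 1} at the winning `b`; then `b` from 0.01 to 10 (decade steps
below 1, unit steps above). Already-visited settings are cached rather
than re-fit, and folds are held fixed across stages so that score
differences are attributable to the hyperparameters alone.

## What the simulator emulates

`simulate_f2_genotypes()` builds each individual from two independent
gamete-level Markov chains along an evenly spaced chromosome:
recombination between adjacent markers occurs with the Haldane fraction
`r = (1 − e^{−2d/100})/2` (d in cM, no interference). This reproduces the
two features the analysis depends on — Mendelian 1:2:1 genotype margins
and an adjacent-marker correlation of `e^{−2d/100}` (0.9048 at 5 cM,
decaying as `e^{−2ℓd/100}` at lag ℓ) — and nothing else. Phenotypes come
from the logistic model applied to a truth table of sparse effects;
`builtin_truth()` carries the two packaged designs (20 main effects; 10
main + 10 epistatic, effect sizes −1.28 … 2.19, QTLs coincident with
markers).

Real cross data differ in ways the simulator deliberately ignores:
multiple chromosomes of varying marker density, genotyping error,
segregation distortion, missing calls, dominance, and polygenic
background. Passing the simulation-based tests therefore demonstrates
correctness of the estimator under its own model, not robustness to those
artifacts; the input layer (imputation, backcross coding, per-chromosome
maps) handles the mechanics, but no claim about real-data power is made.

`evaluate_detection()` scores significant effects against the truth table
with the field's 20 cM rule: a detection within 20 cM of a true QTL is a
true positive, several detections of the same QTL merge into one, an
epistatic pair must match both loci (order-free, assigned by smallest
total distance), and everything else is a false positive. The merging
rule is applied uniformly to every method evaluated, including the
single-locus scan baseline.

## Problem sizes used by the tests

The automated suite regenerates the two packaged designs at their
published sizes (m = 481 at 5 cM; n = 500 with 20 main effects, and
n = 1000 with 10 main + 10 epistatic effects over all 115,922 candidate
effects). Stochastic checks use 10 replicates of the first design, 3 of
the second (the second design's fits dominate runtime at roughly half a
minute each), and 10 replicates for null calibration at m = 50; these
counts make the replicate means tight enough for the ±3 / ±4 acceptance
bands while keeping the whole suite in the minutes range. Oracle checks
(closed-form updates, dense linear algebra identities) run at n ≤ 60 where
brute force is exact and instant.

## Known limitations

* Only additive main effects and their pairwise products are modeled;
  dominance columns are supported by the coding layer but off by default,
  and higher-order interactions are out of scope.
* p-values condition on the final estimated prior variances
  (empirical-Bayes convention); hyperparameter uncertainty is not
  propagated, and post-selection inference caveats apply to borderline
  effects.
* The greedy optimizer finds a local maximum of the marginal posterior;
  with highly correlated markers it may keep one representative of a
  correlated pair (both published estimators share this behavior).
* Binary traits only; ordinal/multinomial extensions would need a
  different likelihood and Laplace step.

## A worked example

```{r example, eval = FALSE}
library(ebqtl)
set.seed(1)
des <- sim_design("main_only")
G <- simulate_f2_genotypes(n = des$n, m = des$m, spacing_cm = des$spacing_cm)
y <- simulate_phenotype(G, des$truth)

fit <- eb_fit(G, y, prior_neg(0.01, 6))
tidy(fit, significant_only = TRUE)
evaluate_detection(tidy(fit, significant_only = TRUE), des$truth, G$pos)
autoplot(fit)
```
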