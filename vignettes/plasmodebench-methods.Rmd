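---
title: "Methods: comparing parametric and Plasmode simulation for classifier benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing parametric and Plasmode simulation for classifier benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the framework answers

Method-comparison studies for binary classifiers are usually run as
*parametric* simulations: the investigator specifies a data-generating
process (DGP) for the covariates and an outcome-generating model (OGM) for
the labels, draws many datasets, and benchmarks the classifiers.
*Plasmode* simulation replaces the covariate half of this recipe with
resampling from one fixed "real-life" dataset, keeping a specified OGM for
the labels. Plasmode is often recommended because no explicit DGP has to be
written down -- but whether it actually recovers true classifier
performance and the true method ranking better than a (possibly
misspecified) parametric study is an empirical question.

`plasmodebench` implements a meta-simulation to answer it. A known,
deliberately complicated "truth" is constructed; comparison studies are
then simulated under that truth -- parametric studies with controlled
misspecifications of the DGP or the OGM, and Plasmode studies with
different resampling schemes -- and each simulated study is scored by how
well it reproduces the true performances and the true ranking of five
classifiers.

## The true data-generating process

The truth for `p = 150` covariates consists of:

* **Marginals** drawn at random from four families: normal, log-normal
  (skewed), two-component Gaussian mixtures with separated means (bimodal),
  and a contamination mixture (a dominant near-standard component plus a
  10%-weight, high-variance outlier component). The layout is 50 normal,
  50 log-normal, 25 bimodal, 25 contamination. Smaller studies
  (`p = 50, 10, 2`) use first-k-per-role subsets of the same 150 marginals
  and the corresponding submatrix of the correlation matrix, so results
  across `p` are comparable; `p = 2` keeps the first normal and the first
  bimodal variable.
* **Marginal parameters** drawn from hyper-distributions with expected
  location 0 and expected variance 1 for first components, expected
  location 4 for the bimodal second component, and expected variance 10
  for the contamination component. The exact hyper-distributions are a
  design choice of this package: locations are Normal with standard
  deviation 0.5 around their expected value, variances are Gamma with
  shape 4 (keeping them bounded away from zero) and the stated mean, and
  the mixture weights are 0.5/0.5 (symmetric bimodality) and 0.9/0.1
  (classical contamination). All of these are configurable through
  `marginal_hyperparams()`, and a previously drawn truth can be loaded
  from CSV (`read_dgp_spec()`).
* **A random correlation matrix**, generated by the C-vine ("onion")
  construction with partial correlations `2 * Beta(a, a) - 1`. The default
  concentration `a = 50` gives pairwise correlations scattered around zero
  with a standard deviation of roughly 0.1, matching the weak-dependence
  regime the framework targets, and is always exactly positive definite.
  Much stronger dependence would be infeasible jointly with many of the
  mixed marginals.

Sampling uses the NORTA / Gaussian-copula mechanism
(`sample_covariates()`): a latent multivariate normal draw with the
specified correlation matrix is pushed through the standard-normal CDF and
each marginal's quantile function. The specified matrix is interpreted as
the *latent* (copula-scale) correlation; no Pearson-matching adjustment is
applied for non-normal marginals. This convention is exactly reproducible
and is the one verified by the copula-fidelity tests (empirical latent
correlations within ±0.03 of the target at `n = 100000`). Mixture
quantiles have no closed form and are inverted numerically (monotone grid
inversion refined by Newton steps on the closed-form CDF); the inversion
error is far below the Monte-Carlo noise at any realistic sample size.

All generated covariates are min-max rescaled to [0, 1] per column
(`rescale_minmax()`), which puts all deviations below on a common scale. A
constant column (possible for extreme mixtures at small `n`) is treated as
a pathological draw and the dataset is redrawn under the same budget as
degenerate outcomes.

## The true outcome-generating model

Outcomes are Bernoulli draws with logistic probabilities
`plogis(b0 + x' beta)` on the rescaled covariates. Coefficient magnitudes
are uniform on [3, 8] for normal, log-normal and contamination variables
and uniform on [10, 15] for bimodal variables, with random signs. Because
covariates live on [0, 1], the realistic reading is the odds ratio per 0.1
increment: `exp(0.1 * beta)`, i.e. 1.35–2.23 for the smaller and 2.72–4.48
for the larger coefficients. The bimodal variables get the larger
coefficients because their separated modes are what keeps the two classes
separable as `p` grows.

The intercept is calibrated (`calibrate_intercept()`) by monotone
root-finding so that the mean predicted probability over a fresh
calibration sample (default 100 000 draws; at least 10 000) is within
`1e-3` of 0.5 -- a nearly balanced outcome. Strong imbalance would make
many generated datasets single-class and the classification task
degenerate.

One deliberate deviation from full per-`p` fidelity: the low-dimensional
coefficient vectors are the plain per-role subsets of the `p = 150` draw,
with no ad-hoc adjustment for separation quality. Any hand-tuning would be
irreproducible; the frozen truth is whatever the seeded draw produces.

## Controlled misspecifications

Parametric comparison studies can misspecify the DGP
(`dgp_deviation_grid()`), applied after rescaling:

| kind | values |
|------|--------|
| shift (add δ) | ±0.125, ±0.25, ±0.5 |
| scale (multiply by s) | 0.25, 0.5, 0.75, 1.33, 2, 4 |
| equicorrelation (all pairwise ρ) | −0.2, −0.1, 0, 0.1, 0.2 |
| whole distribution | standard normal |

The equicorrelation target is infeasible when `1 + (p - 1) ρ < 0` (e.g.
ρ = −0.2 at p = 150); it is then repaired by projection onto the nearest
correlation matrix (`nearest_psd_correlation()`, Higham's alternating
projections with Dykstra correction) rather than rejected. The
standard-normal deviation is min-max rescaled like all other covariate
data before the OGM is applied, so OGM inputs stay on a comparable scale;
this keeps the deviation a pure distribution-shape misspecification.

Both parametric and Plasmode studies can misspecify the OGM by scaling the
log-odds of the predicted probabilities by a factor `c`
(`scale_association()`): `c = 0.5` weakens, `c = 2` strengthens, and
`c = 0` nullifies the covariate-outcome association (the null model,
implemented as an explicit flag to avoid logit edge cases). For the
logistic OGM this is identical to multiplying every coefficient by `c`,
which the tests verify; negative factors only swap the class labels and
are therefore not exposed.

## Plasmode resampling

For each Plasmode scenario a base dataset of `n = 100` rows is drawn once
from the true DGP; each of the 100 iterations then resamples covariates
from it (`resample_covariates()`): m-out-of-n bootstrap or subsampling,
each with proportions 0.632 and 1 (`m = round(proportion * n)`).
Subsampling with proportion 1 is "no resampling": the base dataset itself,
in its original row order, so iterations differ only through the outcome
noise. Resampled outputs have their row order randomized so that fold
assignment downstream carries no artifact of the base ordering. When the
no-resampling scheme degenerates (one outcome class only), only the
outcome vector can be redrawn, since the covariates are fixed -- a
documented softening of the redraw rule that the parametric path applies
to the whole dataset.

## The classifier benchmark

Five classifiers are compared: ridge and LASSO logistic regression
(`glmnet`), an RBF support vector machine (`e1071`), k-nearest neighbors
(`class`) and a random forest (`randomForest`, 500 trees). Each dataset is
evaluated by 5-fold nested stratified cross-validation: outer folds for
performance estimation, inner folds for hyperparameter tuning by random
search (default budget 100 configurations, tuned on accuracy; ties go to
the first-evaluated configuration). All classifiers share the same outer
folds within an iteration. The search spaces are package choices (the
usual log-uniform boxes; see `classifier_spec()`), since no canonical
values exist for this panel.

Two probability details are worth stating. The SVM's probabilities come
from an in-package Platt calibration -- a logistic fit on out-of-fold
decision values from a stratified internal cross-validation of the
training fold -- because AUC and Brier need probabilities and libsvm's
built-in calibration is not reproducibly seedable from R. KNN
probabilities are vote fractions of the k neighbors, without distance
weighting.

If tuning, fitting or predicting fails on an outer fold, a fallback
learner predicting the training-majority class (ties to class 0; class-1
probability equal to the training class-1 frequency) supplies that fold's
predictions, and the fold is counted; warnings are counted separately and
do not trigger the fallback.

Per fold, six measures are computed from the confusion matrix and the
predicted probabilities: accuracy, F1, sensitivity, specificity, AUC (as
the normalized Mann-Whitney rank statistic, ties counted one half) and the
Brier score. Degenerate folds follow fixed rules: no true ones makes
sensitivity, F1 and AUC non-computable; no true zeros makes specificity
and AUC non-computable; true ones present but none predicted gives F1 = 0,
the worst value. Fold values are averaged per measure over the computable
folds only -- probabilities are never pooled across folds for the AUC,
since differently calibrated fold models would distort it.

## Scoring a simulation strategy

The *truth* is estimated once per `p` by a Monte-Carlo oracle
(`estimate_true_performance()`): 500 replicates (at full scale) of the true
DGP + OGM, benchmarked as above; per classifier and measure the mean is
the true value `M`, and ranking the means gives the true ranking (rank 1
is best regardless of orientation; exact ties broken uniformly at random,
with a tie-break RNG stream seeded separately from the data stream so rank
randomization never perturbs data).

Each scenario iteration `i` yields `M_hat_i` per classifier and measure,
and three scores:

* **Error** `M_hat_i - M`.
* **Relative error**: `((1 - M_hat_i) - (1 - M)) / (1 - M)` for the
  high-is-good measures (errors at high true performance weigh more), and
  the ordinary `(M_hat_i - M) / M` for the Brier score. Iterations with a
  vanishing denominator (true value exactly 1, or 0 for Brier) or with
  non-computable measures are excluded and counted.
* **Normalized Kendall distance** between the iteration's ranking and the
  true ranking: discordant pairs over `K (K - 1) / 2`, so 0 means equal
  and 1 means reversed rankings. Random rankings of five methods have
  median distance 0.5, the no-information anchor.

Finally, the **proportion of acceptable results** summarizes everything:
an iteration is acceptable if its relative error lies inside the closed
interval spanned by the 2.5% and 97.5% order statistics of the reference
relative errors -- the parametric simulation under the true scenario, for
the same classifier, measure and `p`. The interval convention
`[x_(ceil(0.025 n)), x_(floor(0.975 n))]` (i.e. `[x_(3), x_(97)]` for
n = 100) is chosen so that a reference of distinct values scores exactly
95% against its own interval; discrete-valued measures (accuracy at
n = 100 is a multiple of 0.01) can tie at the boundary and then score
slightly above 95%.

## Seeds and determinism

Every random decision derives its seed from one master seed via a
documented key path (`derive_seed(master, scenario_id, role, iteration)`),
so a single scenario or iteration can be deleted and re-run bitwise
identically, which the tests assert. Identical master seeds reproduce the
whole study bitwise.

## Problem sizes used in the shipped artifacts

The full study layout (100 iterations per scenario, tuning budget 100, 500
oracle replicates, `p` up to 150 -- 38 scenarios per `p`) is what
`study_config(profile = "full")` describes. The analysis scripts and the
test suite run the reduced *desk profile* (`profile = "desk"`): 20
iterations, budget 10, 50 oracle replicates, `p` in {2, 10}, and a
representative slice of the scenario grid. The package's own validation
uses these sizes: the self-calibration check runs the reference scenario
at `p = 2` with the full 100 iterations (budget 10, 20 oracle replicates
-- the 95%-by-design property is invariant to the oracle means), and the
direction-of-error check runs `p = 10` with 20 iterations. These sizes are
the package's choices for a single-CPU workflow; all counts scale up
through `study_config()`.

## What the synthetic truth does and does not emulate

The generator reproduces the *structure* the framework studies -- mixed
non-normal marginals, weak dependence, a strong sparse-free logistic
signal, near-balance -- but it is not a model of any particular real
dataset: marginals are univariate mixtures (no discrete covariates, no
heavy-tailed families beyond the contamination model), dependence is a
Gaussian copula (no tail dependence), and every covariate carries signal.
Passing tests therefore show that each simulation strategy is scored
correctly under this controlled truth, not that any strategy is superior
on a given real dataset. Numerical parity with any once-drawn external
truth is out of scope: the frozen parameters here are this package's own
seeded draw.

## Known limitations

* Full-scale runs (budget 100, 500 oracle replicates, p = 150) are
  compute-intensive by design; the desk profile is the supported
  single-machine entry point.
* The exact hyper-distributions behind the drawn truth and the correlation
  recipe are package defaults, not reconstructions of any external study's
  unpublished choices; conclusions that depend on the exact truth (e.g.
  published true-performance tables) are not reproduced.
* Only logistic OGMs are supported; fitted black-box OGMs and non-binary
  outcomes are out of scope, as are boosting and neural-network
  classifiers.
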