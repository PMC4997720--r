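---
title: "Comparing model-building strategies before choosing one"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing model-building strategies before choosing one}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratcomp)
```

## The problem

A clinical prediction model fitted to a finite development sample by ordinary
least squares or maximum likelihood is overfitted: its apparent performance
flatters it, its coefficients are too extreme, and its calibration slope in new
patients falls below 1. Several corrections compete — uniform shrinkage of the
slopes estimated in different ways, or penalized estimation — and none of them
wins universally. Their relative merit depends on the development data:
observations per variable (OPV), events per variable (EPV), and the model's
explained variance all matter, and the ranking can flip between data sets from
the same clinical domain.

`stratcomp` therefore compares whole model-building *strategies* in the data
at hand, before a final model is built, using a wrapper design: the unit being
resampled and evaluated is the strategy, not a fitted model.

## The wrapper comparison

Given a development set with outcome $y$ and predictors $X$ (fixed a priori;
the package performs no variable selection), one comparison replicate of
strategies A and B is:

1. draw a bootstrap sample of size $n$ from the development data;
2. apply A and B each to that same bootstrap sample (a *paired* design: both
   strategies face the same resample, which removes between-sample
   Monte-Carlo variance from the contrast);
3. evaluate both fitted models in the original data, taken to represent the
   source population;
4. record $\mathrm{SSE}(B)/\mathrm{SSE}(A)$ for linear models, or
   $-2\ell_B - (-2\ell_A)$ for logistic models.

Over $R$ replicates (defaults: 10,000 linear, 5,000 logistic) this yields a
comparison distribution, summarized by

* the **victory rate** $\Pr[\text{B beats A}]$ — the proportion of values
  *strictly* below the neutral cutoff (1 for ratios, 0 for differences), so a
  strategy compared with itself scores exactly 0;
* the **median**, which calibrates whether the typical win is material; and
* the **IQR** (type-7 linear-interpolation quartiles, fixed for
  reproducibility), which measures the inconsistency of the contrast.

Replicates in which either strategy fails outright — a single-class bootstrap
sample, separation of the full-model fit, every internal shrinkage round
failing — are dropped and counted, never imputed. The drop count is part of
the result on purpose: separation-prone data announce themselves through this
count and through extremely skewed comparison distributions. If more than half
the replicates fail the comparison aborts, as no meaningful summary remains.

### Which data do the models get evaluated in?

With empirical development data the original data set is the only available
stand-in for the source population, and `compare_strategies()` evaluates
there by default. When the data are *simulated from a known population* —
as in the linear sweeps below — the `eval_data` argument lets the sweep
evaluate both models in the actual population. We chose this for the
simulated scenarios: evaluating in a small development sample partially
rewards the unshrunken fit (the bootstrap sample shares ~63% of its rows with
the evaluation data), which at OPV 2.5 visibly distorts the contrast, whereas
population evaluation measures what the simulation is meant to measure. The
empirical-data default is unchanged.

## The six strategies

Let $\hat\beta$ be the full-data OLS/ML fit ("null" strategy). The shrinkage
strategies replace the slopes by $\gamma\hat\beta$ and re-estimate the
intercept — by maximum likelihood with offset $\gamma X\hat\beta$ for logistic
models (so mean predicted risk equals observed prevalence), by
$\bar y - \gamma \hat\beta^\top \bar x$ for linear models. They differ in how
$\gamma$ is estimated:

* **heuristic**: $\gamma = (\chi^2_{\text{model}} - p)/\chi^2_{\text{model}}$,
  where $\chi^2_{\text{model}}$ is the model likelihood-ratio statistic
  (computed as $n\log(\mathrm{SSE}_0/\mathrm{SSE}_1)$ from Gaussian
  likelihoods in the linear family) and $p$ the number of predictors;
* **split**: mean, over 100 random 80/20 splits, of the calibration slope of
  the 80%-fit model's linear predictor in the held-out 20%;
* **cv**: per 10-fold cross-validation replicate, the held-out linear
  predictors of the 10 fold-wise fits are pooled and a single calibration
  slope estimated from the pooled vector; $\gamma$ is the mean over 10
  replicates;
* **boot**: mean, over 100 bootstrap rounds, of the calibration slope, in the
  *original* data, of a model fitted to a bootstrap sample;
* **firth**: no $\gamma$ at all — Firth-penalized logistic regression
  maximizes $\ell(\beta) + \tfrac12 \log\det I(\beta)$ (Jeffreys prior, all
  parameters penalized including the intercept), shrinking during estimation
  and remaining finite under separation.

The *calibration slope* — the slope from regressing the outcome on the
model's linear predictor in data not used for fitting — is used as the
shrinkage estimator throughout the split/cv/boot strategies. It is the
standard choice in the internal-validation literature and the only one
consistent with mean shrinkage factors just below 1 in well-powered data.
Round-level slopes are aggregated by the arithmetic mean; pooling the CV
predictions (rather than averaging ten per-fold slopes per replicate) was
chosen because per-fold slopes from folds of ~130 observations are unstable.

Two further conventions deserve a note. First, $\gamma$ is **never clipped**:
negative or above-one estimates are recorded and applied as-is, because their
distribution is diagnostic (in noise-dominated data the heuristic factor is
frequently $\le 0$). Second, folds and splits are drawn without outcome
stratification; rounds that lose a class are counted as failed rather than
redrawn, which keeps the failure mechanism observable.

## Numerical choices

* **ML logistic fits** use IRLS with a post-fit guard: a fit counts as
  converged only when the maximum absolute score is below $10^{-6}$ *and* no
  coefficient exceeds 20 in absolute value (on 0/1 or standardized predictors
  a true log odds ratio of 20 does not occur; such values indicate
  separation). Non-convergence is a flag, never an exception, so the
  comparison loop can count it.
* **Firth fits** use modified-score IRLS with hat-value corrections and
  step-halving on the penalized likelihood; the intercept-only closed form
  $\hat p = (r + \tfrac12)/(n+1)$ holds to $10^{-8}$ across an $(r, n)$ grid
  in the test suite, and separated fixtures are cross-checked against an
  independent numeric maximization of the penalized likelihood.
* **Probability clipping**: predicted probabilities are clipped to
  $[10^{-12}, 1-10^{-12}]$ before any log-likelihood, because shrunken or
  resampled models can produce $\hat p \in \{0, 1\}$ in evaluation data and
  the comparison value must stay finite.
* **Determinism**: a single master seed feeds named child streams — the
  comparison's bootstrap indices are drawn up-front, and each (replicate,
  strategy) pair gets a seed derived from the master seed, the replicate
  index and the strategy *name*. Strategy-internal rounds therefore cannot
  perturb the comparison's resampling sequence; swapping A and B with the
  same seed reproduces each strategy's fits exactly (negating the logistic
  comparison values); and any sweep row can be recomputed in isolation from
  its derived per-point seed.

## Synthetic data

Real diagnostic data sets of this kind are not openly available, so the
package ships generators that emulate their *structure* only:

* `gen_linear_cholesky()`: $p = 20$ standard-normal predictors, correlated
  through the Cholesky factor of a configurable correlation matrix; equal
  slopes with the noise variance solved so the generating $R^2$ is hit
  exactly (signal variance $R^2$, noise variance $1 - R^2$); a population of
  1000 rows with development samples drawn from it.
* `gen_logistic_dvt_like()`: dichotomous predictors
  $\mathrm{Bernoulli}(0.5)$ by default, optional standard-normal continuous
  predictors, equal log odds ratios of $\log 2$ (a typical moderate
  diagnostic effect), and an intercept calibrated by bisection on a
  $10^5$-row probe sample (tolerance 0.002) to hit a target prevalence —
  289/1295 for the Oudega-like default (1295 rows, 8 binary predictors),
  929 rows with 4 binary + 4 continuous predictors for the Deepvein-like
  variant. Prevalences and effect sizes are exposed as configuration for
  users who have real summary statistics to match.
* `subsample_epv()` removes cases and non-cases at random to reach an exact
  event count $\mathrm{round}(\mathrm{EPV} \times p)$ while preserving
  prevalence within $\pm 0.01$; `subset_predictors_by_r2()` draws predictor
  subsets and keeps one data set per requested Nagelkerke-$R^2$ bin.

What these generators do **not** emulate: predictor–predictor association in
the logistic family (binary predictors are independent), unequal effect
sizes, and any real joint distribution of clinical variables. Tests passing
on these generators therefore demonstrate the machinery and the qualitative
data-dependence of strategy performance, not agreement with results computed
on the real clinical data.

## Scenario sweeps

`run_sweep()` varies one data characteristic and compares each strategy with
the null strategy at every grid point:

* `opv_linear`: the development sample is reduced row-wise (grid in rows;
  $p = 20$ fixed, so OPV = rows/20), $R^2$ fixed at 0.5;
* `r2_linear`: $R^2$ from 0.1 to 0.9 at OPV 5;
* `epv_logistic`: a logistic base set subsampled to each EPV target;
* `nagelkerke_logistic`: predictor subsets of the base set selected into
  $R^2_N$ bins ($\pm 0.025$ by default).

Loess smoothing in `plot_sweep()` is presentation-only; stored values are
never smoothed. Low-EPV grid points where no resampling strategy can fit are
reported as failed rows rather than aborting the sweep.

The default replicate counts (10,000 linear / 5,000 logistic) are the
full-scale settings; the test suite and the acceptance script run the same
code with 250–500 comparison replicates and two-to-four-point grids, which
resolve the qualitative trends (victory rates falling with sample size;
heuristic shrinkage deteriorating at high $R^2$) with Monte-Carlo error of a
few percentage points. At the sparse end (OPV 2.5, i.e. 50 rows for 20
predictors) a victory rate is conditional on the particular development
sample drawn, and seed-to-seed variability is dominated by the data
realization, not the replicate count.

## Known limitations

* Strategies producing models with different degrees of freedom must not be
  compared by likelihood; the package compares fixed-predictor refits only.
* No survival/Cox support; linear and logistic families only.
* The heuristic factor is undefined when the model LR statistic is zero;
  this is reported as a strategy failure, not silently repaired.
* Nagelkerke $R^2$ of penalized or shrunken models can fall marginally below
  zero; it is reported unclipped.
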