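---
title: "Scoring epistasis by rank-one decomposition of fitness matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring epistasis by rank-one decomposition of fitness matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcreen)
```

## The model

A quantitative genetic interaction screen measures the fitness of double
mutants: an `n x m` matrix `W` whose rows are array mutants and whose
columns are query mutants, with a substantial fraction of entries missing
(filtered or unmeasured — roughly 7–34% in the published SGA, GIM and
E-MAP datasets). Under the multiplicative null model of non-interaction,
the expected double-mutant fitness is the product of the two single-mutant
fitness effects, and each query screen carries its own technical scale
factor. Since true interactions are rare, `W` is approximately rank one:

```
W[a,b] ≈ w[a] * w[b] * g[b]
```

with `w` the single-mutant fitness effects and `g` the per-screen factors.
The package estimates `w` by rank-one approximation of `W`, cancels `g`,
and scores each pair by its residual against a null model. Epistasis is
then the deviation that survives this correction: negative (aggravating)
scores indicate synthetic-lethal/sick-type interactions, positive
(alleviating) scores suppression-type interactions.

## Quantile-based matrix approximation (QMA)

`qma()` is a one-pass multiplicative analogue of a two-way median polish:

1. `x[a]` is the p-quantile of the observed entries of row `a`. In rows
   where a strict majority of observed entries is negative — typical of
   zero-centered, custom-scored E-MAP-style matrices — the
   (1-p)-quantile is used instead, so the factor tracks the bulk of the
   row rather than its interacting tail.
2. The rows of `W` are divided by `x`, and `y[b]` is the q-quantile of
   the observed entries of column `b` of the row-scaled matrix.

No iteration follows: if `W` is complete, strictly positive and exactly
rank one, a single pass already reproduces it exactly for *any* (p, q),
and `p = q = 0.5` is exactly the multiplicative median sweep. The freedom
in (p, q) is what makes the method tunable to the interaction class of
interest: a low `p` biases `x` toward the more fit (less interacting) part
of each row, which empirically favors the detection of positive
interactions, while high quantiles favor the negative classes.

Quantiles use linear interpolation between order statistics at plotting
position `(i-1)/(k-1)` (R's type-7 default) — a convention chosen once so
that the factors are continuous in (p, q).

## Alternating robust fitting (ARF)

`arf()` factorizes `W` by alternating single-predictor regressions: each
row of `W` is regressed on the current query factor `y` to update `x`,
then each column on `x` to update `y`, with `y` renormalized to unit
length after every sweep (the scale lives in `x`). The starting `y` is
the leading right singular vector of `W` with missing entries replaced by
ones. Because extreme fitness values (synthetic-lethal zeros, strong
suppressors) would dominate ordinary least squares, each regression is a
least trimmed squares fit: the coefficients minimize the sum of the
`h = ceiling(t*k)` smallest squared residuals, which ignores up to a
fraction `1 - t` of gross outliers. An optional intercept (`a`) is fitted
as a nuisance parameter and excluded from the factors, so both methods
share the same `x %o% y` contract.

`lts_fit()` searches the trimmed optimum with elemental starts followed by
concentration steps (refit on the `h` best-fitting points until the
objective stops decreasing). When the number of distinct elemental
subsets is at most 100 — which covers the row/column lengths where an
exhaustive check is even feasible — all of them are used
deterministically; otherwise `n_starts` random subsets are drawn from the
seeded stream. Convergence defaults are `tol = 1e-8` on the maximum
relative factor change, `max_iter = 100` sweeps, `n_starts = 20`. The
trimming default `t = 0.75` keeps the fit robust to a quarter of
contaminated entries per row or column; `t = 1` reduces the whole
procedure to alternating ordinary least squares. No recommended `t` or
intercept setting is established for screen data, so both are exposed and
`t = 0.75`, no intercept, is the shipped default.

## From factors to fitness estimates

The factors are unique up to a scalar: `(c*x, y/c)` fits equally well. Two
conventions resolve this. First, `fix_sign()` negates both factors when
the median of `x` is negative (alternating fits can converge to the
all-negative solution; the fitted matrix is unchanged). Second,
`scale_single_mutant_fitness()` pins the scale with the mutants that occur
both as arrays and as queries: writing `xh`, `yh` for the unit-length
factors, `M` is the median of the nonnegative ratios `yh[j]/xh[j]` over
shared mutants `j` (negative ratios, which contradict a fitness
interpretation, are excluded), and

```
w = sqrt(M * ||x|| * ||y||) * xh .
```

This is the unique scaling for which `w[a] * w[b]` equals the fitted value
`x[a] * y[b]` whenever `yh = M * xh` holds on the shared set, i.e. it
makes the single-mutant estimates consistent with the rank-one fit under
the multiplicative null. The same constant gives the per-column screen
correction used by `correct_screen_effects()`:

```
Wc[a,b] = W[a,b] * kappa * w_q[b] / y[b],   kappa = sqrt(M*||x||*||y||) / ||x||
```

which maps an exact null matrix onto `w %o% w_q` regardless of the screen
factors — multiplying any column of `W` by a constant changes `y[b]` by
the same constant and cancels. This per-column multiplicative form was
chosen over per-entry residual rescaling because it is the unique
column-wise correction with that exactness property.

Because the query estimates come from looking the query's identifier up in
`w`, scoring and evaluation are restricted to the columns whose query
mutant also occurs among the arrays (`restrict_to_shared_queries()`);
decomposition itself always runs on the full matrix, and preprocessing
(optional row/column/grand-mean subtraction, `apply_preprocessing()`)
runs before decomposition on the full matrix as well. Means are taken
over observed entries only — the only consistent choice at these
missingness levels.

## Scoring functions

With `w_ab` the corrected double-mutant fitness and `w_a`, `w_b` the
single-mutant estimates, `score_pair()` implements

* `product`: `w_ab - w_a*w_b` — the classical epistasis residual;
* `minimum`: `w_ab - min(w_a, w_b)`; `maximum`: `w_ab - max(w_a, w_b)`;
* `scaled_epistasis`: the product residual divided by its extreme value —
  by `w_a*w_b` when negative (so a synthetic-lethal pair with `w_ab = 0`
  scores exactly -1) and by `min(w_a,w_b) - w_a*w_b` when positive (so a
  double mutant as fit as its less-fit single mutant scores +1).

The positive branch of scaled epistasis diverges when one single mutant is
essentially wild type (`min(w_a,w_b) ≈ w_a*w_b`); scores are therefore
truncated at ±1000, symmetrically in sign, and a denominator below 1e-12
in magnitude returns the truncation value with the residual's sign. When
`w_a*w_b <= 0` the ratio has no fitness interpretation and the score is
undefined (missing) — this also sidesteps the ambiguity of ranking
centered, partly negative E-MAP-style estimates with this function.
Undefined single-mutant estimates, and factor components estimated from
fewer than 2 observed values or smaller than 1e-12 in magnitude, likewise
propagate to missing scores rather than to non-finite values.

## Evaluation

`evaluate_category()` labels every non-missing, non-self entry of the
score matrix by whether its unordered gene pair belongs to the chosen
category (SL, SS, PE, PS); the complement of the category — including
pairs of the other categories — serves as the neutral reference set, since
no curated set of non-interacting pairs exists. Reciprocal entries of a
symmetric matrix are kept as distinct items. PS is ranked with the most
positive scores first, the negative classes with the most negative first.

ROC curves group tied scores into single vertices, so the area equals the
Mann–Whitney statistic with half-credit for ties. Four metrics mirror the
conventions of the published evaluations: full AUC; partial AUC up to an
FPR cap (default 0.5) standardized by the cap so its maximum is 1;
sensitivity at 10% FPR; specificity at 70% TPR. Read-offs interpolate
linearly along the curve, taking the upper envelope at vertical jumps —
the same convention the trapezoidal partial area implies.

`adjust_parameters()` tunes (p, q) on a labelled matrix by maximizing mean
AUC over the mode's categories (PS alone, the three negative classes, or
all four). The selection objective is not fixed by any published
convention; overall AUC was chosen as the least threshold-dependent
option. Ties break toward smaller p, then smaller q. The default grid is
p, q in {0.05, 0.10, ..., 0.95}.

Shipped presets (`preset()`) record the recommended combinations per
technology: SGA-style fixed (0.55, 0.95) with product/minimum scoring and
no preprocessing; GIM-style fixed (0.60, 0.50) with minimum/scaled
epistasis; E-MAP-style fixed (0.50, 0.60) with minimum/minimum and row-mean
subtraction; plus the per-class adjusted variants.

## The synthetic screen generator

`generate_screen()` emulates the features the method actually relies on:
a multiplicative null with query strains drawn from the array collection,
per-query screen factors, skewed multiplicative noise, missingness at the
rates of real screens, and rare planted interactions of all four classes.
Specifically: single-mutant fitness is a 90/10 mixture of near-wild-type
(uniform 0.85–1.05) and sick (uniform 0.3–0.85) effects; null entries are
`w_a*w_b*g_b*exp(sigma*Z)` with `g` uniform on 0.8–1.25 (a ±25%
between-screen technical spread) and `sigma = 0.1` by default; planted SL
entries are exactly 0, SS entries scale the null by U(0.05, 0.4), PE by
U(0.5, 0.8), and PS entries are `min(w_a, w_b)*(1+U(0.1, 0.5))` times
screen factor and noise — fitter than either single mutant predicts.
Missingness is uniform by default, with 10% as the default rate (presets
matching the published screens' 10.11%, 6.76% and 34.01% rates are a
`missing_rate` away); a `fitness_dependent` option filters low-fitness
entries preferentially (logistic in the entry value, rescaled to the
target rate), standing in for the unknown non-random filtering of real
screens. All draws come from one seeded stream, so screens are bit
reproducible.

What the generator does *not* emulate: replicate and plate/batch spatial
structure, linkage between neighboring genes, correlated interaction
modules, and the heavy custom normalization of real pipelines. Passing
closed-loop tests on these screens therefore demonstrates correctness of
the estimation and scoring machinery under the stated model, not
performance on any particular real dataset.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen to
exercise every code path while keeping a full run in the tens of seconds:
20 replicate screens of 200 arrays × 80 queries for the closed-loop
benchmarks; rank-one exactness checked on random matrices up to 200 × 100
over a 5 × 5 (p, q) grid; trimmed-regression optimality verified against
exhaustive h-subset enumeration on instances of up to 12 points. On these
screens the median Spearman correlation between estimated and true
single-mutant fitness is above 0.9, and decomposition-based product
scoring improves planted-PS detection over ranking the raw matrix by
about 0.1 AUC — the qualitative signature that motivates the method,
visible already at this scale.

Other fixed numerical choices: zero tolerance 1e-12 before any division
(entries falling below it become missing); the strict-majority negative
rule counts observed entries only; factor components from rows/columns
with fewer than 2 observations are undefined; writers serialize at 15
significant digits so read/write round trips are stable to 1e-12.

## Known limitations

* The scale calibration assumes at least one mutant screened both as
  array and as query with a nonnegative factor ratio; designs with
  disjoint sets cannot be calibrated and error out.
* Screen factors are identifiable only up to the median ratio `M`; when
  the technical factors vary widely, `w` absorbs a factor of
  `sqrt(median(g))`, which leaves rankings (and all ROC metrics)
  unchanged but shifts the absolute fitness scale.
* QMA's exactness argument applies to strictly positive matrices; on
  centered data the quantile-switching rule is a heuristic, and scaled
  epistasis is undefined wherever the estimated null product is
  non-positive.
* `arf()` with trimming is a stochastic optimizer; results are
  reproducible for a fixed seed but the trimmed optimum is only
  guaranteed on small instances where elemental starts are exhaustive.
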