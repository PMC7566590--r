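---
title: "Comparing spatial interaction models with count-data likelihoods"
author: "odmodels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing spatial interaction models with count-data likelihoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odmodels)
```

## The problem

An origin–destination flow dataset records, for every ordered pair of
distinct sites, a nonnegative integer count: how many commuters travel
from county *i* to county *j*, how many passengers fly between two
cities, how many infected hosts move between patches of a
metapopulation. Spatial interaction models predict these flows from a
handful of per-site quantities and the pairwise separations `d_ij`. Such
data have three awkward properties that drive every design decision in
this package: they are integers, they are overwhelmingly zeros and small
counts, and the in- and out-flows of an individual site can differ by
large factors (a dense employment centre receives far more commuters
than it sends). Measures that assume Gaussian residuals — `R²`, RMSE,
Pearson correlations — are poorly matched to the first two properties,
and symmetric models cannot express the third.

## The model family

All models here are *production constrained*: each site carries an
outflow parameter `t_i` and the predicted outflow `Σ_{j≠i} F̂_ij` equals
`t_i` (exactly, or nearly so — see below). Constraining production in
every model keeps the comparison fair: a difference in scores then
reflects how flow is *distributed* over destinations, not how well total
volume was guessed.

**Gravity.** `gravity_predict()` implements

```
F̂_ij = t_i n_j f(d_ij) / Σ_{k≠i} n_k f(d_ik)
```

with `f(d) = d^(-β)` or `exp(-β d)`. Two points deserve note. First, the
normalising sum excludes `k = i`: the diagonal distance is zero, so a
power-law kernel would be singular there, and only the `k ≠ i` reading
yields row sums exactly `t_i`. Second, because the kernel appears in a
ratio, the power-law model is invariant under rescaling all distances —
units (km vs miles) cannot affect predictions, and the tests assert
this. For real data the package follows the commuting convention
`t_i = O_i`, `n_i = I_i`.

**Radiation.** `radiation_predict()` implements

```
F̂_ij = t_i m_i n_j / ((m_i + s_ij)(m_i + n_j + s_ij))
```

where `s_ij` (`intervening_opportunities()`) is the total attractiveness
of sites strictly closer to *i* than *j*, excluding both endpoints. The
aspiration parameter `m_i` sets how far commuters from *i* travel; it
does not change the row total. When `m = n` and the distances from each
site are pairwise distinct, the row sum telescopes to
`t_i (N_c − m_i)/N_c` with `N_c = Σ n_i` — slightly short of `t_i`.
Multiplying row *i* by `N_c/(N_c − m_i)` (`normalised = TRUE`) restores
the constraint exactly; the factor is near 1 whenever `N_c ≫ m_i`.

**Variants.** The radiation site parameters must be mapped to data
values, and the choice matters more than the functional form.
`make_variant()` provides the eight standard mappings, from `A`
(`m = n = t = P`, the population-only original) through `E`
(`m = n = I`, `t = O`, normalised) to the fitted-factor versions `F`,
`G`, `H` with `t = αP` or `αO`. Variant `D` (`m = O`, `n = I`) is
implemented deliberately although it fits data catastrophically badly:
it transplants the gravity intuition "source parameters repel, target
parameters attract" into a model derived under different assumptions,
and its failure is a useful regression check that the framework
penalises an unjustified parameter split.

## Likelihood, BIC, deviance

`poisson_loglik()` scores a model by treating each observed flow as a
Poisson draw with mean `F̂_ij`. Both model families are microscopically
consistent with this: gravity flows arise from entropy-maximising
placement of discrete trips, radiation flows from independent
per-commuter destination choices. The sum runs over ordered pairs with
`F_ij > F_min` — the step is strict, so `f_min = 0` *excludes* the zero
flows, and the sentinel `f_min = -1` (`"include-zeros"`) includes every
pair. Truncation answers a specific worry: with mostly-zero data, a
model could score well merely by predicting zeros well; re-scoring at
`F_min` of 10, 100, 1000 checks whether the ranking is an artefact of
the zeros. `ln F!` uses `lgamma` throughout, so large counts cannot
overflow.

Predictions must be strictly positive on every included pair; a zero
prediction where flow was observed (possible when a marginal used as an
attractiveness is zero) is a data/model inconsistency and raises an
error rather than returning `-Inf`, which in batch evaluation
(`evaluate_models()`) is recorded per model without aborting the run.

`bic_score()` adds the `k ln(n)` parameter penalty. What counts as `n`
is genuinely ambiguous for flow data — the number of included ordered
pairs, or the number of sites? The package defaults to included pairs
(`bic_n = "pairs"`, the literal "number of data points") and offers
`bic_n = "sites"`; with thousands of sites either penalty is a few tens
of units against log-likelihood differences of order 10⁵–10⁷, so the
choice never reorders models with equal `k`, and the mode used is
recorded in every result.

`flow_deviance()` gives an absolute scale: `D = 2(ln L_s − ln L)` where
the saturated likelihood `L_s` (`saturated_loglik()`) is the best any
model could do on those pairs. The identity between the direct deviance
sum and the two-likelihood difference is asserted to 1e-9 against naive
per-pair loop oracles in the tests.

`dice_coefficient()` and `r_squared()` are provided because the field
uses them, with a caveat the README's worked example makes concrete: a
grossly overpredicting model saturates `min(F̂, F)` and can top the DSC
ranking while being worst by likelihood.

## Fitting and standard errors

The fitted-factor variants are linear in `α`, so the MLE has the closed
form `α̂ = ΣF / ΣF̂⁰` with exact Hessian standard error `α̂/√(ΣF)`
(`fit_alpha()`); the tests confirm the closed form against a numerical
1-D maximisation to 1e-6.

The gravity exponent is fitted by bounded golden-section/parabolic
search (`stats::optimize`) on `β ∈ [0.001, 20]` with tolerance 1e-6 — a
bracket comfortably containing every deterrence exponent reported for
mobility data. An optimum within 0.01 of a bound is flagged and warned
about, never silently accepted: flows with no distance dependence
legitimately drive `β̂` to the lower bound, and the flag is the signal to
reconsider the model. The standard error uses a central finite-difference
second derivative with step `1e-4·max(1, |β̂|)`; for `α` the analytic
Hessian is available, for `β` it is not, and the finite-difference
curvature of a smooth 1-D likelihood at this step size is accurate far
beyond the reported digits.

## Ties in the intervening opportunities

The step function in `s_ij` is strict, so two sites at exactly equal
distance from *i* do not count toward each other's intervening mass — and
the telescoping row-sum identity then fails for those rows. Continuous
random coordinates never tie; gridded or heavily rounded data can.
`intervening_opportunities()` detects exact ties and warns;
`jitter_distances()` offers a seeded, symmetric perturbation (default
1e-9 km) as an explicit opt-in tie-break rather than a silent default,
so that results on tied data are never quietly order-dependent.

## The synthetic generator

`generate_system()` exists so that every statistical claim in the
package can be exercised without downloading census tables. It emulates
the structure of county-level commuting data with the simplest
mechanisms that produce it:

* **Heavy-tailed populations**: lognormal with `meanlog = 8`,
  `sdlog = 1.5` — the two-decade spread of US county populations at a
  median of ~3,000 persons, scaled down to a 200-site system — floored
  at 100 persons, roughly the smallest inhabited counties. The floor
  also guarantees positive realised marginals, without which the
  variants that use `O` or `I` as attractiveness are undefined.
* **Geography**: uniform positions on a 1000 km square with Euclidean
  distances (default), or a lat/lon box with great-circle distances.
* **Flows**: a ground-truth model (gravity with `β = 2` by default —
  the middle of the range reported for commuting — or a radiation
  truth), with `t_i = round(0.1 · P_i)`: about one resident in ten
  commutes out of their site, the order of the inter-county share in US
  data. Observed flows are independent Poisson draws from the predicted
  means.
* **Realised marginals**: the sampled row and column sums are written
  back into the site table as `O_i`, `I_i`. Fitting therefore consumes
  *data* values, exactly as with a real census table, not the latent
  truth parameters.

At these defaults roughly 70% of ordered pairs are zero, the flow-size
distribution is strongly right-skewed, and dozens of sites have in-flow
more than double their out-flow or vice versa — the qualitative
fingerprint of real commuter matrices. What the generator does *not*
reproduce: spatially correlated population fields (cities cluster),
within-site flows, reporting artefacts of survey data, or the exact
census flow histogram. Passing recovery tests on this generator
therefore demonstrates the correctness and calibration of the
estimators under the stated model, not that any model fits real
commuting data well — on real data all of these models fit poorly in
the absolute deviance sense, which is precisely what the deviance scale
is for.

All randomness is seeded: the configuration seed is mandatory, each
pipeline stage derives its own sub-seed deterministically, and the tests
assert byte-identical regeneration.

## The recovery protocol

`run_recover()` refits the *generating* model family to each simulated
realisation: for a gravity truth, `β` is refitted with `t` = realised
out-flows and `n` = the truth's attractiveness (the populations). The
alternative — refitting with the commuting convention `n = I` — uses a
noisy realisation of the attractiveness and measurably attenuates the
exponent (the acceptance report's `gravity_beta_hat_default_system`,
fitted with `n = I`, sits well below the truth of 2 while the recovery
estimates straddle it). A recovery experiment asks whether the estimator
is correct and its standard error calibrated, which requires the
correctly specified refit; the errors-in-attractiveness bias is a
property of real-data fitting that the default `fit_beta()` convention
deliberately shares. Over 20 replicates at 200 sites the package's
acceptance suite checks every estimate within 3 standard errors, the
mean within 2%, and the replicate scatter within a factor 2 of the
reported standard error.

## Problem sizes and numerical conventions

Dense matrices are used throughout; at the 3,109 sites of a national
county system the largest objects are ~77 MB and a full nine-model
evaluation is minutes of work, so no out-of-core path is provided (the
practical ceiling is around 5,000 sites). The test suite runs its
property checks on systems of 10–50 sites, parameter recovery on 20
replicates of 200 sites and model selection on 20 replicates of 100
sites — sizes at which every experiment completes in seconds while
standard errors remain tight enough for the 3-SE and 2% assertions to
have teeth. Relative tolerances of 1e-9 are used for algebraic
identities (row sums, deviance identity, oracle equivalence), 1e-6 for
optimiser agreement, matching the optimizer's own tolerance.

Degenerate inputs follow one rule: silently produce nothing. Zero
inter-site distance under a power-law kernel, all-zero attractiveness
seen from an active site, `m_i = 0` with `t_i > 0`, `m_i ≥ N_c` under
normalisation, and zero predictions on included pairs all raise classed
errors (`od_data_error` / `od_numeric_error`) that the CLI maps to
distinct exit codes; `m_i = 0` with `t_i = 0` is a valid inactive site.

## Limitations

* Input (attraction) constraints are not implemented — all models here
  are production constrained only, which suffices for comparing the
  families on an equal footing.
* Only power-law and exponential deterrence kernels are built in.
* The likelihood treats pairs as independent Poisson; overdispersion
  and zero-inflation beyond the model mean are not modelled, so the
  deviance measures misfit relative to the Poisson ideal.
* No multiplicity correction is applied when many models are compared;
  the scores are descriptive rankings, not simultaneous tests.
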