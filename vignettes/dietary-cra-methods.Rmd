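---
title: "Methods: comparative risk assessment of dietary risk factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative risk assessment of dietary risk factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietcra)
```

## The model

`dietcra` implements a desk-scale comparative risk assessment (CRA) of
dietary risk factors for non-communicable disease burden. For a risk factor
with stratum exposure density $P_{ast}(x)$ (age $a$, sex $s$, year $t$),
relative-risk curve $RR_{as}(x)$ and theoretical minimum risk exposure level
(TMREL), the population attributable fraction for one diet–disease pair is

$$
PAF_{ast} \;=\;
\frac{\int_{l}^{u} RR_{as}(x)\,P_{ast}(x)\,dx \;-\; RR_{as}(\mathrm{TMREL})}
     {\int_{l}^{u} RR_{as}(x)\,P_{ast}(x)\,dx},
$$

and the total attributable burden in a stratum sums disease-specific PAFs
against their burden envelopes:

$$
\text{Total attributable burden}_{ast}
  \;=\; \sum_{o=1}^{w} \text{Burden}_{oast}\, PAF_{oast}.
$$

Curves are normalized so that $RR(\mathrm{TMREL}) = 1$; the PAF then reduces
to $1 - 1/\mathbb{E}[RR]$, which lies in $[0, 1)$ for capped curves. Without
this normalization the numerator above is not the conventional attributable
fraction, so the package treats the anchoring as part of the curve contract:
`evaluate_rr()` takes the TMREL at evaluation time and returns exactly 1
there.

### Relative-risk curves

Curves are log-linear in exposure: $RR(x) = \exp\{\beta\,\mathrm{excess}(x)\}$,
where $\mathrm{excess}(x)$ is the signed distance from the TMREL on the
harmful side ($x - \mathrm{TMREL}$ for "diet high in X" risks,
$\mathrm{TMREL} - x$ for "diet low in X" risks), clamped at zero on the
no-excess-risk side when `cap_at_tmrel = TRUE` (the default), giving a
monotone plateau at $RR = 1$. The log-linear form is the standard CRA
working assumption for per-unit relative risks pooled from meta-analyses.

Two risks are quantified indirectly, because direct outcome evidence is
weak: sodium acts through systolic blood pressure (SBP) and sugar-sweetened
beverages through body mass index (BMI). `mediation_chain()` composes an
exposure-to-mediator slope (e.g. mmHg per g/day of sodium) with a log-linear
RR curve on the mediator-change scale, so the effective log-RR per exposure
unit is `slope * mediator_log_rr`. The composed curve is anchored at the
TMREL exactly like a direct curve and enters the PAF integral unchanged.

### Exposure distributions

Intakes are right-skewed, so the default family is lognormal, parameterized
by the stratum mean and standard deviation; gamma and truncated normal are
selectable per risk. The integration bounds $l, u$ are the 0.001 and 0.999
quantiles of the fitted distribution (config-overridable), and the density
is renormalized on $[l, u]$ so it integrates to one. Both choices are
package decisions: the source framework defers to ensemble distributions
and leaves the bounds undefined, and a single conventional family keeps the
ground-truth bookkeeping exact.

### TMREL uncertainty

The TMREL carries a uniform uncertainty band of 20% below and above the
mean optimal intake; `param_tmrel(m)` samples uniformly on $[0.8m, 1.2m]$.

## Exposure estimation: the two-component cascade

Survey data are sparse: in the motivating application the fraction of
countries with any data (the data representativeness index) ranged from 17%
to 94% by risk. Estimation therefore borrows strength down a four-level
location hierarchy (global, super-region, region, country) in two
components:

1. **Global meta-regression** (`fit_global()`): an inverse-variance-weighted
   linear fit of reported stratum means on sex, age-group midpoint, year and
   covariates, with weights $1/SE^2$. Residual heterogeneity beyond the
   stated sampling errors is estimated by a method-of-moments
   $\hat\tau^2 = \max\{0, \overline{w(r^2 - SE^2)}\}$ and folded into
   prediction uncertainty.
2. **Cascade** (`cascade_fit()`): walking the hierarchy top-down, each node
   combines its parent's estimate — as a prior with variance
   $\sigma_{parent}^2 / \kappa$ (prior strength $\kappa$, default 1,
   config-overridable; the original framework does not state its weighting)
   — with the inverse-variance-weighted mean of the survey rows in that
   node's subtree, restricted to one sex-age-year cell at a time. Nodes
   without subtree data inherit the parent estimate unchanged and record
   the level that informed them (`source_level`).

One subtlety matters: the parent's posterior is built from the same subtree
data its children will use, so passing it down at full precision would
double-count those data and swamp the local signal. The cascade therefore
inflates the prior handed to each child by the between-location
heterogeneity, $\sigma_{prior}^2 = \sigma_{parent}^2 + \hat\tau^2$. This
keeps the prior honest about how much a parent mean says about any one
child, makes the noise-free limit exact (with error-free surveys the local
data dominate at every level and estimates equal truth), and gives
downstream uncertainty intervals close-to-nominal coverage.

Two standardization steps precede pooling. Energy adjustment
(`energy_adjust()`) uses the residual method at 2000 kcal/day: intake is
regressed on total energy and each observation is reported as its residual
plus the predicted intake at 2000 kcal/day; the operation is the identity
once all observations sit at the target energy. Dietary sodium is converted
to 24-h urinary-equivalent units by a multiplier estimated as the
through-origin least-squares slope of urinary on dietary sodium across
surveys reporting both (`estimate_sodium_multiplier()`); through-origin
regression is the canonical estimator of a proportional conversion. The
same mechanism serves industry-data calibration (e.g. trans-fat
availability against gold-standard surveys) given a config-supplied pair
set.

## Multi-risk combination

PAFs for several risks acting on one outcome-stratum combine under
independence as $1 - \prod_i (1 - PAF_i)$. Summed single-risk percentages
therefore exceed the all-risk total whenever risks overlap — the combined
value never exceeds $\sum_i PAF_i$ and never falls below $\max_i PAF_i$.
Mediation matrices between dietary and metabolic risks are out of scope.

## Numerical choices

- **Quadrature**: Gauss–Legendre on $[l, u]$, 256 nodes by default,
  refined by node doubling (up to 4096) until $\mathbb{E}[RR]$ is stable to
  $10^{-8}$. The integrand (log-linear RR times a smooth unimodal density)
  is analytic on the support, so 256 nodes are already near machine
  precision; inside Monte Carlo loops refinement is disabled and the node
  count fixed, which keeps the draw path and the deterministic path in
  exact agreement when parameter uncertainty is zero.
- **Degenerate inputs**: a stratum with `sd = 0` is an explicit point mass;
  its "integral" is $RR(\mu)$, so exposure concentrated at the TMREL gives
  PAF 0. A flat curve ($\beta = 0$) gives PAF 0 for any distribution.
  `combine_pafs()` treats any input of exactly 1 as degenerate and flags it.
- **Rounding**: all internal arithmetic is unrounded. Report formatting
  rounds counts and rates to integers and percentages to one decimal, in
  that order, at the very end. `flag_inconsistent_changes()` recomputes
  every change cell from its own start/end columns and flags printed cells
  that cannot be recovered from their printed neighbors (published tables
  contain such cells; the package recomputes from unrounded values and
  flags rather than targets them).
- **Ties and ordering**: uncertainty intervals use empirical 2.5th/97.5th
  percentiles with linear interpolation (quantile type 7); skewed draws may
  legally place the mean outside the interval midpoint.

## Monte Carlo uncertainty

All uncertain parameters — exposure means (normal around the posterior
mean), log-RRs and mediator components (normal around the pooled estimate),
TMRELs (uniform on the 20% band) — are drawn 1000 times by default, one
draw of each parameter per iteration, and every downstream quantity is
recomputed per draw; means and 95% uncertainty intervals come from the
final draws. Three design choices:

- **Named streams**: one root seed; each parameter's stream seed derives
  deterministically from a hash of the parameter's name. Regeneration is
  bit-identical, insensitive to declaration order, and any parameter shared
  between computations (the same RR or TMREL in 1990 and 2013) reuses the
  same draw vector, so period contrasts are properly correlated — the
  conservative choice for differences.
- **Envelopes**: burden envelopes are treated as fixed inputs unless their
  own uncertainty is supplied; envelope sampling would be independent of
  the PAF draws.
- **Draw count**: 1000 draws for production runs; the test-suite and
  acceptance replicate loops use 250 (coverage checks) and 10–100
  (smoke/trend checks), sizes chosen so the whole suite runs on a single
  CPU in a few minutes while leaving percentile estimates stable to well
  under a percentage point.

## The synthetic world

`generate_world()` emulates the data landscape the estimator faces: a
4-level hierarchy (default 2 super-regions x 2 regions x 3 countries),
true country means equal to region means times lognormal noise (sdlog 0.15
regional, 0.10 country), a mild deterministic age profile and sex ratio,
right-skewed intakes (lognormal, CV 0.4), survey coverage fractions
spanning 17%–94% of countries by risk, survey standard errors
$CV \cdot \mu / \sqrt{n}$ (n = 200 by default), and multiplicative burden
envelopes (population pyramid times age-graded cause rates, with all-NCD
and all-cause aggregates for proportion denominators). Default risks cover
both directions and the mediation mechanism: fruits and vegetables
(harmful-low), red meat (harmful-high, direct), sodium (harmful-high,
mediated through SBP). The bundle's ground-truth table holds the exact
quadrature PAF for every pair-stratum, computed from the true parameters,
so the bundle is self-consistent by construction.

Two-period worlds add a multiplicative exposure drift per year, population
growth (default 1.03/yr) and age-specific envelope-rate drift (default
0.99/yr) — enough to reproduce the qualitative pattern of rising
attributable counts with falling crude rates. `calibrate_world_counts()`
rescales one metric's envelopes so the pipeline's attributable totals hit
given values; PAFs are unchanged by envelope scaling, so calibrated worlds
reproduce a target period change exactly.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: real survey instruments and their biases (recall
error, seasonality, household-to-individual conversion), non-lognormal
intake shapes, covariate-driven country adjustments, correlated dietary
risks (fruit and vegetable intakes correlate in practice; combination
assumes independence), and outcome-specific TMRELs.

## Known limitations

- The cascade is a two-level-of-information approximation (parent prior +
  local data) to a full Bayesian hierarchical meta-regression; it preserves
  the borrow-strength semantics, not the machinery (no MCMC, no age-pattern
  splines, no covariate selection).
- Envelope metrics are inputs; DALYs are not rebuilt from YLL + YLD
  internals and no comorbidity correction is applied.
- The independence combination overstates the combined PAF when risks are
  positively correlated.
- Age-standardization defaults to equal weights over the modeled age
  groups (any weight vector is accepted); published age-standardized rows
  built on an unstated standard population are not numerically comparable.
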