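---
title: "Methods: diversity effects, community traits and water use in grass-legume mesocosms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity effects, community traits and water use in grass-legume mesocosms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swardiv)
```

## The experimental system

swardiv analyses pot-scale grassland diversity experiments: large
outdoor containers planted with monocultures and mixtures of perennial
grasses and a legume (white clover), cut repeatedly over one or more
growing seasons. The default design enumerates 5 monocultures (4
replicates each), all 10 two-species mixtures and the single
five-species mixture (3 replicates each) — 53 pots — over six biomass
production periods spanning two calendar years. Pots are watered to a
setpoint of 80% of field capacity, weighed daily, and sampled for leaf
and root traits.

Dates are stored as (year index, day of year) pairs so the
autumn-to-spring period that wraps around the new year stays
representable; interval arithmetic maps them to an absolute day index on
a fixed 365-day year. At the temporal resolution of the analysis
(periods of 30-120 days) leap days are irrelevant, and a fixed-length
year keeps the mapping exactly invertible.

## The additive partition

The central statistic is the additive partition of the net diversity
effect. With observed mixture biomass $Y_i$, monoculture reference $M_i$
(the mean over monoculture replicate pots for that period) and expected
proportion $p_i$, the relative-yield deviation is
$\Delta RY_i = Y_i/M_i - p_i$ and

$$\text{net} = \sum_i (Y_i - M_i p_i), \qquad
  CE = N\,\overline{\Delta RY}\,\overline{M}, \qquad
  SE = N\,\mathrm{cov}(\Delta RY, M),$$

where the covariance uses divisor $N$ (population form). This choice is
not cosmetic: with divisor $N$ the identity $\text{net} = CE + SE$ holds
algebraically, term by term, which the test suite verifies to $10^{-10}$
relative tolerance on random instances. A sample covariance (divisor
$N-1$) would break the identity.

Two conventions were genuinely open and are exposed as options:

* **Expected proportion.** The expectation $M_i p_i$ can use the *sown*
  proportion (equal shares at establishment) or the species' *realized*
  share of mixture biomass. The sown proportion is the default: it is
  the standard convention for the additive partition, matches equal-
  proportion planting, and keeps the expectation independent of the
  outcome it is compared against. Every output row carries the
  convention label.
* **Averaging unit.** Replicate pots of a composition are averaged
  before partitioning (per-composition default); a per-pot variant is
  available through the same function. Averaging first reduces the
  noise in the ratio $Y_i/M_i$ and mirrors how treatment means are
  reported.

Zero observed biomass of a species in a mixture is legal
($\Delta RY_i = -p_i$); a non-positive monoculture mean is an error,
since the relative yield is then undefined. Proportional deviations
$D = (\text{obs} - \text{exp})/\text{exp}$ are computed per species and
pooled over the grass and legume groups by summing biomass within the
group before dividing (the pooled convention weights species by their
expected biomass, so the full-group deviation closes exactly with the
net effect).

## Community traits

Community-weighted means use trait-specific abundance weights: species
share of total biomass for LDMC, of green-leaf biomass for N, and of
leaf area (biomass × SLA) for δ¹³C. Traits without a stated convention
default to total-biomass weights and are flagged (`default_rule`) in the
output; variables measured directly at community level (leaf area, WUE,
Nyield/ET, REW, deep-root growth) pass through unweighted.

Functional diversity is Rao's quadratic entropy
$FD_Q = \sum_i \sum_j p_i p_j d_{ij}$ over six species-level traits
(top-layer biomass share, δ¹³C, height growth, leaf area, LDMC, N). The
dissimilarity is Gower distance on range-standardized traits, giving
$d_{ij} \in [0,1]$; half the squared Euclidean distance on z-scores is
available as an alternative, and the convention label travels with every
result. Constant trait columns carry no information under range
standardization and are dropped with a warning. $FD_Q = 0$ for
monocultures by construction.

## Water and nitrogen metrics

Daily evapotranspiration is recovered from weighed pots by mass
balance, $ET_t = (W_{t-1} - W_t) + \text{additions}_t$. Negative
corrected values (condensation, weighing error) are clipped to zero and
counted — the clip count is exposed so a pipeline can report data
quality rather than silently absorbing it.

Relative extractable water rescales gravimetric moisture between a
drought minimum and a well-watered maximum; the defaults (0.054, 0.379)
are calibration constants for a granitic brown grassland soil in 100 L
pots. Because the minimum comes from external calibration, observed
moisture may leave the interval, so REW clips to [0, 1] with a warning
instead of erroring. REW is invariant to affine rescaling of moisture
and bounds together, which the tests check.

Growth-rate statistics divide the increase between consecutive
measurements by the interval length. An interval is assigned to the
period containing its *end* date — growth is realized by the time it is
measured. Root length from minirhizotron images is cumulative growth, so
negative increments (root disappearance between images) are floored at
zero before the rate is formed; height increments may be negative, but
the reported statistic is the per-period maximum, so transient declines
do not propagate.

## Trait-based model selection

Community biomass, the net effect and the complementarity effect are
regressed on ten community variables. The model space is every subset of
up to five predictors (the cap reflects the point at which additional
variables stop improving fit in this class of data, and is
configurable). Each subset is scored by exact leave-one-out
cross-validation using the hat-matrix identity
$e_{(i)} = e_i/(1 - h_{ii})$ — identical to refitting $n$ times (tested
to $10^{-10}$) at a fraction of the cost. Leverages numerically at 1 and
rank-deficient subsets are excluded. Ties prefer the smaller subset,
then lexicographic order, so selection is deterministic.

Relative importance of the selected predictors is computed two ways:

* **LMG** averages each predictor's sequential $R^2$ increment over all
  $k!$ orderings with equal weights (implemented through the
  subset-size weighting identity, $2^k$ regressions instead of $k!$
  scans; an ordering-enumeration oracle in the tests confirms
  equivalence).
* **PMVD** weights each ordering proportionally to the product over its
  prefixes of the reciprocal remaining contribution. This gives
  predictors with zero partial and zero incremental contribution a
  share tending to zero — the exclusion property LMG lacks.
  Denominators are regularized with $\varepsilon = 10^{-12}$; if the
  weights still degenerate the function falls back to LMG with a
  warning.

Both decompositions sum to the full-model $R^2$; the reported
"% of R²" normalizes shares to the model $R^2$ (each block sums to
100%), not to total variance. Ordering enumeration is capped at $k = 8$;
larger subsets would need ordering sampling, which is deliberately not
implemented — the selection cap makes it unreachable in normal use.

Rows of the predictor matrix are composition means by default (pots of a
composition averaged, then periods averaged for the whole-experiment
scope; responses summed over periods). A per-pot variant exists for
sensitivity analysis. Columns are standardized to zero mean and unit
variance; the constants are recorded so coefficients can be mapped back.

## The synthetic generator

The generator is first-class, tested code: it defines the conditions
under which the analysis stack is validated.

* **Yields.** Species monoculture yield profiles follow published
  treatment means for this design: grass monocultures peak in early
  summer of year 1 and decline; the clover establishes slowly and
  overtakes the grasses from autumn of year 1.
* **Interactions.** Mixture biomass is
  `mono_yield x sown proportion x multipliers x noise`. The multipliers
  encode (i) a symmetric complementarity surplus (default +15% relative
  yield), (ii) a facilitation ramp on grasses grown with the legume,
  zero in the first two periods and rising to +60% by spring of year 2
  (the late onset of legume effects), and (iii) an early suppression of
  the legume in mixtures (0.35 rising to 1.0), squared in the
  five-species mixture where competition from four grasses slows
  establishment further. With these defaults the two-species
  grass-clover swards move from slight under-yielding to a net effect
  of roughly +30 g per pot carried by complementarity, with selection
  nil or negative — the qualitative and quantitative regime the design
  is meant to emulate.
* **Noise.** Pot-level species biomass gets multiplicative mean-one
  lognormal noise (default CV 0.15). Biomass is positive and its
  dispersion roughly scale-free, which makes the lognormal the natural
  error model; no pot-level variance components are published for this
  class of experiment, so the CV is an exposed parameter, not a
  calibrated claim.
* **Water.** A per-pot bucket model: drawdown proportional to the
  noise-free community leaf area (0.5 kg m⁻² day⁻¹, which places
  integrated WUE near 3 g dry mass per kg water, typical for temperate
  grassland mesocosms), refilled to the 80%-of-field-capacity setpoint
  every second day, with every addition logged. Weights are tare plus
  soil water, so daily ET recovered from weights and additions closes
  the mass balance to machine precision — an invariant the tests
  assert at $10^{-9}$ kg. Sensor soil water content at three depths
  shifts uptake toward 50 cm in legume-containing pots as the
  experiment progresses.
* **Ground truth.** The noise-free expected biomass per composition and
  period is partitioned with the same additive-partition code path
  against the true monoculture baselines, giving exact injected
  net/CE/SE values for recovery tests. With neutral interactions and
  zero noise every diversity effect is exactly zero downstream.
* **Seeding.** One master seed; per-pot child seeds are derived
  deterministically (a fixed linear-congruential hash), so regenerating
  with the same specification is hash-stable file for file, and
  results do not depend on pot iteration order.

**What the generator does not emulate:** soil physics (no Richards-type
water movement, no evaporation separate from transpiration), weather,
isotope chemistry, spatial structure among pots, species turnover, or
measurement-instrument error structure beyond i.i.d. noise. Passing
recovery tests therefore demonstrates that the estimators are correct
and unbiased *under the stated statistical model*, not that real
mesocosm data meet that model.

## Numerical choices and degenerate inputs

* Population covariance in the selection effect (identity-preserving).
* REW and negative-ET clipping warn and count rather than error.
* Gower range standardization uses the range within the community being
  scored; constant columns are dropped with a warning.
* LOO-CV guards leverage $h_{ii} > 1 - 10^{-10}$; such subsets score
  `Inf` and cannot win selection.
* PMVD denominators floored at $10^{-12}$; degenerate-weight fallback
  to LMG is warned and counted in the pipeline manifest.
* A period containing no growth-rate interval yields `NA`, not an
  error; a missing monoculture reference is an error naming species and
  period, because no partition is defined without it.
* Zero total biomass makes the top-layer percentage `NA` (undefined),
  not zero.

## Validation problem sizes

The test suite validates the partition identity on 1,000 random
instances (2-8 species), Rao's Q against a double-loop oracle on 100
random five-species communities, LOO-CV against literal refitting on 50
random instances, LMG against full ordering enumeration for subsets up
to size 5, complementarity recovery over 200 replicate datasets at the
full 53-pot design, and planted-signal selection (two active traits at
population $R^2 = 0.9$, $n = 30$) over 200 replicates. These sizes give
Monte-Carlo standard errors small enough for 3-standard-error recovery
bounds while keeping the default suite quick to run.

## Known limitations

* The monoculture reference is a plain mean over replicates; no
  shrinkage or uncertainty propagation into the partition (a percentile
  bootstrap over replicate pots is the intended plumbing for interval
  estimates).
* Model selection is ordinary least squares on community means; the
  mixed-model structure appropriate for nested designs is out of scope
  here, as are significance tests on individual coefficients.
* The exact abundance and standardization conventions behind published
  functional-diversity values vary between studies; swardiv records its
  convention in every output rather than asserting comparability.
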