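# swardiv

Analysis toolkit for pot-scale (mesocosm) grassland diversity experiments
that mix grasses with a legume. It is aimed at plant community ecologists
who measure per-species biomass over repeated cuts, daily pot weights and
soil moisture, and species traits, and who want to answer the classic
biodiversity–ecosystem-function questions: does the mixture over-yield,
is the over-yielding driven by complementarity or by selection, and which
community traits predict it?

## What it computes

**Diversity-effect partition.** For a mixture with observed species
biomass Y\_i, monoculture reference M\_i and expected proportion p\_i,
the relative-yield deviation is ΔRY\_i = Y\_i/M\_i − p\_i and

    net effect       = Σ(Y_i − M_i p_i)
    complementarity  = N · mean(ΔRY) · mean(M)
    selection        = N · cov(ΔRY, M)          (covariance with divisor N)

so that net = CE + SE is an algebraic identity. Proportional deviations
D\_i = (observed − expected)/expected are reported per species and pooled
over the grass and legume groups (D\_Grass, D\_Leg).

**Community traits.** Community-weighted means CWM = Σ p\_i t\_i with
trait-specific abundance weights (total biomass for LDMC, green-leaf
biomass for N, leaf area for δ¹³C), and functional diversity as Rao's
quadratic entropy FD\_Q = Σ Σ p\_i p\_j d\_ij on Gower distances over
range-standardized traits.

**Resource-use metrics.** Daily evapotranspiration from weighed pots by
mass balance (ET\_t = ΔW + additions), relative extractable water
REW = (SM − SM\_min)/(SM\_max − SM\_min), water-use efficiency
WUE = biomass/ET, nitrogen yield and Nyield/ET, community leaf area from
biomass × SLA, per-period maxima of height and deep-root growth rates,
and the top-canopy-layer biomass percentage.

**Trait-based model selection.** Exhaustive best-subset ordinary least
squares over the ten community variables, scored by exact leave-one-out
cross-validation (hat-matrix identity), with relative importance of the
selected predictors by ordering-averaged variance decomposition — both
equal-weight (LMG) and proportional marginal variance decomposition
(PMVD) with data-dependent ordering weights.

**Synthetic-data generator.** A seeded simulator of the canonical 53-pot
design (5 monocultures × 4 replicates, 10 pairs × 3, one five-species
mixture × 3; six cutting periods over two years) with a time-ramped
legume facilitation of neighbouring grasses, early legume suppression, a
symmetric complementarity surplus, lognormal biomass noise, and
bucket-model soil-water dynamics that close the water balance exactly.
The generator returns the noise-free ground-truth partition, enabling
parameter-recovery tests.

## Worked example

```r
library(swardiv)

# partition one two-species mixture cut
part <- additive_partition(
  observed    = c(dg = 38.1, tr = 70.4),   # g per pot in the mixture
  mono_means  = c(dg = 60.1, tr = 118.3),  # monoculture references
  proportions = c(dg = 0.5, tr = 0.5))     # sown shares
part
#> <partition> N = 2 | net 19.300 = complementarity 20.430 + selection -1.130 (g pot^-1)
```

The mixture over-yields by 19.3 g per pot; the surplus is carried by
complementarity (+20.4 g), with a slightly negative selection component:
both species beat their monoculture expectation rather than one dominant
species taking over.

```r
# full synthetic run: design, generation, metrics, partition, models
res <- run_pipeline(default_config(seed = 42, output_dir = "run42"))
subset(res$diversity_effects$sward_means, sward_type == "2+")
#>    sward_type  period  net_g   ce_g   se_g
#> 2          2+ 102-161  33.45  45.78 -12.33
#> 5          2+ 113-143  -2.67 -13.37  10.71
#> 8          2+ 144-190 -28.71 -24.68  -4.04
#> 11         2+ 191-224  -1.11   4.31  -5.42
#> 14         2+ 225-280   5.46  16.54 -11.07
#> 17         2+ 281-101  24.16  30.17  -6.01
```

Grass–legume pairs (sward `2+`) under-yield while the legume establishes
(first three periods), then over-yield increasingly from autumn of year 1
(`225-280`) to spring of year 2 (`102-161`), driven by a positive
complementarity effect with the selection effect nil or negative — the
time-dependence the generator's facilitation ramp injects.

```r
res$reports[[1]]
#> <selection_report> biomass: R2 = 0.976
#>   Nyield.ET   38.4 % of R2
#>   REW         33.4 % of R2
#>   N           23.5 % of R2
#>   L.area       3.4 % of R2
#>   H.growth     1.4 % of R2
```

The best five-trait model for community biomass (selected by LOO-CV over
all subsets of the ten community variables) explains 97.6% of variance;
the PMVD column gives each selected trait's share of that R².

A thin command-line wrapper with verbs `generate`, `analyze`, `run` and
`validate` is installed under `inst/cli/swardiv.R`.

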