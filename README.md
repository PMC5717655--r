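# huddlesim

Newborn rodents huddle because they must: heat generated in brown adipose
tissue (BAT) is expensive, and piling together cuts the cost of keeping warm.
Yet mice and rats keep huddling long after they can sustain a basal metabolism
alone, guided by smell rather than temperature. `huddlesim` implements a
developmental model of how this *filial* huddling can emerge from the earlier
*physiological* huddling: thermally rewarding contacts, experienced while BAT
thermogenesis peaks, condition olfactory preferences among littermates that
keep the huddle together after the thermal payoff is gone.

The package is aimed at computational ethologists and developmental
physiologists who want to simulate the model, explore its parameters, or test
parameter-recovery pipelines against synthetic developmental data.

## The model

Three coupled layers, with calibrated constants
`k = 8.31, c = 19, c1 = 3, c2 = 0.025, Tp = 36 °C, β = 0.2, γ = 0.001, n = 7`:

**Thermal physiology** (closed forms in postnatal day *t*):

- BAT fraction `P = e^(−t/k)` decays from birth with time constant `k`;
- metabolic entropy `S = −kP ln P` and mass-specific metabolic rate
  `G = k(1 + S)` (cal g⁻¹ h⁻¹), which peaks at `t = k ≈ 8.31` days;
- muscle mass `M = k(1 − P)`, non-muscle mass `N = c·e^(−kT₁)`, total
  `W = M + N`;
- preferred-temperature deviations `T₁ = c₁P` (warm-seeking) and
  `T₂ = c₂GN` (cool-seeking): animals settle at `Tp + T₁` early and
  `Tp − T₂` late, switching near day 16.5;
- huddling drive `T = β(T₁ − T₂)`, positive at birth, negative in adulthood.

**Monte Carlo group formation.** The litter is a set partition of `n` pups
into contact groups. Each encounter picks a pup `a` at random and a partner
`b` from another group, then merges their groups with probability
`ρ = (1 + e^(−T))⁻¹`, or else detaches `a` into a singleton. For small
litters the package also builds the exact Markov transition matrix over set
partitions and its stationary distribution, as a reference for simulated
chains.

**Odour-heat conditioning.** Each pup holds a directed associative strength
`α[a,b]` for each littermate's odour. Encounters are conditioning trials: the
pairwise drive is `α[b,a]·(T₁ − T₂)·β`, and the initiator's association moves
by the Delta rule `Δα[a,b] = γ(r − Σᵢ α[a,i])` with reward `r = 1` when the
groups combine. The compound sum keeps total associative strength bounded and
holds the late-development system near the critical regime `ρ ≈ 0.5`, where
learnt preferences — not thermodynamics — sustain large huddles.

## Worked example

```r
library(huddlesim)

physiology_curves(days = c(0, 8, 15, 30, 60))[, c("day","P","G","W","selected_temp","drive")]
#>     day        P     G        W selected_temp   drive
#> 1     0 1         8.31 2.83e-10          39    0.600
#> 2     8 0.382    33.7  5.14e+ 0          37.1  0.229
#> 3    15 0.164    28.8  7.26e+ 0          36.5  0.0533
#> 4    30 0.0270   15.1  1.78e+ 1          32.4 -0.712
#> 5    60 0.000732  8.67 2.70e+ 1          32.0 -0.809

metabolic_peak_day()      # 8.31  — metabolic rate peaks at the BAT time constant
temperature_switch_day()  # 16.45853 — warm-seeking gives way to cool-seeking
```

The neonate prefers 39 °C and has a strong drive to huddle (0.6); by day 60
the preference has fallen to ~32 °C and the drive is firmly negative (−0.81).
Note `W(0) ≈ 3e−10` g: the growth curve is a model of the *shape* of mass
accumulation, not of neonatal mass (see the methods vignette).

Paired developmental simulations (here 3 replicates for speed; analyses use
10 or more):

```r
ctrl <- run_development("control",  replicates = 3, seed = 1)
lrn  <- run_development("learning", replicates = 3, seed = 1)
compare_conditions(ctrl, lrn)
#>   divergence_day rho_learning rho_control late_group_size_learning late_group_size_control
#> 1             17        0.483       0.305                     3.34                    1.62
```

From day 17 the learning litters persistently out-huddle the controls
(the model's physiological-to-filial transition, published as "around day
15"), and their late join probability sits at the critical 0.48 while the
controls decay to 0.31. `autoplot(ctrl, lrn)` draws the two trajectories;
`plot_association_trajectories(lrn)` shows one pup's learnt likes and
dislikes.

Synthetic calibration data and staged least-squares recovery:

```r
synth <- simulate_development_data(noise = 0.05, seed = 7)
fit_constants(synth)
#> <huddle_fit> staged least-squares calibration
#>   k   = 9.1524  (generating 8.31)
#>   c   = 18.808  (generating 19)
#>   c1  = 2.2272  (generating 3)
#>   c2  = 0.024728  (generating 0.025)
#>   Tp  = 36.509  (generating 36)
#>   RMS residuals: BAT 0.127, growth 1.19, temperature 0.341 (60 obs)
```

At zero noise the recovery is exact to optimizer tolerance.

A command-line front end over the same functions lives at
`inst/cli/huddlesim.R` (subcommands `physiology`, `run`, `compare`, `synth`,
`fit`), writing CSV outputs plus a JSON run manifest.

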