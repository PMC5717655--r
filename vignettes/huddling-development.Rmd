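---
title: "Methods: a developmental model of rodent huddling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a developmental model of rodent huddling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huddlesim)
```

## The scientific problem

Neonatal rodents huddle for thermal economy; adults keep huddling at
temperatures where isolation would be metabolically harmless, guided by
olfaction. `huddlesim` implements a parsimonious account of that transition:
contacts that are thermally rewarding while brown-adipose-tissue (BAT)
thermogenesis is high condition odour preferences among littermates, and
those learnt preferences take over the maintenance of the huddle as the
thermal drive wanes. The package couples three layers — closed-form
developmental physiology, a Monte Carlo group-formation process, and
Delta-rule associative learning — and adds a synthetic-data and refitting
layer so the whole calibration pipeline can be exercised end to end.

## The physiology layer

All curves are continuous functions of postnatal day $t \ge 0$; the daily
simulation samples them at integer days. With constants
$(k, c, c_1, c_2, T_p)$:

$$P = e^{-t/k},\qquad S = -kP\ln P,\qquad G = k(1+S),$$
$$M = k(1-P),\qquad N = c\,e^{-kT_1},\qquad W = M+N,$$
$$T_1 = c_1 P,\qquad T_2 = c_2\,G\,N.$$

$P$ is the fraction of the birth BAT store remaining, $S$ the entropy
generated by burning it, $G$ the mass-specific metabolic rate
(cal g$^{-1}$ h$^{-1}$; the unit term in $1+S$ is the basal rate), $M$ and
$N$ muscle and non-muscle mass (g), and $T_1$, $T_2$ the warm- and
cool-preference deviations (°C) from a target adult body temperature $T_p$.
$G$ peaks exactly at $t = k$, which `metabolic_peak_day()` recovers
numerically (grid scan plus golden-section refinement to $10^{-9}$ days)
rather than by using the analytic fact.

Parameters, units and defaults:

| constant | default | units | role |
|---|---|---|---|
| $k$ | 8.31 | days / cal g⁻¹ h⁻¹ / g | BAT depletion time constant; basal-rate scale; muscle asymptote |
| $c$ | 19 | g | asymptotic non-muscle mass |
| $c_1$ | 3 | °C | warm-preference coefficient |
| $c_2$ | 0.025 | °C per (cal g⁻¹ h⁻¹ · g) | cool-preference coefficient |
| $T_p$ | 36 | °C | target adult body temperature |
| $\beta$ | 0.2 | — | drive scaling |
| $\gamma$ | 0.001 | — | Delta-rule learning rate |
| $n$ | 7 | pups | litter size |

$k$ is treated as a free constant whose fitted value happens to land near the
universal gas constant; nothing in the code depends on that reading.

Three modelling notes a user should know:

* **Preferred-temperature competition.** The two thermoregulatory systems
  compete without a stated arbitration mechanism, so
  `selected_temperature()` uses a *dominant-deviation* rule: $T_p + T_1$
  when $T_1 \ge T_2$, else $T_p - T_2$. It is the only deterministic rule
  consistent with both asymptotes (39 °C at birth, ≈ 32 °C in adulthood) and
  it places the switch at day ≈ 16.5, matching the early-warm/late-cool
  pattern in thermocline data.
* **$W(0)$ is an artifact.** The exponent in $N = c\,e^{-kT_1}$ is taken
  exactly as the model defines it, which makes $N(0) \approx 2.8\times
  10^{-10}$ g. The growth curve models the shape of mass accumulation, not
  neonatal mass; we flag rather than "fix" this.
* **Growth-rate identity.** The closed form $M = k(1-e^{-t/k})$ satisfies
  $dM/dt = (k - M)/k$ — the deficit $k-M$ decays with time constant $k$, not
  1 — and $dN/dM = c_1 N$ exactly. The test suite asserts both by finite
  differences; informal statements of the first identity sometimes omit the
  $1/k$ time scaling, which is dimensionally loose.

Numerical care: $S$ is computed as $-kP\ln P$ with the $P\to 0$ underflow
limit handled (so $G \to k$ holds for arbitrarily large $t$), and the
equivalence $S = t\,e^{-t/k}$ is verified to $10^{-12}$ relative error.

## The Monte Carlo huddling layer

The simulator state is a set partition of the $n$ pups into contact groups.
One encounter: draw initiator $a$ uniformly; draw partner $b$ uniformly from
the pups outside $a$'s group; join the two groups with probability
$\rho = (1+e^{-T})^{-1}$ of the pairwise drive $T$, otherwise detach $a$
into a singleton. Decisions left open by that description, and how we
resolved them:

* **Single-group state.** "A pup from a different group" is undefined when
  the whole litter is one huddle. We draw $b$ uniformly from all other pups;
  the join outcome is then a no-op (they are already together) and the
  detach outcome applies as usual. This keeps the chain irreducible, keeps
  the encounter/reward stream defined for learning, and makes the
  single-group state sticky but not absorbing. A no-op "join" still counts
  as a rewarded encounter ($r = 1$): the groups of $a$ and $b$ are combined,
  trivially.
* **Detaching a singleton** leaves the grouping unchanged (it already has
  size 1) but still counts as an unrewarded encounter.
* **Labels.** Merged groups take the initiator's label; equality of
  partitions is label-invariant everywhere (canonical restricted-growth
  relabelling), and tests enforce this.
* **"Average group size"** is ambiguous. The default estimator is
  $n/\#\text{groups}$ (the literal average over groups); a pup-weighted
  variant $\sum s_i^2 / n$ (the expected size of the group a random pup sits
  in) is exposed via `estimator = "pup_weighted"`. Both equal 1 on
  all-singletons and $n$ on a single huddle.
* **Randomness.** All draws come from R's global Mersenne-Twister stream;
  run-level functions take explicit `seed` arguments, recorded in their
  outputs, and replicate $r$ of a run with base seed $s$ uses $s + r - 1$,
  so control and learning runs with the same base seed are paired.

For litters of up to 5 pups the package also constructs the exact transition
matrix of this chain over all set partitions (Bell(5) = 52 states) and
returns its stationary distribution from the leading left eigenvector
(`stationary_partition_distribution()`). This is the independent reference
for the simulator: empirical visit frequencies of a $2\times 10^5$-step run
with 4 pups match the exact law within total-variation distance 0.02 at
drives $-1, 0, 1$.

## The learning layer

Each pup $a$ holds a directed associative strength $\alpha_{a,b}$ for the
odour of littermate $b$ (diagonal unused). The pairwise drive of an
encounter initiated by $a$ with partner $b$ is
$$T = \alpha_{b,a}\,(T_1 - T_2)\,\beta,$$
— the *partner's* association for the *initiator's* odour does the gating —
and after the outcome the *initiator's* entry moves by the Delta rule with a
compound prediction:
$$\Delta\alpha_{a,b} = \gamma\left(r - \sum_{i\ne a}\alpha_{a,i}\right),
\qquad r\in\{0,1\}.$$

Design choices, each deliberate and configurable:

* Exactly one update per encounter, to $\alpha_{a,b}$, preserving the
  index asymmetry between gating and learning as the equations are written.
  A `symmetric_update` flag additionally applies the mirrored update to
  $\alpha_{b,a}$ (off by default).
* Learning-condition initialisation is $\alpha = 0$ (trajectories grow from
  nothing); the control condition fixes $\alpha = 1$, reducing the drive to
  the pure thermal term. Running the learning machinery with $\gamma = 0$
  and $\alpha_0 = 1$ reproduces the control trajectories bit-for-bit on the
  same seeds (tested), which is why the constructor admits $\gamma = 0$.
* No clamping or decay: boundedness is emergent. Under i.i.d. rewards with
  rate $q$, each row sum $\sum_{i\ne a}\alpha_{a,i}$ converges to $q$ with
  fluctuation sd $\approx\sqrt{\gamma q(1-q)/2}$; in the closed loop this
  competition holds the late-development system near the critical regime
  $\rho \approx 0.5$.

**Encounter budget and heterogeneity.** The per-day iteration count is not a
published constant; we default to 1000 encounters per day (≈ $6.1\times
10^4$ per replicate over days 0–60, satisfying "many thousands"), exposed in
the configuration. One emergent property is sensitive to it: the
amplification of early individual differences into strong positive *and*
negative associations requires each ordered pair to experience well over
$1/\gamma$ conditioning trials. At 1000 encounters/day each pair sees only
~1450 trials by day 60 and the strengths stay clustered near $+0.08$; at
10000 encounters/day (with $\gamma = 0.001$ unchanged) every replicate
litter develops both strong likes and strong dislikes (day-60 range roughly
$-0.4$ to $+0.6$). The group-size and join-probability results reported by
the package (divergence day, late-phase $\rho$) are robust across this
choice; the heterogeneity test therefore uses the richer budget, and users
studying individual preference structure should too.

## The developmental experiment

`run_development()` starts the litter joined in a single group on day 0 and
carries partition and associations across days; each day evaluates the
thermal drive at that integer day and runs the encounter loop. Daily
statistics average the group-size estimator and $\rho$ over *all* encounters
of the day (not just the final state), which reduces variance; replicate
means are then averaged, with the between-replicate sd retained.

`detect_divergence_day()` reports the smallest day $d$ from which the
learning trace exceeds the control trace on every day of $[d, d+5)$; the
5-day persistence window (a flag) guards against single-day noise crossings,
and the window must fit inside the simulated range. Under the default
conditions with 10 paired replicates the divergence lands on day 17, stable
across base seeds, consistent with the published transition "around day 15";
the learning condition's mean $\rho$ over days 45–60 is 0.483 versus 0.305
for the control.

## Synthetic data and parameter recovery

`simulate_development_data()` emulates the *structure* of the classic
developmental measurements this model family is calibrated to: one
observation per postnatal day over days 1–60 of BAT weight (as % of body
weight), mass-specific metabolic rate, body mass, and thermocline-selected
temperature, with independent Gaussian noise. Choices:

* **BAT anchors** $p_1 = 4\,\%$ at birth and $p_0 = 1\,\%$ at day 60 place
  the unit decay curve on a raw percent scale realistic for mouse
  interscapular BAT; `normalize_bat()` maps the anchors back to $[0, 1]$.
* **Noise default** is sd = 5 % of each variable's dynamic range — scatter
  comparable to the historical plots — settable per variable in absolute
  units.
* The generator does **not** emulate litter-level random effects,
  heteroscedastic measurement error, missing days, or the correlation
  between variables measured on the same animal. Passing recovery tests
  therefore shows the fitting pipeline is correct and stable under honest
  i.i.d. noise, not that it is robust to every pathology of real data.

`fit_constants()` is staged, mirroring how the quantities build on each
other: (1) $k$ (with nuisance anchors) from the BAT decay by nonlinear least
squares (`minpack.lm::nlsLM`); (2) $c, c_1$ from body mass with $k$ fixed;
(3) $c_2, T_p$ from the selected temperatures. Estimating the anchors
jointly in stage 1 is the noise-robust version of normalising by the first
and last observations. Stage 3 exploits the dominant-deviation rule: branch
membership is a threshold in age, so the fit enumerates every candidate
switch day (a linear least-squares solve each), keeps the best, and refines
by nearest-branch reassignment to convergence — exact on noiseless data,
with no fragile general-purpose optimiser. Staging also makes $\hat k$
provably blind to noise in the mass and temperature columns (tested). The
least-squares criterion is an assumption; $T_p$ can be fixed at 36 °C via
`fix_Tp` instead of estimated, since either reading is defensible. Fits
refuse datasets with fewer than 10 distinct days or without coverage both
below $\hat k$ and above $3\hat k$.

On noiseless self-generated data the recovery is exact to optimizer
tolerance; at 5 %-of-range noise the median relative error on $k$ over 20
seeds is well under 5 %.

## Problem sizes and runtime

The package's standard experiment is 2 conditions × 10 replicates × 61 days
× 1000 encounters (≈ $1.2\times 10^6$ encounters, under a minute in pure R).
The test suite uses that experiment once (shared across checks), a
$2\times 10^5$-step chain per drive for the stationary comparison, reduced
chain lengths ($2\times 10^4$ steps per drive and seed) for the
drive-monotonicity property, and a single 10-replicate run at the
10000-encounter budget for the heterogeneity property. These sizes were
chosen to give comfortable statistical margins for each assertion.

## Known limitations

* The model is zero-dimensional: no spatial geometry, body contact surfaces,
  pup flow between huddle core and periphery, or explicit ambient
  temperature field.
* Continuous physiology is sampled at integer days by the driver; the curves
  themselves are exact at any real $t$.
* The learning rule is the simplest error-correcting form; richer
  conditioning models are expected to behave qualitatively alike but are out
  of scope.
* Refitting digitised historical scatter is out of scope — the calibration
  layer targets synthetic data with known ground truth.
* Uncertainty reporting is limited to per-stage RMS residuals (no bootstrap
  or profile intervals).
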