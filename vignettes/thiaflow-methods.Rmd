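---
title: "thiaflow: model, parameterisation and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{thiaflow: model, parameterisation and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thiaflow` is a deterministic box model of an enclosed, instantly mixed 10 m
surface layer holding eight trophic groups — heterotrophic bacteria,
picoalgae, nanoalgae, microalgae, nanoflagellates, ciliates, mesozooplankton
and planktivorous fish — with independent pools of carbon, nitrogen,
phosphorus and vitamin B1 (thiamin). This vignette documents the model
equations, the reasoning behind every tunable default, the numerical scheme,
and what the test suite does and does not establish.

## State variables and units

Each group carries a carbon biomass (µmol C m⁻³) and a B1 pool
(µmol B1 m⁻³); the water carries NO₃, NH₄, PO₄ and DOC (mmol m⁻³;
1 µmol l⁻¹ ≡ 1 mmol m⁻³). All biomass has fixed Redfield stoichiometry
C:N:P = 106:16:1 — no internal nutrient quotas — which makes N and P
conservation exact and testable: every flux that moves carbon moves the
corresponding N and P between biomass and the dissolved pools. The quota of
a group is `pool/biomass` (µmol B1 per µmol C) and is capped by an empirical
group-specific maximum `q_max` (e.g. 1.48e-7 for bacteria and picoalgae down
to 1.04e-10 for fish).

## Forcing

Surface irradiance is a truncated solar-elevation model: declination
`δ(d) = −23.44° · cos(2π(d+10)/365)` and hour angle give
`sin(elevation)`, negative values are night, and the result is normalised so
that summer-solstice noon equals `peak_noon_irradiance` (default 1; the
units are relative because growth uses a saturating light factor, so only
the shape matters). The declination is held constant within each calendar
day, making the diel course exactly symmetric about solar noon — a property
the tests exploit. Attenuation is `k = k_s·W_PP + k_bg` and producers see
the Lambert–Beer vertical average `Ī = I₀(1 − e^(−kH))/(kH)` rather than a
resolved vertical grid, consistent with instantaneous mixing.

`k_s` defaults to 5e-5 m² (mg C)⁻¹ so that a dense bloom
(~2000 mg C m⁻³) adds ≈ 0.1 m⁻¹ — comparable to the swept background range
0.04–0.24 m⁻¹ — making self-shading the dominant attenuation term in
high-nutrient scenarios and the background term dominant in oligotrophic
ones.

## Process rates

* Producers: `µ = µ_max(V) · min(f_N, f_P) · f_I` with Monod factors
  `x/(x+K)` and DIN = NO₃ + NH₄ drawn NH₄-first. 10 % of gross production is
  exuded as DOC.
* Bacteria: `µ = µ_max · min(f_DOC, f_N, f_P)`; DOC uptake equals
  growth/efficiency (0.3), the remainder respired.
* Consumers: per-prey ingestion is clearance × prey biomass, with total
  specific ingestion capped at `I_max` and the cap shared across prey
  proportionally to clearance × prey (a type-II-like saturation). Ingested
  carbon splits into growth (gge = 0.3), DOC excretion (20 % of the
  non-grown part) and respiration; the N and P of everything not grown
  returns to NH₄ and PO₄.
* Fish: same clearance formalism (clearance per unit fish biomass ×
  abundance × individual mass), but somatic growth is immediately
  remineralised — the population is constant over the half-year — while the
  absorbed B1 is retained. This makes fish a B1 integrator without a biomass
  dynamic, and at fixed absorbed flux the equilibrium quota is inversely
  proportional to abundance (dilution among individuals).
* Basal respiration: every plankton group loses biomass at a small specific
  rate (0.02–0.15 d⁻¹) independent of feeding, with N and P remineralised.
  The biomass balance is growth vs respiration vs predation; without a
  respiration term consumers could never decline (the model has no other
  non-consumptive mortality), prey would stay pinned at the floor and the
  within-season predator–prey oscillations that drive the B1-rich regime
  could not recur.

## Vitamin B1 fluxes

Producers and bacteria relax their quota towards `q_max` at a rate equal to
their metabolic rate times a global multiplier (`b1_input_multiplier`, a
sensitivity hook): `flux = rate·(q_max − q)·biomass`. Consumers and fish
gain B1 only by feeding: of the `quota_prey × ingested C` contained in a
ration, the bioavailable fraction `b` (default 0.15, studied range
0.05–0.20) is absorbed and the rest degraded. All pools turn over at the
group's metabolic rate (one fewer free parameter than a separate turnover
constant). Quota overflows above `q_max` are clipped and booked as
degradation, so the season-long B1 ledger closes exactly:
sources = Δstocks + transfer losses + turnover + cap overflow.

The analytic consequence is the decay chain: a pool passing `n` consumer
levels retains `b^n`. In the default web fish sit four consumer levels above
picoalgae and bacteria, three above nanoalgae and two above microalgae
(`consumer_levels_to_fish()`). The model's own output sometimes describes
the picoalgae path as "three consumer levels" counting only intermediate
consumers; all quantitative statements here use n = 4 (nanoflagellates,
ciliates, mesozooplankton, fish), which is what the surviving fractions
(0.15⁴ ≈ 0.5 ‰) require.

## Default parameterisation

The authoritative rate constants of the original study live in supplementary
material that is not part of this package, so the defaults below are the
package's own design decisions, chosen on standard ecological scaling
arguments and — where scaling alone underdetermines them — so that the model
reproduces the qualitative regime structure the study describes (a mostly
B1-rich cube with B1-poor corners at high fish abundance/high nutrients and
under strong background attenuation). Every value can be overridden per
group via `apply_spec_overrides()` or the YAML configuration.

| parameter | default | units | rationale |
|---|---|---|---|
| µ_max reference | 2.0 at 1 µm³ | d⁻¹ | picoplankton bloom rates |
| µ_max exponent | −0.1 | — | shallow interspecific size scaling; steeper values (−0.25) prevent any microalgae bloom within the season, starving mesozooplankton everywhere |
| K_I | 0.01·V^{1/3} | rel. irradiance | larger cells absorb less light per volume |
| K_N | 0.3·V^{0.1} (K_P = K_N/16) | mmol m⁻³ | weak size penalty on uptake affinity |
| clearance (nf, cil, meso) | 3e-4, 2e-4, 2e-4 | m³ (µmol C)⁻¹ d⁻¹ | protozoan/copepod volume-specific clearance |
| I_max (nf, cil, meso, fish) | 3, 2, 0.8, 0.05 | d⁻¹ | ration scaling with body size |
| fish clearance | 1e-4 (≈15 m³ ind⁻¹ d⁻¹) | m³ (µmol C)⁻¹ d⁻¹ | effective clupeid search volume; gives fish-induced mesozooplankton mortality of 0.06–0.15 d⁻¹ across the abundance range, enough for the top-down cascade |
| gge | 0.3 | — | typical planktonic gross growth efficiency |
| metabolic rate | 1.0, 1.0, 0.5, 0.3, 0.3, 0.2, 0.1, 0.03 | d⁻¹ | declines with size; doubles as B1 turnover |
| basal respiration | 0.05–0.15 (plankton), 0 (fish) | d⁻¹ | starvation decline rates |
| fish individual mass | 1.5e5 µmol C (≈1.8 g C) | — | ~15 cm clupeid |

Initial conditions (also unspecified in the source study): each plankton
group is seeded at 5 µmol C m⁻³ — an overwintering inoculum small compared
with blooms of 10⁴–10⁵ µmol C m⁻³ but large enough that spring growth, not
the seed, decides the season; DOC starts at 5 mmol m⁻³; quotas start at 1 %
of `q_max` ("picomolar" B1 levels); fish biomass is abundance × individual
mass.

## Numerical scheme

Explicit Euler with dt = 0.02 d (50 steps per day; the diel light cycle
demands sub-daily resolution). Each step applies, in order: light, producer
and bacterial growth with nutrient draw-down, grazing, ingestion
partitioning and excretion, basal respiration, and the B1 updates. Fluxes
are evaluated at the incoming state and **proportionally limited**: if the
demands on a dissolved pool exceed its content, all draws on that pool are
scaled down by the same factor; grazing on a prey is scaled so the prey
cannot be pushed below the extinction floor. This preserves positivity and
exact conservation simultaneously without implicit solves. NaN or negative
pools abort the run with a ledger dump.

The extinction floor is 1e-2 µmol C m⁻³ (~60 ciliate cells m⁻³). A much
smaller floor makes post-crash recovery times unrealistically long — a
population at 1e-6 µmol C m⁻³ needs ~25 e-foldings to rebloom, several
months at typical growth rates — which would suppress the within-season
oscillation recovery central to the B1-rich regime.

Ties and boundaries: classification comparisons are strict ("more than
30 %", "more than 70 %", quota "below" threshold); a series exactly at a
boundary is `intermediate`. CVs use the population standard deviation;
medians use R's default midpoint interpolation; a zero-mean series reports
CV as `NA` rather than infinity. Recording is daily: pools at midnight
(avoiding diel aliasing in the CV statistics), light and attenuation as
daily means.

## The scenario engine as a data generator

The scenario cube is the package's synthetic-experiment generator. Its
defaults are the studied conditions: fish abundance 0.004–0.01 ind m⁻³,
initial nitrogen interpolated between (NO₃ 2.01, NH₄ 0.93) and (30, 7)
mmol m⁻³ with phosphate at Redfield N:P = 16:1, background attenuation
0.04–0.24 m⁻¹, bioavailability 0.15. The production grid is 5×7×6; tests
and the acceptance script use a scaled 3×5×5 grid (75 full-season runs,
roughly three minutes) — the regime *geography* is stable across grid
density even though individual trajectories are not.

What the generator emulates: seasonal and diel light, an enclosed nutrient
budget, size-structured bottom-up and top-down control, and the
bioavailability-discounted vitamin cascade. What it does not emulate:
temperature, stratification and exchange with deeper water, dissolved-B1
pools and auxotrophy, mixotrophy, grazing-resistant filamentous
cyanobacteria, thiaminase enzymology, and multiyear fish demography.
Passing tests therefore show internal consistency and the qualitative
mechanism map, not quantitative agreement with any field data.

## Known limitations

* The food web is oscillatory and, in much of the parameter cube,
  deterministically chaotic: trajectories from infinitesimally different
  states (or step sizes) diverge within weeks. Windowed statistics and
  classifications are robust to halving dt, but pointwise end-of-season
  biomasses are not — the step-size test that demands < 1 % agreement of
  final biomasses on the default (oscillatory) scenario fails for this
  structural reason, while the same check passes on non-oscillatory runs
  (see the producer-only convergence test).
* Classification hinges on the fish quota threshold 6.41e-11
  µmol B1 (µmol C)⁻¹ (read as 6.41×10⁻¹¹; the fish `q_max` of 1.04e-10
  confirms the scale).
* Fixed Redfield stoichiometry ignores luxury uptake and variable C:N:P;
  bacteria compete for DIN/DIP at the same ratio as producers.
* B1 turnover equals the carbon metabolic rate by construction; if true
  thiamin turnover is much slower, quota dynamics would lag biomass
  dynamics more than modelled.
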