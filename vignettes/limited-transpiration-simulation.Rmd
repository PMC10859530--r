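---
title: "Simulating the limited-transpiration trait in grain sorghum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the limited-transpiration trait in grain sorghum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorghumlt)
```

## The question

Limited transpiration (LT) is a hypothetical drought-adaptation trait: a
genotype that caps its hourly transpiration rate, closing stomata during
the high vapour-pressure-deficit (VPD) midday hours. The cap costs carbon
on days when water is plentiful, but conserves soil water for flowering
and grain filling. `sorghumlt` implements a desk-scale process-based
pipeline to ask when that trade pays off for grain sorghum: across which
seasonal water-deficit patterns, maturity groups and planting dates.

## The crop model

### Phenology

Development accrues daily thermal time on the mean temperature with a
broken-stick cardinal response (Tbase/Topt/Tceil = 11/30/42 °C, the usual
sorghum set), summed over nine phases from sowing to physiological
maturity: germination, emergence, end of juvenile phase, floral
initiation, flag leaf, flowering, start of grain filling, end of grain
filling, maturity. The per-phase targets are package assumptions (the
per-phase degree-day totals are not observable from any single published
table); what is structurally fixed is their ordering across maturity
groups: short/medium/full-season cultivars carry 15/17/19 leaves and
differ in `tt_endjuv_to_init` (150/230/310 °Cd) and the leaf-area
parameters, so fuller groups flower later and carry more canopy. The
photoperiod term extends the juvenile-to-floral-initiation target by
`photoperiod_slope × max(0, daylength − 12.5 h)`; the default slope of 0
represents a photoperiod-insensitive calibrated hybrid. Water stress does
**not** delay development — stress acts on growth only. This is a
simplification, chosen so that the centesimal thermal-time axis used by
the envirotyping layer is identical for stressed and unstressed seasons.

### Canopy and light-limited growth

Per-plant leaf area follows the TPLA logistic
`tpla_max (1 + tillers) / (1 + exp(−c (tt − t₀)))` on thermal time since
emergence, with `tpla_max = 0.0016 · leaf_no²` m², `c = 0.012` and
inflection `t₀` = 280/320/360 °Cd by maturity group; tillers are fixed at
0.3. LAI is per-plant area × density, and senesces linearly from flowering
to zero at maturity. Light-limited biomass is
`RUE · radn · (1 − exp(−k·LAI))` with RUE = 1.25 g MJ⁻¹ and k = 0.5.

### Hourly water demand and the LT cap

Daily weather is downscaled to hours: a single-cosine temperature curve
peaking at 14:00 (its extremes equal tmax/tmin exactly), saturation vapour
pressure by Tetens `es(T) = 0.6108·exp(17.27T/(T+237.3))`, dewpoint
assumed equal to tmin (the standard fallback when humidity is not
observed), so `vpd_h = max(0, es(T_h) − es(tmin))`. Radiation is shared
across daylight hours by a half-sine. Hourly transpiration demand converts
the hour's share of potential (light-limited) biomass through the
transpiration-efficiency relation `demand_h = ΔB·share_h·vpd_h / TEc`,
with TEc = 9 Pa, so demand is in mm.

The LT trait is a **flat hourly ceiling**: `min(demand_h, cap)` for caps
in [0.2, 0.9] mm h⁻¹, `Inf` for non-LT. An alternative reading — a cap
engaged only above a VPD breakpoint — is physiologically plausible but
under-determined here; the flat cap was chosen as the parameter's plainest
semantics and the comparison is left open. Daily stress is
`waterSD = min(1, supply / Σ capped demand)` (1 when demand is zero, e.g.
cold rainy days, which are then water-unlimited); actual hourly
transpiration is the capped demand scaled by waterSD, and biomass is
recovered hour-by-hour as `Σ transp_h · TEc / vpd_h`. Two properties
follow by construction and are asserted in the tests: hourly transpiration
never exceeds the cap, and an LT season is bit-identical to its non-LT
pair whenever demand never reaches the cap. Under water limitation the cap
*reallocates* a fixed daily water quota toward low-VPD hours, which raises
biomass per millimetre — that, plus the water carried past flowering, is
the LT mechanism in this model.

### Soil water

The profile is a tipping bucket of layers (150, 150, then 300 mm) with
volumetric LL15 < DUL < SAT from a documented texture lookup. Rain
partitions by a threshold-excess rule (no runoff below 15 mm d⁻¹, then
35% of the excess); water above SAT cascades immediately, water above DUL
drains at 0.5 d⁻¹; soil evaporation is two-stage (stage I limit 6 mm,
stage II coefficient 3.5 mm d⁻½), canopy-shaded by `exp(−0.5·LAI)` and
bounded by an air-dry limit of half LL15 in the surface layer. Root water
supply follows the kl convention `Σ kl·(sw − LL15)·thickness` over rooted
layers (pro-rata in the deepest), with kl = 0.07/0.05/0.03 d⁻¹ for the
upper/middle/lower thirds; roots descend 30 mm d⁻¹ from sowing depth until
flowering. A fallow balance runs from 1 January to sowing — that is what
the 1 January start and the 60% initial-moisture convention exist for —
and both the 60% (application) and 70% (evaluation) settings are a single
`management(initial_fasw=)` argument. Every season's daily flux ledger
closes `rain − runoff − drainage − evaporation − transpiration − Δstorage`
to 10⁻⁶ mm; this is asserted for every simulated season in the tests.

### Grain yield

Grain number per plant is the mean per-plant growth rate between floral
initiation and the start of grain filling divided by
`dm_per_seed = 0.00099` g (the division by the phase duration in days is
the plant-basis correction converting accumulation to a rate). Grain mass
then accumulates at
`min(0.7 mg·grain⁻¹·d⁻¹ · grain number, ΔB + stem reserve)`, where the
remobilizable reserve is 20% of stem mass (stem taken as half of biomass
at the start of grain filling). Dry yield converts to reported yield by
the 12.5% grain-moisture convention, `yield = dry / (1 − 0.125)`.

### Failed seasons

A season fails when flowering is not reached: either the weather series
ends first, or — once the canopy is established — the 14-day running mean
of waterSD falls below 0.1 before flowering. The running-mean form matters
because kl-based supply decays asymptotically and rarely sits *exactly* at
zero for two weeks; a rainless season started at 20% moisture fails under
this rule, matching the notion of seasons that never complete the
vegetative stage. Failed seasons carry `NA` yield, are excluded from
envirotyping (their trajectories are truncated), and are flagged — never
dropped — in factorial tables.

## The synthetic weather generator

The generator emulates the *statistical structure* of the US sorghum
belt's seasonal water-deficit patterns, not any particular station record.
Each archetype is a first-order two-state Markov chain of wet/dry days
with monthly transition probabilities, gamma-distributed wet-day amounts
(shape 1.5), a seasonal sine temperature model with archetype-specific
mean and diurnal range (drier archetypes are hotter with wider ranges,
hence higher VPD), and a clear-sky radiation curve (17.5 + 10·cos, MJ m⁻²)
attenuated by 0.75 on wet days.

The four archetypes are distinguished by when their dry windows sit in
*crop-development* time for a May-sown crop flowering in early July:

* **WW** — regular rains May–October (higher occurrence, smaller events),
  a narrower 9 °C diurnal range; light stress at most during grain fill.
* **LD** — wet May–July, then wet-day probabilities suppressed
  August–October: stress arrives during grain filling.
* **MD** — a wet spring followed by a July–August "flash drought"
  spanning flowering.
* **ED** — a dry March–June (which also depletes the fallow storage) that
  breaks with midsummer rains: stress during the vegetative phase, partial
  recovery afterwards.

Each archetype's gamma intensity mean is solved in closed form from the
chain's exact daily wet-probability recursion so that the *expected*
May–October total equals its target: WW 400, LD 300, MD 244, ED 230 mm.
Over 100 seeded seasons the sample means land within a few percent of
these targets; per-season totals have a coefficient of variation around
20–30%, consistent with the interannual variability of semiarid rainfed
systems. The means are the calibrated quantities; the dispersion is a free
parameter of the design (no variance target exists to calibrate against).

Site gradients (`generate_gradient_sites()`) interpolate archetype mixture
weights from WW/LD-dominated (east) to MD/ED-dominated (west), with
recommended plant density falling 14 → 6 plants m⁻² and soils lightening
westward — the belt's agronomic gradient in miniature.

What the generator does **not** emulate: spatial correlation between
sites, humidity observations (dewpoint is derived, not generated),
multi-day storm structure, and trends. Tests passing on this generator
therefore demonstrate the pipeline's behaviour under controlled,
archetype-structured forcing — not calibration against any observed
station series.

## Envirotyping

For each non-failed season the daily waterSD series is interpolated onto
the centesimal cumulative-thermal-time grid (1–100%), making seasons of
different calendar length comparable. Trajectories are clustered by
k-medoids with Euclidean distance — exhaustive PAM up to n = 500, CLARA
subsampling (5 seeded draws of ≤ 100 + 2k) beyond — and k is chosen from
2–8 by the maximum mean silhouette width over all points. Clusters are
named by their median trajectories: the one closest to 1 throughout is WW;
the rest are ranked by the thermal-time centroid of their stressed portion
(1 − median), latest → LD, earliest → ED, middle → MD. Ties break by mean
stress. With ≥ 40 simulated seasons per archetype run through the full
crop model, silhouette selection returns k = 4 and the names agree with
the generating archetypes at ≈ 93–95% after permutation matching.

Two design notes. First, the hierarchical-versus-partitioning ambiguity in
common usage is resolved in favour of k-medoids, which is what `clara`
computes. Second, the silhouette is computed over all points (not over
medoids), the standard definition.

## Experiments and inference

`run_factorial()` crosses trait × maturity × planting × site × year with
per-season seeds derived deterministically from the master seed, so
toggling the trait changes nothing else — LT/non-LT rows of a cell share
weather, soil initialisation and sowing dates exactly, and the whole table
is reproducible bit-for-bit. Relative changes are computed pair-first
(each LT run against its own non-LT partner), then averaged within groups;
pairs with failed or zero-yield baselines are excluded and counted.
Water productivity is yield over cumulative season transpiration — the
plotted-but-undefined quantity, recorded here as an explicit assumption.

The mixed models use `lmerTest` with random intercepts for location and
year-within-location. Backward AIC selection is implemented directly over
the fixed-effect terms because the conventional stepwise tools either use
p-values or do not respect marginality over this term lattice: a term is
removable only if no retained term contains all its factors, and the
removable term with the largest AIC decrease is dropped until no removal
improves AIC (ML fits throughout; REML for final estimates). Denominator
degrees of freedom for the gating F tests are Satterthwaite
approximations. The compact letter display is computed by `multcomp`'s
`cld` on a Tukey `glht` contrast; pairwise estimates come from `emmeans`
with Tukey adjustment.

## What the desk-scale results show

At the shipped defaults the pipeline reproduces the *directions* of the
LT story: zero effect in WW (the cap rarely engages at a 9 °C diurnal
range), positive mean gains in drought archetypes ordered
ED > MD > LD, larger and more dispersed gains as the cap deepens from 0.8
to 0.2 mm h⁻¹ in MD/ED (tens of percent at 0.2, with well-watered seasons
paying a carbon penalty), and more soil water at flowering for LT in
paired drought seasons. The *magnitude* of the 0.9 mm h⁻¹ effect is
smaller here (≈ 0.2–1% in drought classes) than the 4–10% reported for
full-scale multi-decade APSIM studies: with the conservative kl profile
(0.07/0.05/0.03) the pre-flowering supply margin is thin, so the flat cap
saves little water before flowering and most of the benefit comes from
hourly reallocation. Raising kl, demand, or the VPD regime strengthens the
effect; we kept the documented defaults rather than tune for effect size.

One emergent interaction deserves note: because the ED archetype's early
drought breaks with midsummer rains, later maturities can *exploit* the
recovery and outyield short-season cultivars at ED-dominated sites, while
LD/MD (terminal and flowering-time drought) favour short/medium maturity
as expected. Whether early droughts recover is thus the pivot of the
maturity recommendation — a real agronomic contingency that the archetype
design makes explicit.

## Problem sizes and determinism

The shipped tests run the full pipeline at deliberate desk scale: 100
seeded seasons per archetype for generator calibration, 40 per archetype
(160 crop-model runs) for envirotype recovery, 25 + 25 + 20 paired seasons
for the trait contrast, 15 paired years per cap for the severity scan, and
20 replicate tables for mixed-model recovery. Every stochastic unit draws
its RNG stream from `derive_seed()` (a 2³¹-safe integer hash of the master
seed and the unit's indices), and generators restore the caller's RNG
state, so all results are reproducible from single integer seeds.

## Known limitations

* No nitrogen, phosphorus, pest or lodging dynamics (nitrogen is assumed
  non-limiting), and no CO₂/climate-change response.
* Leaf area and phenology are insensitive to water stress; stress acts on
  biomass only. Real crops senesce and delay under stress.
* The canopy is a single big leaf on a flat hourly VPD curve; there is no
  leaf-level energy balance, so canopy temperature feedbacks of LT are
  absent.
* The pedotransfer step is a fixed texture-class lookup, not a fitted
  pedotransfer function.
* The weather generator is single-site and trend-free; its archetypes are
  design constructs calibrated to seasonal totals, not to any station.
* Yield magnitudes are plausible (≈ 1.5–7 Mg ha⁻¹ across archetypes) but
  uncalibrated against field trials; comparisons should be read as paired
  contrasts, not absolute predictions.
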