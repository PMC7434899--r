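---
title: "Modelling green and blue crop water requirements with watneeds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling green and blue crop water requirements with watneeds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(watneeds)
```

## The problem

The consumptive water requirement of a crop is the volume of water its
evapotranspiration would draw over the growing period if the crop never
experienced water stress. Splitting that volume into a *green* share
(met by precipitation stored as soil moisture) and a *blue* share (the
irrigation needed to top the green share up to the unstressed demand)
is the standard water-footprint decomposition, and it is what this
package computes: crop-specific, monthly and annual green and blue
requirements on a WGS84 latitude–longitude grid, from daily
precipitation, monthly reference evapotranspiration, gridded soil
parameters and regional crop calendars.

## The model

For crop $i$ on day $t$ the potential evapotranspiration is

$$ET_{i,t} = k_{c,i,t}\, ET_{0,t},$$

with $k_c$ the FAO-56 crop coefficient of the growth stage day $t$
falls in, and $ET_0$ the reference evapotranspiration (an input: the
package never computes Penman–Monteith itself). Actual
evapotranspiration is reduced by a stress coefficient,

$$ET_{a,i,t} = k_{s,i,t}\, ET_{i,t}, \qquad
k_{s,i,t} = \begin{cases} S_{i,t-1}/RAW_i & S_{i,t-1} < RAW_i \\
1 & S_{i,t-1} \ge RAW_i \end{cases}$$

where $S$ is the depth-averaged root-zone moisture and
$RAW_i = p_i\,TAW_i = p_i (\theta_{fc} - \theta_{wp}) z_{r,i}$ is the
readily available water ($p$ the critical depletion factor, $z_r$ the
regime-specific rooting depth, $\theta_{fc}-\theta_{wp}$ the storage
capacity per metre of soil). The store obeys the daily balance

$$S_{i,t} = S_{i,t-1} + \Delta t\,(P_{\mathrm{eff}} - ET_{a,i,t}
  - D_{i,t} - R_{i,t}),$$

with $\Delta t = 1$ day. Effective precipitation is a fixed 95% of
precipitation (5% is routed to surface runoff). Deep percolation ramps
linearly with the previous day's store,

$$D_{i,t} = \begin{cases}
F_{\max}\,\dfrac{S_{i,t-1} - RAW_i}{TAW_i - RAW_i} &
RAW_i \le S_{i,t-1} \le TAW_i\\[4pt]
0 & S_{i,t-1} < RAW_i,\end{cases}$$

where $F_{\max}$ is the soil's maximum infiltration rate. Two closure
rules complete the step: if the tentative balance goes negative,
$ET_a$ and $D$ are scaled by a common factor so the store closes
exactly at zero (preserving their ratio); if it exceeds $TAW$, the
excess leaves as sub-surface runoff $R$ and the store closes at $TAW$.
The per-day identity
$S_t - S_{t-1} = P_{\mathrm{eff}} - ET_a - D - R$ then holds exactly,
and the test suite asserts it to $10^{-9}$ mm on randomised two-year
scenarios.

Each cell–crop–regime combination is simulated twice in concept: a
*stressed* run fed by precipitation only, and a *well-watered* run in
which $k_s \equiv 1$. Green water is the stressed actual
evapotranspiration; blue water is the difference between unstressed and
stressed actual evapotranspiration, counted on irrigated land only.
Because the well-watered crop always transpires at the potential rate
— any storage deficit is read as implicitly supplied by irrigation,
which is deliberately never simulated as a balance input — the
unstressed series equals $k_c\,ET_0$ identically, and the paired runs
collapse to one stressed simulation plus the potential series. The
engine still exposes `stressed = FALSE` and the suite pins its
semantics: in that mode $ET_a$ is never scaled by the closure, so it is
independent of the soil state.

Daily green and blue values are summed over each calendar month of the
growing season; off-season days are simulated (they move soil moisture)
but never contribute to the reported requirement. Annual values are the
monthly sums, and multi-year products are element-wise means of yearly
simulations.

## Crop phenology

Stage lengths are the crop's four stage fractions (initial,
development, mid-season, late) scaled to the regional growing period.
Stage boundaries use cumulative rounding,
$b_k = \lfloor L \sum_{j \le k} f_j + 0.5\rfloor$, so per-stage
rounding cannot drift and the four intervals always total the season
length $L$. Within stages the daily $k_c$ follows the FAO-56
convention — constant $k_{c,\mathrm{ini}}$, linear rise to
$k_{c,\mathrm{mid}}$, constant plateau, linear change to
$k_{c,\mathrm{end}}$ — sampled at day centres of the continuous
piecewise-linear curve, which makes the series continuous across stage
boundaries by construction. Outside the season $k_c$ is the off-season
value (default 0.5, an average of bare soil, grassland or a second
crop covering the field).

Seasons may wrap the calendar year (harvest day-of-year before planting
day-of-year); their days are assigned to actual calendar dates, and
day-of-year 366 falls back to December 31 in non-leap years. Where a
calendar reports more than two growing periods for a crop, the two with
the largest harvested areas are retained (ties broken by earliest
planting) and each discarded period's area is added to the retained
period nearest in planting day, so total harvested area is conserved
exactly. With two seasons, each is simulated independently and the
monthly fields are summed — summation, rather than averaging, conserves
the combined seasonal demand where both seasons occur.

## Initial conditions and spin-up

Simulations start at 50% of $TAW$ and run three spin-up years before
the production period, using three forcing years drawn (with
replacement, from a seeded generator) out of the available years; the
draw is made once per run and reused for every crop, regime and cell,
so results are comparable across simulations and reproducible from the
run seed. The spin-up years use the crop's own annual $k_c$ cycle. The
`sensitivity_initial_condition()` driver repeats full runs with the
initial fraction forced to 0 and 1: on the bundled seasonal scenario
the domain total moves by far less than 1%, because the store saturates
during the low-demand season and the two trajectories collapse onto the
same path.

## Tunable parameters

| parameter | units | default | role |
|---|---|---|---|
| `surface_runoff_fraction` | – | 0.05 | share of precipitation lost to surface runoff |
| `off_season_kc` | – | 0.5 | crop coefficient outside the growing season |
| `initial_moisture_fraction` | – | 0.5 | spin-up start, as a fraction of $TAW$ |
| `spin_up_years` | yr | 3 | pre-simulation years before the production period |
| `seed` | – | 1 | governs the spin-up year draw |
| `p` | – | per crop | depletion factor: $RAW = p\,TAW$ |
| `zr` | m | per crop, per regime | rooting depth |
| `theta_diff` | mm m⁻¹ | per cell | $\theta_{fc}-\theta_{wp}$ storage capacity |
| `f_max` | mm day⁻¹ | per cell | maximum infiltration rate |

## Numerical and design choices

* **Explicit scheme.** Both $k_s$ and $D$ are evaluated on the previous
  day's store. This avoids the implicit circularity of evaluating them
  on the day being solved and matches the percolation rule's stated
  condition on $S_{t-1}$.
* **Order of operations.** Within a day: effective precipitation, then
  potential ET, stress, percolation, the negative-balance closure, and
  finally saturation excess. The closure factor is
  $\lambda = (S_{t-1}+P_{\mathrm{eff}})/(ET_a + D)$, defined as 0 when
  the denominator vanishes.
* **ET0 disaggregation.** Monthly reference ET is spread uniformly over
  the days of each month, so monthly sums are conserved exactly
  (including leap Februaries). Mid-month interpolation was rejected
  because it breaks that conservation.
* **Production span.** Reported fields cover the requested production
  calendar years; a season wrapping past the last simulated year
  contributes its tail to the following year's maps (each day is
  attributed to its actual calendar month), and a tail beyond the
  forcing span is not simulated.
* **Grid conventions.** Cell-centre coordinates, row 1 northernmost,
  longitudes −180→180; no-data is IEEE NaN with `_FillValue` set in the
  NetCDF files. The published annual layout is a 2160 × 4320 grid at
  5 arcmin with a fixed 26-class crop dimension; crops absent from a
  run are written as all-fill slices. Only nearest-neighbour regridding
  is provided, and the readers are NetCDF-only — the same format the
  synthetic bundle writes.
* **Cell independence.** The grid engine is a plain loop over cells
  calling the point pipeline; permuting iteration order cannot change
  results, and the suite pins the grid run bit-for-bit against an
  independent per-cell loop.

## The synthetic forcing generator

Every test and the acceptance harness run on generated inputs, so the
package is exercisable end-to-end offline. The generator emulates the
*statistical shape* the model consumes: Bernoulli wet-day occurrence
with exponential depths (a fixture choice — the engine only requires
non-negative daily values), a sinusoidal annual ET0 cycle delivered as
monthly totals, soil parameters uniform in 100–250 mm/m and
5–50 mm/day, and calendars that deliberately include a single-season,
a double-season, a three-period (consolidation-exercising) and a
wrap-around region. Three presets are analytic end-members: `humid`
(daily constant rain exceeding demand plus $F_{\max}$, forcing blue
water to zero and green water to the full potential demand), `arid`
(no rain: green water zero from an empty store, blue water the full
demand on irrigated land) and `seasonal` (intermittent rain against a
3.5 ± 2.5 mm/day ET0 cycle, producing realistic stress episodes).

What the generator does **not** emulate: spatial autocorrelation and
storm structure of real precipitation, ET0 spatial gradients, soil
spatial coherence, or realistic calendar geography. Passing tests
therefore demonstrate the correctness of the water-balance arithmetic,
phenology, aggregation and file layout — not the realism of any
particular regional requirement estimate, which depends entirely on the
real forcing, soil and calendar products supplied through the readers.

## Problem sizes

The bundled study conditions are a 10 × 10 grid, three crops
(wheat-, maize- and rice-like parameter sets), two regimes, five years
of forcing (2001–2005), a three-year spin-up and production year 2004
— about 780 point simulations of ~1460 days per full grid run, a few
seconds of compute. The initial-condition sensitivity repeats the full
run at three initial fractions. These sizes keep every property
checkable in seconds while still exercising multi-season, wrap-around
and consolidation paths; the engine itself is size-agnostic and writes
the full global 2160 × 4320 layout.

## Known limitations

* Irrigation is a derived demand, never a simulated supply: actual
  withdrawals, conveyance losses and deficit irrigation are out of
  scope, so blue requirements can exceed what fields actually receive.
* One root-zone bucket: no capillary rise, groundwater coupling, snow,
  interception, multi-layer soils or sub-daily dynamics.
* Calendars, soil and land use are static inputs; deriving them from
  climate or native binary inventory formats is out of scope.
* The comparison statistic (`compare_fields()`) uses the reference
  field as denominator with explicit zero-cell conventions; it is
  deliberately one-sided, and scale-invariant rather than symmetric.
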