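---
title: "Rapid typical-facility costing of public health supply chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rapid typical-facility costing of public health supply chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rapidsc)
```

## The model

rapidsc estimates the annual operating cost of a tiered public health
distribution network (a national store feeding provincial/district stores
feeding health facilities) from a small set of *typical-facility*
parameters, for situations where time and budget rule out collecting
facility-level data. Three simplifying assumptions make this possible:

1. **Identical facilities within a tier.** Every facility at a tier shares
   one demand quantity per order period, one distance profile and one cost
   profile.
2. **Stationary demand.** Demand is the same every order period.
3. **Even spatial distribution.** Facilities are spread uniformly over the
   region, so each sits the same average distance from its resupply point.

Under these assumptions a whole tier is costed by evaluating one typical
facility and multiplying by the facility count, and distances follow from
area alone — no coordinates are needed.

Costs are reported as line items keyed by *tier* and *function*
(storage, transportation, management), alongside resource utilization
(storage and vehicle) and operational statistics (km travelled, volume
delivered per facility).

### Demand and volume

Demand can be derived from demographics:

$$\text{doses/yr} = \frac{\text{population} \times \text{target fraction}
\times \text{doses per course} \times \text{coverage}}{1 -
\text{wastage}}$$

with volume $= \text{doses} \times \text{cm}^3/\text{dose} \times
\text{packaging factor} / 10^6$ m³ — or supplied directly as monthly m³
per bottom-tier facility. Wastage is treated as a fraction of *supplied*
stock (the immunization-forecasting convention), so supplied doses and
commodity value are both grossed up by $1/(1-w)$. Intermediate tiers are
pass-through: a tier's throughput is the system volume divided by its
facility count, which makes volume conservation across tiers exact by
construction.

### Geometry

Two continuous-approximation constants convert area to expected road
distance:

* hub to a uniform point in its square service area:
  $\bar d = k_{near}\sqrt{A}$, with $k_{near} = 0.3826$, the exact value
  $(\sqrt2 + \operatorname{asinh} 1)/6$ for the centre of a square;
* a closed tour through $n$ uniform points in area $A$:
  $L \approx k_{tour}\sqrt{nA}$, with $k_{tour} = 0.75$, the classical
  tour-length constant.

Both are multiplied by a road circuity factor ($\ge 1$) and both are
user-overridable. Service areas are modelled as equal squares; hexagonal
or Voronoi refinements would add false precision for a rapid tool.
Multi-stop loops are assigned whole facilities by ceiling division; the
final, possibly partial, loop is charged the full approximation length (a
deliberately conservative choice). The test suite recalibrates both
constants against independent oracles: a Monte-Carlo mean over $10^5$
uniform points for $k_{near}$, and nearest-neighbour + 2-opt heuristic
tours regressed on $\sqrt{nA}$ for $k_{tour}$ (the fitted coefficient
must land in $[0.6, 0.9]$).

### Inventory and storage

Storage uses the **max-stock convention**: immediately after a delivery a
site holds `replenishment_interval + safety_stock` months of demand, and
that peak capacity must exist year-round, so annual storage cost is
`peak × rate` with separate per-m³-year rates for cold-chain and dry
volume (cold rates embed annualized equipment cost). The published
spreadsheet lineage of this methodology does not document whether it
charges peak or average stock; we chose peak because capacity is physical
(a cold room sized for the average would overflow after every delivery).
Charging *required* rather than owned capacity also means a scenario's
storage cost automatically prices the closure of any existing capacity
shortage — the "ideal baseline" framing.

### Transport

For the link into each tier, shipments per year $= 12/\text{interval}$;
trips per shipment $= \lceil \text{shipment volume} / (\text{capacity}
\times \text{load factor}) \rceil$; annual km $=$ route km $\times$ trips
$\times$ shipments $\times$ routes. Variable lines are fuel, maintenance
and driver per-diem (one day per started block of `workday_hours` trip
hours, default 8 h); fixed lines are straight-line depreciation and
insurance. No discounting is applied anywhere — rapid-tool fidelity.
Fleets are sized per supplying hub against the buffered workload, with a
floor of one vehicle per hub running a link: a route cannot be operated
with zero vehicles, which is why fixed vehicle lines persist at zero
demand. Cost lines are charged to the tier *operating* the transport
(`operator = "supplying_tier"` for delivery designs,
`"receiving_tier"` for facility-collection designs — same distance
arithmetic, different cost owner).

A *utilized-assets* mode (`evaluate_scenario(s, utilized_assets = TRUE)`)
costs fractional vehicles (annual trip-hours over available hours, no
ceiling), matching reference analyses that track only actively used
assets.

### Campaign throughput buffers

Periodic campaigns (e.g. supplemental immunization activities raising
throughput ~30% in campaign months) are handled with a two-part rule:
capacity-sizing quantities (peak stock, trips per shipment, fleet size)
use demand × multiplier, while annual flow-proportional quantities (km,
fuel, per-diem, volume delivered) use the time-weighted blend
$1 + (m - 1)\,\text{months}/12$. Both components are separately
inspectable in the utilization report.

### Scenario transforms and comparison

`apply_level_skip()` removes a middle tier and re-links the tier below to
the tier above; levels are re-indexed. The re-linked tier *retains* its
inbound transport policy unless an override is passed — the alternative
(forcing re-entry) seemed worse for a rapid tool, but the retained policy
(vehicle, loop size) may genuinely need revisiting after a redesign, so
the override parameter is part of the transform's signature.
`set_replenishment_interval()` and `set_throughput_buffer()` cover
resupply-frequency and campaign-buffer redesigns. All transforms are
pure (they return new scenarios), so a dashboard can hold a baseline and
its variants simultaneously; `compare_scenarios()` reports each variant
as a percent of a designated baseline (one decimal in displays, full
precision underneath). Whether level skipping saves money depends
entirely on the inputs — it trades the skipped tier's storage and
management cost against longer direct routes — and the package asserts
only the structural semantics, never a savings direction. Networks using
different designs per subregion are modelled separately and combined
with `aggregate_submodels()`, which concatenates cost lines under a
submodel tag and never merges utilization.

### Validation against reference analyses

`mape_three_levels()` compares model output to an external reference cost
study at three aggregation levels — individual line items, tier ×
category totals, and the system total — each summarized as a mean
absolute percent error. Matching uses normalized
`(tier, category, label)` keys plus an explicit alias map; unmatched
items are *reported, never averaged in* (we match on the intersection of
keys, with the unmatched remainder listed on both sides). Cells with a
zero reference value are excluded with a warning rather than dividing by
zero. Comparability adjustments mirror the transformations such
comparisons need in practice: costing only utilized assets, reassigning
cost ownership to where the budget line sits (conserves the grand total
exactly), and excluding cost categories the reference analysis omitted.

## The synthetic oracle

`generate_network()` builds explicit facility-level networks — uniform or
hub-clustered placement in a square region, log-normal demand
parameterized by mean and coefficient of variation (CV 0 degenerates to
equal demands; log-normal was chosen for positivity and a heavy tail) —
and `brute_force_cost()` prices them with the *same cost formulas* but
exact Euclidean×circuity distances and per-facility demands.

Two properties anchor the implementation:

* **Exact equivalence**: with homogeneous demands and distances pinned to
  the typical value, the brute-force and typical-facility totals agree to
  relative error below $10^{-9}$ — the two code paths collapse to the
  same arithmetic.
* **Averaging out**: on homogeneous uniform networks the mean relative
  gap shrinks as facility counts grow (about 1% at $n=20$, a few tenths
  of a percent at $n=400$ over 20 seeds), quantifying why small networks
  deserve facility-level modelling while large ones tolerate the
  typical-facility simplification. A single 50× demand outlier in a
  20-facility network measurably widens the gap.

What the generator does **not** emulate: real road networks (circuity is
a scalar), facility-size correlation with accessibility, seasonal demand,
and stockout dynamics. Passing tests therefore show internal consistency
of the approximation, not calibration against any real country's costs.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `circuity_factor` | — | 1 (templates: 1.4–1.5) | road vs straight-line distance |
| `k_nearest` | — | 0.3826 | exact square-centre constant |
| `k_tour` | — | 0.75 | classical tour-length constant |
| `max_load_factor` | — | 1 | usable fraction of vehicle capacity |
| `safety_stock_months` | months | 0 | buffer stock beyond the cycle |
| `workday_hours` | h | 8 | per-diem day conversion |
| warehouse `utilization_fraction` | — | 0.3 | commercial usable-volume heuristic |
| `packaging_factor` | — | 1 | secondary/tertiary packaging overhead |

## Numerical choices

Ceilings appear exactly where physical integrality does: trips per
shipment, loops per cycle, per-diem days, vehicles per hub. Cost as a
function of demand is therefore piecewise linear with jumps only at
capacity boundaries. Zero-demand scenarios are well-defined (variable
lines zero, minimum fleet and management persist). Degenerate division
is guarded: zero reference values are excluded from MAPE, a zero-cost
baseline is rejected in comparisons, and a 1-stop "loop" collapses to
hub-and-spoke semantics. Monotonicity of total cost is guaranteed in
demand and every unit rate; for facility count it holds when per-facility
demand is held fixed (a larger network serves more people), which is how
the property is tested — redistributing a *fixed* system volume over more
facilities can lower cost at trip-ceiling boundaries, and that is real
behaviour, not an error.

## Problem sizes in the test suite

The suite exercises: $10^5$-point Monte-Carlo distance calibration; 24
heuristic tour instances up to 100 stops; 100 randomized scenarios for
conservation; 20-point parameter sweeps for monotonicity; and 20-seed
oracle comparisons at $n = 20$ and $n = 400$ facilities. These sizes make
the full suite run in well under a minute while keeping Monte-Carlo
standard errors far below the asserted tolerances.

## Known limitations

* Strictly linear hierarchies (each tier resupplied only by the tier
  above); mixed designs are handled by aggregation of separate models.
* Management FTE is per-site constant; if ordering effort scales with
  shipment frequency, redesigns that change frequency will misstate
  management cost.
* No stockout/availability simulation, lead-time variability, or
  multi-echelon inventory optimization — outputs are cost and
  utilization only.
* The wastage convention inflates both volume and value; analyses that
  apply wastage only to value should adjust `price_per_dose` instead.
* Equal-partition loops are an approximation; a dispatcher would balance
  loops by geography, not facility count.
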