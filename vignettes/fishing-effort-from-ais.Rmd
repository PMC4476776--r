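---
title: "Identifying fishing activity and mapping effort from AIS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying fishing activity and mapping effort from AIS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aiseffort)
```

## The problem

AIS position reports carry a vessel identifier, a timestamp, coordinates
and speed over ground. For fleets towing mobile gear, the at-sea speed
distribution is strongly bimodal: a low mode (roughly 2–4 kn for trawlers)
while the gear is in the water and a high mode (8–12 kn) while steaming to
and from the grounds. `aiseffort` exploits that structure to label every
message as fishing or non-fishing, and from the labels builds effort maps
in kW-days at nautical-mile resolution — far finer than the 0.5° × 1°
ICES rectangles of logbook reporting.

The package is written for the realistic situation in which the three
input tables — AIS messages, a fleet register and logbooks — cannot be
redistributed. A simulator with known ground truth stands in for them, so
every claim made below is backed by a test the reader can run.

## Speed-profile model

Per vessel, cleaned speeds $v$ are modelled as

$$ f(v) = \pi\, \mathcal N(v;\mu_1,\sigma_1^2)
        + (1-\pi)\, \mathcal N(v;\mu_2,\sigma_2^2), \qquad \mu_1 < \mu_2 .$$

`fit_speed_mixture()` maximises the likelihood by EM: the E-step computes
each observation's ownership probability under the current parameters, the
M-step re-estimates $(\pi, \mu_k, \sigma_k)$ as responsibility-weighted
moments. Numerical choices, all overridable:

* **Stopping rule**: change in log-likelihood below $10^{-8}$, at most
  1000 iterations; `converged = FALSE` when the cap is hit. Well-separated
  profiles converge in a handful of iterations; near-unimodal data can
  legitimately need thousands (the likelihood surface is a shallow
  plateau), which is why `max_iter` is exposed.
* **Initialisation**: means at the 25th/75th speed percentiles, SDs at
  half the sample SD, $\pi = 0.5$; two further restarts from random
  responsibilities guard against local optima, best log-likelihood wins.
* **Variance floor** $\sigma \ge 0.05$ kn, which bounds the likelihood and
  prevents the classical EM collapse onto a single observation.
* **Component ordering**: components are sorted so $\mu_1 < \mu_2$;
  component 1 is by definition the fishing mode.
* **Overlap diagnostic**: vessels with $|\mu_2-\mu_1| < 2\max(\sigma_1,
  \sigma_2)$ are flagged — the two-regime model fits trawlers, not
  longliners or potters, and the flag propagates rather than failing.

The fishing band is $[\mu_1 - k\sigma_1,\ \mu_1 + k\sigma_1]$ floored at
0 kn, with $k = 1.5$ fleet-wide by default; classification is inclusive at
both ends (a measure-zero choice fixed for reproducibility). An immediate
analytic consequence, used as a test oracle: when the modes are well
separated, the band captures $\Phi(1.5)-\Phi(-1.5) \approx 0.8664$ of true
fishing messages.

## Cleaning

`clean_messages()` applies three filters in a fixed, ledgered order:

1. **speed > 0.5 kn** (strict): removes the in-port/idle component that
   would otherwise add a third mode at zero;
2. **more than 300 messages per vessel** (strict): below that the EM
   estimates are not considered robust;
3. **per-vessel speeds ≤ Q3 + 1.5 IQR**: drops sensor spikes. Quartiles
   use linear interpolation between order statistics (the `quantile()`
   type-7 default); the rule is applied per vessel, not fleet-wide,
   because the profiles it protects are per-vessel. Vessels with fewer
   than four messages skip this filter (quartiles ill-defined) and are
   logged.

The chain is defined as single-pass: filters 1–2 are idempotent, filter 3
re-applied could remove more rows (the quartiles move), which is why the
chain is not re-run to a fixed point.

## Record linkage and uptake

Register rows and AIS vessels are matched in three steps after
case-folding and stripping punctuation: exact callsign join; fuzzy match
on names; fuzzy match on callsigns. A fuzzy candidate pair is accepted
only if (a) the larger of the normalised Levenshtein similarity
$1 - d/\max(\text{len})$ and the Jaro similarity reaches the threshold
(default 0.85), and (b) the pair is the *unique mutual best* — each side
is the other's argmax with a strictly positive margin; exact ties reject
both sides. The disjunction of the two scores maximises recall (Jaro
forgives the adjacent transpositions that cost Levenshtein 2 edits);
the uniqueness rule guards precision and makes the output one-to-one by
construction. The threshold and the combination rule are this package's
own defaults, exposed as parameters.

Uptake is reported per stratum as $100\,n_{\text{with AIS}} /
n_{\text{registered}}$, a vessel counting as "with AIS" iff at least one
message exists in the window; the monthly variant counts vessels from
their first-message month onward and is therefore non-decreasing.

## Validation against logbooks

Logbooks give one point per fishing operation. Instead of a binary
confusion matrix against an arbitrary spatio-temporal window, validation
is stochastic: a bivariate Gaussian kernel utilisation distribution is
estimated from each vessel's operation points (`MASS::kde2d` under the
hood), every message takes the raster value of its cell — 0 outside the
raster — normalised by the vessel's raster maximum so scores lie in
$[0,1]$ with higher = closer to the core grounds, and a two-sided paired
t test compares per-vessel mean scores of the two label groups.

Choices: bandwidth $h = 0.5\,(s_x + s_y)\, n^{-1/6}$ (an ad hoc reference
rule from the kernel home-range literature; co-located points fall back to
the cell size), raster cell 0.01°, bounds the points' bounding box padded
by $3h$, density renormalised to integrate to 1 on the raster. Vessels
with fewer than 5 logbook points, or missing one label group, are
excluded and logged; degrees of freedom come from the actual pair count.
Zero-variance differences would make the t statistic undefined, so
identical score vectors report $t=0, p=1$ and a constant non-zero
difference reports $p=0$ with a degeneracy flag — fleet reports always
complete.

## Effort

Each fishing-labelled message represents one nominal reporting interval
(300 s) of fishing, contributing $P \cdot 300/86400$ kW-days for engine
power $P$; an optional mode weights messages by the gap to the next
message capped at twice the interval, for irregular feeds. The 1×1 NM
grid is a local equirectangular grid anchored at the region's south-west
corner — $\Delta\text{lat} = 1/60°$, $\Delta\text{lon} =
1/(60\cos\text{lat}_0)°$, half-open cells — a documented convention, since
nautical-mile cells cannot be exactly georeferenced in an unprojected
CRS. The grid total equals the closed-form message sum to $10^{-9}$
relative error by construction, and is asserted.

The logbook comparator allocates each trip's departure-to-arrival duration
(fractional days) to the ICES rectangles where it notified catches,
proportionally to catch weight (equal split with a warning when a
multi-rectangle trip reports zero catch), times engine power.
`ices_encode()`/`ices_decode()` implement the published rectangle scheme —
0.5° rows numbered from 36°N, lettered 1° columns from 44°W with `I`
unused — and are mutually inverse on the valid domain, with half-open
cells. Comparison re-aggregates the fine grid to rectangles and reports a
Spearman rank correlation: AIS totals are expected *below* logbook totals
(fishing time vs days at sea); it is the spatial pattern that should
agree.

## Coverage

Reception is estimated by reconstructing what should have been received:
per-vessel message series are split into segments wherever the time gap
exceeds 6 h or the great-circle jump exceeds 20 NM (defaults; they also
separate two physical ships sharing an identifier), linearly interpolated
in lon/lat at the 300-s cadence (AIS cadence is high enough that splines
or behavioural models add nothing at 0.1° resolution), and the per-cell
ratio observed/expected is reported. Cells with no expected traffic are a
distinct *indeterminate* category rather than 0 — an empty cell cannot
distinguish absent ships from absent reception. Under perfect reception
and matching cadence the ratio is exactly 1 in every traversed cell.

## The simulator

`simulate_fleet()` generates the study conditions the pipeline assumes.
Defaults, chosen once as a realistic small demersal-trawler fleet and not
tuned thereafter: 30 vessels in a Skagerrak/Kattegat bounding box
(9.5–13.5°E, 56.5–58.5°N), towing at 3 ± 0.5 kn, steaming at 10 ± 1 kn,
300-s cadence, 60% of at-sea time fishing, 8 trips per vessel, engine
power uniform on 200–1500 kW. Each vessel cycles port → steam → fish →
steam → port; port messages report exactly 0 kn (exercising the zero-speed
filter), speeds are state Gaussians truncated at 0, tracks are piecewise
linear with towing positions scattered (SD 0.02°) around a per-vessel
ground centroid, and one logbook operation per fishing segment is emitted
at the centroid with a positive log-normal catch. Messages are sampled at
the segment start and every interval, half-open at the segment end;
segment durations are snapped to whole multiples of the interval so that
a segment of duration $d$ emits exactly $d/300$ messages and counting
invariants are exact. Reception dropout is a scalar or a
`function(lon, lat)` probability; typos (`inject_typos()`) apply one
keystroke error — substitution, deletion or adjacent transposition, each
one unit of optimal-string-alignment distance — to a configurable fraction
of register rows.

What the simulator does *not* emulate — and what passing tests therefore
do not establish about real data: hydrodynamics and weather, gear types
other than the two-regime trawl pattern (fixed gears produce zero-speed
fishing messages the method deliberately excludes), satellite-AIS message
collisions, misreported logbooks, and the register heterogeneity of a
real multi-national fleet. Results on real data will degrade exactly where
the underlying assumptions do: unimodal or overlapping speed profiles
(watch the overlap flag), sparse transmitters, and poor reception areas.

## Problem sizes and determinism

Everything is seeded and deterministic: the simulation is a pure function
of its configuration, EM restarts take an explicit seed, and scoring is a
deterministic overlay. The shipped tests and the acceptance script run on
a few tens of vessels, $10^3$–$10^4$ messages per vessel and 50-replicate
parameter-recovery studies — sizes chosen so the whole suite completes in
well under a minute on a laptop while every statistical check retains
enough power (binomial tolerances are stated as 3 SDs at the simulated
$n$). Grids and rasters are exchanged as plain CSV (cell centroid plus
value), a format every GIS imports.

## Known limitations

* Two components only: a third "searching" mode, present in some fleets,
  is out of scope; affected vessels surface through the overlap flag.
* The classification band uses speed alone — no bearing, no positional
  context.
* The UD validation is itself limited by logbooks: one point per
  operation stands in for the whole towed track.
* Effort assumes one engine power per vessel from the register; missing
  powers skip messages and are counted, not imputed.
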