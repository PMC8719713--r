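---
title: "Methods: delineating the annual cycle from duty-cycled satellite telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delineating the annual cycle from duty-cycled satellite telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flyway)
```

This vignette is the package's account of its methods: the models and rules
each stage implements, the tunable parameters and why their defaults are what
they are, what the synthetic-telemetry generator does and does not emulate,
and the numerical and design choices a maintainer should know about. No
number quoted here is asserted as a result; everything checkable is computed
by the test suite or by `scripts/acceptance.R`.

## The observation process

ARGOS satellite transmitters report Doppler-derived positions tagged with a
location class: LC3 (< 150 m), LC2 (150–350 m), LC1 (350–1000 m), LC0
(> 1 km), and LCA/LCB/LCZ with no accuracy estimate. Solar tags run on duty
cycles — here 48 h off / 10 h on (or 24 h off / 5 h on) — and collect 1–34
fixes per on-period. The analysis keeps LC1–LC3 only (`filter_quality()`);
LC0/A/B/Z fixes inform no downstream step. An optional speed-spike filter
(off by default, since the core protocol does not use one) iteratively drops
fixes implying an implausible speed to both temporal neighbours, which makes
the filter idempotent.

All coordinates are unprojected WGS84 decimal degrees with longitudes
normalized to (−180, 180]; all distances are haversine great-circle
distances on a sphere of radius 6371.0088 km (IUGG mean radius). A spherical
rather than ellipsoidal earth is a deliberate simplification: the test suite
carries a WGS84 geodesic oracle (`geosphere::distGeo`) and checks the
spherical approximation stays within 0.6% for arbitrary point pairs.

## Season delineation

A territory model (`fit_territory_model()`) is the arithmetic mean latitude
and circular mean longitude of early-residency fixes, plus the mean and SD
of great-circle displacements of those fixes from the centroid. The fitting
window is the first 14 days of a residency (`territory_window_d`): long
enough for a stable estimate under the sparsest duty cycle (~25 fixes after
filtering), short enough never to contaminate the model with departure
movement.

A **departure** is the first subsequent fix whose displacement exceeds
`mean + 2 SD`. Raw single-fix exceedance is noise-fragile, so the event must
be confirmed: either the fix is already more than 100 km out, or the next
fix also exceeds the threshold *and* has gained at least 5 km of
displacement. The gain requirement is this package's addition to the plain
two-in-a-row rule: consecutive foraging commutes can graze a
slightly-underestimated threshold, but they cannot gain 5 km outward twice
in a row, whereas a genuine departure at flight speed gains tens of
kilometres between fixes. On data where departures are abrupt the guard is
inert. An **arrival** is read from the other side: the first fix of the next
stationary residency is the observed arrival fix, and its in-flight
predecessor anchors the timing.

When a transition happens during a transmitter off-period, the observed fix
lags the true event. Following the flight-speed rule, the apparent speed
between the event fix and its adjacent in-flight fix is compared with
`v̄ − 2·SD(v)` where the mean flight speed is 14.7 m/s. The printed
uncertainty "± 0.3, n = 45" is read as a standard error, so the SD is
`0.3·√45 ≈ 2.01 m/s` and the threshold 10.68 m/s; both are configuration
(`mean_speed_mps`, `sd_speed_mps`). An apparent speed below the threshold
means the interval contained stationary time, and the event time is offset
from the in-flight fix by great-circle distance ÷ 14.7 m/s: departures are
shifted earlier from the breakout fix, arrivals later from the last
in-flight fix. One consequence worth stating: an interpolated arrival time
lies *at or before* the first on-territory fix, between it and the last
in-flight fix — the natural reading of the rule, and the one the test suite
pins down.

**Stationary periods** (`detect_stationary_periods()`) are maximal runs of
fixes whose segment displacements are site-scale — segment speed below
5 km/h *or* a hop shorter than the 25 km site radius (closely spaced fixes
inside a site imply arbitrarily high apparent speeds from positional error
alone) — that stay within 25 km of the running centroid and span at least
6 h. The defaults sit below any sustained flight speed and above the scale
of roosting/foraging commutes; all three are configurable.

**Territory identification.** Season boundaries need to know which
stationary periods are breeding/winter territories rather than staging
stays. Duration alone cannot decide this: a breeding residency can be
shorter than a long spring staging stay. Field studies know where animals
were deployed, so `segment_annual_cycle()` accepts `territory_hints` —
known breeding/winter regions; a stationary period within 120 km of a hint
is a territory. Without hints, a fallback duration rule (≥ 45 d) applies,
appropriate when winters dominate and residencies are long. The four
transition events per animal-year then partition the year: autumn =
[breeding departure, winter arrival), winter = [winter arrival, winter
departure), spring = [winter departure, breeding arrival).

## The movement model

Duty cycles leave multi-day observation gaps along migration. They are
bridged with a continuous-time correlated random walk: per planar axis the
velocity is an Ornstein–Uhlenbeck process (`dv = −β v dt + σ dW`) and
position its integral. β (1/h) sets the velocity autocorrelation
(`exp(−β τ)` at lag τ); σ (km/h per √h) the velocity stochasticity. The
exact discrete-time transition over an arbitrary step is Gaussian with
closed-form moments (coded once in `iou_step()` and reused by the filter,
the smoother, and the simulator), so irregular fix intervals cost nothing.

Choices a user should know:

- **Working frame.** Each leg is projected with a spherical
  azimuthal-equidistant projection centred on the leg's temporally middle
  fix, fitted and smoothed in the plane, and inverse-projected before any
  distance is measured. Radial distances from the centre are exact; the
  bounded tangential distortion affects only the fitted path shape, never
  the geodesic measurement of it.
- **Observation error is fixed, not estimated**: LC3 = 100 m, LC2 = 250 m,
  LC1 = 700 m (midpoints of the class definitions). Estimating error scales
  alongside β and σ on duty-cycled data is poorly conditioned.
- **Likelihood and prior.** The Kalman filter evaluates the exact
  likelihood; the state prior at the first fix is position ~ N(first
  observation, 100² km²) with the stationary velocity distribution
  N(0, σ²/(2β)). The same prior is used by the brute-force joint
  multivariate-normal oracle in the tests, which must agree with the filter
  to 10⁻⁶ relative on small instances.
- **Optimization** is L-BFGS-B on (log β, log σ) from a fixed init
  (β = 0.5/h, σ = 5), deterministic by construction. Standard errors come
  from the numerical Hessian by the delta method. A track with no movement
  pins σ at its lower bound and is flagged `degenerate` rather than
  erroring.
- **Numerics.** The covariance update is written in its cancellation-free
  form (`P′ = P·τ²/S` for the position block, clamped Schur complement for
  velocity): long legs mix huge prediction variances with sub-km
  observation variances, and the textbook subtraction form loses positive
  definiteness there.
- **Prediction** (`predict_path()`) runs the fixed-interval (RTS) smoother
  over the union of fix times and a regular grid, default `dt = 15 min` —
  fine relative to flight timescales (~13 km of flight per step), coarse
  enough that a year of track smooths in seconds.

## Migration metrics

Migration length is measured along the smoothed pathway as a sum of
great-circle segments, **excluding local movements**: grid segments falling
inside a detected stationary period are replaced by the entry-to-exit
great-circle step of that period, so wander at a 20-day staging site cannot
inflate a migration distance. Duration is elapsed time from departure to
arrival including stops, and migration speed their ratio in km/d — so added
stopover time lowers speed monotonically, a property the tests assert.
Repeat seasons from one animal are treated as independent samples in group
summaries, matching the study design this mirrors; pooled Student's t
(df = n₁+n₂−2) is the default because printed df subscripts follow that
convention, with Welch available. The Bonferroni family is the set of tests
in one output table.

## Staging areas and stopovers

Stationary periods away from territories are clustered by single linkage on
great-circle distance, cut at 250 km — staging areas in this flyway are
regional (a single "South Atlantic" area spans several hundred km of
coast). Cluster labels are deterministic: clusters are relabelled by the
lexicographic (lat, lon) order of their centroids, making the clustering
invariant to input permutation. Classification operationalizes the
staging-area concept: median stay ≥ 7 d, onward leg > 1,000 km, and reuse
(≥ 2 years, or ≥ 20% of tracked animals — the fraction matters because
single-year datasets cannot show between-year reuse). The "high resource
density" criterion of the underlying ecological definition is unobservable
from telemetry and intentionally not part of the classifier. The 7-day
boundary admits the shortest genuine staging stays while excluding typical
1–3 day stopovers; stays that are long but fail the other criteria are left
`unclassified` rather than forced into a bin. Stopovers are associated with
the staging area their visitors most recently left (majority vote, ties to
the earliest site id; stopovers before any staging are flagged as
origin-associated). Fidelity counts, over all (animal, staging site, year)
events with the animal tracked through the same season the following year,
the fraction in which the site was used again; overflying a previously used
site counts against fidelity, and no repeat-year data yields NA, not zero.

## The synthetic-telemetry generator

No tracking data are distributed with this package, so verification rests
on a generator whose defaults encode the study conditions it emulates:

- **Schedules.** Per-individual transition dates are Gaussian around the
  published population means (e.g. Mackenzie-like autumn departure 7 July,
  winter arrival 30 August; Hudson-like 22 July / 18 September), with
  between-individual SDs reconstructed as SE·√(seasons) from the printed
  standard errors. Infeasible draws (a season span shorter than its flight
  time, or a residency too short to fit a territory window) are rejected
  and redrawn; this truncation shifts cohort means by well under a day.
- **Routes** are great-circle polylines through shaping waypoints chosen
  once so that each leg's true length matches the published mean migration
  distances to within 2 SE; the winter centroid sits on the Amapá coast
  inside the published winter range. The geography is synthetic — it
  reproduces lengths and the staging sequence, not actual coastlines.
- **Staging stays** are Gaussian around the published per-site means, then
  rescaled so flights plus stays exactly fill the drawn season span. The
  published tables are not mutually consistent here (mean stays plus flight
  times do not everywhere equal the implied season spans), and the
  phenology is what the acceptance checks target, so dates win: simulated
  stays deviate from their table means by the rescale factor.
- **Unplanned stopovers** are Poisson per leg (population- and
  season-specific rates at the published scale) with exponential 2-day
  stays, placed on long flight segments at least 150 km from any endpoint
  so they never merge with a staging site or territory.
- **Within-territory wander** is an independent per-fix draw from a
  central-place commuting mixture: with probability 0.65 the bird is at
  foraging range (0.92–1 × the 5 km territory radius), otherwise near the
  roost. The mixture is chosen so that the displacement distribution's
  mean + 2 SD sits near 1.5 × the radius — safely above the maximum
  possible displacement — making false breakout confirmations essentially
  impossible, consistent with the abrupt, false-start-free departures the
  rule assumes. A smooth bounded random walk would look the same through a
  duty cycle but can linger at the disc edge and fake a departure.
- **Observation** samples 1 + Poisson(4.48) fixes (capped at 34, mean
  ≈ 5.48) uniformly within each on-window, labels each fix with a location
  class drawn from a realistic mix, and perturbs it with circular Gaussian
  error of per-class RMS 100/250/700/1500/3000/5000 m. Fix times are
  rounded to seconds and coordinates to 10⁻⁶ degrees, which defines the
  canonical form on which read/write round-trips are exact.

What the generator does **not** emulate: wind and weather, coastline
affinity, energetics, behavioural route choice, the small
Mackenzie-spring subpopulation that stages on the South Atlantic rather
than the Gulf Coast, and real ARGOS error tails (which are longer than
Gaussian). Passing tests therefore demonstrate that the pipeline recovers
truth under idealized-but-duty-cycled observation of schedule-driven
movement, not that it is robust to every pathology of field data.

## Problem sizes and runtime choices

The test suite and acceptance script run on deliberately modest sizes: 10
animals per cohort for event-accuracy properties, 30 per population for the
between-population phenology recovery, 20 replicates of 500 fixes for
movement-model parameter recovery, and 8 animals for the along-path distance
check (on the denser 24 h off / 5 h on duty cycle, whose ~1,300 km
between-fix flight scale resolves the route structure; the sparser 48/10
cycle shortcuts corners and biases length low by around 10% — a real
resolution limit of such data, stated here so nobody mistakes the distance
numbers for duty-cycle-independent). These sizes give stable statistics in
minutes on one core.

## Known limitations

- Event recovery near a staging site close to the territory (e.g. a
  Beaufort-Sea-like area a few hundred km from breeding) is the hardest
  case: the bird may already be staging when the transmitter wakes, and the
  flight-speed rule can only partly reconstruct the departure time. Median
  event errors stay well under a duty cycle; individual autumn departures
  can err by 1–2 days.
- Migration distances inherit the duty-cycle resolution limit above.
- The 2-SD breakout rule assumes displacement-from-centroid; an alternative
  reading (step-length based) is not implemented.
- Multi-year segmentation relies on territory hints; fully blind multi-year
  delineation with short breeding residencies is out of scope.
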