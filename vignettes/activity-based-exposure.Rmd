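---
title: "Activity-based exposure assessment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-based exposure assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Epidemiological studies of traffic-related air pollution usually assign each
person the ambient concentration at their residence address. People move,
though, and traffic-related pollutants such as NOx vary strongly over both
space (highest along major roads and in urban cores) and time of day
(morning and evening commute peaks). `airtrace` implements the
*activity-based* alternative: a person's full 24-hour travel diary is routed
over the road network, discretized into a space–time trace, and matched
point-by-point to a diurnally varying gridded concentration field. The
package then quantifies what the simpler residence-based estimate gets
wrong — the *exposure error* and the *attenuation bias* it induces in
health-effect estimates — and how exposure and error are distributed across
sociodemographic and urbanicity groups.

## Exposure model

Both estimators are time-weighted means over an averaging period of
$T = 24$ h,

$$C = \frac{1}{T}\int c\,\mathrm{d}t .$$

The **residence-based** concentration uses the 24 hourly values
$c_\tau$ of the diurnal cycle at the residence cell only
($\Delta t_\tau = 1$ h):

$$C_R = \frac{\sum_\tau c_\tau \Delta t_\tau}{T}.$$

The **activity-based** concentration sums over every discretized
space–time element $\sigma$ of the person-day trace, with $c_\sigma$ the
concentration of the grid cell and hour containing that element and
$\Delta t_\sigma$ the time spent there:

$$C_A = \frac{\sum_\sigma c_\sigma \Delta t_\sigma}{T},
\qquad E_A = \sum_\sigma c_\sigma \Delta t_\sigma .$$

Exposure error is the percent difference $100\,(C_A - C_R)/C_A$; positive
values mean the residence-based estimate *under*estimates true exposure.
The attenuation **bias factor** is the OLS slope of $C_A$ on $C_R$ across a
sample: in a linear health model fitted with the residence-based surrogate,
relative-risk estimates scale by roughly this slope, so values below one
mean attenuated risk estimates. The slope definition is the standard
surrogate-exposure attenuation factor; it is consistent with the direction
of the bias the method is meant to reveal.

Implementation details that matter for exactness:

* Time is minutes from midnight with half-open intervals
  $[t, t + \Delta t)$; diaries use integer minutes, traces may be
  fractional. Each trace element is split at hour boundaries before lookup,
  so the integral is computed exactly for the piecewise-constant field (the
  test suite checks agreement with a 1-second Riemann sum to $10^{-6}$
  relative).
* A zero-travel day evaluates $C_A$ through the *same* weighted-sum code
  path as $C_R$, so its exposure error is exactly zero in floating point,
  not merely small.
* Concentration lookup is piecewise constant in space (cell assignment, no
  interpolation — matching how gridded dispersion-model receptors are
  intersected with locations) and in hour of day. Out-of-domain points
  raise an error by default, mirroring the exclusion of out-of-area travel
  from the study sample; a clamp option exists for robustness experiments.

## Diaries, routing, and traces

A *person-day* is one individual's 24-hour record: sociodemographics
(age group 5–18 / 19–45 / 46–65 / >65; non-exclusive self-identified race
flags; income below poverty / middle / ≥\$75,000; gender), a residence
point, and an ordered trip list (start minute, reported travel minutes,
dwell minutes at the destination, purpose). Records pass through:

1. **Filtering** — incomplete (`missing`), internally contradictory
   (`inconsistent`: overlapping or out-of-order trips, a trip origin more
   than 1 m from the previous destination, negative durations), or
   out-of-domain (`out_of_domain`) records are excluded with reason codes.
   The consistency rules are our operationalisation; survey practice does
   not enumerate them.
2. **Paring** to exactly `[0, 1440)` minutes: trips past midnight are
   dropped or truncated (a trip in progress at minute 1440 keeps its
   clipped travel time; its trace is thereby clipped proportionally in
   time).
3. **Timeline construction** — a gapless partition of the day into
   `at_residence`, `nonresidential`, and `in_travel` episodes. Purposes map
   home → at-residence, travel → in-travel, and work/meals/other →
   nonresidential. A zero-trip day is one 1440-minute at-residence episode.

Trips are routed on the road network by **shortest travel time** under
free-flow link speeds (time = length/speed), traversal undirected. Ties are
broken deterministically (fewer links, then smaller node ids); trip
endpoints snap to the nearest network node (sub-link precision is
immaterial against 1-km concentration cells). The routed path is sampled
every 100 m of arc length plus the terminal endpoint, and each sample
receives the travel time of its midpoint-to-midpoint span under link times
rescaled by reported/free-flow total time. The midpoint-span rule is one
defensible reading of fixed-interval path sampling — the alternative of
equal time shares per sample point ignores local speed — and it makes the
per-trip time sum *exactly* the reported travel time (the final span
absorbs floating-point residue). Congestion-dependent routing, turn
penalties, and route-choice heterogeneity are out of scope; computed routes
need not coincide with actual paths.

## The synthetic city

Real inputs of this kind (a household travel survey, a commercial road
network, dispersion-model output) are proprietary, so the package generates
a self-consistent synthetic study area. The generator is first-class,
seeded, and fully deterministic: identical configurations reproduce
identical networks, fields, and diaries byte for byte. Randomness is one
master stream that draws a sub-seed per person-day, so individual diaries
are reproducible even under parallel generation.

* **Network** — a planar `grid_n` × `grid_n` graph (default 25 × 25 at
  1 km spacing, about the extent of a mid-sized county) with every 5th row
  and column an arterial (80 vs 50 km/h free-flow). Coordinates are planar
  meters; there is no geographic projection since all inputs are synthetic.
* **Urbanicity zones** — concentric urban (4 km) and suburban (9 km) radii
  around the center, discrete outlying second-city disks, rural elsewhere;
  inner boundaries are half-open.
* **Concentration field** — `profile[h] * (background + urban Gaussian +
  road kernels)`, cells centered on nodes. The urban bump (12 µg/m³ over an
  8 µg/m³ background) and per-arterial-link Gaussian kernels (6 µg/m³,
  300 m scale) put the highest concentrations along major roadways and over
  the core; the 24 shared multipliers impose a sharp morning (6–8 h) and a
  broader, slightly lower evening (17–21 h) peak. These amplitudes were
  chosen once so that daily exposures land in the low tens of µg/m³, the
  range typical of modeled NOx in sprawling US counties.
* **Population** — households placed uniformly on nodes; sociodemographics
  drawn *conditional on the residence zone* (residential sorting, e.g.
  P(black | urban) = 0.35 vs 0.06 rural), so group exposure disparities
  emerge from sorting rather than being painted on. About 19.5% of
  person-days have no travel (more for the elderly and children, matching
  the share of no-travel records in county travel-survey samples).
  Travelling diaries are home-anchored tours: a bimodal commute departure
  mixture, 1–3 destinations drawn with exponential distance decay
  (5 km scale) weighted toward urban destinations (job centralisation),
  work dwells near 7 h, other dwells lognormal near 1.5 h, and reported
  travel times equal to a network-distance estimate inflated by 5–45%
  (so the link-time rescaling in discretization is exercised). Infeasible
  schedules are redrawn with bounded retries, falling back to single-stop
  tours.

Survey sources give no quantitative trip-rate or dwell-time distributions,
so those defaults are free parameters chosen for plausibility — they are
the package's study conditions, not calibrated claims. What the generator
deliberately does *not* emulate: real geography, emissions or meteorology,
survey weighting, indoor/microenvironment concentrations, multi-pollutant
chemistry. Passing tests therefore demonstrate correctness of the
*method* — integration, routing, statistics — and qualitative
reproduction of the published disparity and attenuation structure, not
quantitative claims about any real population.

## Disparity statistics

Group summaries report n, mean, a t-based 95% CI (correct for small
groups; the source analysis states only "95% confidence intervals"), range,
and interpolated percentiles. Differences between group means use one-way
ANOVA followed by Games-Howell post hoc testing, which drops the
equal-variance assumption: Welch standard errors and degrees of freedom
(used unrounded) with the studentized range distribution over all $k$
groups. With $k = 2$ it reduces to the Welch t test, and for homoscedastic
equal-n groups it approaches Tukey's HSD; both identities are verified in
the tests, along with agreement with an independent implementation.
Racioethnic groups are non-exclusive (self-identified flags), so they are
summarised as overlapping subsamples rather than as levels of one factor.

The exposure model itself is a **hierarchical stepwise OLS**: predictor
blocks enter in a fixed order — sociodemographics (gender, age,
racioethnicity), income, urbanicity, then continuous hours away from home —
and within each block the least-significant predictor with $p \ge 0.05$ is
dropped, one at a time, until the block's survivors are all significant.
Earlier-block retentions are never re-dropped; whether the original
procedure ever re-dropped them is unstated, so we fix the
simpler convention and report dropped predictors explicitly. Categorical
predictors are 0/1 dummies against reference categories (female, 19–45,
nonblack, income ≥\$75,000, rural residence, no time away). Interactions
(urban × black, suburban × black, suburban × below-poverty) are refit on
the retained model as elementwise-product columns named `a_x_b`
(syntactic so they work in formulas).

Survey-weighted inference, household random effects, and multiple-testing
corrections beyond Games-Howell's familywise control are deliberately
omitted, matching the scope of the analysis the package reproduces.

## Numerical and design choices

* Half-open intervals everywhere (cells, hours, zone radii) make boundary
  assignment unambiguous; a point exactly on an interior cell edge belongs
  to the higher-index cell.
* The gas conversion NOx → NO2 ppbv uses a typical NO2/NOx mass fraction
  of 0.8 and the ideal-gas molar volume $V_m = 22.414\,(T/273.15)/P$ L/mol
  at 25 °C and 1 atm (overridable). The same fraction is applied before
  scaling µg/m³-based risk slopes; for the mortality-slope example both
  readings (with and without the fraction) round to the same whole percent,
  and the poverty-gap figure is consistent only with applying it, so it is
  applied uniformly and documented here.
* Games-Howell p-values require Welch df ≥ 2 (a limit of the studentized
  range distribution); near-singleton groups yield `NA` with a warning.
* Degenerate paired t tests are explicit: identical pairs give
  $t = 0, p = 1$; constant nonzero differences give $t = \pm\infty, p = 0$.
* The pipeline drops predictors that are inestimable in a given sample
  (zero variance or aliased columns) before the stepwise fit, with a
  message — small synthetic samples may lack, say, rural residents.

## Problem sizes

The shipped tests run the pipeline end-to-end on cities of roughly 60–150
households (one to a few hundred person-days) and verify the routing,
conservation, and integration oracles on hundreds of randomized small
instances; the full default configuration (25 km grid, 800 households,
~1,400 person-days) runs in a few minutes on one core thanks to cached
single-source shortest-path trees. These sizes were chosen as the smallest
that exercise every code path and leave the statistical checks
well-powered.

## Known limitations

Single pollutant; ambient concentrations only (no inhalation, infiltration,
or microenvironments); free-flow shortest-time routing only; planar
geometry; urbanicity from a single radial zoning rule. Group-level
disparity statistics do not represent individual exposures.
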