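# airtrace

Activity-based assessment of exposure to traffic-related air pollution
(NOx) from 24-hour travel diaries, for exposure scientists and
environmental epidemiologists who want to quantify what residence-only
exposure assignment misses.

Most large health studies assign each person the ambient concentration at
their home address. `airtrace` implements the activity-based alternative
and the error analysis around it:

* **Diaries → traces.** Person-day travel diaries are validated, filtered
  (with `missing` / `inconsistent` / `out_of_domain` reason codes), pared
  to exactly 24 h, routed over a road network by shortest travel time, and
  discretized every 100 m of path into a space–time trace whose times sum
  exactly to the reported trip times.
* **Traces → exposures.** Each trace is matched in space and hour-of-day to
  a gridded diurnal NOx field, giving the time-weighted daily
  activity-based exposure concentration `C_A = Σ c_σ Δt_σ / T` alongside
  the conventional residence-based `C_R = Σ c_τ Δt_τ / T` (T = 24 h), the
  exposure error `100 (C_A − C_R) / C_A`, per-activity-kind exposures, and
  the attenuation bias factor (OLS slope of `C_A` on `C_R`; values < 1 mean
  residence-based studies understate relative risks).
* **Exposures → disparities.** Group distribution summaries with t-based
  95% CIs, one-way ANOVA with Games-Howell post hoc tests (unequal
  variances, Welch df, studentized range), paired t tests, and a
  hierarchical stepwise OLS of exposure on sociodemographics, income,
  urbanicity, and time away from home, with urbanicity × group
  interactions.
* **A synthetic city.** Because travel surveys, commercial networks, and
  dispersion fields are proprietary, a seeded generator produces a
  self-consistent study area: a planar road grid with arterials, radial
  urbanicity zones with second-city pockets, a diurnal concentration field
  peaked along roadways and commute hours, and a diary population whose
  sociodemographics are residentially sorted by urbanicity — so configured
  exposure disparities are recoverable end to end.

Conversions to NO2 ppbv (ideal-gas molar volume, NO2/NOx mass fraction
0.8) and linear scaling of literature concentration–response slopes turn
exposure differences into excess-risk estimates.

## Worked example

```r
library(airtrace)

city <- city_generate(city_config(seed = 2026, n_households = 300))
res  <- run_exposure_pipeline(city$person_days, city$network, city$field,
                              quiet = TRUE)
res
#> <exposure_analysis> 553 person-days
#>   mean C_A 17.0 ug/m3 (range 8.7-42.5), mean C_R 16.5 ug/m3
#>   mean exposure error 4.5% (range -80% to 60%), 52% positive
#>   bias factor: 0.82 (full), 0.78 (travelling)
#>   regression: Hierarchical stepwise OLS: c_activity ~ age_5_18 + black + urban + suburban
#>   n = 553, R^2 = 0.180, adj. R^2 = 0.174
#>   (Intercept)                15.444  t =  43.61  p = 2.36e-180
#>   age_5_18                   -1.817  t =  -2.41  p = 0.0165
#>   black                       0.399  t =   0.43  p = 0.665
#>   urban                       8.700  t =   8.93  p = 6.61e-18
#>   suburban                    3.845  t =   5.99  p = 3.85e-09
```

Reading this: across 553 simulated person-days the activity-based daily
exposure averages 17.0 µg/m³ NOx, and ignoring movement (using `C_R`)
underestimates exposure for 52% of person-days, by 4.5% on average. The
bias factor 0.82 says a health study using residence-based exposures here
would attenuate relative-risk estimates by ~18%. Urban residence is by far
the strongest predictor of exposure (+8.7 µg/m³ vs rural), the signature of
residential sorting built into the synthetic city.

Group tables and figures come from the same object:

```r
subset(res$summaries, metric == "c_activity" & group_type == "urbanicity")
#>   group        n  mean ci_lo ci_hi ...
#> 1 suburban   133  19.1  17.8  20.4
#> 2 second_city 31  14.8  12.9  16.8
#> 3 rural      333  15.2  14.6  15.9
#> 4 urban       56  24.0  22.6  25.4

tidy(res$regression)          # broom-style coefficients
glance(res$regression)        # R^2, adjusted R^2, n
autoplot(city$field, hour = 7)  # morning-peak concentration map
plot_exposure_cdf(res$records, c_activity, residence_urbanicity)
```

Turning a group difference into health terms:

```r
mortality <- risk_slope(2.9, "ug_m3_no2", 10, "all-cause mortality")
excess_risk(4, mortality)   # 4 ug/m3 NOx group-mean gap -> 0.93 % excess risk
#> [1] 0.928
```

All generation and analysis is deterministic under the configuration seed;
`city_write()` / `city_read()` round-trip every input through plain-text
CSV/JSON files with a manifest hash.

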