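#' Residence-based daily exposure concentration
#'
#' The conventional estimate: the time-weighted mean of the 24 hourly
#' concentrations at the residence cell, i.e. `C_R = sum(c_tau * dt_tau) / T`
#' with `dt_tau` = 1 h and `T` = 24 h. Computed with the same weighted-sum
#' arithmetic as [activity_exposure()], so a zero-travel day reproduces it
#' exactly.
#'
#' @param field A [conc_field()].
#' @param x,y Residence coordinates, meters (vectorised).
#' @return Daily mean concentration(s), ug/m3.
#' @export
residence_exposure <- function(field, x, y) {
  ij <- cell_index(field$grid, x, y)
  vapply(seq_along(ij$i), function(k) {
    vals <- field$values[ij$i[k] + 1L, ij$j[k] + 1L, ]
    sum(vals * 60) / 1440
  }, numeric(1))
}

# split trace points at hour boundaries; returns the trace with one row per
# (point, hour) fragment and columns hour, frag_dt
split_trace_hours <- function(trace) {
  lo <- floor(trace$t_start / 60)
  hi <- ceiling((trace$t_start + trace$dt) / 60) - 1
  hi <- pmax(hi, lo)
  frag <- tidyr::uncount(
    dplyr::mutate(trace, .lo = lo, .n = hi - lo + 1), .data$.n,
    .remove = FALSE, .id = ".k")
  frag$hour <- frag$.lo + frag$.k - 1
  f_start <- pmax(frag$t_start, frag$hour * 60)
  f_end <- pmin(frag$t_start + frag$dt, (frag$hour + 1) * 60)
  frag$frag_dt <- f_end - f_start
  frag <- frag[frag$frag_dt > 0, ]
  dplyr::select(frag, -".lo", -".n", -".k")
}

#' Activity-based daily exposure of one person-day
#'
#' Integrates concentration along the space-time trace:
#' `C_A = sum(c_sigma * dt_sigma) / T` with `T` = 24 h. Every trace point is
#' split at hour boundaries so each fragment is matched to the concentration
#' of its cell and hour; exposures `E = sum(c * dt)` and occupancy times are
#' accumulated by activity kind; the exposure error
#' `100 * (C_A - C_R) / C_A` is computed against [residence_exposure()] at
#' the given residence.
#'
#' @param trace A trace tibble for one person-day (see [build_trace()]),
#'   covering exactly 1440 minutes.
#' @param field A [conc_field()].
#' @param res_x,res_y Residence coordinates, meters.
#' @param clamp Clamp out-of-domain trace points to the grid edge (off by
#'   default: out-of-domain travel is an error, matching the exclusion of
#'   out-of-county records).
#' @return A one-row exposure-record tibble: `person_id`, `c_activity`,
#'   `c_residence` (ug/m3), `error_pct`, per-kind exposures
#'   `e_at_residence`, `e_nonresidential`, `e_in_travel` ((ug/m3) h),
#'   per-kind minutes `min_*`, and `travel_minutes`.
#' @export
activity_exposure <- function(trace, field, res_x, res_y, clamp = FALSE) {
  total <- sum(trace$dt)
  if (abs(total - 1440) > 1e-6) {
    stop("trace must cover exactly 1440 minutes (got ", format(total), ")",
         call. = FALSE)
  }
  frag <- split_trace_hours(trace)
  conc <- tryCatch(
    conc_lookup(field, frag$x, frag$y, pmin(frag$hour * 60, 1439),
                clamp = clamp),
    error = function(e) {
      stop("trace point outside the concentration domain for ",
           trace$person_id[1], ": ", conditionMessage(e), call. = FALSE)
    })
  w <- conc * frag$frag_dt
  c_a <- sum(w) / 1440
  c_r <- residence_exposure(field, res_x, res_y)
  kinds <- c("at_residence", "nonresidential", "in_travel")
  e_kind <- vapply(kinds, function(k) sum(w[frag$kind == k]) / 60, numeric(1))
  min_kind <- vapply(kinds, function(k) sum(trace$dt[trace$kind == k]),
                     numeric(1))
  tibble::tibble(
    person_id = trace$person_id[1] %||% NA_character_,
    c_activity = c_a,
    c_residence = c_r,
    error_pct = exposure_error(c_a, c_r),
    e_at_residence = e_kind[["at_residence"]],
    e_nonresidential = e_kind[["nonresidential"]],
    e_in_travel = e_kind[["in_travel"]],
    min_at_residence = min_kind[["at_residence"]],
    min_nonresidential = min_kind[["nonresidential"]],
    min_in_travel = min_kind[["in_travel"]],
    travel_minutes = min_kind[["in_travel"]]
  )
}

#' Exposure records for a filtered population
#'
#' Routes, traces, and integrates every person-day, returning one exposure
#' record per row joined to the sociodemographic columns.
#'
#' @param person_days A filtered, pared `person_days` tibble.
#' @param network A `road_network`.
#' @param field A [conc_field()].
#' @param interval_m Path sampling interval, meters.
#' @return A tibble: sociodemographics plus the [activity_exposure()]
#'   columns.
#' @export
exposure_records <- function(person_days, network, field, interval_m = 100) {
  cache <- new.env(parent = emptyenv())
  recs <- purrr::map_dfr(seq_len(nrow(person_days)), function(r) {
    pd <- person_days[r, ]
    trace <- build_trace(pd, network, interval_m, tree_cache = cache)
    activity_exposure(trace, field, pd$res_x, pd$res_y)
  })
  demo <- dplyr::select(person_days, -dplyr::any_of(c("trips")))
  dplyr::left_join(demo, recs, by = "person_id")
}

#' Exposure error of the residence-based estimate
#'
#' `100 * (C_A - C_R) / C_A`: positive when the residence-based estimate
#' underestimates the activity-based exposure.
#'
#' @param c_activity,c_residence Daily exposure concentrations, ug/m3
#'   (vectorised). `c_activity` must be positive.
#' @return Percent error(s).
#' @export
exposure_error <- function(c_activity, c_residence) {
  if (any(c_activity == 0)) {
    stop("exposure error is undefined for zero activity-based exposure",
         call. = FALSE)
  }
  100 * (c_activity - c_residence) / c_activity
}

#' Attenuation bias factor of residence-based exposure
#'
#' The ordinary least-squares slope of the activity-based on the
#' residence-based daily exposure concentration across a sample,
#' `cov(C_R, C_A) / var(C_R)`. In a linear health model fitted with the
#' residence-based surrogate, relative-risk estimates are multiplied by
#' roughly this factor, so values below 1 indicate attenuation.
#'
#' @param c_residence,c_activity Paired daily exposure concentrations,
#'   ug/m3.
#' @return The unitless slope.
#' @export
bias_factor <- function(c_residence, c_activity) {
  if (length(c_residence) != length(c_activity) || length(c_residence) < 3) {
    stop("need at least 3 paired exposure values", call. = FALSE)
  }
  if (stats::var(c_residence) == 0) {
    stop("residence-based exposures have zero variance", call. = FALSE)
  }
  fit <- stats::lm(c_activity ~ c_residence)
  unname(stats::coef(fit)[2])
}

#' Percent contribution of each activity kind to daily exposure
#'
#' @param records An exposure-record tibble (see [activity_exposure()]).
#' @return A long tibble `person_id`, `kind`, `percent`; percentages sum to
#'   100 within each person-day.
#' @export
activity_contributions <- function(records) {
  long <- records |>
    dplyr::select("person_id", dplyr::starts_with("e_")) |>
    tidyr::pivot_longer(dplyr::starts_with("e_"), names_to = "kind",
                        names_prefix = "e_", values_to = "e")
  totals <- long |>
    dplyr::summarise(total = sum(.data$e), .by = "person_id")
  if (any(totals$total == 0)) {
    stop("contributions are undefined for zero total exposure",
         call. = FALSE)
  }
  long |>
    dplyr::left_join(totals, by = "person_id") |>
    dplyr::mutate(percent = 100 * .data$e / .data$total) |>
    dplyr::select("person_id", "kind", "percent")
}

#' Convert an NOx mass concentration to an NO2 mixing ratio
#'
#' Applies a typical NO2 fraction of NOx, then converts the NO2 mass
#' concentration to ppbv with the ideal-gas molar volume
#' `V_m = 22.414 (T / 273.15) / P` L/mol (about 24.5 at 25 degrees C) and a
#' molecular weight of 46.01 g/mol.
#'
#' @param c_nox NOx concentration, ug/m3 (vectorised, non-negative).
#' @param no2_fraction Fraction of NOx mass that is NO2, in (0, 1].
#' @param temp_c Temperature, degrees C (above absolute zero).
#' @param pressure_atm Pressure, atm (positive).
#' @return NO2 mixing ratio(s), ppbv.
#' @export
nox_to_no2_ppbv <- function(c_nox, no2_fraction = 0.8, temp_c = 25,
                            pressure_atm = 1) {
  if (any(c_nox < 0)) stop("concentration must be non-negative", call. = FALSE)
  if (no2_fraction <= 0 || no2_fraction > 1) {
    stop("`no2_fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (temp_c <= -273.15 || pressure_atm <= 0) {
    stop("nonphysical temperature or pressure", call. = FALSE)
  }
  v_m <- 22.414 * ((temp_c + 273.15) / 273.15) / pressure_atm
  c_nox * no2_fraction * v_m / 46.01
}

#' Concentration-response slope from the epidemiological literature
#'
#' @param percent Percent increase in risk per `unit_size` of exposure.
#' @param unit Exposure unit of the slope: `"ug_m3_no2"` or `"ppbv_no2"`.
#' @param unit_size Size of the exposure increment the slope refers to
#'   (e.g. 10 ug/m3, 20 ppbv).
#' @param source Free-text label for the study the slope comes from.
#' @return A `risk_slope` list.
#' @export
risk_slope <- function(percent, unit = c("ug_m3_no2", "ppbv_no2"),
                       unit_size, source = "") {
  unit <- match.arg(unit)
  if (unit_size <= 0) stop("`unit_size` must be positive", call. = FALSE)
  structure(list(percent = percent, unit = unit, unit_size = unit_size,
                 source = source), class = "risk_slope")
}

#' Excess health risk implied by an NOx exposure difference
#'
#' Linearly scales a literature concentration-response slope to a difference
#' in daily NOx exposure concentration: the difference is converted to the
#' slope's NO2 unit (mass fraction for ug/m3 NO2; additionally the
#' ideal-gas conversion of [nox_to_no2_ppbv()] for ppbv), then multiplied by
#' `percent / unit_size`.
#'
#' @param delta_c Difference in daily NOx exposure concentration, ug/m3.
#' @param slope A [risk_slope()].
#' @param no2_fraction Fraction of NOx mass that is NO2.
#' @param temp_c,pressure_atm Gas-conversion conditions (ppbv slopes only).
#' @return Percent excess risk.
#' @export
excess_risk <- function(delta_c, slope, no2_fraction = 0.8, temp_c = 25,
                        pressure_atm = 1) {
  stopifnot(inherits(slope, "risk_slope"))
  converted <- switch(slope$unit,
    ug_m3_no2 = delta_c * no2_fraction,
    ppbv_no2 = nox_to_no2_ppbv(delta_c, no2_fraction, temp_c, pressure_atm),
    stop("unknown slope unit", call. = FALSE)
  )
  slope$percent * converted / slope$unit_size
}
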