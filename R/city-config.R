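#' Configuration for a synthetic study area
#'
#' Bundles every knob of the synthetic city: the road grid, the urbanicity
#' zoning, the diurnal NOx concentration field, and the diary population with
#' its zone-conditional sociodemographic structure (residential sorting).
#' Defaults describe a mid-sized sprawling county: a 24 x 24 km road grid at
#' 1 km spacing with arterials every 5th row/column, an urban core of 4 km
#' radius inside a 9 km suburban ring, two outlying second-city pockets, and
#' a concentration field with morning (6-8 h) and broader evening (17-21 h)
#' traffic peaks superimposed on an urban bump and roadway kernels.
#'
#' @param seed Integer seed controlling all generation randomness.
#' @param grid_n Nodes per side of the square road grid (>= 2).
#' @param node_spacing Distance between adjacent grid nodes, meters.
#' @param arterial_every Every `arterial_every`-th row/column is an arterial.
#' @param local_speed,arterial_speed Free-flow speeds, m/s.
#' @param zone_radii Named numeric, meters: `urban` and `suburban` radii of
#'   the concentric zones around the domain center.
#' @param second_city_centers Two-column matrix (x, y meters) of second-city
#'   pocket centers.
#' @param second_city_radius Radius of each second-city pocket, meters.
#' @param field_background Background concentration, ug/m3.
#' @param field_urban_amplitude Peak amplitude of the urban Gaussian bump,
#'   ug/m3.
#' @param field_road_amplitude Amplitude of each arterial-link proximity
#'   kernel, ug/m3.
#' @param field_kernel_scale Gaussian scale of the road kernel, meters.
#' @param field_urban_scale Gaussian scale of the urban bump, meters
#'   (defaults to the urban zone radius).
#' @param diurnal_profile 24 positive hourly multipliers (hour 0 first).
#' @param n_households Number of households to generate.
#' @param group_probs_by_zone Zone-conditional sociodemographics: a list with
#'   elements `black`, `hispanic`, `white`, `asian` (named probability per
#'   zone) and `income` (zone x 3 matrix over below_poverty / middle /
#'   higher, rows summing to 1).
#' @param trips_per_day_rate Per age group, a list of probability vectors
#'   over the number of out-of-home destinations (1, 2, ...) on travel days.
#' @param no_travel_frac Probability of a zero-trip person-day, either a
#'   scalar or a named vector per age group.
#' @param dest_decay_m Exponential distance-decay scale for destination
#'   choice, meters.
#' @param dest_zone_weights Named attraction multipliers by destination zone
#'   (job centralisation: urban areas attract more trips).
#' @param start_time_mix Morning/evening mixture for first-trip departure:
#'   list with `p_morning`, `morning_mean`, `morning_sd`, `evening_mean`,
#'   `evening_sd` (minutes from midnight).
#' @param dwell_work_mean,dwell_work_sd Normal parameters for work dwell,
#'   minutes.
#' @param dwell_other_meanlog,dwell_other_sdlog Lognormal parameters for
#'   non-work dwell, minutes.
#' @param travel_time_factor Range (length 2) of the multiplicative factor
#'   relating reported travel time to the free-flow estimate.
#'
#' @return A validated list of class `city_config`.
#' @export
city_config <- function(seed = 1L,
                        grid_n = 25L,
                        node_spacing = 1000,
                        arterial_every = 5L,
                        local_speed = 13.9,
                        arterial_speed = 22.2,
                        zone_radii = c(urban = 4000, suburban = 9000),
                        second_city_centers = NULL,
                        second_city_radius = 2500,
                        field_background = 8,
                        field_urban_amplitude = 12,
                        field_road_amplitude = 6,
                        field_kernel_scale = 300,
                        field_urban_scale = NULL,
                        diurnal_profile = NULL,
                        n_households = 800L,
                        group_probs_by_zone = NULL,
                        trips_per_day_rate = NULL,
                        no_travel_frac = NULL,
                        dest_decay_m = 5000,
                        dest_zone_weights = c(urban = 4, suburban = 1.5,
                                              second_city = 2, rural = 1),
                        start_time_mix = list(p_morning = 0.65,
                                              morning_mean = 470,
                                              morning_sd = 45,
                                              evening_mean = 960,
                                              evening_sd = 120),
                        dwell_work_mean = 420,
                        dwell_work_sd = 60,
                        dwell_other_meanlog = log(90),
                        dwell_other_sdlog = 0.6,
                        travel_time_factor = c(1.05, 1.45)) {
  extent <- (grid_n - 1) * node_spacing
  if (is.null(second_city_centers)) {
    second_city_centers <- rbind(c(0.75, 0.20), c(0.25, 0.83)) * extent
  }
  second_city_centers <- matrix(as.numeric(second_city_centers), ncol = 2)
  if (is.null(field_urban_scale)) field_urban_scale <- zone_radii[["urban"]]
  if (is.null(diurnal_profile)) {
    diurnal_profile <- c(0.70, 0.65, 0.60, 0.60, 0.70, 0.95,
                         1.60, 1.80, 1.55, 1.15, 1.00, 0.95,
                         0.95, 0.95, 1.00, 1.10, 1.25, 1.45,
                         1.50, 1.45, 1.35, 1.20, 0.95, 0.80)
  }
  if (is.null(group_probs_by_zone)) {
    zones <- c("urban", "suburban", "second_city", "rural")
    group_probs_by_zone <- list(
      black    = c(urban = 0.35, suburban = 0.12, second_city = 0.10, rural = 0.06),
      hispanic = c(urban = 0.30, suburban = 0.20, second_city = 0.25, rural = 0.15),
      white    = c(urban = 0.55, suburban = 0.80, second_city = 0.78, rural = 0.85),
      asian    = c(urban = 0.04, suburban = 0.03, second_city = 0.03, rural = 0.02),
      income   = matrix(c(0.25, 0.50, 0.25,
                          0.08, 0.45, 0.47,
                          0.12, 0.55, 0.33,
                          0.10, 0.55, 0.35),
                        nrow = 4, byrow = TRUE,
                        dimnames = list(zones,
                                        c("below_poverty", "middle", "higher")))
    )
  }
  if (is.null(trips_per_day_rate)) {
    trips_per_day_rate <- list(
      "5-18"  = c(0.70, 0.30),
      "19-45" = c(0.45, 0.35, 0.20),
      "46-65" = c(0.50, 0.35, 0.15),
      ">65"   = c(0.75, 0.25)
    )
  }
  if (is.null(no_travel_frac)) {
    no_travel_frac <- c("5-18" = 0.20, "19-45" = 0.10,
                        "46-65" = 0.15, ">65" = 0.35)
  }
  if (length(no_travel_frac) == 1L) {
    no_travel_frac <- stats::setNames(rep(no_travel_frac, 4),
                                      c("5-18", "19-45", "46-65", ">65"))
  }
  cfg <- structure(list(
    seed = as.integer(seed),
    grid_n = as.integer(grid_n),
    node_spacing = node_spacing,
    arterial_every = as.integer(arterial_every),
    local_speed = local_speed,
    arterial_speed = arterial_speed,
    zone_radii = zone_radii,
    second_city_centers = second_city_centers,
    second_city_radius = second_city_radius,
    field_background = field_background,
    field_urban_amplitude = field_urban_amplitude,
    field_road_amplitude = field_road_amplitude,
    field_kernel_scale = field_kernel_scale,
    field_urban_scale = field_urban_scale,
    diurnal_profile = diurnal_profile,
    n_households = as.integer(n_households),
    group_probs_by_zone = group_probs_by_zone,
    trips_per_day_rate = trips_per_day_rate,
    no_travel_frac = no_travel_frac,
    dest_decay_m = dest_decay_m,
    dest_zone_weights = dest_zone_weights,
    start_time_mix = start_time_mix,
    dwell_work_mean = dwell_work_mean,
    dwell_work_sd = dwell_work_sd,
    dwell_other_meanlog = dwell_other_meanlog,
    dwell_other_sdlog = dwell_other_sdlog,
    travel_time_factor = travel_time_factor
  ), class = "city_config")
  validate_city_config(cfg)
}

validate_city_config <- function(cfg) {
  stopifnot(inherits(cfg, "city_config"))
  if (cfg$grid_n < 2L) {
    stop("`grid_n` must be at least 2", call. = FALSE)
  }
  if (cfg$node_spacing <= 0) {
    stop("`node_spacing` must be positive", call. = FALSE)
  }
  if (cfg$local_speed <= 0 || cfg$arterial_speed <= 0) {
    stop("speeds must be positive", call. = FALSE)
  }
  if (length(cfg$diurnal_profile) != 24L || any(cfg$diurnal_profile <= 0)) {
    stop("`diurnal_profile` needs exactly 24 positive entries", call. = FALSE)
  }
  if (!all(c("urban", "suburban") %in% names(cfg$zone_radii)) ||
      cfg$zone_radii[["urban"]] >= cfg$zone_radii[["suburban"]]) {
    stop("`zone_radii` must name urban < suburban", call. = FALSE)
  }
  inc <- cfg$group_probs_by_zone$income
  if (any(abs(rowSums(inc) - 1) > 1e-9)) {
    stop("income probabilities must sum to 1 in every zone", call. = FALSE)
  }
  for (nm in c("black", "hispanic", "white", "asian")) {
    p <- cfg$group_probs_by_zone[[nm]]
    if (any(p < 0 | p > 1)) {
      stop("group probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  bad <- vapply(cfg$trips_per_day_rate,
                function(p) abs(sum(p) - 1) > 1e-9 || any(p < 0),
                logical(1))
  if (any(bad)) {
    stop("`trips_per_day_rate` entries must be probability vectors",
         call. = FALSE)
  }
  if (any(cfg$no_travel_frac < 0 | cfg$no_travel_frac > 1)) {
    stop("`no_travel_frac` must lie in [0, 1]", call. = FALSE)
  }
  cfg
}

#' Domain bounding box of a city configuration
#'
#' The domain is the concentration-grid footprint: cells of size
#' `node_spacing` centered on the road-grid nodes, so it extends half a cell
#' beyond the outermost nodes on every side.
#'
#' @param config A [city_config()].
#' @return Named numeric: `xmin`, `xmax`, `ymin`, `ymax` (meters).
#' @export
city_bbox <- function(config) {
  half <- config$node_spacing / 2
  extent <- (config$grid_n - 1) * config$node_spacing
  c(xmin = -half, xmax = extent + half, ymin = -half, ymax = extent + half)
}
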