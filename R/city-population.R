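#' Generate a synthetic population of person-day travel diaries
#'
#' Draws households at network nodes (uniformly over nodes), assigns
#' sociodemographics conditional on the urbanicity zone of the residence
#' (residential sorting: the zone-conditional probabilities in
#' `config$group_probs_by_zone` induce, e.g., a higher urban-residence
#' probability for the black group), and schedules one 24-h diary per person.
#' A configurable fraction of person-days has no travel; travelling diaries
#' are home-anchored tours (start and end at the residence), with first-trip
#' departure from a bimodal commute mixture, destinations drawn with
#' exponential distance decay weighted by destination-zone attractiveness
#' (job centralisation), and positive dwell times. Schedules that cannot
#' close back at the residence by minute 1440 are redrawn with bounded
#' retries.
#'
#' Randomness is a single stream split per person-day: the master seed draws
#' one sub-seed per person, and each person-day is generated under its own
#' sub-seed, so populations are reproducible person-by-person.
#'
#' @param config A [city_config()].
#' @param network The matching [generate_network()] output.
#' @param field Optional [conc_field()]; accepted for interface symmetry with
#'   the other generators, not used (diaries do not depend on concentrations).
#' @return A `person_days` tibble: one row per person-day with
#'   sociodemographics, residence node/coordinates/urbanicity, `n_trips`, and
#'   a `trips` list-column of per-trip tibbles (`trip_index`, `origin_node`,
#'   `dest_node`, `origin_x`, `origin_y`, `dest_x`, `dest_y`, `start_min`,
#'   `travel_min`, `dwell_min`, `purpose`). Times are integer minutes from
#'   midnight.
#' @export
generate_population <- function(config, network, field = NULL) {
  config <- validate_city_config(config)
  nodes <- network$nodes

  withr::local_seed(config$seed)
  hh_node <- sample(nodes$id, config$n_households, replace = TRUE)
  hh_size <- pmin(1L + stats::rpois(config$n_households, 0.9), 4L)
  person_hh <- rep(seq_len(config$n_households), hh_size)
  n_persons <- length(person_hh)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_persons)

  rows <- vector("list", n_persons)
  for (p in seq_len(n_persons)) {
    res_node <- hh_node[person_hh[p]]
    rows[[p]] <- withr::with_seed(
      sub_seeds[p],
      generate_person_day(config, nodes, res_node,
                          person_id = sprintf("p%05d", p),
                          household_id = sprintf("h%04d", person_hh[p]))
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("person_days", class(out))
  out
}

age_group_probs <- c("5-18" = 0.15, "19-45" = 0.30, "46-65" = 0.30, ">65" = 0.25)

generate_person_day <- function(config, nodes, res_node, person_id,
                                household_id) {
  zone <- nodes$zone[match(res_node, nodes$id)]
  gp <- config$group_probs_by_zone
  age <- sample(names(age_group_probs), 1L, prob = age_group_probs)
  demo <- tibble::tibble(
    person_id = person_id,
    household_id = household_id,
    age_group = age,
    gender = sample(c("female", "male"), 1L),
    black = stats::runif(1) < gp$black[[zone]],
    hispanic = stats::runif(1) < gp$hispanic[[zone]],
    white = stats::runif(1) < gp$white[[zone]],
    asian = stats::runif(1) < gp$asian[[zone]],
    income_category = sample(colnames(gp$income), 1L, prob = gp$income[zone, ]),
    residence_node = res_node,
    res_x = nodes$x[match(res_node, nodes$id)],
    res_y = nodes$y[match(res_node, nodes$id)],
    residence_urbanicity = zone
  )

  if (stats::runif(1) < config$no_travel_frac[[age]]) {
    demo$n_trips <- 0L
    demo$trips <- list(empty_trips())
    return(demo)
  }

  trips <- NULL
  for (attempt in seq_len(25L)) {
    k_probs <- config$trips_per_day_rate[[age]]
    if (attempt > 10L) k_probs <- c(1)  # fall back to a single destination
    k <- sample(seq_along(k_probs), 1L, prob = k_probs)
    trips <- try_schedule(config, nodes, demo, k)
    if (!is.null(trips)) break
  }
  if (is.null(trips)) {
    stop("could not build a feasible 24-h schedule for ", person_id,
         call. = FALSE)
  }
  demo$n_trips <- nrow(trips)
  demo$trips <- list(trips)
  demo
}

empty_trips <- function() {
  tibble::tibble(trip_index = integer(), origin_node = integer(),
                 dest_node = integer(), origin_x = double(),
                 origin_y = double(), dest_x = double(), dest_y = double(),
                 start_min = integer(), travel_min = integer(),
                 dwell_min = integer(), purpose = character())
}

# one home-anchored tour: residence -> k destinations -> residence;
# returns NULL when the schedule cannot close by minute 1440
try_schedule <- function(config, nodes, demo, k) {
  mix <- config$start_time_mix
  start <- if (stats::runif(1) < mix$p_morning) {
    stats::rnorm(1, mix$morning_mean, mix$morning_sd)
  } else {
    stats::rnorm(1, mix$evening_mean, mix$evening_sd)
  }
  start <- as.integer(round(min(max(start, 300), 1140)))

  cur <- demo$residence_node
  dest_nodes <- integer(k)
  purposes <- character(k)
  dwells <- integer(k)
  travels <- integer(k + 1L)
  approx_speed <- 0.8 * config$arterial_speed  # m/s, for reported trip times

  for (j in seq_len(k)) {
    dest <- sample_destination(config, nodes, cur)
    dest_nodes[j] <- dest
    purposes[j] <- draw_purpose(demo$age_group, first = j == 1L)
    dwells[j] <- draw_dwell(config, purposes[j])
    travels[j] <- reported_travel_min(config, nodes, cur, dest, approx_speed)
    cur <- dest
  }
  travels[k + 1L] <- reported_travel_min(config, nodes, cur,
                                         demo$residence_node, approx_speed)

  arrive_home <- start + sum(travels) + sum(dwells)
  if (arrive_home > 1439L) return(NULL)

  origin <- c(demo$residence_node, dest_nodes)
  dest <- c(dest_nodes, demo$residence_node)
  starts <- start + c(0L, cumsum(travels[-(k + 1L)] + dwells))
  tibble::tibble(
    trip_index = seq_len(k + 1L),
    origin_node = origin,
    dest_node = dest,
    origin_x = nodes$x[match(origin, nodes$id)],
    origin_y = nodes$y[match(origin, nodes$id)],
    dest_x = nodes$x[match(dest, nodes$id)],
    dest_y = nodes$y[match(dest, nodes$id)],
    start_min = as.integer(starts),
    travel_min = travels,
    dwell_min = c(dwells, 1440L - arrive_home),
    purpose = c(purposes, "home")
  )
}

sample_destination <- function(config, nodes, cur) {
  cx <- nodes$x[match(cur, nodes$id)]
  cy <- nodes$y[match(cur, nodes$id)]
  d <- abs(nodes$x - cx) + abs(nodes$y - cy)
  w <- exp(-d / config$dest_decay_m) * config$dest_zone_weights[nodes$zone]
  w[nodes$id == cur] <- 0
  sample(nodes$id, 1L, prob = w)
}

draw_purpose <- function(age_group, first) {
  if (age_group %in% c("19-45", "46-65") && first && stats::runif(1) < 0.6) {
    return("work")
  }
  sample(c("other", "meals"), 1L, prob = c(0.75, 0.25))
}

draw_dwell <- function(config, purpose) {
  d <- if (purpose == "work") {
    stats::rnorm(1, config$dwell_work_mean, config$dwell_work_sd)
  } else {
    stats::rlnorm(1, config$dwell_other_meanlog, config$dwell_other_sdlog)
  }
  as.integer(round(min(max(d, 10), 660)))
}

reported_travel_min <- function(config, nodes, from, to, approx_speed) {
  d <- abs(nodes$x[match(from, nodes$id)] - nodes$x[match(to, nodes$id)]) +
    abs(nodes$y[match(from, nodes$id)] - nodes$y[match(to, nodes$id)])
  factor <- stats::runif(1, config$travel_time_factor[1],
                         config$travel_time_factor[2])
  max(1L, as.integer(round(d / approx_speed / 60 * factor)))
}

#' Residential-sorting probabilities implied by a configuration
#'
#' Computes, for a binary group flag (e.g. `black`), the configured
#' probability of an urban residence given group membership via Bayes' rule,
#' using the share of network nodes per zone as the residence marginal
#' (households are placed uniformly over nodes). Used to check that the
#' generated population recovers the configured sorting.
#'
#' @param config A [city_config()].
#' @param network The matching road network.
#' @param group One of `"black"`, `"hispanic"`, `"white"`, `"asian"`.
#' @return Named numeric: `p_urban_given_group`, `p_urban_given_nongroup`.
#' @export
configured_sorting <- function(config, network, group = "black") {
  p_group_zone <- config$group_probs_by_zone[[group]]
  zone_share <- table(factor(network$nodes$zone, levels = zone_levels()))
  zone_share <- as.numeric(zone_share) / sum(zone_share)
  names(zone_share) <- zone_levels()
  p_group <- sum(p_group_zone[zone_levels()] * zone_share)
  p_urb_g <- p_group_zone[["urban"]] * zone_share[["urban"]] / p_group
  p_urb_ng <- (1 - p_group_zone[["urban"]]) * zone_share[["urban"]] /
    (1 - p_group)
  c(p_urban_given_group = p_urb_g, p_urban_given_nongroup = p_urb_ng)
}
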