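# shared fixtures, all built in code

# a small city whose zone radii are scaled to the smaller grid so that all
# four urbanicity categories are populated
tiny_config <- function(seed = 1L, grid_n = 8L, n_households = 60L, ...) {
  extent <- (grid_n - 1) * 1000
  city_config(
    seed = seed, grid_n = grid_n, n_households = n_households,
    zone_radii = c(urban = 0.30 * extent, suburban = 0.55 * extent),
    second_city_centers = rbind(c(0.85, 0.15), c(0.15, 0.85)) * extent,
    second_city_radius = 0.15 * extent,
    dest_decay_m = 3000,
    ...
  )
}

# spatially uniform field: every cell and hour has `value`
uniform_field <- function(value = 10, nx = 4, ny = 4, cell = 1000,
                          x0 = 0, y0 = 0) {
  conc_field(grid_spec(x0, y0, cell, nx, ny),
             array(value, c(nx, ny, 24)))
}

# field with distinct per-cell diurnal profiles, reproducible from a seed
random_field <- function(seed, nx = 4, ny = 4, cell = 1000, x0 = 0, y0 = 0) {
  withr::with_seed(seed, {
    conc_field(grid_spec(x0, y0, cell, nx, ny),
               array(stats::runif(nx * ny * 24, 1, 50), c(nx, ny, 24)))
  })
}

# a 2x2 km four-node square network with uniform speeds
square_network <- function(speed = 10) {
  road_network(
    nodes = data.frame(id = 1:4,
                       x = c(0, 1000, 0, 1000),
                       y = c(0, 0, 1000, 1000)),
    links = data.frame(from = c(1, 1, 2, 3), to = c(2, 3, 4, 4),
                       length_m = 1000, speed_mps = speed)
  )
}

# one-row person_days tibble with the given trips
make_person_day <- function(trips, res_x = 0, res_y = 0,
                            person_id = "p1", age_group = "19-45",
                            income = "middle", zone = "urban",
                            black = FALSE, hispanic = FALSE,
                            white = TRUE, asian = FALSE) {
  pd <- tibble::tibble(
    person_id = person_id, household_id = "h1", age_group = age_group,
    gender = "female", black = black, hispanic = hispanic, white = white,
    asian = asian, income_category = income, res_x = res_x, res_y = res_y,
    residence_urbanicity = zone, n_trips = nrow(trips), trips = list(trips)
  )
  class(pd) <- c("person_days", class(pd))
  pd
}

no_trips <- function() {
  tibble::tibble(trip_index = integer(), origin_x = double(),
                 origin_y = double(), dest_x = double(), dest_y = double(),
                 start_min = integer(), travel_min = integer(),
                 dwell_min = integer(), purpose = character())
}

# a simple out-and-back tour: leave at `start`, travel, dwell, travel home
round_trip <- function(res_x = 0, res_y = 0, dest_x = 1000, dest_y = 0,
                       start = 480L, travel = 30L, dwell = 480L,
                       purpose = "work") {
  tibble::tibble(
    trip_index = 1:2,
    origin_x = c(res_x, dest_x), origin_y = c(res_y, dest_y),
    dest_x = c(dest_x, res_x), dest_y = c(dest_y, res_y),
    start_min = c(start, start + travel + dwell),
    travel_min = c(travel, travel),
    dwell_min = c(dwell, 1440L - start - 2L * travel - dwell),
    purpose = c(purpose, "home")
  )
}

# exhaustive shortest-time oracle: enumerate all simple paths
enumerate_shortest_time <- function(network, origin, dest) {
  adj <- lapply(seq_len(nrow(network$nodes)), function(i) {
    id <- network$nodes$id[i]
    l <- network$links
    rbind(
      data.frame(nb = l$to[l$from == id], t = l$length_m[l$from == id] /
                   l$speed_mps[l$from == id]),
      data.frame(nb = l$from[l$to == id], t = l$length_m[l$to == id] /
                   l$speed_mps[l$to == id])
    )
  })
  names(adj) <- as.character(network$nodes$id)
  best <- Inf
  recurse <- function(node, time, visited) {
    if (node == dest) {
      best <<- min(best, time)
      return(invisible())
    }
    nb <- adj[[as.character(node)]]
    for (r in seq_len(nrow(nb))) {
      if (!(nb$nb[r] %in% visited)) {
        recurse(nb$nb[r], time + nb$t[r], c(visited, nb$nb[r]))
      }
    }
  }
  recurse(origin, 0, origin)
  best
}

# random connected network with <= n_nodes nodes for oracle comparisons
random_small_network <- function(seed, n_nodes = 8) {
  withr::with_seed(seed, {
    n <- sample(4:n_nodes, 1)
    nodes <- data.frame(id = 1:n, x = stats::runif(n, 0, 5000),
                        y = stats::runif(n, 0, 5000))
    # spanning chain guarantees connectivity, then random extra links
    from <- 1:(n - 1)
    to <- 2:n
    extra <- utils::combn(n, 2)
    extra <- extra[, sample(ncol(extra), min(n, ncol(extra))), drop = FALSE]
    links <- unique(data.frame(
      from = c(from, extra[1, ]), to = c(to, extra[2, ])))
    links <- links[links$from != links$to, ]
    links$length_m <- round(stats::runif(nrow(links), 100, 3000))
    links$speed_mps <- sample(c(5, 10, 20), nrow(links), replace = TRUE)
    road_network(nodes, links)
  })
}

# random valid trace for one person-day with whole-second durations
random_trace <- function(seed, field, n_points = 30) {
  withr::with_seed(seed, {
    g <- field$grid
    sec <- as.vector(stats::rmultinom(1, 1440 * 60 - n_points, rep(1, n_points))) + 1
    dt <- sec / 60
    tibble::tibble(
      person_id = "p1",
      x = stats::runif(n_points, g$x0, g$x0 + g$nx * g$cell_size_m - 1e-6),
      y = stats::runif(n_points, g$y0, g$y0 + g$ny * g$cell_size_m - 1e-6),
      t_start = cumsum(c(0, dt[-n_points])),
      dt = dt,
      kind = sample(c("at_residence", "nonresidential", "in_travel"),
                    n_points, replace = TRUE),
      trip_index = NA_integer_
    )
  })
}
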