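#' Free-flow traversal time of links
#'
#' @param length_m Link length, meters.
#' @param speed_mps Free-flow speed, m/s (must be positive).
#' @return Travel time in seconds (vectorised).
#' @export
link_time <- function(length_m, speed_mps) {
  if (any(speed_mps <= 0)) stop("link speed must be positive", call. = FALSE)
  if (any(length_m <= 0)) stop("link length must be positive", call. = FALSE)
  length_m / speed_mps
}

# Single-source Dijkstra over free-flow link times with a deterministic
# tie-break: among equal-time labels prefer fewer links, then the smaller
# predecessor node id. Returns parallel vectors over node positions.
dijkstra_tree <- function(network, origin_pos) {
  adj <- network$adj
  n <- length(adj$node_ids)
  dist <- rep(Inf, n)
  hops <- rep(Inf, n)
  pred <- rep(NA_integer_, n)
  pred_link <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  dist[origin_pos] <- 0
  hops[origin_pos] <- 0

  for (iter in seq_len(n)) {
    d <- ifelse(visited, Inf, dist)
    u <- which.min(d)
    if (!is.finite(d[u])) break
    cand <- which(d <= d[u] * (1 + 1e-12) & !visited & is.finite(d))
    if (length(cand) > 1) {
      u <- cand[order(hops[cand], adj$node_ids[cand])][1]
    }
    visited[u] <- TRUE
    vs <- adj$head[[u]]
    if (length(vs) == 0) next
    nd <- dist[u] + adj$time[[u]]
    nh <- hops[u] + 1
    for (k in seq_along(vs)) {
      v <- vs[k]
      if (visited[v]) next
      tol <- 1e-9 * (1 + min(nd[k], dist[v]))
      if (nd[k] < dist[v] - tol) {
        dist[v] <- nd[k]
        hops[v] <- nh
        pred[v] <- u
        pred_link[v] <- adj$link[[u]][k]
      } else if (nd[k] <= dist[v] + tol) {
        better <- nh < hops[v] ||
          (nh == hops[v] && !is.na(pred[v]) &&
             adj$node_ids[u] < adj$node_ids[pred[v]])
        if (better) {
          hops[v] <- nh
          pred[v] <- u
          pred_link[v] <- adj$link[[u]][k]
        }
      }
    }
  }
  list(dist = dist, hops = hops, pred = pred, pred_link = pred_link)
}

#' Shortest-time path between two network nodes
#'
#' Minimises the sum of free-flow link times over the undirected network.
#' Ties are broken deterministically: among minimum-time paths, the one with
#' fewer links, then with smaller node ids (chosen greedily from the
#' destination backwards).
#'
#' @param network A `road_network`.
#' @param origin_node,dest_node Node ids.
#' @param tree Optional precomputed `dijkstra_tree` for `origin_node`
#'   (internal caching hook).
#' @return A `route_path`: list with `node_ids`, `links` (tibble `from`,
#'   `to`, `length_m`, `speed_mps`, `x0`, `y0`, `x1`, `y1`),
#'   `total_length_m`, and `freeflow_time_s`. An origin equal to the
#'   destination gives an empty path with zero time.
#' @export
shortest_time_path <- function(network, origin_node, dest_node, tree = NULL) {
  nid <- network$adj$node_ids
  o <- match(origin_node, nid)
  d <- match(dest_node, nid)
  if (is.na(o) || is.na(d)) stop("unknown node id", call. = FALSE)
  nodes <- network$nodes
  if (o == d) {
    return(new_route_path(origin_node, network))
  }
  if (is.null(tree)) tree <- dijkstra_tree(network, o)
  if (!is.finite(tree$dist[d])) {
    stop("no route between nodes ", origin_node, " and ", dest_node,
         call. = FALSE)
  }
  pos_path <- integer(0)
  link_path <- integer(0)
  cur <- d
  while (cur != o) {
    pos_path <- c(cur, pos_path)
    link_path <- c(tree$pred_link[cur], link_path)
    cur <- tree$pred[cur]
  }
  pos_path <- c(o, pos_path)
  new_route_path(nid[pos_path], network, link_path)
}

new_route_path <- function(node_ids, network, link_ids = integer(0)) {
  nodes <- network$nodes
  links <- network$links[match(link_ids, network$links$link_id), , drop = FALSE]
  n <- length(node_ids)
  seg <- tibble::tibble(
    from = node_ids[-n][seq_along(link_ids)],
    to = node_ids[-1][seq_along(link_ids)],
    length_m = links$length_m,
    speed_mps = links$speed_mps,
    x0 = nodes$x[match(node_ids[-n][seq_along(link_ids)], nodes$id)],
    y0 = nodes$y[match(node_ids[-n][seq_along(link_ids)], nodes$id)],
    x1 = nodes$x[match(node_ids[-1][seq_along(link_ids)], nodes$id)],
    y1 = nodes$y[match(node_ids[-1][seq_along(link_ids)], nodes$id)]
  )
  structure(list(
    node_ids = node_ids,
    coords = tibble::tibble(x = nodes$x[match(node_ids, nodes$id)],
                            y = nodes$y[match(node_ids, nodes$id)]),
    links = seg,
    total_length_m = sum(seg$length_m),
    freeflow_time_s = sum(link_time(seg$length_m, seg$speed_mps))
  ), class = "route_path")
}

#' @export
print.route_path <- function(x, ...) {
  cat("<route_path> ", length(x$node_ids), " nodes, ",
      format(x$total_length_m), " m, free-flow ",
      format(x$freeflow_time_s, digits = 4), " s\n", sep = "")
  invisible(x)
}

#' Snap points to the nearest network node
#'
#' Nearest by Euclidean distance; ties go to the smallest node id.
#'
#' @param network A `road_network`.
#' @param x,y Coordinates, meters (vectorised).
#' @return Integer vector of node ids.
#' @export
snap_point <- function(network, x, y) {
  nodes <- network$nodes  # ordered by id, so which.min returns smallest id
  vapply(seq_along(x), function(k) {
    d2 <- (nodes$x - x[k])^2 + (nodes$y - y[k])^2
    nodes$id[which.min(d2)]
  }, integer(1))
}

#' Discretize a trip path into timed trace points
#'
#' Samples the path at arc lengths 0, `interval_m`, 2 `interval_m`, ... plus
#' the terminal endpoint (duplicates suppressed). Each link's free-flow time
#' is rescaled by the ratio of the reported trip time to the path free-flow
#' time, and each sample receives the rescaled traversal time of its
#' midpoint-to-midpoint arc-length span (first and last spans run to the
#' path ends), so point durations reflect local scaled speed and sum exactly
#' to the reported trip time (the last span absorbs floating-point residue).
#'
#' @param path A `route_path`.
#' @param reported_travel_minutes Reported (survey) trip duration, minutes.
#' @param interval_m Sampling interval along the path, meters.
#' @return A tibble of trace points: `x`, `y`, `dt` (minutes). A zero-length
#'   path yields a single point carrying the whole reported time.
#' @export
discretize_trip <- function(path, reported_travel_minutes, interval_m = 100) {
  if (reported_travel_minutes <= 0) {
    stop("`reported_travel_minutes` must be positive", call. = FALSE)
  }
  if (interval_m <= 0) stop("`interval_m` must be positive", call. = FALSE)
  seg <- path$links
  L <- path$total_length_m
  if (nrow(seg) == 0 || L == 0) {
    # degenerate trip: origin == destination; all time at the single point
    return(tibble::tibble(x = path$coords$x[1], y = path$coords$y[1],
                          dt = reported_travel_minutes))
  }
  s <- seq(0, L, by = interval_m)
  if (s[length(s)] < L - 1e-9) s <- c(s, L)
  pts <- path_point(path, s)
  # span boundaries: path start, midpoints between samples, path end
  b <- c(0, (s[-1] + s[-length(s)]) / 2, L)
  r <- reported_travel_minutes * 60 / path$freeflow_time_s
  tau <- freeflow_time_at(path, b) * r / 60  # scaled minutes
  dt <- diff(tau)
  dt[length(dt)] <- reported_travel_minutes - sum(dt[-length(dt)])
  tibble::tibble(x = pts$x, y = pts$y, dt = dt)
}

# coordinates at arc lengths s along the path polyline (vectorised)
path_point <- function(path, s) {
  seg <- path$links
  if (nrow(seg) == 0) {
    return(tibble::tibble(x = rep(NA_real_, length(s)),
                          y = rep(NA_real_, length(s))))
  }
  ends <- cumsum(seg$length_m)
  starts <- c(0, ends[-length(ends)])
  idx <- pmin(findInterval(s, starts), nrow(seg))
  f <- (s - starts[idx]) / seg$length_m[idx]
  f <- pmin(pmax(f, 0), 1)
  tibble::tibble(x = seg$x0[idx] + f * (seg$x1[idx] - seg$x0[idx]),
                 y = seg$y0[idx] + f * (seg$y1[idx] - seg$y0[idx]))
}

# free-flow seconds to reach arc length s along the path (vectorised)
freeflow_time_at <- function(path, s) {
  seg <- path$links
  tt <- link_time(seg$length_m, seg$speed_mps)
  t_ends <- cumsum(tt)
  t_starts <- c(0, t_ends[-length(t_ends)])
  ends <- cumsum(seg$length_m)
  starts <- c(0, ends[-length(ends)])
  idx <- pmin(findInterval(s, starts), nrow(seg))
  t_starts[idx] + (s - starts[idx]) / seg$speed_mps[idx]
}

#' Assemble the space-time trace of a person-day
#'
#' Expands the activity timeline into the discretized sequence of
#' (location, time-interval, activity-kind) elements covering exactly 24 h:
#' dwell episodes become single fixed-location trace points; travel episodes
#' are routed between their snapped endpoints by [shortest_time_path()] and
#' expanded with [discretize_trip()] using the (possibly pared) reported
#' travel time.
#'
#' @param person_day A single-row `person_days` tibble (filtered and pared).
#' @param network A `road_network`.
#' @param interval_m Path sampling interval, meters.
#' @param tree_cache Optional environment caching Dijkstra trees by origin
#'   node (used by [build_traces()] across person-days).
#' @return A tibble of trace points: `person_id`, `x`, `y`, `t_start`, `dt`
#'   (minutes), `kind`, `trip_index`; `dt` sums to 1440.
#' @export
build_trace <- function(person_day, network, interval_m = 100,
                        tree_cache = NULL) {
  timeline <- build_timeline(person_day)
  trips <- person_day$trips[[1]]
  parts <- vector("list", nrow(timeline))
  for (k in seq_len(nrow(timeline))) {
    ep <- timeline[k, ]
    if (ep$kind != "in_travel") {
      parts[[k]] <- tibble::tibble(x = ep$x, y = ep$y, t_start = ep$start_min,
                                   dt = ep$duration_min, kind = ep$kind,
                                   trip_index = NA_integer_)
      next
    }
    tr <- trips[trips$trip_index == ep$trip_index, ]
    o <- snap_point(network, tr$origin_x, tr$origin_y)
    d <- snap_point(network, tr$dest_x, tr$dest_y)
    path <- tryCatch(
      cached_path(network, o, d, tree_cache),
      error = function(e) {
        stop("routing failed for trip ", ep$trip_index, " of ",
             person_day$person_id, ": ", conditionMessage(e), call. = FALSE)
      })
    pts <- if (length(path$node_ids) == 1L) {
      # snapped endpoints coincide: hold the whole travel time at the node
      nd <- network$nodes[match(o, network$nodes$id), ]
      tibble::tibble(x = nd$x, y = nd$y, dt = ep$duration_min)
    } else {
      discretize_trip(path, ep$duration_min, interval_m)
    }
    pts$t_start <- ep$start_min + cumsum(c(0, pts$dt[-nrow(pts)]))
    pts$kind <- "in_travel"
    pts$trip_index <- ep$trip_index
    parts[[k]] <- pts
  }
  out <- dplyr::bind_rows(parts)
  out$person_id <- person_day$person_id
  dplyr::select(out, "person_id", "x", "y", "t_start", "dt", "kind",
                "trip_index")
}

cached_path <- function(network, o, d, tree_cache) {
  if (is.null(tree_cache)) {
    return(shortest_time_path(network, o, d))
  }
  key <- as.character(o)
  if (is.null(tree_cache[[key]])) {
    tree_cache[[key]] <- dijkstra_tree(network,
                                       match(o, network$adj$node_ids))
  }
  shortest_time_path(network, o, d, tree = tree_cache[[key]])
}

#' Build traces for many person-days, reusing shortest-path trees
#'
#' @param person_days A `person_days` tibble (filtered and pared).
#' @param network A `road_network`.
#' @param interval_m Path sampling interval, meters.
#' @return One tibble of trace points for all person-days (see
#'   [build_trace()]).
#' @export
build_traces <- function(person_days, network, interval_m = 100) {
  cache <- new.env(parent = emptyenv())
  purrr::map_dfr(seq_len(nrow(person_days)), function(r) {
    build_trace(person_days[r, ], network, interval_m, tree_cache = cache)
  })
}
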