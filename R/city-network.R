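#' Generate the synthetic road network
#'
#' Builds a connected planar grid graph: `grid_n` x `grid_n` nodes at
#' `node_spacing` meters, linked to their horizontal and vertical neighbours.
#' Every `arterial_every`-th row and column carries `arterial_speed`; all
#' other links carry `local_speed`. The construction is deterministic.
#'
#' @param config A [city_config()].
#' @return A `road_network`: list with tibbles `nodes` (`id`, `x`, `y`,
#'   `zone`) and `links` (`link_id`, `from`, `to`, `length_m`, `speed_mps`,
#'   `arterial`). Links are undirected.
#' @export
generate_network <- function(config) {
  config <- validate_city_config(config)
  n <- config$grid_n
  sp <- config$node_spacing
  idx <- seq_len(n)
  nodes <- tidyr::expand_grid(row = idx, col = idx) |>
    dplyr::mutate(
      id = (.data$row - 1L) * n + .data$col,
      x = (.data$col - 1L) * sp,
      y = (.data$row - 1L) * sp
    ) |>
    dplyr::arrange(.data$id)
  nodes$zone <- assign_urbanicity(nodes$x, nodes$y, config)
  arterial_line <- function(i) i %% config$arterial_every == 0L

  # horizontal links join columns c, c+1 within a row; arterial iff the row is
  horiz <- tidyr::expand_grid(row = idx, col = idx[-n]) |>
    dplyr::mutate(
      from = (.data$row - 1L) * n + .data$col,
      to = .data$from + 1L,
      arterial = arterial_line(.data$row)
    )
  vert <- tidyr::expand_grid(row = idx[-n], col = idx) |>
    dplyr::mutate(
      from = (.data$row - 1L) * n + .data$col,
      to = .data$from + n,
      arterial = arterial_line(.data$col)
    )
  links <- dplyr::bind_rows(horiz, vert) |>
    dplyr::transmute(
      from = as.integer(.data$from),
      to = as.integer(.data$to),
      length_m = sp,
      speed_mps = ifelse(.data$arterial, config$arterial_speed,
                         config$local_speed),
      arterial = .data$arterial
    ) |>
    dplyr::arrange(.data$from, .data$to) |>
    dplyr::mutate(link_id = dplyr::row_number(), .before = 1)

  new_road_network(
    nodes = dplyr::select(nodes, "id", "x", "y", "zone"),
    links = links
  )
}

#' Construct a road network from node and link tables
#'
#' @param nodes Data frame with `id`, `x`, `y` (meters) and optionally
#'   `zone`.
#' @param links Data frame with `link_id`, `from`, `to`, `length_m`,
#'   `speed_mps` and optionally `arterial`. Links are traversed undirected.
#' @return A `road_network` with a prebuilt routing adjacency.
#' @export
road_network <- function(nodes, links) {
  nodes <- tibble::as_tibble(nodes)
  links <- tibble::as_tibble(links)
  if (!"zone" %in% names(nodes)) nodes$zone <- NA_character_
  if (!"arterial" %in% names(links)) links$arterial <- FALSE
  if (!"link_id" %in% names(links)) links$link_id <- seq_len(nrow(links))
  new_road_network(nodes, links)
}

new_road_network <- function(nodes, links) {
  nodes <- dplyr::arrange(tibble::as_tibble(nodes), .data$id)
  links <- dplyr::arrange(tibble::as_tibble(links), .data$link_id)
  if (!all(c(links$from, links$to) %in% nodes$id)) {
    stop("link endpoints must be network nodes", call. = FALSE)
  }
  if (any(links$length_m <= 0) || any(links$speed_mps <= 0)) {
    stop("link lengths and speeds must be positive", call. = FALSE)
  }
  structure(list(nodes = nodes, links = links, adj = build_adjacency(nodes, links)),
            class = "road_network")
}

# forward-star adjacency over both link directions, used by Dijkstra
build_adjacency <- function(nodes, links) {
  nid <- nodes$id
  pos <- match(c(links$from, links$to), nid)
  opp <- match(c(links$to, links$from), nid)
  tt <- rep(links$length_m / links$speed_mps, 2)
  lid <- rep(links$link_id, 2)
  ord <- order(pos, opp)
  list(
    node_ids = nid,
    head = split(opp[ord], factor(pos[ord], levels = seq_along(nid))),
    time = split(tt[ord], factor(pos[ord], levels = seq_along(nid))),
    link = split(lid[ord], factor(pos[ord], levels = seq_along(nid)))
  )
}

#' @export
print.road_network <- function(x, ...) {
  cat("<road_network> ", nrow(x$nodes), " nodes, ", nrow(x$links),
      " undirected links\n", sep = "")
  invisible(x)
}

#' Write / read a road network as a GMNS-like CSV pair
#'
#' `write_network()` writes `nodes.csv` (`id,x,y,zone`) and `links.csv`
#' (`link_id,from,to,length_m,speed_mps,arterial`) under `dir`;
#' `read_network()` reads them back and rebuilds the routing adjacency.
#'
#' @param network A `road_network`.
#' @param dir Directory (created if missing).
#' @return `write_network()` the paths written, invisibly; `read_network()`
#'   a `road_network`.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(nodes = file.path(dir, "nodes.csv"),
             links = file.path(dir, "links.csv"))
  readr::write_csv(network$nodes, paths[["nodes"]])
  readr::write_csv(network$links, paths[["links"]])
  invisible(paths)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  nodes <- readr::read_csv(file.path(dir, "nodes.csv"),
                           show_col_types = FALSE,
                           col_types = readr::cols(
                             id = "i", x = "d", y = "d", zone = "c"))
  links <- readr::read_csv(file.path(dir, "links.csv"),
                           show_col_types = FALSE,
                           col_types = readr::cols(
                             link_id = "i", from = "i", to = "i",
                             length_m = "d", speed_mps = "d", arterial = "l"))
  new_road_network(nodes, links)
}
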