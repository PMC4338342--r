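#' Generate the synthetic diurnal concentration field
#'
#' Builds a 24-layer diurnal NOx cycle on a 1-cell-per-node grid:
#' \deqn{c(h, cell) = profile[h] \cdot (background + urban\ bump + road\ kernels)}
#' where the urban bump is a Gaussian of the distance to the domain center
#' and each arterial link contributes a Gaussian kernel of the perpendicular
#' distance from the cell center to the link segment. Concentrations are
#' therefore highest along major roadways and over the urban core, and the
#' shared diurnal profile imposes the morning (6-8 h) and broader evening
#' (17-21 h) traffic peaks.
#'
#' @param config A [city_config()].
#' @param network The [generate_network()] output for the same config.
#' @return A [conc_field()] with cells centered on the network nodes.
#' @export
generate_field <- function(config, network) {
  config <- validate_city_config(config)
  n <- config$grid_n
  sp <- config$node_spacing
  grid <- grid_spec(x0 = -sp / 2, y0 = -sp / 2, cell_size_m = sp,
                    nx = n, ny = n)
  centers <- tidyr::expand_grid(j = seq_len(n) - 1L, i = seq_len(n) - 1L) |>
    dplyr::mutate(x = grid$x0 + (.data$i + 0.5) * sp,
                  y = grid$y0 + (.data$j + 0.5) * sp)

  extent <- (n - 1) * sp
  d_center <- sqrt((centers$x - extent / 2)^2 + (centers$y - extent / 2)^2)
  spatial <- config$field_background +
    config$field_urban_amplitude *
      exp(-d_center^2 / (2 * config$field_urban_scale^2))

  arterials <- dplyr::filter(network$links, .data$arterial)
  if (nrow(arterials) > 0 && config$field_road_amplitude > 0) {
    a <- network$nodes[match(arterials$from, network$nodes$id), ]
    b <- network$nodes[match(arterials$to, network$nodes$id), ]
    road <- numeric(nrow(centers))
    for (k in seq_len(nrow(arterials))) {
      d <- dist_point_segment(centers$x, centers$y,
                              a$x[k], a$y[k], b$x[k], b$y[k])
      road <- road + exp(-d^2 / (2 * config$field_kernel_scale^2))
    }
    spatial <- spatial + config$field_road_amplitude * road
  }

  values <- array(0, c(n, n, 24L))
  for (h in 0:23) {
    layer <- config$diurnal_profile[h + 1L] * spatial
    values[cbind(centers$i + 1L, centers$j + 1L, h + 1L)] <- layer
  }
  conc_field(grid, values)
}

# Euclidean distance from points (px, py) to segment (ax, ay)-(bx, by)
dist_point_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax
  vy <- by - ay
  len2 <- vx^2 + vy^2
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(pmax(((px - ax) * vx + (py - ay) * vy) / len2, 0), 1)
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}
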