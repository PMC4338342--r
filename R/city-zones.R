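#' Classify points by residence urbanicity
#'
#' Maps every in-domain point to exactly one of four urbanicity categories:
#' `urban` inside the urban radius around the domain center, `second_city`
#' inside any outlying pocket disk, `suburban` inside the suburban radius,
#' `rural` elsewhere. Inner-zone boundaries are half-open: a point exactly at
#' the urban radius is suburban, one exactly at a pocket radius is not
#' second-city.
#'
#' @param x,y Numeric vectors of coordinates, meters.
#' @param config A [city_config()].
#' @return Character vector of zone labels.
#' @export
assign_urbanicity <- function(x, y, config) {
  bbox <- city_bbox(config)
  if (any(x < bbox["xmin"] | x > bbox["xmax"] |
          y < bbox["ymin"] | y > bbox["ymax"])) {
    stop("point outside the study domain", call. = FALSE)
  }
  extent <- (config$grid_n - 1) * config$node_spacing
  cx <- extent / 2
  cy <- extent / 2
  d_center <- sqrt((x - cx)^2 + (y - cy)^2)

  in_pocket <- rep(FALSE, length(x))
  for (k in seq_len(nrow(config$second_city_centers))) {
    ctr <- config$second_city_centers[k, ]
    d <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
    in_pocket <- in_pocket | d < config$second_city_radius
  }

  out <- rep("rural", length(x))
  out[d_center < config$zone_radii[["suburban"]]] <- "suburban"
  out[in_pocket] <- "second_city"
  out[d_center < config$zone_radii[["urban"]]] <- "urban"
  out
}

zone_levels <- function() c("urban", "suburban", "second_city", "rural")
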