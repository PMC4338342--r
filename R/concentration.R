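#' Grid geometry for a concentration field
#'
#' @param x0,y0 Southwest corner of the grid, meters.
#' @param cell_size_m Cell edge length, meters (default 1000, i.e. 1-km
#'   receptor resolution).
#' @param nx,ny Number of cells east and north.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(x0, y0, cell_size_m = 1000, nx, ny) {
  if (cell_size_m <= 0) stop("`cell_size_m` must be positive", call. = FALSE)
  if (nx < 1 || ny < 1) stop("grid needs at least one cell", call. = FALSE)
  structure(list(x0 = x0, y0 = y0, cell_size_m = cell_size_m,
                 nx = as.integer(nx), ny = as.integer(ny)),
            class = "grid_spec")
}

#' Diurnal gridded concentration field
#'
#' Holds the 24-hour diurnal cycle of a gridded pollutant concentration: one
#' layer per hour of day (hour 0 first), each `nx` x `ny`, in ug/m3.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric array of dim `c(nx, ny, 24)`; all values must be
#'   non-negative.
#' @return A `conc_field`.
#' @export
conc_field <- function(grid, values) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.array(values)
  if (length(dim(values)) != 3L ||
      !all(dim(values) == c(grid$nx, grid$ny, 24L))) {
    stop("`values` must be an nx x ny x 24 array", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  structure(list(grid = grid, values = values), class = "conc_field")
}

#' @export
print.conc_field <- function(x, ...) {
  g <- x$grid
  cat("<conc_field> ", g$nx, " x ", g$ny, " cells of ", g$cell_size_m,
      " m, 24 hourly layers\n", sep = "")
  cat("  range ", format(min(x$values), digits = 4), " - ",
      format(max(x$values), digits = 4), " ug/m3\n", sep = "")
  invisible(x)
}

#' Reduce a multi-day hourly stack to the 24-hour diurnal cycle
#'
#' Averages hourly concentration layers at each receptor over each hour of
#' the day: layer `h` of the result is the mean across days of the hour-`h`
#' layers of the input. A single-day stack is returned unchanged.
#'
#' @param grid A [grid_spec()].
#' @param hourly_stack Array of dim `c(nx, ny, 24 * D)` for `D >= 1` days,
#'   hours in chronological order.
#' @return A [conc_field()].
#' @export
diurnal_average <- function(grid, hourly_stack) {
  hourly_stack <- as.array(hourly_stack)
  d <- dim(hourly_stack)
  if (length(d) != 3L || d[3] %% 24L != 0L || d[3] < 24L) {
    stop("stack depth must be a positive multiple of 24 hours", call. = FALSE)
  }
  n_days <- d[3] %/% 24L
  if (n_days == 1L) return(conc_field(grid, hourly_stack))
  dim(hourly_stack) <- c(d[1] * d[2], 24L, n_days)
  avg <- rowMeans(hourly_stack, dims = 2)
  dim(avg) <- c(d[1], d[2], 24L)
  conc_field(grid, avg)
}

#' Map points to grid cells
#'
#' Cells are half-open: `i = floor((x - x0) / cell_size)`, so a point exactly
#' on an interior cell boundary belongs to the higher-index cell. Indices are
#' zero-based.
#'
#' @param grid A [grid_spec()].
#' @param x,y Point coordinates, meters (vectorised).
#' @param clamp If `TRUE`, out-of-domain points are clamped to the edge cell
#'   instead of raising an error.
#' @return A tibble with zero-based integer columns `i`, `j`.
#' @export
cell_index <- function(grid, x, y, clamp = FALSE) {
  i <- floor((x - grid$x0) / grid$cell_size_m)
  j <- floor((y - grid$y0) / grid$cell_size_m)
  bad <- i < 0 | i >= grid$nx | j < 0 | j >= grid$ny
  if (any(bad)) {
    if (!clamp) {
      k <- which(bad)[1]
      stop(sprintf("point (%g, %g) is outside the concentration grid",
                   x[k], y[k]), call. = FALSE)
    }
    i <- pmin(pmax(i, 0), grid$nx - 1L)
    j <- pmin(pmax(j, 0), grid$ny - 1L)
  }
  tibble::tibble(i = as.integer(i), j = as.integer(j))
}

#' Look up concentrations at points and minutes of day
#'
#' Piecewise-constant in both space and hour: returns the hour-`floor(min/60)`
#' layer value of the cell containing each point. No interpolation is done,
#' matching receptor-cell assignment of gridded dispersion output.
#'
#' @param field A [conc_field()].
#' @param x,y Coordinates, meters (vectorised).
#' @param minute Minute of day in `[0, 1440)` (vectorised).
#' @param clamp Clamp out-of-domain points to the nearest edge cell.
#' @return Numeric vector of concentrations, ug/m3.
#' @export
conc_lookup <- function(field, x, y, minute, clamp = FALSE) {
  if (any(minute < 0 | minute >= 1440)) {
    stop("`minute` must lie in [0, 1440)", call. = FALSE)
  }
  ij <- cell_index(field$grid, x, y, clamp = clamp)
  hour <- as.integer(floor(minute / 60))
  n <- max(length(x), length(hour))
  idx <- cbind(rep_len(ij$i + 1L, n), rep_len(ij$j + 1L, n),
               rep_len(hour + 1L, n))
  field$values[idx]
}

#' Write / read a concentration field as plain text
#'
#' The field is stored as a JSON header (`x0`, `y0`, `cell_size_m`, `nx`,
#' `ny`) plus a long-format CSV of the 24 layers (`hour`, `i`, `j`, `value`
#' with zero-based cell indices). The reader validates shape and
#' non-negativity.
#'
#' @param field A [conc_field()].
#' @param dir Directory (created if missing).
#' @return `write_field()` the paths, invisibly; `read_field()` a
#'   [conc_field()].
#' @export
write_field <- function(field, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(header = file.path(dir, "field_header.json"),
             values = file.path(dir, "field_values.csv"))
  jsonlite::write_json(unclass(field$grid), paths[["header"]],
                       auto_unbox = TRUE, digits = NA)
  g <- field$grid
  long <- tidyr::expand_grid(hour = 0:23, j = seq_len(g$ny) - 1L,
                             i = seq_len(g$nx) - 1L) |>
    dplyr::mutate(value = field$values[cbind(i + 1L, j + 1L, hour + 1L)]) |>
    dplyr::select("hour", "i", "j", "value")
  readr::write_csv(long, paths[["values"]])
  invisible(paths)
}

#' @rdname write_field
#' @export
read_field <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "field_header.json"),
                             simplifyVector = TRUE)
  grid <- grid_spec(hdr$x0, hdr$y0, hdr$cell_size_m, hdr$nx, hdr$ny)
  long <- readr::read_csv(file.path(dir, "field_values.csv"),
                          show_col_types = FALSE,
                          col_types = readr::cols(hour = "i", i = "i",
                                                  j = "i", value = "d"))
  if (nrow(long) != grid$nx * grid$ny * 24L) {
    stop("field file has the wrong number of cell-hours", call. = FALSE)
  }
  values <- array(NA_real_, c(grid$nx, grid$ny, 24L))
  values[cbind(long$i + 1L, long$j + 1L, long$hour + 1L)] <- long$value
  if (anyNA(values)) stop("field file is missing cell-hours", call. = FALSE)
  conc_field(grid, values)
}
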