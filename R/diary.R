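#' Write / read person-day diaries as a flat CSV
#'
#' One row per trip, carrying the person-level columns (`person_id`,
#' `household_id`, `age_group`, `gender`, `black`, `hispanic`, `white`,
#' `asian`, `income_category`, `res_x`, `res_y`, `residence_urbanicity`)
#' alongside the per-trip columns (`trip_index`, `origin_x`, `origin_y`,
#' `dest_x`, `dest_y`, `start_min`, `travel_min`, `dwell_min`, `purpose`).
#' Zero-trip person-days get a single row with `NA` trip columns. Node ids
#' are not stored; endpoints are re-snapped to the network at routing time.
#'
#' `read_diaries()` parses every row or records it as a rejection with its
#' CSV line number; nothing is silently dropped. Structurally invalid rows
#' (unknown age group - which also rejects under-5 records, for which no
#' survey category exists - invalid purpose, negative travel or dwell time,
#' out-of-range start time) go to the rejection report, available via
#' `diary_rejections()`.
#'
#' @param person_days A `person_days` tibble (see [generate_population()]).
#' @param path CSV file path.
#' @return `write_diaries()` returns `path` invisibly. `read_diaries()`
#'   returns a `person_days` tibble with a `rejections` attribute (tibble
#'   with `line`, `reason`).
#' @export
write_diaries <- function(person_days, path) {
  flat <- person_days |>
    dplyr::select(-dplyr::any_of(c("residence_node", "n_trips"))) |>
    tidyr::unnest("trips", keep_empty = TRUE) |>
    dplyr::select(-dplyr::any_of(c("origin_node", "dest_node")))
  readr::write_csv(flat, path, na = "")
  invisible(path)
}

diary_csv_cols <- function() {
  readr::cols(
    person_id = "c", household_id = "c", age_group = "c", gender = "c",
    black = "l", hispanic = "l", white = "l", asian = "l",
    income_category = "c", res_x = "d", res_y = "d",
    residence_urbanicity = "c", trip_index = "i",
    origin_x = "d", origin_y = "d", dest_x = "d", dest_y = "d",
    start_min = "d", travel_min = "d", dwell_min = "d", purpose = "c"
  )
}

#' @rdname write_diaries
#' @export
read_diaries <- function(path) {
  raw <- readr::read_csv(path, col_types = diary_csv_cols(), na = "")
  prob <- readr::problems(raw)
  raw$.line <- seq_len(nrow(raw)) + 1L  # header occupies line 1
  rejections <- tibble::tibble(line = integer(), reason = character())
  if (nrow(prob) > 0) {
    rejections <- tibble::tibble(line = unique(prob$row) + 1L,
                                 reason = "parse failure")
    raw <- raw[-unique(prob$row), , drop = FALSE]
  }

  has_trip <- !is.na(raw$trip_index)
  bad_age <- !(raw$age_group %in% names(age_group_probs))
  bad_purpose <- has_trip & !is.na(raw$purpose) &
    !(raw$purpose %in% c("home", "work", "meals", "other", "travel"))
  bad_time <- has_trip &
    ((!is.na(raw$travel_min) & raw$travel_min <= 0) |
       (!is.na(raw$dwell_min) & raw$dwell_min < 0) |
       (!is.na(raw$start_min) & (raw$start_min < 0 | raw$start_min >= 1440)))
  bad <- bad_age | bad_purpose | bad_time
  if (any(bad)) {
    reason <- dplyr::case_when(
      bad_age ~ "invalid age group",
      bad_purpose ~ "invalid purpose",
      TRUE ~ "invalid trip times"
    )[bad]
    rejections <- dplyr::bind_rows(
      rejections, tibble::tibble(line = raw$.line[bad], reason = reason))
    raw <- raw[!bad, , drop = FALSE]
  }

  person_cols <- c("person_id", "household_id", "age_group", "gender",
                   "black", "hispanic", "white", "asian", "income_category",
                   "res_x", "res_y", "residence_urbanicity")
  trip_cols <- c("trip_index", "origin_x", "origin_y", "dest_x", "dest_y",
                 "start_min", "travel_min", "dwell_min", "purpose")
  if (nrow(raw) == 0) {
    out <- tibble::tibble(!!!stats::setNames(
      rep(list(character(0)), length(person_cols)), person_cols))
    out$black <- out$hispanic <- out$white <- out$asian <- logical(0)
    out$res_x <- out$res_y <- double(0)
    out$n_trips <- integer(0)
    out$trips <- list()
    out <- out[, c(person_cols, "n_trips", "trips")]
    class(out) <- c("person_days", class(out))
    attr(out, "rejections") <- rejections
    return(out)
  }
  out <- raw |>
    dplyr::group_by(dplyr::across(dplyr::all_of(person_cols))) |>
    dplyr::group_modify(function(rows, key) {
      trips <- rows[!is.na(rows$trip_index), trip_cols]
      trips <- trips[order(trips$trip_index), ]
      trips$trip_index <- as.integer(trips$trip_index)
      trips$start_min <- as.integer(trips$start_min)
      trips$travel_min <- as.integer(trips$travel_min)
      trips$dwell_min <- as.integer(trips$dwell_min)
      tibble::tibble(n_trips = nrow(trips), trips = list(trips))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$person_id)
  class(out) <- c("person_days", class(out))
  attr(out, "rejections") <- dplyr::arrange(rejections, .data$line)
  out
}

#' @rdname write_diaries
#' @param diaries The result of `read_diaries()`.
#' @export
diary_rejections <- function(diaries) {
  rej <- attr(diaries, "rejections")
  if (is.null(rej)) tibble::tibble(line = integer(), reason = character())
  else rej
}

#' Filter person-days to consistent, complete, in-domain records
#'
#' Mirrors survey-sample cleaning: records that are incomplete, internally
#' inconsistent, or that contain travel outside the study domain are
#' excluded, each with a machine-readable reason:
#'
#' * `missing` - any required sociodemographic or trip field is `NA`;
#' * `inconsistent` - non-positive travel time, negative dwell, trips out of
#'   order or overlapping (each trip must depart exactly when the previous
#'   dwell ends), first origin away from the residence, or a trip origin
#'   more than 1 m from the previous destination;
#' * `out_of_domain` - any trip endpoint outside `domain_bbox`.
#'
#' Filtering is total (it never errors on a record) and idempotent.
#'
#' @param person_days A `person_days` tibble.
#' @param domain_bbox Named numeric with `xmin`, `xmax`, `ymin`, `ymax`,
#'   e.g. [city_bbox()].
#' @return A list with `kept` (a `person_days` tibble) and `excluded` (tibble
#'   with `person_id`, `reason`).
#' @export
filter_person_days <- function(person_days, domain_bbox) {
  person_cols <- c("person_id", "household_id", "age_group", "gender",
                   "black", "hispanic", "white", "asian", "income_category",
                   "res_x", "res_y", "residence_urbanicity")
  reason <- purrr::pmap_chr(
    list(seq_len(nrow(person_days))),
    function(r) {
      row <- person_days[r, ]
      if (anyNA(row[person_cols])) return("missing")
      tr <- row$trips[[1]]
      if (nrow(tr) == 0) return("")
      if (anyNA(tr)) return("missing")
      if (any(tr$travel_min <= 0) || any(tr$dwell_min < 0)) {
        return("inconsistent")
      }
      ends <- tr$start_min + tr$travel_min + tr$dwell_min
      n <- nrow(tr)
      if (n > 1 && any(tr$start_min[-1] != ends[-n])) {
        return("inconsistent")
      }
      if (max(abs(c(tr$origin_x[1] - row$res_x,
                    tr$origin_y[1] - row$res_y))) > 1) {
        return("inconsistent")
      }
      if (n > 1) {
        jump <- pmax(abs(tr$origin_x[-1] - tr$dest_x[-n]),
                     abs(tr$origin_y[-1] - tr$dest_y[-n]))
        if (any(jump > 1)) return("inconsistent")
      }
      xs <- c(tr$origin_x, tr$dest_x)
      ys <- c(tr$origin_y, tr$dest_y)
      if (any(xs < domain_bbox[["xmin"]] | xs > domain_bbox[["xmax"]] |
              ys < domain_bbox[["ymin"]] | ys > domain_bbox[["ymax"]])) {
        return("out_of_domain")
      }
      ""
    }
  )
  kept <- person_days[reason == "", ]
  class(kept) <- class(person_days)
  list(
    kept = kept,
    excluded = tibble::tibble(person_id = person_days$person_id,
                              reason = reason)[reason != "", ]
  )
}

#' Pare person-days to exactly 24 hours
#'
#' Clips each diary to the day window `[0, 1440)` minutes (midnight to
#' midnight). Trips starting at or after minute 1440 are dropped; a trip in
#' progress at 1440 has its travel time truncated (its trace is later clipped
#' proportionally by time) and its dwell removed; a dwell crossing 1440 is
#' truncated. The resulting timeline covers exactly 1440 minutes.
#'
#' @param person_days A `person_days` tibble.
#' @return The pared `person_days` tibble.
#' @export
pare_to_24h <- function(person_days) {
  person_days$trips <- purrr::map(person_days$trips, function(tr) {
    tr <- tr[tr$start_min < 1440, , drop = FALSE]
    if (nrow(tr) == 0) return(tr)
    n <- nrow(tr)
    over_travel <- tr$start_min + tr$travel_min > 1440
    tr$dwell_min[over_travel] <- 0L
    tr$travel_min[over_travel] <- 1440L - tr$start_min[over_travel]
    end <- tr$start_min + tr$travel_min + tr$dwell_min
    over_dwell <- end > 1440
    tr$dwell_min[over_dwell] <- 1440L - tr$start_min[over_dwell] -
      tr$travel_min[over_dwell]
    tr
  })
  person_days$n_trips <- purrr::map_int(person_days$trips, nrow)
  person_days
}

purpose_to_kind <- function(purpose) {
  dplyr::case_when(
    purpose == "home" ~ "at_residence",
    purpose == "travel" ~ "in_travel",
    TRUE ~ "nonresidential"
  )
}

#' Build the gapless 24-h activity timeline of one person-day
#'
#' Partitions `[0, 1440)` minutes into contiguous activity episodes of three
#' kinds - `at_residence`, `nonresidential`, `in_travel` - from the trip
#' sequence. A zero-trip record yields a single 1440-minute at-residence
#' episode. The final activity location is occupied until minute 1440.
#' Purposes map to kinds as: home to at_residence, travel to in_travel,
#' work/meals/other to nonresidential.
#'
#' @param person_day A single-row `person_days` tibble.
#' @return A tibble of episodes: `kind`, `x`, `y` (`NA` for travel episodes,
#'   which reference the trip's route), `start_min`, `duration_min`,
#'   `trip_index` (`NA` for dwell episodes). Durations are positive and sum
#'   to exactly 1440.
#' @export
build_timeline <- function(person_day) {
  stopifnot(nrow(person_day) == 1)
  tr <- person_day$trips[[1]]
  res_x <- person_day$res_x
  res_y <- person_day$res_y
  if (nrow(tr) == 0) {
    return(tibble::tibble(kind = "at_residence", x = res_x, y = res_y,
                          start_min = 0, duration_min = 1440,
                          trip_index = NA_integer_))
  }
  eps <- list()
  if (tr$start_min[1] > 0) {
    eps[[1]] <- tibble::tibble(kind = "at_residence", x = res_x, y = res_y,
                               start_min = 0,
                               duration_min = tr$start_min[1],
                               trip_index = NA_integer_)
  }
  n <- nrow(tr)
  for (k in seq_len(n)) {
    t0 <- tr$start_min[k]
    arrive <- t0 + tr$travel_min[k]
    next_start <- if (k < n) tr$start_min[k + 1] else 1440
    if (arrive > next_start) {
      stop("overlapping trips in person-day ", person_day$person_id,
           call. = FALSE)
    }
    eps[[length(eps) + 1L]] <- tibble::tibble(
      kind = "in_travel", x = NA_real_, y = NA_real_, start_min = t0,
      duration_min = tr$travel_min[k], trip_index = tr$trip_index[k])
    if (next_start > arrive) {
      eps[[length(eps) + 1L]] <- tibble::tibble(
        kind = purpose_to_kind(tr$purpose[k]),
        x = tr$dest_x[k], y = tr$dest_y[k], start_min = arrive,
        duration_min = next_start - arrive, trip_index = NA_integer_)
    }
  }
  out <- dplyr::bind_rows(eps)
  out <- out[out$duration_min > 0, ]
  if (sum(out$duration_min) != 1440 ||
      any(out$start_min[-1] != (out$start_min + out$duration_min)[-nrow(out)])) {
    stop("timeline of ", person_day$person_id,
         " does not partition the 24-h day", call. = FALSE)
  }
  out
}
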