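#' Generate a complete synthetic city
#'
#' Runs the three generators in sequence — road network, diurnal
#' concentration field, diary population — under one configuration and seed.
#'
#' @param config A [city_config()].
#' @return A `synthetic_city`: list with `config`, `network`, `field`,
#'   `person_days`.
#' @export
city_generate <- function(config) {
  config <- validate_city_config(config)
  network <- generate_network(config)
  field <- generate_field(config, network)
  person_days <- generate_population(config, network, field)
  structure(list(config = config, network = network, field = field,
                 person_days = person_days),
            class = "synthetic_city")
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat("<synthetic_city> seed ", x$config$seed, ": ",
      nrow(x$network$nodes), " nodes, ", nrow(x$person_days),
      " person-days (", sum(x$person_days$n_trips == 0), " with no travel)\n",
      sep = "")
  invisible(x)
}

#' Write / read a synthetic city as plain-text files
#'
#' `city_write()` writes the network CSV pair, the field header + layers,
#' the diary CSV, and a `manifest.json` recording the seed, a hash of the
#' full configuration, and record counts (no timestamps, so identical
#' configurations produce identical manifests). `city_read()` reads the
#' files back.
#'
#' @param city A `synthetic_city`.
#' @param dir Output directory (created if missing).
#' @return `city_write()` the manifest path, invisibly; `city_read()` a list
#'   with `network`, `field`, `person_days`, `manifest`.
#' @export
city_write <- function(city, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network(city$network, dir)
  write_field(city$field, dir)
  write_diaries(city$person_days, file.path(dir, "diaries.csv"))
  manifest <- list(
    seed = city$config$seed,
    config_hash = rlang::hash(city$config),
    n_nodes = nrow(city$network$nodes),
    n_links = nrow(city$network$links),
    n_person_days = nrow(city$person_days),
    n_no_travel = sum(city$person_days$n_trips == 0)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname city_write
#' @export
city_read <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  list(
    network = read_network(dir),
    field = read_field(dir),
    person_days = read_diaries(file.path(dir, "diaries.csv")),
    manifest = if (file.exists(manifest_path)) {
      jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    }
  )
}

#' Build the regression design from exposure records
#'
#' Codes the predictors of the exposure model as 0/1 columns with the
#' reference categories: female, age 19-45, nonblack (etc.), higher income
#' (>= $75,000), rural residence, and no time away from home. The continuous
#' `hours_away` variable is daily travel plus nonresidential time, in hours.
#'
#' @param records An [exposure_records()] tibble.
#' @return A tibble with the response `c_activity` and predictor columns.
#' @export
exposure_design <- function(records) {
  tibble::tibble(
    c_activity = records$c_activity,
    male = as.numeric(records$gender == "male"),
    age_5_18 = as.numeric(records$age_group == "5-18"),
    age_46_65 = as.numeric(records$age_group == "46-65"),
    age_over_65 = as.numeric(records$age_group == ">65"),
    black = as.numeric(records$black),
    hispanic = as.numeric(records$hispanic),
    asian = as.numeric(records$asian),
    below_poverty = as.numeric(records$income_category == "below_poverty"),
    middle_income = as.numeric(records$income_category == "middle"),
    urban = as.numeric(records$residence_urbanicity == "urban"),
    suburban = as.numeric(records$residence_urbanicity == "suburban"),
    second_city = as.numeric(records$residence_urbanicity == "second_city"),
    hours_away = (records$min_nonresidential + records$min_in_travel) / 60
  )
}

#' Default predictor blocks of the hierarchical exposure model
#'
#' Sociodemographics first (gender, age, racioethnicity), then income, then
#' urbanicity, then the continuous activity-time variable.
#'
#' @return A named list of predictor-column vectors for
#'   [hierarchical_stepwise_ols()].
#' @export
exposure_blocks <- function() {
  list(
    sociodemographic = c("male", "age_5_18", "age_46_65", "age_over_65",
                         "black", "hispanic", "asian"),
    income = c("below_poverty", "middle_income"),
    urbanicity = c("urban", "suburban", "second_city"),
    activity = "hours_away"
  )
}

travel_stratum <- function(travel_minutes) {
  dplyr::case_when(
    travel_minutes == 0 ~ "no_travel",
    travel_minutes <= 60 ~ "up_to_60",
    TRUE ~ "more_than_60"
  )
}

#' Run the full exposure-assessment pipeline
#'
#' Filters and pares the diaries, routes and discretizes every trip, matches
#' the space-time traces to the diurnal concentration field, and produces:
#' per-person-day exposure records; group distribution summaries of the
#' activity-based exposure concentration and the exposure error by
#' racioethnicity, income, age, urbanicity, and daily travel time (no
#' travel / up to 60 min / more than 60 min); one-way ANOVA with
#' Games-Howell post hoc tests; the paired t test of the activity- vs
#' residence-based means; attenuation bias factors for the full and the
#' travelling sample; mean activity-kind contributions; and the hierarchical
#' stepwise regression with the urbanicity-sociodemographic interaction
#' refit.
#'
#' @param person_days A `person_days` tibble (e.g. from
#'   [generate_population()] or [read_diaries()]).
#' @param network A `road_network`.
#' @param field A [conc_field()].
#' @param domain_bbox Filtering bounding box; defaults to the field
#'   footprint.
#' @param alpha Significance threshold for tests and stepwise retention.
#' @param interval_m Path sampling interval, meters.
#' @param quiet Suppress per-stage progress messages.
#' @return An `exposure_analysis` list; see the individual components.
#' @export
run_exposure_pipeline <- function(person_days, network, field,
                                  domain_bbox = NULL, alpha = 0.05,
                                  interval_m = 100, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (is.null(domain_bbox)) {
    g <- field$grid
    domain_bbox <- c(xmin = g$x0, xmax = g$x0 + g$nx * g$cell_size_m,
                     ymin = g$y0, ymax = g$y0 + g$ny * g$cell_size_m)
  }
  filt <- filter_person_days(person_days, domain_bbox)
  say("filter: kept ", nrow(filt$kept), " of ", nrow(person_days),
      " person-days (",
      paste(sprintf("%s: %d", names(table(filt$excluded$reason)),
                    table(filt$excluded$reason)), collapse = ", "), ")")
  kept <- pare_to_24h(filt$kept)

  say("routing and exposure integration for ", nrow(kept), " person-days")
  records <- exposure_records(kept, network, field, interval_m)
  records$travel_stratum <- travel_stratum(records$travel_minutes)

  summaries <- exposure_group_summaries(records)
  tests <- exposure_group_tests(records, alpha)
  paired <- paired_t(records$c_activity, records$c_residence)
  travelling <- records[records$travel_minutes > 0, ]
  bias <- tibble::tibble(
    sample = c("full", "travelling"),
    n = c(nrow(records), nrow(travelling)),
    bias_factor = c(bias_factor(records$c_residence, records$c_activity),
                    if (nrow(travelling) >= 3 &&
                          stats::var(travelling$c_residence) > 0) {
                      bias_factor(travelling$c_residence,
                                  travelling$c_activity)
                    } else NA_real_)
  )
  error_summary <- tibble::tibble(
    mean = mean(records$error_pct),
    min = min(records$error_pct),
    max = max(records$error_pct),
    pct_positive = 100 * mean(records$error_pct > 0)
  )
  contributions <- activity_contributions(records) |>
    dplyr::left_join(dplyr::select(records, "person_id", "travel_stratum"),
                     by = "person_id") |>
    dplyr::summarise(mean_percent = mean(.data$percent), .by = "kind")

  say("fitting hierarchical stepwise regression")
  design <- exposure_design(records)
  # categories absent from the sample (zero-variance columns) cannot be
  # estimated and are dropped from the blocks, like subgroups too small to
  # report in survey analyses
  blocks <- purrr::map(exposure_blocks(), function(vars) {
    vars[vapply(vars, function(v) stats::var(design[[v]]) > 0, logical(1))]
  })
  blocks <- blocks[lengths(blocks) > 0]
  # with sparse samples a category can be implied by the others (e.g. no
  # rural residents makes the urbanicity dummies sum to one); drop aliased
  # columns so every remaining predictor is estimable
  full <- stats::lm(stats::reformulate(unlist(blocks), "c_activity"),
                    data = design)
  aliased <- names(which(summary(full)$aliased))
  if (length(aliased) > 0) {
    say("dropping inestimable predictor(s): ",
        paste(aliased, collapse = ", "))
    blocks <- purrr::map(blocks, setdiff, aliased)
    blocks <- blocks[lengths(blocks) > 0]
  }
  regression <- hierarchical_stepwise_ols(design, "c_activity", blocks,
                                          alpha)
  interaction_fit <- fit_interactions(design, regression)

  structure(list(
    records = records,
    counts = list(kept = nrow(kept), excluded = table(filt$excluded$reason)),
    summaries = summaries,
    tests = tests,
    paired = paired,
    bias = bias,
    error_summary = error_summary,
    contributions = contributions,
    regression = regression,
    interaction_fit = interaction_fit
  ), class = "exposure_analysis")
}

# urbanicity x sociodemographic interactions added to the retained model
fit_interactions <- function(design, regression) {
  terms <- c("urban:black", "suburban:black", "suburban:below_poverty")
  needed <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  design2 <- add_interactions(design, terms)
  vars <- unique(c(regression$retained, needed, gsub(":", "_x_", terms)))
  stats::lm(stats::reformulate(vars, regression$response), data = design2)
}

exposure_group_summaries <- function(records) {
  # racioethnic flags are non-exclusive, so each is summarised as its own
  # subsample rather than as levels of one factor
  race <- purrr::map_dfr(c("black", "hispanic", "white"), function(flag) {
    sub <- records[records[[flag]], ]
    purrr::map_dfr(c("c_activity", "error_pct"), function(m) {
      dplyr::mutate(one_group_stats(sub[[m]]),
                    metric = m, group_type = "race_ethnicity",
                    group = flag, .before = 1)
    })
  })

  exclusive <- purrr::map_dfr(
    c(income = "income_category", age = "age_group",
      urbanicity = "residence_urbanicity", travel_time = "travel_stratum"),
    function(col) {
      purrr::map_dfr(c("c_activity", "error_pct"), function(m) {
        group_summary(records, !!rlang::sym(m), !!rlang::sym(col)) |>
          dplyr::rename(group = !!rlang::sym(col)) |>
          dplyr::mutate(metric = m, .before = 1)
      })
    }, .id = "group_type") |>
    dplyr::relocate("metric", "group_type", "group")

  dplyr::bind_rows(race, exclusive)
}

one_group_stats <- function(v) {
  d <- tibble::tibble(v = v, g = "all")
  out <- group_summary(d, !!rlang::sym("v"), !!rlang::sym("g"))
  dplyr::select(out, -"g")
}

exposure_group_tests <- function(records, alpha) {
  stacked_race <- purrr::map_dfr(c("black", "hispanic", "white"),
    function(flag) {
      tibble::tibble(group = flag,
                     c_activity = records$c_activity[records[[flag]]],
                     error_pct = records$error_pct[records[[flag]]])
    })
  specs <- list(
    race_ethnicity = list(data = stacked_race, col = "group"),
    income = list(data = records, col = "income_category"),
    age = list(data = records, col = "age_group"),
    urbanicity = list(data = records, col = "residence_urbanicity"),
    travel_time = list(data = records, col = "travel_stratum")
  )
  purrr::map_dfr(names(specs), function(nm) {
    d <- specs[[nm]]$data
    col <- rlang::sym(specs[[nm]]$col)
    purrr::map_dfr(c("c_activity", "error_pct"), function(m) {
      v <- rlang::sym(m)
      av <- tryCatch(one_way_anova(d, !!v, !!col),
                     error = function(e) tibble::tibble(
                       f = NA_real_, df1 = NA_real_, df2 = NA_real_,
                       p = NA_real_))
      gh <- tryCatch(suppressWarnings(games_howell(d, !!v, !!col, alpha)),
                     error = function(e) tibble::tibble())
      tibble::tibble(group_type = nm, metric = m, anova = list(av),
                     games_howell = list(gh))
    })
  })
}

#' @export
print.exposure_analysis <- function(x, ...) {
  cat("<exposure_analysis> ", nrow(x$records), " person-days\n", sep = "")
  cat(sprintf("  mean C_A %.1f ug/m3 (range %.1f-%.1f), mean C_R %.1f ug/m3\n",
              mean(x$records$c_activity), min(x$records$c_activity),
              max(x$records$c_activity), mean(x$records$c_residence)))
  cat(sprintf("  mean exposure error %.1f%% (range %.0f%% to %.0f%%), %0.f%% positive\n",
              x$error_summary$mean, x$error_summary$min, x$error_summary$max,
              x$error_summary$pct_positive))
  cat(sprintf("  bias factor: %.2f (full), %.2f (travelling)\n",
              x$bias$bias_factor[1], x$bias$bias_factor[2]))
  cat("  regression: ")
  print(x$regression)
  invisible(x)
}
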