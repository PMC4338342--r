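#' Group distribution summaries with confidence intervals
#'
#' For each group: n, mean, a t-based 95% confidence interval
#' (`mean +/- t(0.975, n-1) * s / sqrt(n)`; `NA` for singleton groups), the
#' range, and the 5/25/50/75/95th percentiles by linear interpolation.
#'
#' @param data A data frame.
#' @param value Column of values to summarise (tidy-eval).
#' @param by Grouping column (tidy-eval).
#' @param conf Confidence level.
#' @return A tibble with one row per group. Groups with no non-missing
#'   values are skipped with a warning.
#' @export
group_summary <- function(data, value, by, conf = 0.95) {
  data <- dplyr::filter(data, !is.na({{ value }}), !is.na({{ by }}))
  if (nrow(data) == 0) {
    warning("no non-empty groups to summarise")
    return(dplyr::summarise(data, .by = {{ by }}))
  }
  out <- data |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean({{ value }}),
      ci_lo = if (dplyr::n() >= 2) {
        mean({{ value }}) - stats::qt(1 - (1 - conf) / 2, dplyr::n() - 1) *
          stats::sd({{ value }}) / sqrt(dplyr::n())
      } else NA_real_,
      ci_hi = if (dplyr::n() >= 2) {
        mean({{ value }}) + stats::qt(1 - (1 - conf) / 2, dplyr::n() - 1) *
          stats::sd({{ value }}) / sqrt(dplyr::n())
      } else NA_real_,
      min = min({{ value }}),
      max = max({{ value }}),
      p5 = stats::quantile({{ value }}, 0.05, names = FALSE),
      p25 = stats::quantile({{ value }}, 0.25, names = FALSE),
      p50 = stats::quantile({{ value }}, 0.50, names = FALSE),
      p75 = stats::quantile({{ value }}, 0.75, names = FALSE),
      p95 = stats::quantile({{ value }}, 0.95, names = FALSE),
      .by = {{ by }}
    )
  out
}

#' One-way analysis of variance
#'
#' Classical between/within F test with degrees of freedom (k - 1, N - k).
#'
#' @param data A data frame.
#' @param value Value column (tidy-eval).
#' @param by Grouping column (tidy-eval).
#' @return A one-row tibble: `f`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(data, value, by) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ by }}))
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs n >= 2", call. = FALSE)
  ft <- stats::oneway.test(v ~ g, var.equal = TRUE)
  if (!is.finite(ft$statistic)) {
    stop("F is undefined: no within-group or between-group variance",
         call. = FALSE)
  }
  tibble::tibble(f = unname(ft$statistic),
                 df1 = unname(ft$parameter[1]),
                 df2 = unname(ft$parameter[2]),
                 p = unname(ft$p.value))
}

#' Games-Howell post hoc pairwise comparisons
#'
#' Pairwise mean comparisons that do not assume equal variances or sample
#' sizes: each pair uses the Welch standard error
#' `se = sqrt(s_i^2/n_i + s_j^2/n_j)` and Welch-Satterthwaite degrees of
#' freedom (used unrounded), with the statistic `q = |m_i - m_j| sqrt(2) / se`
#' referred to the studentized range distribution with `k` groups, giving
#' familywise control over all pairs. With two groups it reduces to the
#' Welch two-sample t test. Pairs whose Welch df falls below 2 (possible
#' only with near-singleton groups) get an `NA` p-value with a warning, as
#' the studentized range distribution is not available there.
#'
#' @param data A data frame.
#' @param value Value column (tidy-eval).
#' @param by Grouping column (tidy-eval).
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble with one row per unordered pair: `group1`, `group2`,
#'   `diff` (mean of `group1` minus mean of `group2`), `se`, `statistic`
#'   (the studentized range q), `df`, `p`, `significant`.
#' @export
games_howell <- function(data, value, by, alpha = 0.05) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ by }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- droplevels(g[keep])
  k <- nlevels(g)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  n <- tapply(v, g, length)
  m <- tapply(v, g, mean)
  s2 <- tapply(v, g, stats::var)
  if (any(n < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (any(s2 == 0)) {
    stop("zero variance in group(s): ",
         paste(levels(g)[s2 == 0], collapse = ", "), call. = FALSE)
  }
  pairs <- utils::combn(levels(g), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(c0) {
    i <- pairs[1, c0]
    j <- pairs[2, c0]
    se <- sqrt(s2[[i]] / n[[i]] + s2[[j]] / n[[j]])
    df <- se^4 / ((s2[[i]] / n[[i]])^2 / (n[[i]] - 1) +
                    (s2[[j]] / n[[j]])^2 / (n[[j]] - 1))
    q <- abs(m[[i]] - m[[j]]) * sqrt(2) / se
    # the studentized range distribution is defined here for df >= 2;
    # smaller Welch df (possible only for near-singleton groups) give NA
    p <- if (df >= 2) {
      stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    } else {
      warning("Welch df < 2 for pair ", i, "-", j,
              "; p-value set to NA", call. = FALSE)
      NA_real_
    }
    tibble::tibble(group1 = i, group2 = j, diff = m[[i]] - m[[j]],
                   se = se, statistic = q, df = df, p = p,
                   significant = p < alpha)
  })
}

#' Paired t test with explicit degenerate handling
#'
#' Standard paired t test on the differences. If every difference is zero
#' the pairs are identical and `t = 0`, `p = 1` is returned; if the
#' differences are a nonzero constant the test statistic diverges and
#' `t = +/- Inf`, `p = 0` is returned.
#'
#' @param a,b Equal-length numeric vectors of paired observations.
#' @return A one-row tibble: `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("`a` and `b` must be paired with n >= 2", call. = FALSE)
  }
  d <- a - b
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(t = 0, df = n - 1, p = 1, mean_diff = 0))
    }
    return(tibble::tibble(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                          mean_diff = mean(d)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Append interaction columns to a design data frame
#'
#' Appends the elementwise product of each named pair as a new column with
#' the deterministic name `a_x_b`.
#'
#' @param data A data frame.
#' @param terms Character vector of pairs `"a:b"` naming existing columns.
#' @return `data` with the interaction columns appended.
#' @export
add_interactions <- function(data, terms) {
  for (term in terms) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !all(parts %in% names(data))) {
      stop("unknown interaction term `", term, "`", call. = FALSE)
    }
    data[[paste0(parts[1], "_x_", parts[2])]] <-
      as.numeric(data[[parts[1]]]) * as.numeric(data[[parts[2]]])
  }
  data
}

#' Hierarchical stepwise OLS regression of exposure concentration
#'
#' Fits an ordinary least-squares model block by block. Blocks enter in the
#' given order (sociodemographics, then income, then urbanicity, then the
#' continuous activity-time variable, for the exposure model); within each
#' block the least-significant predictor with `p >= alpha` is dropped and
#' the model refitted, one at a time, until every current-block predictor is
#' significant. Predictors retained from earlier blocks are never
#' re-dropped. Categorical predictors must be pre-coded as 0/1 columns, with
#' the reference category omitted.
#'
#' @param data A data frame holding the response and all predictor columns.
#' @param response Name of the response column.
#' @param blocks Ordered named list of character vectors of predictor
#'   columns.
#' @param alpha Retention threshold (two-sided p-value).
#' @return A `stepwise_ols` object: the final `lm` fit plus the retention
#'   history. Use [tidy()] for coefficients and [glance()] for fit
#'   statistics.
#' @export
hierarchical_stepwise_ols <- function(data, response, blocks, alpha = 0.05) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  missing_cols <- setdiff(c(response, unlist(blocks)), names(data))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  retained <- character(0)
  history <- list()
  for (b in seq_along(blocks)) {
    block_name <- names(blocks)[b] %||% as.character(b)
    block_vars <- blocks[[b]]
    repeat {
      current <- c(retained, block_vars)
      fit <- stats::lm(stats::reformulate(if (length(current)) current else "1",
                                          response), data = data)
      aliased <- names(which(summary(fit)$aliased))
      if (length(aliased) > 0) {
        stop("rank-deficient design; collinear column(s): ",
             paste(aliased, collapse = ", "), call. = FALSE)
      }
      if (length(block_vars) == 0) break
      coefs <- summary(fit)$coefficients
      pv <- coefs[block_vars, "Pr(>|t|)"]
      worst <- which.max(pv)
      if (pv[worst] < alpha) break
      history[[length(history) + 1L]] <- tibble::tibble(
        term = block_vars[worst], block = block_name,
        p_at_drop = unname(pv[worst]))
      block_vars <- block_vars[-worst]
    }
    retained <- c(retained, block_vars)
  }
  fit <- stats::lm(stats::reformulate(if (length(retained)) retained else "1",
                                      response), data = data)
  structure(list(
    fit = fit,
    retained = retained,
    dropped = if (length(history)) dplyr::bind_rows(history) else
      tibble::tibble(term = character(), block = character(),
                     p_at_drop = double()),
    blocks = blocks,
    response = response,
    alpha = alpha,
    n = stats::nobs(fit)
  ), class = "stepwise_ols")
}

#' @export
print.stepwise_ols <- function(x, ...) {
  cat("Hierarchical stepwise OLS:", x$response, "~",
      paste(x$retained, collapse = " + "), "\n")
  s <- summary(x$fit)
  co <- s$coefficients
  cat(sprintf("  n = %d, R^2 = %.3f, adj. R^2 = %.3f\n",
              x$n, s$r.squared, s$adj.r.squared))
  for (r in seq_len(nrow(co))) {
    cat(sprintf("  %-24s %8.3f  t = %6.2f  p = %.3g\n",
                rownames(co)[r], co[r, 1], co[r, 3], co[r, 4]))
  }
  if (nrow(x$dropped) > 0) {
    cat("  dropped:", paste(x$dropped$term, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname hierarchical_stepwise_ols
#' @param x A `stepwise_ols` object.
#' @param ... Unused.
#' @export
tidy.stepwise_ols <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = unname(co[, 1]),
                 std.error = unname(co[, 2]), statistic = unname(co[, 3]),
                 p.value = unname(co[, 4]))
}

#' @rdname hierarchical_stepwise_ols
#' @export
glance.stepwise_ols <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 sigma = s$sigma, n = x$n,
                 n_dropped = nrow(x$dropped))
}
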