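# Cohort characteristics table, market-share extrapolation, and plotting.

#' Format a cohort percentage
#'
#' Percent of a column total, rounded half-up to one decimal. Any nonzero
#' count below 0.05% renders `"<0.1"` rather than a misleading `"0.0"`.
#'
#' @param level_count,column_total Non-negative counts with
#'   `level_count <= column_total` and `column_total > 0`.
#' @return Character scalar, e.g. `"52.2"` or `"<0.1"`.
#' @examples
#' cohort_percent(1941970, 3717210)
#' @export
cohort_percent <- function(level_count, column_total) {
  if (column_total <= 0) stop("column total must be > 0", call. = FALSE)
  stopifnot(level_count >= 0, level_count <= column_total)
  pct <- 100 * level_count / column_total
  if (level_count > 0 && pct < 0.05) return("<0.1")
  sprintf("%.1f", floor(pct * 10 + 0.5) / 10)  # round half up
}

fmt_count_pct <- function(count, total) {
  if (total == 0) return("0 (—)")
  paste0(count, " (", cohort_percent(count, total), ")")
}

fmt_median_iqr <- function(ages) {
  if (length(ages) == 0) return("—")
  q <- quantile(ages, c(0.25, 0.5, 0.75), type = 7)  # linear interpolation
  r <- function(x) floor(x + 0.5)
  sprintf("%d (%d-%d)", r(q[2]), r(q[1]), r(q[3]))
}

#' Cohort characteristics table by exposure zone
#'
#' Counts and formatted percents of sex and race/ethnicity levels, plus
#' median (IQR) age in years at `reference_date`, for the total cohort and
#' each exposure-zone column. Unknown levels are reported, never dropped;
#' quartiles use linear interpolation.
#'
#' @param members Member table ([generate_members()] schema).
#' @param zoning [classify_tracts()] output covering every member tract.
#' @param reference_date Date at which age is computed.
#' @return Tibble with columns `attribute`, `level`, `total`, `high`,
#'   `moderate`, `minimal`; cells are formatted strings (`"count (pct)"`,
#'   `"median (q1-q3)"`, or `"0 (—)"` for an empty stratum).
#' @export
cohort_table <- function(members, zoning, reference_date) {
  reference_date <- as.Date(reference_date)
  unzoned <- setdiff(unique(members$tract_id), zoning$tract_id)
  if (length(unzoned) > 0) {
    stop("member tract(s) missing from zoning: ",
         paste(unzoned, collapse = ", "), call. = FALSE)
  }
  members$zone <- zoning$zone[match(members$tract_id, zoning$tract_id)]
  members$age <- as.numeric(reference_date - as.Date(members$birth_date)) / 365.25
  cols <- c("total", exposure_levels())
  col_members <- function(col) {
    if (col == "total") members else members[members$zone == col, , drop = FALSE]
  }
  levels_of <- list(
    sex = c("female", "male", "other", "unknown"),
    race_ethnicity = c("hispanic", "nh_asian", "nh_black", "nh_white",
                       "other", "unknown")
  )
  rows <- list(tibble::tibble(
    attribute = "age", level = "median_iqr_years",
    !!!setNames(lapply(cols, function(cl) fmt_median_iqr(col_members(cl)$age)), cols)
  ))
  for (attr_name in names(levels_of)) {
    for (lv in levels_of[[attr_name]]) {
      rows <- c(rows, list(tibble::tibble(
        attribute = attr_name, level = lv,
        !!!setNames(lapply(cols, function(cl) {
          m <- col_members(cl)
          fmt_count_pct(sum(m[[attr_name]] == lv), nrow(m))
        }), cols)
      )))
    }
  }
  dplyr::bind_rows(rows)
}

#' Render a cohort table as Markdown
#'
#' @param tbl Output of [cohort_table()].
#' @return Character scalar containing a Markdown pipe table.
#' @export
render_cohort_markdown <- function(tbl) {
  hdr <- names(tbl)
  lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
             vapply(seq_len(nrow(tbl)), function(i) {
               paste0("| ", paste(unlist(tbl[i, ]), collapse = " | "), " |")
             }, character(1)))
  paste(lines, collapse = "\n")
}

#' Extrapolate cohort excess to the insured population
#'
#' Divides cohort-level excess (point estimate and both CI bounds alike) by
#' the zone's market-share coverage fraction — the share of the insured
#' population the analyzed cohort represents in that zone. When the estimate
#' spans several zones a `"combined"` row sums the zone-level results.
#'
#' @param estimates Excess-estimate tibble (e.g. [monte_carlo_ci()] rows)
#'   with an added `zone` column.
#' @param coverage Named numeric vector (or data frame with `zone`,
#'   `coverage_fraction`) of fractions in (0, 1]; one per zone present.
#' @return Tibble with `zone`, `population_excess`, `population_ci_low`,
#'   `population_ci_high`.
#' @examples
#' est <- tibble::tibble(zone = "high", excess = 136,
#'                       excess_ci_low = 100, excess_ci_high = 170)
#' extrapolate_excess(est, c(high = 0.136))
#' @export
extrapolate_excess <- function(estimates, coverage) {
  if (is.data.frame(coverage)) {
    coverage <- setNames(coverage$coverage_fraction, coverage$zone)
  }
  if (!"zone" %in% names(estimates)) {
    stop("estimates must carry a 'zone' column", call. = FALSE)
  }
  missing_z <- setdiff(unique(estimates$zone), names(coverage))
  if (length(missing_z) > 0) {
    stop("missing coverage fraction for zone(s): ",
         paste(missing_z, collapse = ", "), call. = FALSE)
  }
  f <- unname(coverage[estimates$zone])
  if (any(f <= 0 | f > 1)) stop("coverage fractions must be in (0, 1]", call. = FALSE)
  out <- tibble::tibble(
    zone = estimates$zone,
    population_excess = estimates$excess / f,
    population_ci_low = estimates$excess_ci_low / f,
    population_ci_high = estimates$excess_ci_high / f
  )
  if (nrow(out) > 1) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      zone = "combined",
      population_excess = sum(out$population_excess),
      population_ci_low = sum(out$population_ci_low),
      population_ci_high = sum(out$population_ci_high)
    ))
  }
  out
}

#' Plot a daily excess profile
#'
#' Point estimates of daily percent excess with 95% empirical CI whiskers,
#' one panel per stratum when a `stratum` column is present.
#'
#' @param daily `daily` tibble from [daily_excess_profile()].
#' @return A ggplot object.
#' @export
plot_excess <- function(daily) {
  p <- ggplot2::ggplot(daily, ggplot2::aes(x = .data$date, y = .data$pct_excess)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.25) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "Excess visits (%)",
                  title = "Daily percent excess with 95% empirical CIs") +
    ggplot2::theme_minimal()
  if ("stratum" %in% names(daily)) {
    p <- p + ggplot2::facet_wrap(~stratum)
  }
  p
}
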