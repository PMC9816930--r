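#' Percentile by linear interpolation
#'
#' Linear interpolation between closest order statistics (the default
#' convention of R and of mainstream numerical environments).
#'
#' @param values numeric vector (non-empty).
#' @param p percentile(s) in `[0, 100]`.
#' @return Interpolated percentile value(s).
#' @export
percentile <- function(values, p) {
  if (length(values) == 0L) stop_fp("percentile: empty input")
  if (any(p < 0 | p > 100)) stop_fp("percentile: p must be in [0, 100]")
  as.numeric(quantile(values, probs = p / 100, type = 7, names = FALSE))
}

#' Notch (95% CI of the median) for a notched boxplot
#'
#' The standard notched-boxplot rule: `median +/- 1.57 * IQR / sqrt(n)`.
#' Non-overlapping notches between two boxes indicate a significant
#' difference in medians.
#'
#' @param values numeric vector (non-empty).
#' @return Numeric `c(low, high)`.
#' @export
notch_ci <- function(values) {
  if (length(values) == 0L) stop_fp("notch_ci: empty input")
  m <- median(values)
  iqr <- diff(percentile(values, c(25, 75)))
  half <- 1.57 * iqr / sqrt(length(values))
  c(low = m - half, high = m + half)
}

#' Boxplot statistics for one set of values
#'
#' Quartiles, whiskers at the most extreme data points within 1.5 IQR of the
#' box, and the median notch, as plot-ready numbers.
#'
#' @param values numeric vector (non-empty).
#' @return One-row data frame.
#' @export
boxplot_stats <- function(values) {
  if (length(values) == 0L) stop_fp("boxplot_stats: empty input")
  q <- percentile(values, c(25, 50, 75))
  iqr <- q[3] - q[1]
  lo <- values[values >= q[1] - 1.5 * iqr]
  hi <- values[values <= q[3] + 1.5 * iqr]
  notch <- notch_ci(values)
  data.frame(n = length(values), q1 = q[1], median = q[2], q3 = q[3],
             whisker_low = min(lo), whisker_high = max(hi),
             notch_low = notch[["low"]], notch_high = notch[["high"]],
             p5 = percentile(values, 5), p95 = percentile(values, 95))
}

#' Evaluate a fortification scenario on individual survey data
#'
#' Recomputes every person's nutrient intake on the (fortified) food table
#' and summarizes each stratum: median, P5, P95 and the median notch. The
#' stratum median is compared to its RI (`target_reached`) and the P95 to
#' its UL (`ul_exceeded`).
#'
#' @param records,persons survey inputs.
#' @param fortified_table the (fortified) food table to evaluate; pass the
#'   unfortified table to summarize background intake.
#' @param strata stratum partition.
#' @param targets a [target_spec()].
#' @param scenario_name label stored on the summary.
#' @param background_table optional unfortified table; adds a
#'   `background_median_ug` column.
#' @return An `evaluation_summary` data frame (one row per stratum). The
#'   per-person intakes and per-stratum boxplot statistics are attached as
#'   attributes `"person_values"` and `"boxplot"`.
#' @export
evaluate_scenario <- function(records, persons, fortified_table, strata,
                              targets, scenario_name = "scenario",
                              background_table = NULL) {
  totals <- compute_person_group_totals(records, fortified_table, persons)
  sid <- assign_strata(persons, strata)
  x <- totals$totals$nutrient_ug_per_day
  sids <- as.character(strata$stratum_id)
  if (!all(sids %in% targets$stratum_id)) {
    stop_fp("targets missing for stratum(s): %s",
            paste(setdiff(sids, targets$stratum_id), collapse = ", "))
  }
  rows <- lapply(sids, function(s) {
    v <- x[sid == s]
    if (length(v) == 0L) stop_fp("evaluate_scenario: empty stratum '%s'", s)
    t <- targets[targets$stratum_id == s, ]
    notch <- notch_ci(v)
    data.frame(stratum_id = s, n = length(v),
               median_ug = median(v),
               p5_ug = percentile(v, 5), p95_ug = percentile(v, 95),
               notch_low = notch[["low"]], notch_high = notch[["high"]],
               ri_ug_per_day = t$ri_ug_per_day,
               ul_ug_per_day = t$ul_ug_per_day,
               target_reached = median(v) >= t$ri_ug_per_day,
               ul_exceeded = percentile(v, 95) > t$ul_ug_per_day,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- merge(strata[, c("stratum_id", "sexes", "age_min", "age_max")], out,
               by = "stratum_id", sort = FALSE)
  out <- out[match(sids, out$stratum_id), ]
  rownames(out) <- NULL
  if (!is.null(background_table)) {
    bt <- compute_person_group_totals(records, background_table, persons)
    out$background_median_ug <- vapply(sids, function(s) {
      median(bt$totals$nutrient_ug_per_day[sid == s])
    }, numeric(1))
  }
  bx <- do.call(rbind, lapply(sids, function(s) {
    cbind(data.frame(stratum_id = s, stringsAsFactors = FALSE),
          boxplot_stats(x[sid == s]))
  }))
  attr(out, "scenario") <- scenario_name
  attr(out, "person_values") <- data.frame(person_id = persons$person_id,
                                           stratum_id = sid,
                                           nutrient_ug_per_day = x,
                                           stringsAsFactors = FALSE)
  attr(out, "boxplot") <- bx
  class(out) <- c("evaluation_summary", "data.frame")
  out
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("evaluation summary for scenario '%s'\n",
              attr(x, "scenario") %||% "?"))
  df <- as.data.frame(x)
  df$intake <- sprintf("%.1f (%.1f, %.1f)", df$median_ug, df$p5_ug, df$p95_ug)
  print(df[, c("stratum_id", "n", "intake", "target_reached", "ul_exceeded")],
        row.names = FALSE)
  invisible(x)
}

#' Long-format comparison of background and scenario summaries
#'
#' One row per (stratum, scenario), background first, with the median
#' (P5, P95) layout used in intake-distribution reports, plus the per-row
#' boxplot statistics (quartiles, 1.5 IQR whiskers, notches) for external
#' plotting.
#'
#' @param background an `evaluation_summary` of the unfortified table.
#' @param scenarios named list of `evaluation_summary` objects.
#' @return A `scenario_comparison` object: list with `table` (long format)
#'   and `boxplot` data frames.
#' @export
scenario_comparison_table <- function(background, scenarios) {
  if (is.null(names(scenarios)) || any(names(scenarios) == "")) {
    names(scenarios) <- vapply(scenarios, function(s) {
      as.character(attr(s, "scenario") %||% "scenario")
    }, character(1))
  }
  all_s <- c(list(background = background), scenarios)
  ref <- background$stratum_id
  one <- function(name, s) {
    if (!identical(sort(s$stratum_id), sort(ref))) {
      stop_fp("scenario '%s': stratum set differs from background", name)
    }
    s <- s[match(ref, s$stratum_id), ]
    data.frame(scenario = name,
               stratum_id = s$stratum_id, sex = s$sexes,
               age_group = sprintf("%d-%d", s$age_min, s$age_max),
               n = s$n, median_ug = s$median_ug,
               p5_ug = s$p5_ug, p95_ug = s$p95_ug,
               intake = sprintf("%.1f (%.1f, %.1f)",
                                s$median_ug, s$p5_ug, s$p95_ug),
               target_reached = s$target_reached,
               ul_exceeded = s$ul_exceeded,
               stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, Map(one, names(all_s), all_s))
  rownames(tab) <- NULL
  bx <- do.call(rbind, Map(function(name, s) {
    b <- attr(s, "boxplot")
    if (is.null(b)) return(NULL)
    cbind(data.frame(scenario = name, stringsAsFactors = FALSE), b)
  }, names(all_s), all_s))
  rownames(bx) <- NULL
  structure(list(table = tab, boxplot = bx), class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  wide <- stats::reshape(
    x$table[, c("scenario", "stratum_id", "sex", "age_group", "n", "intake")],
    direction = "wide", idvar = c("stratum_id", "sex", "age_group", "n"),
    timevar = "scenario")
  names(wide) <- sub("^intake\\.", "", names(wide))
  cat("median (P5, P95) nutrient intake, ug/day\n")
  print(wide, row.names = FALSE)
  invisible(x)
}
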