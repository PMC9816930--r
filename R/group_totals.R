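#' Per-person food-group totals
#'
#' For every person and food group, sums grams/day, energy (MJ/day) and
#' nutrient (µg/day) over the group's items. Persons with no record in a
#' group get explicit zeros, so non-consumers enter later medians as zeros.
#' Person totals are computed directly from the record level (not by summing
#' the group matrices), so the group/total conservation identity is a real
#' cross-check.
#'
#' @param records intake records ([read_intake_records()]).
#' @param food_table food-composition table ([read_food_table()]).
#' @param persons person roster ([read_persons()]).
#' @return A `person_group_totals` object: matrices `grams`, `energy_mj`,
#'   `nutrient_ug` (persons x groups) and a `totals` data frame with
#'   per-person sums of the same three quantities.
#' @export
compute_person_group_totals <- function(records, food_table, persons) {
  records <- as_intake_records(records, persons = persons,
                               food_table = food_table)
  groups <- food_groups(food_table)
  idx <- match(records$food_code, food_table$food_code)
  energy_mj <- records$grams_per_day * food_table$energy_kj_per_100g[idx] / 1e5
  nutrient_ug <- records$grams_per_day * food_table$nutrient_ug_per_100g[idx] / 100

  pid <- factor(records$person_id, levels = persons$person_id)
  gid <- factor(food_table$group_id[idx], levels = groups$group_id)
  by2 <- list(pid, gid)
  g_mat <- tapply(records$grams_per_day, by2, sum, default = 0)
  e_mat <- tapply(energy_mj, by2, sum, default = 0)
  n_mat <- tapply(nutrient_ug, by2, sum, default = 0)
  g_mat[is.na(g_mat)] <- 0; e_mat[is.na(e_mat)] <- 0; n_mat[is.na(n_mat)] <- 0

  # totals straight from the records, independent of the group split
  tot <- data.frame(
    person_id = persons$person_id,
    grams_per_day = as.numeric(tapply(records$grams_per_day, pid, sum, default = 0)),
    energy_mj_per_day = as.numeric(tapply(energy_mj, pid, sum, default = 0)),
    nutrient_ug_per_day = as.numeric(tapply(nutrient_ug, pid, sum, default = 0)),
    stringsAsFactors = FALSE
  )
  tot[is.na(tot)] <- 0

  structure(list(person_ids = persons$person_id,
                 group_ids = groups$group_id,
                 grams = g_mat, energy_mj = e_mat, nutrient_ug = n_mat,
                 totals = tot),
            class = "person_group_totals")
}

#' @export
print.person_group_totals <- function(x, ...) {
  cat(sprintf("person_group_totals: %d persons x %d food groups\n",
              length(x$person_ids), length(x$group_ids)))
  cat(sprintf("  median total energy: %.2f MJ/day, median nutrient: %.2f ug/day\n",
              median(x$totals$energy_mj_per_day),
              median(x$totals$nutrient_ug_per_day)))
  invisible(x)
}

#' Aggregate person-level totals into per-stratum medians
#'
#' Medians are taken over all persons of a stratum, including those who did
#' not consume a group (zeros). The background nutrient median is the median
#' per-person total nutrient intake from the unfortified diet.
#'
#' @param totals result of [compute_person_group_totals()].
#' @param persons person roster.
#' @param strata stratum partition, e.g. [default_strata()].
#' @param groups optional group table; defaults to the groups seen in
#'   `totals`.
#' @return A `stratum_aggregates` object.
#' @export
aggregate_strata <- function(totals, persons, strata, groups = NULL) {
  sid <- assign_strata(persons, strata)
  strata$stratum_id <- as.character(strata$stratum_id)
  f <- factor(sid, levels = strata$stratum_id)
  n_by <- table(f)
  empty <- names(n_by)[n_by == 0L]
  if (length(empty) > 0L) {
    stop_fp("aggregate_strata: empty stratum(s): %s", paste(empty, collapse = ", "))
  }
  med_by_stratum <- function(mat) {
    out <- do.call(rbind, lapply(strata$stratum_id, function(s) {
      apply(mat[f == s, , drop = FALSE], 2L, median)
    }))
    rownames(out) <- strata$stratum_id
    out
  }
  if (is.null(groups)) {
    groups <- data.frame(group_id = totals$group_ids, name = totals$group_ids,
                         fortifiable = TRUE, stringsAsFactors = FALSE)
  }
  stratum_aggregates(
    stratum_id = strata$stratum_id,
    n_persons = as.integer(n_by),
    median_total_energy_mj =
      as.numeric(tapply(totals$totals$energy_mj_per_day, f, median)),
    median_background_nutrient_ug =
      as.numeric(tapply(totals$totals$nutrient_ug_per_day, f, median)),
    median_group_energy_mj = med_by_stratum(totals$energy_mj),
    median_group_grams = med_by_stratum(totals$grams),
    median_group_nutrient_ug = med_by_stratum(totals$nutrient_ug),
    groups = groups,
    strata_def = strata
  )
}

#' Construct stratum aggregates directly
#'
#' Builds the aggregate object the optimizer consumes from already-computed
#' medians, e.g. published aggregate tables when individual records are not
#' available.
#'
#' @param stratum_id character vector of stratum ids.
#' @param median_group_energy_mj strata x groups matrix of median food-group
#'   energy intakes (MJ/day), with column names as group ids.
#' @param median_background_nutrient_ug per-stratum median nutrient intake
#'   from the unfortified diet (µg/day).
#' @param n_persons per-stratum person counts (default 1 when unknown).
#' @param median_total_energy_mj per-stratum median total energy; defaults to
#'   the row sums of the group medians when not supplied.
#' @param median_group_grams,median_group_nutrient_ug optional companion
#'   matrices (g/day, µg/day).
#' @param groups optional group table (`group_id,name,fortifiable`).
#' @param strata_def optional stratum definition data frame.
#' @return A `stratum_aggregates` object.
#' @export
stratum_aggregates <- function(stratum_id, median_group_energy_mj,
                               median_background_nutrient_ug,
                               n_persons = NULL,
                               median_total_energy_mj = NULL,
                               median_group_grams = NULL,
                               median_group_nutrient_ug = NULL,
                               groups = NULL, strata_def = NULL) {
  stratum_id <- as.character(stratum_id)
  E <- as.matrix(median_group_energy_mj)
  if (is.null(colnames(E))) stop_fp("aggregates: group energy matrix needs group ids as column names")
  rownames(E) <- stratum_id
  if (nrow(E) != length(stratum_id)) {
    stop_fp("aggregates: %d strata but %d rows of group medians",
            length(stratum_id), nrow(E))
  }
  if (any(!is.finite(E)) || any(E < 0)) stop_fp("aggregates: group energy medians must be finite and >= 0")
  B <- as.numeric(median_background_nutrient_ug)
  if (length(B) != length(stratum_id) || any(!is.finite(B)) || any(B < 0)) {
    stop_fp("aggregates: background medians must be one finite non-negative value per stratum")
  }
  n_persons <- as.integer(n_persons %||% rep(1L, length(stratum_id)))
  if (any(n_persons < 1L)) stop_fp("aggregates: n_persons must be >= 1")
  if (is.null(groups)) {
    groups <- data.frame(group_id = colnames(E), name = colnames(E),
                         fortifiable = TRUE, stringsAsFactors = FALSE)
  }
  structure(list(
    strata = data.frame(
      stratum_id = stratum_id, n_persons = n_persons,
      median_total_energy_mj =
        as.numeric(median_total_energy_mj %||% rowSums(E)),
      median_background_nutrient_ug = B,
      stringsAsFactors = FALSE),
    median_group_energy_mj = E,
    median_group_grams = median_group_grams,
    median_group_nutrient_ug = median_group_nutrient_ug,
    groups = groups,
    strata_def = strata_def
  ), class = "stratum_aggregates")
}

#' @export
print.stratum_aggregates <- function(x, ...) {
  cat(sprintf("stratum_aggregates: %d strata x %d food groups\n",
              nrow(x$strata), ncol(x$median_group_energy_mj)))
  print(x$strata, row.names = FALSE)
  invisible(x)
}

#' Write / read stratum aggregates as a long CSV
#'
#' One row per (stratum, group); stratum-level quantities (n, median total
#' energy, background nutrient median) and the group `fortifiable` flag are
#' repeated on each row. This is the "aggregates CSV" interface that lets
#' published aggregate data drive the optimizer without individual records.
#'
#' @param aggregates a `stratum_aggregates` object.
#' @param path CSV path.
#' @return `read_aggregates_csv()` returns a `stratum_aggregates` object.
#' @export
write_aggregates_csv <- function(aggregates, path) {
  E <- aggregates$median_group_energy_mj
  s <- aggregates$strata
  gidx <- match(colnames(E), aggregates$groups$group_id)
  long <- do.call(rbind, lapply(seq_len(nrow(E)), function(i) {
    data.frame(
      stratum_id = s$stratum_id[i],
      group_id = colnames(E),
      fortifiable = aggregates$groups$fortifiable[gidx],
      median_group_energy_mj = as.numeric(E[i, ]),
      median_group_grams =
        if (is.null(aggregates$median_group_grams)) NA_real_
        else as.numeric(aggregates$median_group_grams[i, ]),
      median_group_nutrient_ug =
        if (is.null(aggregates$median_group_nutrient_ug)) NA_real_
        else as.numeric(aggregates$median_group_nutrient_ug[i, ]),
      n_persons = s$n_persons[i],
      median_total_energy_mj = s$median_total_energy_mj[i],
      median_background_nutrient_ug = s$median_background_nutrient_ug[i],
      stringsAsFactors = FALSE)
  }))
  write.csv(long, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_aggregates_csv
#' @export
read_aggregates_csv <- function(path) {
  long <- read_csv_keys(path, c("stratum_id", "group_id"))
  assert_cols(long, c("stratum_id", "group_id", "median_group_energy_mj",
                      "n_persons", "median_total_energy_mj",
                      "median_background_nutrient_ug"), "aggregates CSV")
  long$stratum_id <- as.character(long$stratum_id)
  long$group_id <- as.character(long$group_id)
  sids <- unique(long$stratum_id)
  gids <- unique(long$group_id)
  to_mat <- function(col) {
    if (!col %in% names(long) || all(is.na(long[[col]]))) return(NULL)
    m <- matrix(NA_real_, length(sids), length(gids),
                dimnames = list(sids, gids))
    m[cbind(match(long$stratum_id, sids), match(long$group_id, gids))] <-
      long[[col]]
    if (anyNA(m)) stop_fp("aggregates CSV: missing (stratum, group) cell in '%s'", col)
    m
  }
  first_per_stratum <- function(col) {
    as.numeric(long[[col]][match(sids, long$stratum_id)])
  }
  groups <- NULL
  if ("fortifiable" %in% names(long)) {
    groups <- data.frame(group_id = gids, name = gids,
                         fortifiable = as.logical(
                           long$fortifiable[match(gids, long$group_id)]),
                         stringsAsFactors = FALSE)
  }
  stratum_aggregates(
    stratum_id = sids,
    median_group_energy_mj = to_mat("median_group_energy_mj"),
    median_background_nutrient_ug =
      first_per_stratum("median_background_nutrient_ug"),
    n_persons = as.integer(first_per_stratum("n_persons")),
    median_total_energy_mj = first_per_stratum("median_total_energy_mj"),
    median_group_grams = to_mat("median_group_grams"),
    median_group_nutrient_ug = to_mat("median_group_nutrient_ug"),
    groups = groups
  )
}
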