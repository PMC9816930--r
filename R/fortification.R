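#' Population-level group energy density
#'
#' For each food group, the ratio of total population energy from the group
#' (MJ) to the total population grams of the group, pooled over every person
#' and item: `rho_g` in MJ/g. The derived conversion factor
#' `k_g = 10 * rho_g` maps a fortification level in µg/10 MJ to µg/100 g,
#' because 100 g of "group-average" food carries `100 * rho_g` MJ.
#'
#' @param records intake records.
#' @param food_table food-composition table.
#' @return A `group_energy_density` data frame: `group_id, total_grams,
#'   total_energy_mj, rho_mj_per_g, k_per_100g`. Groups never consumed get
#'   `rho = 0` with a warning.
#' @export
group_energy_density <- function(records, food_table) {
  records <- as_intake_records(records, food_table = food_table)
  groups <- food_groups(food_table)
  idx <- match(records$food_code, food_table$food_code)
  gid <- factor(food_table$group_id[idx], levels = groups$group_id)
  energy_mj <- records$grams_per_day * food_table$energy_kj_per_100g[idx] / 1e5
  tg <- as.numeric(tapply(records$grams_per_day, gid, sum, default = 0))
  te <- as.numeric(tapply(energy_mj, gid, sum, default = 0))
  rho <- ifelse(tg > 0, te / tg, 0)
  if (any(tg == 0)) {
    warning(sprintf("group(s) with no recorded intake get rho = 0: %s",
                    paste(groups$group_id[tg == 0], collapse = ", ")),
            call. = FALSE)
  }
  out <- data.frame(group_id = groups$group_id,
                    total_grams = tg, total_energy_mj = te,
                    rho_mj_per_g = rho, k_per_100g = 10 * rho,
                    stringsAsFactors = FALSE)
  class(out) <- c("group_energy_density", "data.frame")
  out
}

#' Convert a scheme from µg/10 MJ to µg/100 g
#'
#' `level_ug_per_100g(g) = level_ug_per_10mj(g) * k_g`. The 3-decimal report
#' form is added alongside full precision. A fortified group whose
#' conversion factor is zero (no recorded energy) cannot carry fortificant
#' and is an error.
#'
#' @param scheme a `fortification_scheme`.
#' @param density result of [group_energy_density()], or any data frame with
#'   `group_id` and `k_per_100g`.
#' @return The scheme with `level_ug_per_100g` and `level_ug_per_100g_3dp`
#'   columns on its levels table.
#' @export
convert_scheme <- function(scheme, density) {
  if (!scheme$feasible) stop_fp("cannot convert an infeasible scheme")
  assert_cols(density, c("group_id", "k_per_100g"), "density")
  lv <- scheme$levels
  k <- density$k_per_100g[match(lv$group_id, density$group_id)]
  if (anyNA(k)) {
    stop_fp("no energy density for group(s): %s",
            paste(lv$group_id[is.na(k)], collapse = ", "))
  }
  dead <- lv$level_ug_per_10mj > 1e-9 & k == 0
  if (any(dead)) {
    stop_fp("fortified group(s) with zero energy density cannot carry fortificant: %s",
            paste(lv$group_id[dead], collapse = ", "))
  }
  lv$level_ug_per_100g <- lv$level_ug_per_10mj * k
  lv$level_ug_per_100g_3dp <- round(lv$level_ug_per_100g, 3)
  scheme$levels <- lv
  scheme$k_per_100g <- setNames(k, lv$group_id)
  scheme
}

#' Apply a converted scheme to a food-composition table
#'
#' Every item of a fortified group gains exactly the group's per-100 g level
#' on its nutrient density; everything else is untouched. The whole group is
#' fortified (100% market penetration).
#'
#' @param food_table a `food_table`.
#' @param scheme a converted `fortification_scheme` (see [convert_scheme()]).
#' @return The fortified `food_table`; the applied levels are kept in the
#'   `"fortification"` attribute.
#' @export
fortify_food_table <- function(food_table, scheme) {
  lv <- scheme$levels
  if (is.null(lv$level_ug_per_100g)) {
    stop_fp("scheme has no per-100 g levels; run convert_scheme() first")
  }
  add <- lv$level_ug_per_100g[match(food_table$group_id, lv$group_id)]
  add[is.na(add)] <- 0
  if (any(add < 0)) stop_fp("negative fortification increment")
  out <- food_table
  out$nutrient_ug_per_100g <- out$nutrient_ug_per_100g + add
  attr(out, "fortification") <- list(scenario = scheme$scenario,
                                     levels = lv)
  out
}

#' Model-predicted added intake per person
#'
#' The added intake the optimizer's energy-based model predicts for each
#' person: `sum_g f_g * (person's energy from g) / 10`. This equals the
#' intake recomputed from the fortified table only when item energy
#' densities within each group are uniform; comparing the two exposes the
#' group-average conversion approximation.
#'
#' @param totals a `person_group_totals` object (unfortified table).
#' @param scheme a `fortification_scheme`.
#' @return Numeric vector of added µg/day, one per person, named by
#'   person id.
#' @export
predicted_added_intake <- function(totals, scheme) {
  f <- scheme$levels$level_ug_per_10mj[
    match(totals$group_ids, scheme$levels$group_id)]
  f[is.na(f)] <- 0
  setNames(as.numeric(totals$energy_mj %*% f) / 10, totals$person_ids)
}

#' Compare model-predicted and table-recalculated added intake
#'
#' @param records,persons survey inputs.
#' @param food_table unfortified table.
#' @param fortified_table output of [fortify_food_table()].
#' @param scheme the applied scheme.
#' @return Data frame per person: `person_id, added_model_ug,
#'   added_table_ug`.
#' @export
added_intake_comparison <- function(records, persons, food_table,
                                    fortified_table, scheme) {
  t0 <- compute_person_group_totals(records, food_table, persons)
  t1 <- compute_person_group_totals(records, fortified_table, persons)
  data.frame(person_id = persons$person_id,
             added_model_ug = as.numeric(predicted_added_intake(t0, scheme)),
             added_table_ug = t1$totals$nutrient_ug_per_day -
               t0$totals$nutrient_ug_per_day,
             stringsAsFactors = FALSE)
}
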