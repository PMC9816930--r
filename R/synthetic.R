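#' Default food-group parameters for the synthetic survey
#'
#' Seventeen food groups of a northern-European food-composition table, with
#' per-group consumption probability, adult median intake (g/day, the
#' log-normal median), log-scale spread, and uniform ranges for item energy
#' (kJ/100 g) and background vitamin-D (µg/100 g) densities. Values are
#' round figures in the range of national 7-day-record surveys: adult median
#' energy close to 10 MJ/day and background vitamin-D intake of a few
#' µg/day, dominated by fish, eggs, fats and meat.
#'
#' @return Data frame of group parameters consumed by [survey_spec()].
#' @export
default_group_params <- function() {
  p <- read.csv(text = "
group_id,name,fortifiable,consumer_prob,gram_median_adult,gram_sdlog,energy_kj_lo,energy_kj_hi,nutrient_ug_lo,nutrient_ug_hi
milk,Milk and milk products,TRUE,0.95,300,0.8,150,300,0.03,0.10
cheese,Cheese and cheese products,TRUE,0.85,40,0.8,1100,1600,0.10,0.40
icecream,Ice cream and edible ices,TRUE,0.55,15,0.9,700,1000,0.05,0.20
cereals,Cereals and cereal products,TRUE,0.99,200,0.6,900,1500,0.00,0.05
vegetables,Vegetables and vegetable products,TRUE,0.95,150,0.7,100,300,0.00,0.02
fruit,Fruit and fruit products,TRUE,0.90,150,0.8,150,350,0.00,0.01
meat,Meat and meat products,TRUE,0.95,120,0.6,600,1200,0.20,1.00
fish,Fish and fish products,TRUE,0.65,30,0.9,500,900,3.00,10.00
poultry,Poultry and poultry products,TRUE,0.70,40,0.8,500,800,0.10,0.50
eggs,Egg and egg products,TRUE,0.80,25,0.7,550,650,1.50,2.20
fats,Fats oils and their products,TRUE,0.90,30,0.7,2500,3300,0.50,1.50
sugar,Sugar honey and products thereof,TRUE,0.80,30,0.9,1200,1700,0.00,0.10
beverages,Beverages,TRUE,0.98,1500,0.6,10,150,0.00,0.00
spices,Spices and other ingredients,TRUE,0.75,10,0.9,300,1000,0.00,0.20
other,Other foods,TRUE,0.55,30,0.9,500,1500,0.00,0.50
potato,Potato and products thereof,TRUE,0.80,100,0.7,300,400,0.00,0.00
juice,Juice,TRUE,0.65,100,0.8,150,200,0.00,0.00
", stringsAsFactors = FALSE, strip.white = TRUE)
  p$fortifiable <- as.logical(p$fortifiable)
  p
}

#' Default stratum sampling weights
#'
#' Roster mix per sex/age stratum, shaped like a national survey with a
#' large adult block: per sex, bands 4-6, 7-10, 11-14, 15-17, 18-50 and
#' 51-75 get 3.2%, 3.2%, 2.8%, 2.8%, 24.5% and 13.5% of persons.
#'
#' @param strata a stratum partition (default [default_strata()]).
#' @return Named numeric vector of proportions summing to 1.
#' @export
default_stratum_weights <- function(strata = default_strata()) {
  w <- c("4-6" = 0.032, "7-10" = 0.032, "11-14" = 0.028, "15-17" = 0.028,
         "18-50" = 0.245, "51-75" = 0.135)
  band <- sprintf("%d-%d", strata$age_min, strata$age_max)
  out <- setNames(w[band], strata$stratum_id)
  out / sum(out)
}

# energy scale relative to an adult male, by age band and sex
stratum_intake_scale <- function(strata) {
  band <- sprintf("%d-%d", strata$age_min, strata$age_max)
  age_scale <- c("4-6" = 0.70, "7-10" = 0.80, "11-14" = 0.90,
                 "15-17" = 1.00, "18-50" = 1.00, "51-75" = 0.90)[band]
  age_scale[is.na(age_scale)] <- 1
  sex_scale <- ifelse(strata$sexes == "F", 0.85, 1)
  setNames(as.numeric(age_scale) * sex_scale, strata$stratum_id)
}

#' Specify a synthetic dietary survey
#'
#' Gram intakes per person and group follow a Bernoulli consumption gate
#' (probability `consumer_prob`) times a log-normal amount, reproducing the
#' right skew and zero inflation of food-group intake data; children and
#' women get proportionally scaled log-normal medians.
#'
#' @param n_persons roster size (default 3946, a national-survey margin).
#' @param groups group parameter table ([default_group_params()]).
#' @param strata stratum partition ([default_strata()]).
#' @param stratum_weights roster proportions per stratum
#'   ([default_stratum_weights()]).
#' @param items_per_group food items generated per group.
#' @param seed integer seed fixing the full output.
#' @return A `survey_spec` object.
#' @export
survey_spec <- function(n_persons = 3946, groups = default_group_params(),
                        strata = default_strata(),
                        stratum_weights = default_stratum_weights(strata),
                        items_per_group = 3, seed = 1) {
  if (n_persons < 1L) stop_fp("survey_spec: n_persons must be >= 1")
  if (nrow(groups) < 1L) stop_fp("survey_spec: at least one food group")
  assert_cols(groups, c("group_id", "name", "fortifiable", "consumer_prob",
                        "gram_median_adult", "gram_sdlog", "energy_kj_lo",
                        "energy_kj_hi", "nutrient_ug_lo", "nutrient_ug_hi"),
              "group params")
  if (any(groups$gram_sdlog < 0)) stop_fp("survey_spec: gram_sdlog must be >= 0")
  if (any(groups$consumer_prob < 0 | groups$consumer_prob > 1)) {
    stop_fp("survey_spec: consumer_prob must be in [0, 1]")
  }
  strata <- validate_strata(strata)
  stratum_weights <- stratum_weights[strata$stratum_id]
  if (anyNA(stratum_weights) || abs(sum(stratum_weights) - 1) > 1e-6) {
    stop_fp("survey_spec: stratum_weights must cover all strata and sum to 1")
  }
  structure(list(n_persons = as.integer(n_persons), groups = groups,
                 strata = strata, stratum_weights = stratum_weights,
                 items_per_group = as.integer(items_per_group),
                 seed = as.integer(seed)),
            class = "survey_spec")
}

#' @export
print.survey_spec <- function(x, ...) {
  cat(sprintf("survey_spec: %d persons, %d food groups, %d strata, seed %d\n",
              x$n_persons, nrow(x$groups), nrow(x$strata), x$seed))
  invisible(x)
}

#' Generate a synthetic dietary survey
#'
#' Draws a person roster, a food-composition table and individual intake
#' records from a [survey_spec()]. Fully deterministic for a fixed seed;
#' non-consumers of a group get no record for it. All numeric outputs are
#' rounded to reporting precision (grams 2 dp, kJ 1 dp, µg 3 dp) so the CSV
#' files round-trip exactly.
#'
#' @param spec a `survey_spec`.
#' @return A `synthetic_survey` list: `persons`, `records`, `food_table`,
#'   `spec`.
#' @export
generate_survey <- function(spec) {
  stopifnot(inherits(spec, "survey_spec"))
  set.seed(spec$seed)
  g <- spec$groups
  strata <- spec$strata

  sidx <- sample.int(nrow(strata), spec$n_persons, replace = TRUE,
                     prob = spec$stratum_weights)
  age <- strata$age_min[sidx] +
    floor(runif(spec$n_persons) * (strata$age_max[sidx] - strata$age_min[sidx] + 1))
  sex <- vapply(strata$sexes[sidx], function(s) {
    ss <- strsplit(s, "")[[1]]
    if (length(ss) == 1L) ss else sample(ss, 1L)
  }, character(1), USE.NAMES = FALSE)
  persons <- data.frame(person_id = sprintf("P%05d", seq_len(spec$n_persons)),
                        sex = sex, age_years = as.integer(age),
                        stringsAsFactors = FALSE)

  items <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    k <- spec$items_per_group
    data.frame(
      food_code = sprintf("%s_%02d", g$group_id[i], seq_len(k)),
      name = sprintf("%s item %d", g$name[i], seq_len(k)),
      group_id = g$group_id[i],
      energy_kj_per_100g = round(runif(k, g$energy_kj_lo[i], g$energy_kj_hi[i]), 1),
      nutrient_ug_per_100g = round(runif(k, g$nutrient_ug_lo[i], g$nutrient_ug_hi[i]), 3),
      stringsAsFactors = FALSE)
  }))
  food_table <- as_food_table(items,
                              groups = g[, c("group_id", "name", "fortifiable")])

  scale <- stratum_intake_scale(strata)[sidx]
  recs <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    eats <- rbinom(spec$n_persons, 1L, g$consumer_prob[i]) == 1L
    grams <- rlnorm(spec$n_persons,
                    meanlog = log(g$gram_median_adult[i] * scale),
                    sdlog = g$gram_sdlog[i])
    item <- sample(spec$items_per_group, spec$n_persons, replace = TRUE)
    recs[[i]] <- data.frame(
      person_id = persons$person_id[eats],
      food_code = sprintf("%s_%02d", g$group_id[i], item[eats]),
      grams_per_day = round(grams[eats], 2),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL

  structure(list(persons = persons, records = records,
                 food_table = food_table, spec = spec),
            class = "synthetic_survey")
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat(sprintf("synthetic_survey: %d persons, %d records, %d items in %d groups\n",
              nrow(x$persons), nrow(x$records), nrow(x$food_table),
              nrow(food_groups(x$food_table))))
  invisible(x)
}

#' Write a survey to the CSV dialects the readers expect
#'
#' @param survey a `synthetic_survey` (or any list with `persons`, `records`,
#'   `food_table`).
#' @param dir output directory (created if missing).
#' @return Named vector of the four file paths.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(persons = file.path(dir, "persons.csv"),
             records = file.path(dir, "records.csv"),
             food_table = file.path(dir, "food_table.csv"),
             food_groups = file.path(dir, "food_groups.csv"))
  write.csv(survey$persons, paths["persons"], row.names = FALSE, quote = TRUE)
  write.csv(survey$records, paths["records"], row.names = FALSE, quote = TRUE)
  write_food_table(survey$food_table, paths["food_table"],
                   groups_path = paths["food_groups"])
  paths
}

#' A small survey whose optimal fortification level is known in closed form
#'
#' Builds a survey with one stratum of identical persons, a single
#' fortifiable "carrier" group supplying `e_mj` MJ/day and a non-fortifiable
#' "base" group supplying the background intake `b_ug` µg/day. With one
#' carrier group, the attainment constraint pins the optimum at
#' `f* = 10 * (RI - B) / E` exactly, so the whole pipeline can be checked
#' against a planted answer.
#'
#' @param ri_ug_per_day recommended intake (µg/day).
#' @param e_mj carrier-group energy per person (MJ/day).
#' @param b_ug background nutrient intake per person (µg/day).
#' @param cap_ug_per_10mj scenario cap; `NULL` picks a cap comfortably above
#'   the planted optimum.
#' @param n_persons roster size (identical persons, so medians are exact).
#' @param seed if non-`NULL`, draws `e_mj` and `b_ug` at random (RI fixed)
#'   for parameter-recovery sweeps.
#' @return List: `persons`, `records`, `food_table`, `strata`, `targets`,
#'   `scenario`, and `expected` (`f_ug_per_10mj`, `min_cap`).
#' @export
generate_known_answer_case <- function(ri_ug_per_day = 10, e_mj = 4,
                                       b_ug = 2, cap_ug_per_10mj = NULL,
                                       n_persons = 5, seed = NULL) {
  if (!is.null(seed)) {
    set.seed(seed)
    e_mj <- round(runif(1, 2, 6), 2)
    b_ug <- round(runif(1, 0.5, 5), 2)
  }
  stopifnot(b_ug < ri_ug_per_day, e_mj > 0)
  f_star <- 10 * (ri_ug_per_day - b_ug) / e_mj
  cap <- cap_ug_per_10mj %||% (ceiling(f_star) + 5)

  food_table <- as_food_table(
    data.frame(food_code = c("carrier_01", "base_01"),
               name = c("carrier food", "base food"),
               group_id = c("carrier", "base"),
               energy_kj_per_100g = c(1000, 100),
               nutrient_ug_per_100g = c(0, 1),
               stringsAsFactors = FALSE),
    groups = data.frame(group_id = c("carrier", "base"),
                        name = c("carrier", "base"),
                        fortifiable = c(TRUE, FALSE),
                        stringsAsFactors = FALSE))
  persons <- data.frame(person_id = sprintf("K%03d", seq_len(n_persons)),
                        sex = rep(c("M", "F"), length.out = n_persons),
                        age_years = 30L, stringsAsFactors = FALSE)
  records <- do.call(rbind, lapply(persons$person_id, function(p) {
    data.frame(person_id = p,
               food_code = c("carrier_01", "base_01"),
               grams_per_day = c(100 * e_mj,  # grams * 1000 kJ/100g = e_mj MJ
                                 100 * b_ug), # grams * 1 ug/100g = b_ug
               stringsAsFactors = FALSE)
  }))
  strata <- data.frame(stratum_id = "all", sexes = "MF",
                       age_min = 4L, age_max = 75L, stringsAsFactors = FALSE)
  list(persons = persons, records = records, food_table = food_table,
       strata = strata,
       targets = target_spec("all", ri_ug_per_day, 100),
       scenario = scenario("known_answer", cap, "carrier"),
       expected = list(f_ug_per_10mj = f_star,
                       min_cap = max(10, ceiling(f_star))))
}
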