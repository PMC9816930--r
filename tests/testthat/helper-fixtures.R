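# shared fixtures and independent oracles, all built in code

tiny_food_table <- function() {
  as_food_table(data.frame(
    food_code = c("0001", "0002", "0003"),
    name = c("semi-skimmed milk", "rye bread", "herring"),
    group_id = c("milk", "cereals", "fish"),
    energy_kj_per_100g = c(200, 950, 800),
    nutrient_ug_per_100g = c(0.5, 0, 8),
    stringsAsFactors = FALSE
  ))
}

tiny_persons <- function() {
  data.frame(person_id = c("A", "B", "C"),
             sex = c("M", "F", "M"),
             age_years = c(30L, 9L, 65L),
             stringsAsFactors = FALSE)
}

tiny_records <- function() {
  data.frame(person_id = c("A", "A", "B"),
             food_code = c("0001", "0002", "0001"),
             grams_per_day = c(250, 100, 150),
             stringsAsFactors = FALSE)
}

# independent linear-interpolation percentile (sort + closest-rank blend),
# written without quantile() so it can cross-check the implementation
manual_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# small random LP instance with guaranteed feasibility margin at its cap
random_lp_instance <- function(seed, n_strata = 2, n_groups = 2,
                               margin = 1.5) {
  set.seed(seed)
  E <- matrix(runif(n_strata * n_groups, 1, 5), n_strata, n_groups,
              dimnames = list(sprintf("s%d", seq_len(n_strata)),
                              sprintf("g%d", seq_len(n_groups))))
  B <- runif(n_strata, 0, 3)
  RI <- B + runif(n_strata, 1, 5)
  cap_needed <- 10 * max((RI - B) / rowSums(E))
  cap <- ceiling(cap_needed * margin)
  agg <- stratum_aggregates(stratum_id = rownames(E),
                            median_group_energy_mj = E,
                            median_background_nutrient_ug = B)
  list(agg = agg,
       targets = target_spec(rownames(E), RI, RI + 100),
       cap = cap)
}

write_test_config <- function(dir, survey_dir, scenarios, output_dir) {
  cfg <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(
    seed = 1L,
    output_dir = output_dir,
    inputs = list(
      persons = file.path(survey_dir, "persons.csv"),
      records = file.path(survey_dir, "records.csv"),
      food_table = file.path(survey_dir, "food_table.csv"),
      food_groups = file.path(survey_dir, "food_groups.csv")),
    strata = "default",
    targets = list(default = list(ri = 10), age_based_ul = TRUE),
    scenarios = scenarios), cfg)
  cfg
}

# one medium synthetic survey shared across test files (cached per session)
shared_survey <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_survey(survey_spec(n_persons = 800, seed = 101))
    }
    cache
  }
})

shared_totals <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sv <- shared_survey()
      cache <<- compute_person_group_totals(sv$records, sv$food_table,
                                            sv$persons)
    }
    cache
  }
})
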