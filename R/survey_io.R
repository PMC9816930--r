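#' Read a food-composition table
#'
#' Reads a CSV food-composition table with one row per food item: its energy
#' density (kJ/100 g), nutrient density (µg/100 g) and food-group assignment.
#' An optional companion groups file carries group names and a `fortifiable`
#' flag; without it the group set is inferred from the table and every group
#' is treated as fortifiable.
#'
#' @param path CSV file with header
#'   `food_code,name,group_id,energy_kj_per_100g,nutrient_ug_per_100g`.
#' @param groups_path optional CSV with header `group_id,name,fortifiable`.
#' @return A `food_table` data frame; the group table is attached as the
#'   `"groups"` attribute and retrieved with [food_groups()].
#' @export
read_food_table <- function(path, groups_path = NULL) {
  df <- read_csv_keys(path, c("food_code", "group_id"))
  groups <- if (!is.null(groups_path)) read_food_groups(groups_path) else NULL
  as_food_table(df, groups = groups)
}

#' Validate a data frame as a food-composition table
#'
#' @param df data frame with the [read_food_table()] columns.
#' @param groups optional group data frame (`group_id,name,fortifiable`).
#' @return A validated `food_table` object.
#' @export
as_food_table <- function(df, groups = NULL) {
  assert_cols(df, c("food_code", "name", "group_id",
                    "energy_kj_per_100g", "nutrient_ug_per_100g"),
              "food table")
  df$food_code <- as.character(df$food_code)
  df$group_id <- as.character(df$group_id)
  dup <- first_dups(df$food_code)
  if (length(dup) > 0L) {
    stop_fp("food table: duplicate food_code(s): %s",
            paste(dup, collapse = ", "))
  }
  df$energy_kj_per_100g <-
    assert_nonneg_finite(df$energy_kj_per_100g, "energy_kj_per_100g",
                         "food table")
  df$nutrient_ug_per_100g <-
    assert_nonneg_finite(df$nutrient_ug_per_100g, "nutrient_ug_per_100g",
                         "food table")
  if (is.null(groups)) {
    gid <- unique(df$group_id)
    groups <- data.frame(group_id = gid, name = gid, fortifiable = TRUE,
                         stringsAsFactors = FALSE)
  } else {
    unknown <- setdiff(df$group_id, groups$group_id)
    if (length(unknown) > 0L) {
      stop_fp("food table: group_id(s) not in the groups table: %s",
              paste(unknown, collapse = ", "))
    }
  }
  if (nrow(groups) < 1L) stop_fp("food table: at least one food group is required")
  attr(df, "groups") <- groups
  class(df) <- c("food_table", "data.frame")
  df
}

#' Read a food-group table
#'
#' @param path CSV with header `group_id,name,fortifiable`.
#' @return Data frame with character `group_id`, `name` and logical
#'   `fortifiable`.
#' @export
read_food_groups <- function(path) {
  g <- read_csv_keys(path, "group_id")
  assert_cols(g, c("group_id", "name", "fortifiable"), "groups table")
  g$group_id <- as.character(g$group_id)
  g$fortifiable <- as.logical(g$fortifiable)
  dup <- first_dups(g$group_id)
  if (length(dup) > 0L) {
    stop_fp("groups table: duplicate group_id(s): %s", paste(dup, collapse = ", "))
  }
  if (anyNA(g$fortifiable)) stop_fp("groups table: 'fortifiable' must be TRUE/FALSE")
  g
}

#' Food groups of a food table
#'
#' @param food_table a `food_table` object.
#' @return The group data frame (`group_id,name,fortifiable`).
#' @export
food_groups <- function(food_table) {
  g <- attr(food_table, "groups")
  if (is.null(g)) stop_fp("not a validated food table (no groups attribute)")
  g
}

#' Write a food table (and its groups) back to CSV
#'
#' Writes the same dialect [read_food_table()] reads, so a table round-trips
#' unchanged.
#'
#' @param food_table a `food_table` object.
#' @param path output CSV path for the items.
#' @param groups_path optional output CSV path for the groups.
#' @export
write_food_table <- function(food_table, path, groups_path = NULL) {
  cols <- c("food_code", "name", "group_id",
            "energy_kj_per_100g", "nutrient_ug_per_100g")
  write.csv(as.data.frame(food_table)[, cols], path, row.names = FALSE,
            quote = TRUE)
  if (!is.null(groups_path)) {
    write.csv(food_groups(food_table), groups_path, row.names = FALSE,
              quote = TRUE)
  }
  invisible(path)
}

#' Read a survey person roster
#'
#' @param path CSV with header `person_id,sex,age_years`.
#' @param age_range inclusive survey age range; ages outside it are an error.
#' @return Data frame `person_id,sex,age_years`.
#' @export
read_persons <- function(path, age_range = c(4, 75)) {
  p <- read_csv_keys(path, "person_id")
  as_persons(p, age_range = age_range)
}

#' @rdname read_persons
#' @param df data frame to validate in place of a file.
#' @export
as_persons <- function(df, age_range = c(4, 75)) {
  assert_cols(df, c("person_id", "sex", "age_years"), "persons")
  df$person_id <- as.character(df$person_id)
  dup <- first_dups(df$person_id)
  if (length(dup) > 0L) {
    stop_fp("persons: duplicate person_id(s): %s", paste(dup, collapse = ", "))
  }
  if (!all(df$sex %in% c("M", "F"))) {
    stop_fp("persons: sex must be 'M' or 'F'")
  }
  age <- as.numeric(df$age_years)
  if (any(!is.finite(age) | age < 0 | age != round(age))) {
    stop_fp("persons: age_years must be non-negative integers")
  }
  if (any(age < age_range[1] | age > age_range[2])) {
    stop_fp("persons: age_years outside the survey range [%d, %d]",
            age_range[1], age_range[2])
  }
  df$age_years <- as.integer(age)
  df
}

#' Read individual intake records
#'
#' One row per person and food item: mean grams per day over the recording
#' period. Referential integrity against the roster and food table is checked
#' when those are supplied.
#'
#' @param path CSV with header `person_id,food_code,grams_per_day`.
#' @param persons optional roster from [read_persons()].
#' @param food_table optional table from [read_food_table()].
#' @return Data frame `person_id,food_code,grams_per_day`.
#' @export
read_intake_records <- function(path, persons = NULL, food_table = NULL) {
  r <- read_csv_keys(path, c("person_id", "food_code"))
  as_intake_records(r, persons = persons, food_table = food_table)
}

#' @rdname read_intake_records
#' @param df data frame to validate in place of a file.
#' @export
as_intake_records <- function(df, persons = NULL, food_table = NULL) {
  assert_cols(df, c("person_id", "food_code", "grams_per_day"), "records")
  df$person_id <- as.character(df$person_id)
  df$food_code <- as.character(df$food_code)
  df$grams_per_day <-
    assert_nonneg_finite(df$grams_per_day, "grams_per_day", "records")
  if (!is.null(persons)) {
    unknown <- setdiff(df$person_id, persons$person_id)
    if (length(unknown) > 0L) {
      stop_fp("records: unknown person_id(s): %s",
              paste(utils::head(unknown, 10L), collapse = ", "))
    }
  }
  if (!is.null(food_table)) {
    unknown <- setdiff(df$food_code, food_table$food_code)
    if (length(unknown) > 0L) {
      stop_fp("records: unknown food_code(s): %s",
              paste(utils::head(unknown, 10L), collapse = ", "))
    }
  }
  df
}
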