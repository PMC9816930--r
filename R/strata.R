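#' Default sex/age stratification
#'
#' Twelve strata: the six age bands 4-6, 7-10, 11-14, 15-17, 18-50 and 51-75
#' years, crossed with sex. These are the model strata the optimizer places
#' one target-attainment constraint on; any other partition covering the
#' survey age range can be supplied instead.
#'
#' @return Data frame `stratum_id,sexes,age_min,age_max`, where `sexes` is
#'   `"M"`, `"F"` or `"MF"`.
#' @export
default_strata <- function() {
  bands <- data.frame(age_min = c(4L, 7L, 11L, 15L, 18L, 51L),
                      age_max = c(6L, 10L, 14L, 17L, 50L, 75L))
  out <- do.call(rbind, lapply(c("M", "F"), function(s) {
    data.frame(stratum_id = sprintf("%s_%d-%d", s, bands$age_min, bands$age_max),
               sexes = s, bands, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Validate a stratum partition
#'
#' Strata must be mutually exclusive and jointly cover every (sex, age)
#' combination of the survey range.
#'
#' @param strata data frame `stratum_id,sexes,age_min,age_max`.
#' @param age_range inclusive survey age range the partition must cover.
#' @return The validated strata data frame, invisibly usable downstream.
#' @export
validate_strata <- function(strata, age_range = c(4, 75)) {
  assert_cols(strata, c("stratum_id", "sexes", "age_min", "age_max"), "strata")
  strata$stratum_id <- as.character(strata$stratum_id)
  dup <- first_dups(strata$stratum_id)
  if (length(dup) > 0L) {
    stop_fp("strata: duplicate stratum_id(s): %s", paste(dup, collapse = ", "))
  }
  if (!all(strata$sexes %in% c("M", "F", "MF"))) {
    stop_fp("strata: sexes must be 'M', 'F' or 'MF'")
  }
  if (any(strata$age_min > strata$age_max)) {
    stop_fp("strata: age_min must be <= age_max")
  }
  for (sex in c("M", "F")) {
    for (age in seq(age_range[1], age_range[2])) {
      hit <- sum(grepl(sex, strata$sexes, fixed = TRUE) &
                   strata$age_min <= age & age <= strata$age_max)
      if (hit != 1L) {
        stop_fp("strata: sex %s age %d is covered by %d strata (need exactly 1)",
                sex, age, hit)
      }
    }
  }
  strata
}

#' Assign each person to a stratum
#'
#' @param persons roster from [read_persons()].
#' @param strata partition, e.g. [default_strata()].
#' @return Character vector of stratum ids, one per person.
#' @export
assign_strata <- function(persons, strata) {
  strata <- validate_strata(strata, age_range = range(persons$age_years))
  sid <- rep(NA_character_, nrow(persons))
  for (i in seq_len(nrow(strata))) {
    hit <- persons$sex %in% strsplit(strata$sexes[i], "")[[1]] &
      persons$age_years >= strata$age_min[i] &
      persons$age_years <= strata$age_max[i]
    sid[hit] <- strata$stratum_id[i]
  }
  sid
}
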