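#' Read a run configuration
#'
#' YAML keys: `inputs` (paths: `persons`, `records`, `food_table`, optional
#' `food_groups`, or `aggregates` for aggregate-only runs), `strata`
#' (`"default"` or a list of `{stratum_id, sexes, age_min, age_max}`),
#' `targets` (`default: {ri, ul}` with optional `age_based_ul` and
#' `by_stratum` overrides), `scenarios` (list of `{name, cap_ug_per_10mj,
#' allowed_groups, objective_mode}`), `output_dir`, `seed`. Relative paths
#' are used as given (i.e. resolved against the working directory).
#'
#' @param path YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- path
  if (is.null(cfg$scenarios) || length(cfg$scenarios) == 0L) {
    stop_fp("config: at least one scenario is required")
  }
  nm <- vapply(cfg$scenarios, function(s) as.character(s$name %||% ""), character(1))
  if (any(nm == "")) stop_fp("config: every scenario needs a name")
  dup <- first_dups(nm)
  if (length(dup) > 0L) stop_fp("config: duplicate scenario name(s): %s",
                                paste(dup, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "fortiplan_out"
  class(cfg) <- "run_config"
  cfg
}

config_strata <- function(cfg) {
  s <- cfg$strata
  if (is.null(s) || identical(s, "default")) return(default_strata())
  validate_strata(do.call(rbind, lapply(s, function(r) {
    data.frame(stratum_id = r$stratum_id, sexes = r$sexes,
               age_min = as.integer(r$age_min), age_max = as.integer(r$age_max),
               stringsAsFactors = FALSE)
  })))
}

config_targets <- function(cfg, strata) {
  t <- cfg$targets
  ri <- as.numeric(t$default$ri %||% 10)
  ul <- t$default$ul
  if (!is.null(strata$age_max) && isTRUE(t$age_based_ul %||% TRUE) && is.null(ul)) {
    ts <- default_targets(strata, ri_ug_per_day = ri)
  } else {
    ts <- target_spec(strata$stratum_id, ri, as.numeric(ul %||% 100))
  }
  for (sid in names(t$by_stratum %||% list())) {
    i <- match(sid, ts$stratum_id)
    if (is.na(i)) stop_fp("config targets: unknown stratum '%s'", sid)
    ov <- t$by_stratum[[sid]]
    if (!is.null(ov$ri)) ts$ri_ug_per_day[i] <- as.numeric(ov$ri)
    if (!is.null(ov$ul)) ts$ul_ug_per_day[i] <- as.numeric(ov$ul)
  }
  target_spec(ts$stratum_id, ts$ri_ug_per_day, ts$ul_ug_per_day)
}

config_scenarios <- function(cfg) {
  lapply(cfg$scenarios, function(s) {
    ag <- s$allowed_groups %||% "all_fortifiable"
    scenario(name = s$name, cap_ug_per_10mj = s$cap_ug_per_10mj,
             allowed_groups = unlist(ag),
             objective_mode = s$objective_mode %||% "sum_overshoot")
  })
}

read_config_inputs <- function(cfg) {
  inp <- cfg$inputs %||% list()
  if (!is.null(inp$aggregates)) {
    return(list(aggregates = read_aggregates_csv(inp$aggregates),
                survey = NULL))
  }
  need <- c("persons", "records", "food_table")
  miss <- setdiff(need, names(inp))
  if (length(miss) > 0L) {
    stop_fp("config inputs: need %s (or an 'aggregates' CSV)",
            paste(miss, collapse = ", "))
  }
  ft <- read_food_table(inp$food_table, groups_path = inp$food_groups)
  persons <- read_persons(inp$persons)
  records <- read_intake_records(inp$records, persons = persons,
                                 food_table = ft)
  list(aggregates = NULL,
       survey = list(persons = persons, records = records, food_table = ft))
}

write_manifest <- function(cfg, dir, artifacts) {
  man <- list(
    package = "fortiplan",
    version = as.character(utils::packageVersion("fortiplan")),
    r_version = R.version.string,
    seed = cfg$seed,
    config = cfg$config_path,
    config_md5 = unname(tools::md5sum(cfg$config_path)),
    artifacts = artifacts
  )
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full fortification pipeline for every configured scenario
#'
#' From individual survey data: aggregate to stratum medians, solve each
#' scenario's LP, convert levels to µg/100 g, fortify the food table,
#' evaluate individual intakes, and write a comparison table plus a run
#' manifest. From an aggregates CSV (no individual records): solve and write
#' the schemes only.
#'
#' @param cfg a `run_config` from [read_run_config()].
#' @param output_dir overrides the configured output directory.
#' @return Invisibly, a list with the schemes, evaluation summaries and the
#'   comparison table (where applicable).
#' @export
run_pipeline <- function(cfg, output_dir = NULL) {
  dir <- output_dir %||% cfg$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- read_config_inputs(cfg)
  scens <- config_scenarios(cfg)
  artifacts <- character(0)

  if (is.null(inputs$aggregates)) {
    sv <- inputs$survey
    strata <- config_strata(cfg)
    totals <- compute_person_group_totals(sv$records, sv$food_table, sv$persons)
    agg <- aggregate_strata(totals, sv$persons, strata,
                            groups = food_groups(sv$food_table))
    density <- group_energy_density(sv$records, sv$food_table)
    p <- file.path(dir, "aggregates.csv")
    write_aggregates_csv(agg, p); artifacts <- c(artifacts, p)
    p <- file.path(dir, "group_energy_density.csv")
    write.csv(density, p, row.names = FALSE); artifacts <- c(artifacts, p)
  } else {
    agg <- inputs$aggregates
    strata <- NULL
    density <- NULL
  }
  targets <- config_targets(cfg, strata %||% agg$strata)

  schemes <- list(); summaries <- list()
  for (sc in scens) {
    sch <- solve_scheme(build_lp(agg, sc, targets))
    if (!sch$feasible) {
      message(sprintf("scenario '%s': infeasible at cap %g ug/10 MJ; skipped",
                      sc$name, sc$cap_ug_per_10mj))
      next
    }
    if (!is.null(density)) sch <- convert_scheme(sch, density)
    schemes[[sc$name]] <- sch
    p <- file.path(dir, sprintf("scheme_%s.csv", sc$name))
    write_scheme_csv(sch, p); artifacts <- c(artifacts, p)
    p <- file.path(dir, sprintf("scheme_%s.json", sc$name))
    write_scheme_json(sch, p); artifacts <- c(artifacts, p)
    if (!is.null(inputs$survey)) {
      sv <- inputs$survey
      fort <- fortify_food_table(sv$food_table, sch)
      p <- file.path(dir, sprintf("fortified_table_%s.csv", sc$name))
      write_food_table(fort, p); artifacts <- c(artifacts, p)
      summ <- evaluate_scenario(sv$records, sv$persons, fort, strata, targets,
                                scenario_name = sc$name)
      summaries[[sc$name]] <- summ
      p <- file.path(dir, sprintf("evaluation_%s.csv", sc$name))
      write.csv(as.data.frame(summ), p, row.names = FALSE)
      artifacts <- c(artifacts, p)
    }
  }
  comparison <- NULL
  if (length(summaries) > 0L) {
    background <- evaluate_scenario(inputs$survey$records, inputs$survey$persons,
                                    inputs$survey$food_table, strata, targets,
                                    scenario_name = "background")
    comparison <- scenario_comparison_table(background, summaries)
    p <- file.path(dir, "comparison.csv")
    write.csv(comparison$table, p, row.names = FALSE); artifacts <- c(artifacts, p)
    p <- file.path(dir, "boxplot_stats.csv")
    write.csv(comparison$boxplot, p, row.names = FALSE); artifacts <- c(artifacts, p)
  }
  write_manifest(cfg, dir, artifacts)
  invisible(list(aggregates = agg, schemes = schemes, summaries = summaries,
                 comparison = comparison))
}
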