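#' Per-stratum intake targets
#'
#' @param stratum_id character vector of stratum ids.
#' @param ri_ug_per_day recommended intake per stratum (µg/day); recycled.
#' @param ul_ug_per_day tolerable upper intake level per stratum (µg/day);
#'   recycled.
#' @return A `target_spec` data frame.
#' @export
target_spec <- function(stratum_id, ri_ug_per_day = 10, ul_ug_per_day = 100) {
  df <- data.frame(stratum_id = as.character(stratum_id),
                   ri_ug_per_day = as.numeric(ri_ug_per_day),
                   ul_ug_per_day = as.numeric(ul_ug_per_day),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$ri_ug_per_day)) || any(!is.finite(df$ul_ug_per_day)) ||
      any(df$ri_ug_per_day <= 0) || any(df$ri_ug_per_day >= df$ul_ug_per_day)) {
    stop_fp("targets: need 0 < RI < UL for every stratum")
  }
  class(df) <- c("target_spec", "data.frame")
  df
}

#' Default targets for a stratum partition
#'
#' RI defaults to 10 µg/day for every stratum. The UL follows the standard
#' vitamin-D age rule: 50 µg/day for strata entirely within ages 4-10,
#' 100 µg/day otherwise.
#'
#' @param strata stratum partition with `age_max` column.
#' @param ri_ug_per_day recommended intake (µg/day).
#' @return A `target_spec` data frame.
#' @export
default_targets <- function(strata, ri_ug_per_day = 10) {
  target_spec(strata$stratum_id, ri_ug_per_day = ri_ug_per_day,
              ul_ug_per_day = ifelse(strata$age_max <= 10, 50, 100))
}

#' Define a fortification scenario
#'
#' @param name scenario name.
#' @param cap_ug_per_10mj common upper bound on every group's fortification
#'   level (µg per 10 MJ of the group's energy). Because daily energy intake
#'   is roughly 10 MJ, the cap bounds the added intake of a hypothetical
#'   consumer eating only fortified foods.
#' @param allowed_groups character vector of fortifiable group ids, or
#'   `"all_fortifiable"` to allow every fortifiable group.
#' @param objective_mode `"sum_overshoot"` minimizes the summed overshoot of
#'   modelled stratum intakes above their RI; `"max_overshoot"` minimizes the
#'   largest single overshoot.
#' @return A `scenario` object.
#' @export
scenario <- function(name, cap_ug_per_10mj, allowed_groups,
                     objective_mode = c("sum_overshoot", "max_overshoot")) {
  objective_mode <- match.arg(objective_mode)
  cap_ug_per_10mj <- as.numeric(cap_ug_per_10mj)
  if (!is.finite(cap_ug_per_10mj) || cap_ug_per_10mj <= 0) {
    stop_fp("scenario '%s': cap must be > 0", name)
  }
  if (length(allowed_groups) < 1L) {
    stop_fp("scenario '%s': allowed_groups must be non-empty", name)
  }
  structure(list(name = as.character(name),
                 cap_ug_per_10mj = cap_ug_per_10mj,
                 allowed_groups = as.character(allowed_groups),
                 objective_mode = objective_mode),
            class = "scenario")
}

resolve_allowed_groups <- function(allowed, groups) {
  if (length(allowed) == 1L && allowed == "all_fortifiable") {
    allowed <- groups$group_id[groups$fortifiable]
  }
  unknown <- setdiff(allowed, groups$group_id)
  if (length(unknown) > 0L) {
    stop_fp("allowed_groups not in the aggregates: %s",
            paste(unknown, collapse = ", "))
  }
  not_fort <- allowed[!groups$fortifiable[match(allowed, groups$group_id)]]
  if (length(not_fort) > 0L) {
    stop_fp("allowed_groups not flagged fortifiable: %s",
            paste(not_fort, collapse = ", "))
  }
  allowed
}

#' Build the fortification linear program
#'
#' Decision variables are the fortification levels `f_g` (µg/10 MJ) of the
#' allowed groups; disallowed groups are fixed at zero. For stratum `s` with
#' median group energies `E_sg` (MJ/day) and background median `B_s`
#' (µg/day), the modelled intake is `T_s = B_s + sum_g f_g * E_sg / 10`, so
#' the contribution coefficient of `f_g` is `E_sg / 10` µg/day per µg/10 MJ.
#' Target attainment `T_s >= RI_s` is a hard constraint; auxiliary overshoot
#' variables `d_s >= T_s - RI_s` carry the objective.
#'
#' @param aggregates a `stratum_aggregates` object.
#' @param scenario a [scenario()].
#' @param targets a [target_spec()] covering every stratum in `aggregates`.
#' @return An `lp_model` object.
#' @export
build_lp <- function(aggregates, scenario, targets) {
  sids <- aggregates$strata$stratum_id
  miss <- setdiff(sids, targets$stratum_id)
  if (length(miss) > 0L) {
    stop_fp("targets missing for stratum(s): %s", paste(miss, collapse = ", "))
  }
  ti <- match(sids, targets$stratum_id)
  allowed <- resolve_allowed_groups(scenario$allowed_groups, aggregates$groups)
  E <- aggregates$median_group_energy_mj[, allowed, drop = FALSE]
  zero <- colnames(E)[colSums(E) == 0]
  if (length(zero) > 0L) {
    warning(sprintf("allowed group(s) with zero median energy in every stratum (no effect): %s",
                    paste(zero, collapse = ", ")), call. = FALSE)
  }
  structure(list(
    E = E,
    B = aggregates$strata$median_background_nutrient_ug,
    RI = targets$ri_ug_per_day[ti],
    UL = targets$ul_ug_per_day[ti],
    cap = scenario$cap_ug_per_10mj,
    objective_mode = scenario$objective_mode,
    group_ids = allowed,
    all_group_ids = aggregates$groups$group_id,
    stratum_ids = sids,
    scenario_name = scenario$name
  ), class = "lp_model")
}

#' Solve a fortification LP
#'
#' Minimizes the configured overshoot objective subject to per-stratum target
#' attainment and `0 <= f_g <= cap`, with a deterministic two-phase simplex
#' (variable order is the model's fixed group order, so repeated solves of
#' the same model give identical schemes). Infeasible models return a scheme
#' with `feasible = FALSE` and no levels.
#'
#' @param model an `lp_model` from [build_lp()].
#' @param tol attainment tolerance (µg/day) used when flagging constraints.
#' @return A `fortification_scheme` object.
#' @export
solve_scheme <- function(model, tol = 1e-6) {
  E10 <- model$E / 10
  ng <- ncol(E10)
  ns <- nrow(E10)
  rhs_att <- model$RI - model$B
  if (model$objective_mode == "sum_overshoot") {
    naux <- ns
    a <- c(rep(0, ng), rep(1, ns))
    A2 <- rbind(cbind(E10, matrix(0, ns, ns)),
                cbind(-E10, diag(ns)))
  } else {
    naux <- 1L
    a <- c(rep(0, ng), 1)
    A2 <- rbind(cbind(E10, matrix(0, ns, 1L)),
                cbind(-E10, matrix(1, ns, 1L)))
  }
  b2 <- c(rhs_att, -rhs_att)
  A1 <- cbind(diag(ng), matrix(0, ng, naux))
  b1 <- rep(model$cap, ng)
  sol <- boot::simplex(a = a, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       maxi = FALSE, n.iter = max(200L, 20L * (ng + naux)),
                       eps = 1e-10)
  if (sol$solved == 0L) {
    stop_fp("solve_scheme: simplex did not converge (status 0) for scenario '%s'",
            model$scenario_name)
  }
  feasible <- sol$solved == 1L
  f <- if (feasible) pmin(pmax(as.numeric(sol$soln[seq_len(ng)]), 0), model$cap)
       else rep(NA_real_, ng)

  levels <- data.frame(group_id = model$all_group_ids,
                       allowed = model$all_group_ids %in% model$group_ids,
                       level_ug_per_10mj = 0,
                       stringsAsFactors = FALSE)
  modelled <- NULL
  objective <- NA_real_
  rounded_feasible <- NA
  if (feasible) {
    levels$level_ug_per_10mj[match(model$group_ids, levels$group_id)] <- f
    Tvec <- model$B + as.numeric(E10 %*% f)
    over <- Tvec - model$RI
    objective <- if (model$objective_mode == "sum_overshoot") sum(over) else max(over)
    fr <- round(f)
    Tr <- model$B + as.numeric(E10 %*% fr)
    rounded_feasible <- all(Tr >= model$RI - tol)
    modelled <- data.frame(stratum_id = model$stratum_ids,
                           background_ug = model$B,
                           modelled_intake_ug = Tvec,
                           ri_ug_per_day = model$RI,
                           attained = Tvec >= model$RI - tol,
                           stringsAsFactors = FALSE)
  }
  levels$level_ug_per_10mj_rounded <- round(levels$level_ug_per_10mj)
  structure(list(scenario = model$scenario_name,
                 feasible = feasible,
                 cap_ug_per_10mj = model$cap,
                 objective_mode = model$objective_mode,
                 objective_value = objective,
                 levels = levels,
                 modelled_intake = modelled,
                 rounded_feasible = rounded_feasible),
            class = "fortification_scheme")
}

#' @export
print.fortification_scheme <- function(x, ...) {
  cat(sprintf("fortification scheme '%s' (cap %.4g ug/10 MJ, %s)\n",
              x$scenario, x$cap_ug_per_10mj, x$objective_mode))
  if (!x$feasible) {
    cat("  INFEASIBLE: targets cannot be reached under this cap\n")
    return(invisible(x))
  }
  cat(sprintf("  objective (overshoot): %.4f ug/day\n", x$objective_value))
  nz <- x$levels[x$levels$level_ug_per_10mj > 1e-8, ]
  cat(sprintf("  %d of %d allowed groups fortified:\n",
              nrow(nz), sum(x$levels$allowed)))
  for (i in seq_len(nrow(nz))) {
    cat(sprintf("    %-12s %8.3f ug/10 MJ\n", nz$group_id[i],
                nz$level_ug_per_10mj[i]))
  }
  invisible(x)
}

#' Find the lowest feasible fortification cap
#'
#' Sweeps the common cap upward from `start` in steps of `step` and returns
#' the first value at which the target-attainment LP is feasible. Feasibility
#' is monotone in the cap, so an optional bisection refines over the same
#' grid with fewer solves.
#'
#' @param aggregates a `stratum_aggregates` object.
#' @param allowed_groups group ids (or `"all_fortifiable"`).
#' @param targets a [target_spec()].
#' @param start,step,cap_max sweep grid (µg/10 MJ).
#' @param objective_mode passed to [scenario()].
#' @param bisection use bisection over the grid instead of a linear sweep.
#' @return List with `cap` (the minimal feasible cap) and `scheme` (its
#'   solved scheme).
#' @export
find_min_cap <- function(aggregates, allowed_groups, targets,
                         start = 10, step = 1, cap_max = 100,
                         objective_mode = "sum_overshoot",
                         bisection = FALSE) {
  if (start < 1) stop_fp("find_min_cap: start must be >= 1")
  caps <- seq(start, cap_max, by = step)
  solve_at <- function(cap) {
    sc <- scenario(name = sprintf("cap_%g", cap), cap_ug_per_10mj = cap,
                   allowed_groups = allowed_groups,
                   objective_mode = objective_mode)
    solve_scheme(build_lp(aggregates, sc, targets))
  }
  fail <- function() {
    # max attainable intake at cap_max: B + cap_max * sum_g E_sg / 10
    sc <- scenario("probe", cap_max, allowed_groups)
    m <- suppressWarnings(build_lp(aggregates, sc, targets))
    deficit <- m$RI - (m$B + cap_max * rowSums(m$E) / 10)
    worst <- which.max(deficit)
    stop_fp("find_min_cap: infeasible at cap_max = %g; most-violated stratum '%s' (deficit %.3f ug/day)",
            cap_max, m$stratum_ids[worst], max(deficit))
  }
  if (bisection) {
    lo <- 1L; hi <- length(caps)
    if (!solve_at(caps[hi])$feasible) fail()
    s_lo <- solve_at(caps[lo])
    if (s_lo$feasible) return(list(cap = caps[lo], scheme = s_lo))
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (solve_at(caps[mid])$feasible) hi <- mid else lo <- mid
    }
    return(list(cap = caps[hi], scheme = solve_at(caps[hi])))
  }
  for (cap in caps) {
    sch <- solve_at(cap)
    if (sch$feasible) return(list(cap = cap, scheme = sch))
  }
  fail()
}

#' Exhaustive grid-search oracle for small fortification problems
#'
#' Enumerates every combination of levels on a regular grid
#' `{0, grid_step, ..., cap}` per allowed group and returns the best feasible
#' grid point under the scenario's objective. Intended as an independent
#' cross-check of [solve_scheme()] on instances with at most 3 groups.
#'
#' @inheritParams build_lp
#' @param grid_step grid resolution (µg/10 MJ).
#' @param max_points refuse instances whose grid exceeds this many points.
#' @return List with `feasible`, `levels` (named vector at the best grid
#'   point) and `objective_value`.
#' @export
brute_force_scheme_oracle <- function(aggregates, scenario, targets,
                                      grid_step = 0.1, max_points = 2e7) {
  model <- suppressWarnings(build_lp(aggregates, scenario, targets))
  ng <- length(model$group_ids)
  if (ng > 3L) stop_fp("grid oracle: refusing instance with %d groups (max 3)", ng)
  axis <- seq(0, model$cap, by = grid_step)
  if (length(axis)^ng > max_points) {
    stop_fp("grid oracle: grid of %g points too large", length(axis)^ng)
  }
  grid <- as.matrix(expand.grid(rep(list(axis), ng), KEEP.OUT.ATTRS = FALSE))
  contrib <- grid %*% t(model$E / 10)           # points x strata
  over <- sweep(contrib, 2L, model$RI - model$B) # overshoot per stratum
  feas <- rowSums(over < -1e-9) == 0L
  if (!any(feas)) {
    return(list(feasible = FALSE, levels = NULL, objective_value = NA_real_))
  }
  obj <- if (model$objective_mode == "sum_overshoot") {
    rowSums(over)
  } else {
    apply(over, 1L, max)
  }
  obj[!feas] <- Inf
  best <- which.min(obj)  # first minimum: deterministic tie-break
  list(feasible = TRUE,
       levels = setNames(as.numeric(grid[best, ]), model$group_ids),
       objective_value = obj[best])
}

#' Write / read a fortification scheme as CSV
#'
#' Columns: `group_id, allowed, level_ug_per_10mj, level_ug_per_10mj_rounded`
#' plus, after [convert_scheme()], `level_ug_per_100g` and its 3-decimal
#' report form.
#'
#' @param scheme a `fortification_scheme`.
#' @param path CSV path.
#' @export
write_scheme_csv <- function(scheme, path) {
  if (!scheme$feasible) stop_fp("cannot write an infeasible scheme")
  write.csv(scheme$levels, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_scheme_csv
#' @param cap_ug_per_10mj,scenario_name metadata to attach on read.
#' @export
read_scheme_csv <- function(path, cap_ug_per_10mj = NA_real_,
                            scenario_name = "scheme") {
  lv <- read_csv_keys(path, "group_id")
  assert_cols(lv, c("group_id", "level_ug_per_10mj"), "scheme CSV")
  lv$group_id <- as.character(lv$group_id)
  if (!"allowed" %in% names(lv)) lv$allowed <- lv$level_ug_per_10mj > 0
  if (!"level_ug_per_10mj_rounded" %in% names(lv)) {
    lv$level_ug_per_10mj_rounded <- round(lv$level_ug_per_10mj)
  }
  structure(list(scenario = scenario_name, feasible = TRUE,
                 cap_ug_per_10mj = cap_ug_per_10mj,
                 objective_mode = NA_character_, objective_value = NA_real_,
                 levels = lv, modelled_intake = NULL, rounded_feasible = NA),
            class = "fortification_scheme")
}

#' Scheme metadata as JSON
#'
#' @param scheme a `fortification_scheme`.
#' @param path JSON path.
#' @export
write_scheme_json <- function(scheme, path) {
  jsonlite::write_json(list(
    scenario = scheme$scenario,
    feasible = scheme$feasible,
    cap_ug_per_10mj = scheme$cap_ug_per_10mj,
    objective_mode = scheme$objective_mode,
    objective_value = scheme$objective_value,
    rounded_feasible = scheme$rounded_feasible,
    levels = scheme$levels,
    modelled_intake = scheme$modelled_intake
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
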