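one_group_agg <- function(E = 4, B = 2) {
  stratum_aggregates(stratum_id = "all",
                     median_group_energy_mj = matrix(E, 1, 1,
                                                     dimnames = list("all", "g1")),
                     median_background_nutrient_ug = B)
}

test_that("the LP encodes one attainment row per stratum with E/10 coefficients", {
  m <- build_lp(one_group_agg(E = 4), scenario("x", 25, "g1"),
                target_spec("all", 10, 100))
  expect_equal(unname(m$E / 10), matrix(0.4, 1, 1))
  expect_equal(m$B, 2)
  expect_equal(m$RI, 10)

  # groups outside the allow-list get no decision variable
  inst <- random_lp_instance(3, n_strata = 6, n_groups = 5)
  sc <- scenario("shape", inst$cap, c("g1", "g3"))
  m2 <- build_lp(inst$agg, sc, inst$targets)
  expect_equal(dim(m2$E), c(6L, 2L))
  expect_equal(m2$group_ids, c("g1", "g3"))
  m3 <- build_lp(inst$agg, scenario("all5", inst$cap,
                                    paste0("g", 1:5)), inst$targets)
  expect_equal(dim(m3$E), c(6L, 5L))

  # an allowed group with zero energy in every stratum has no effect
  agg0 <- stratum_aggregates(
    stratum_id = "all",
    median_group_energy_mj = matrix(c(4, 0), 1, 2,
                                    dimnames = list("all", c("g1", "g2"))),
    median_background_nutrient_ug = 2)
  expect_warning(build_lp(agg0, scenario("z", 25, c("g1", "g2")),
                          target_spec("all", 10, 100)),
                 "zero median energy")

  # non-fortifiable groups cannot be allowed
  aggf <- one_group_agg()
  aggf$groups$fortifiable <- FALSE
  expect_error(build_lp(aggf, scenario("nf", 25, "g1"),
                        target_spec("all", 10, 100)), "fortifiable")
})

test_that("the solver recovers the closed-form level and detects infeasibility", {
  # B = 2, RI = 10, E = 4 MJ: f* = 10 * (10 - 2) / 4 = 20 exactly
  targets <- target_spec("all", 10, 100)
  sch <- solve_scheme(build_lp(one_group_agg(), scenario("cf", 25, "g1"), targets))
  expect_true(sch$feasible)
  expect_equal(sch$levels$level_ug_per_10mj[sch$levels$group_id == "g1"], 20,
               tolerance = 1e-9)
  expect_equal(sch$objective_value, 0, tolerance = 1e-9)
  expect_equal(sch$modelled_intake$modelled_intake_ug, 10, tolerance = 1e-9)

  # cap 15: max attainable 2 + 15 * 0.4 = 8 < 10
  sch2 <- solve_scheme(build_lp(one_group_agg(), scenario("inf", 15, "g1"), targets))
  expect_false(sch2$feasible)
  expect_true(all(sch2$levels$level_ug_per_10mj == 0))
})

test_that("feasible schemes attain every stratum target within tolerance and respect the cap", {
  for (seed in 1:8) {
    inst <- random_lp_instance(seed, n_strata = 3, n_groups = 3)
    for (mode in c("sum_overshoot", "max_overshoot")) {
      sch <- solve_scheme(build_lp(inst$agg,
                                   scenario("p", inst$cap, paste0("g", 1:3),
                                            objective_mode = mode),
                                   inst$targets))
      expect_true(sch$feasible)
      f <- sch$levels$level_ug_per_10mj
      expect_true(all(f >= -1e-12 & f <= inst$cap + 1e-9))
      expect_true(all(sch$modelled_intake$modelled_intake_ug >=
                        inst$targets$ri_ug_per_day - 1e-6))
    }
  }
})

test_that("LP optimum matches the exhaustive grid oracle within grid resolution", {
  # closed-form case: exact match on a grid that contains 20
  targets <- target_spec("all", 10, 100)
  sc <- scenario("cf", 25, "g1")
  lp <- solve_scheme(build_lp(one_group_agg(), sc, targets))
  gr <- brute_force_scheme_oracle(one_group_agg(), sc, targets, grid_step = 0.5)
  expect_equal(unname(gr$levels["g1"]), 20)
  expect_equal(gr$objective_value, lp$objective_value, tolerance = 1e-9)

  # infeasible instance: both routes agree
  sc_inf <- scenario("inf", 15, "g1")
  expect_false(solve_scheme(build_lp(one_group_agg(), sc_inf, targets))$feasible)
  expect_false(brute_force_scheme_oracle(one_group_agg(), sc_inf, targets,
                                         grid_step = 0.5)$feasible)

  # refuses combinatorial instances
  inst5 <- random_lp_instance(11, n_strata = 2, n_groups = 5)
  expect_error(brute_force_scheme_oracle(inst5$agg,
                                         scenario("big", inst5$cap, paste0("g", 1:5)),
                                         inst5$targets, grid_step = 1),
               "3")

  # random 2-group instances: grid best within a Lipschitz step of the LP
  set.seed(1)
  for (seed in sample.int(1e6, 20)) {
    inst <- random_lp_instance(seed)
    sc <- scenario("r", inst$cap, c("g1", "g2"))
    lp <- solve_scheme(build_lp(inst$agg, sc, inst$targets))
    step <- 0.25
    gr <- brute_force_scheme_oracle(inst$agg, sc, inst$targets, grid_step = step)
    expect_true(lp$feasible && gr$feasible)
    # grid can only be worse, and by at most one step times the objective slope
    lips <- step * sum(inst$agg$median_group_energy_mj) / 10
    expect_gte(gr$objective_value, lp$objective_value - 1e-9)
    expect_lte(gr$objective_value - lp$objective_value, lips + 1e-9)
  }
})

test_that("feasibility is monotone in the cap and min-cap finds the threshold", {
  # threshold of the closed form: f* = 20 -> min integer cap 20
  targets <- target_spec("all", 10, 100)
  res <- find_min_cap(one_group_agg(), "g1", targets, start = 10, step = 1)
  expect_equal(res$cap, 20)
  expect_true(res$scheme$feasible)

  # already feasible at start
  res2 <- find_min_cap(one_group_agg(E = 40), "g1", targets, start = 10)
  expect_equal(res2$cap, 10)

  # bisection agrees with the linear sweep on the same grid
  res3 <- find_min_cap(one_group_agg(), "g1", targets, bisection = TRUE)
  expect_equal(res3$cap, 20)

  # infeasible everywhere: error names the most-violated stratum
  expect_error(find_min_cap(one_group_agg(E = 0.1), "g1", targets,
                            cap_max = 40), "all")

  # monotone: once feasible, stays feasible over a cap sweep
  inst <- random_lp_instance(42, n_strata = 3, n_groups = 2, margin = 1)
  feas <- vapply(1:40, function(cap) {
    solve_scheme(build_lp(inst$agg, scenario("m", cap, c("g1", "g2")),
                          inst$targets))$feasible
  }, logical(1))
  expect_true(all(diff(feas) >= 0))
  expect_true(any(feas) && !feas[1])
})

test_that("solver output is deterministic and integer reporting is re-checked", {
  inst <- random_lp_instance(5, n_strata = 4, n_groups = 3)
  sc <- scenario("det", inst$cap, paste0("g", 1:3))
  s1 <- solve_scheme(build_lp(inst$agg, sc, inst$targets))
  s2 <- solve_scheme(build_lp(inst$agg, sc, inst$targets))
  expect_identical(s1$levels, s2$levels)
  expect_identical(s1$objective_value, s2$objective_value)
  expect_equal(s1$levels$level_ug_per_10mj_rounded,
               round(s1$levels$level_ug_per_10mj))
  expect_type(s1$rounded_feasible, "logical")
})
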