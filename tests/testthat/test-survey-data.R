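test_that("food table CSV parses, validates and reports bad rows", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("food_code,name,group_id,energy_kj_per_100g,nutrient_ug_per_100g",
               '"0001","milk","milk",200,0.5',
               '"0002","bread","cereals",950,0'), p)
  ft <- read_food_table(p)
  expect_s3_class(ft, "food_table")
  expect_equal(nrow(ft), 2L)
  expect_setequal(food_groups(ft)$group_id, c("milk", "cereals"))

  writeLines(c("food_code,name,group_id,energy_kj_per_100g,nutrient_ug_per_100g",
               '"0001","milk","milk",200,0.5',
               '"0001","milk2","milk",210,0.4'), p)
  expect_error(read_food_table(p), "0001")

  writeLines(c("food_code,name,group_id,energy_kj_per_100g,nutrient_ug_per_100g",
               '"0001","milk","milk",200,0.5',
               '"0002","bread","cereals",-10,0'), p)
  expect_error(read_food_table(p), "row.*2")
})

test_that("intake records validate values and referential integrity", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,food_code,grams_per_day",
               '"A","0001",250', '"A","0002",100', '"A","0003",20'), p)
  r <- read_intake_records(p, persons = tiny_persons(),
                           food_table = tiny_food_table())
  expect_equal(nrow(r), 3L)

  writeLines(c("person_id,food_code,grams_per_day", '"A","0001",-1'), p)
  expect_error(read_intake_records(p), "grams_per_day")

  writeLines(c("person_id,food_code,grams_per_day", '"ZZ","0001",10'), p)
  expect_error(read_intake_records(p, persons = tiny_persons()), "ZZ")
  writeLines(c("person_id,food_code,grams_per_day", '"A","9999",10'), p)
  expect_error(read_intake_records(p, food_table = tiny_food_table()), "9999")
})

test_that("person roster validation enforces sex, ages and uniqueness", {
  expect_silent(as_persons(tiny_persons()))
  expect_error(as_persons(rbind(tiny_persons(), tiny_persons()[1, ])), "duplicate")
  bad <- tiny_persons(); bad$sex[1] <- "X"
  expect_error(as_persons(bad), "sex")
  bad <- tiny_persons(); bad$age_years[1] <- 99L
  expect_error(as_persons(bad), "range")
})

test_that("person-group totals follow the density arithmetic and give explicit zeros", {
  # 250 g/day at 200 kJ/100 g and 0.5 ug/100 g -> 0.5 MJ/day and 1.25 ug/day
  tot <- compute_person_group_totals(tiny_records(), tiny_food_table(),
                                     tiny_persons())
  expect_equal(tot$energy_mj["A", "milk"], 250 * 200 / 1e5)
  expect_equal(tot$nutrient_ug["A", "milk"], 250 * 0.5 / 100)
  expect_equal(tot$grams["A", "cereals"], 100)
  # person C has no records: all-zero row, still present
  expect_true(all(tot$grams["C", ] == 0))
  expect_equal(tot$totals$energy_mj_per_day[3], 0)
  # zero-consumer groups are explicit zeros
  expect_equal(tot$nutrient_ug["B", "fish"], 0)
})

test_that("group totals conserve person totals and ignore record order", {
  tot <- shared_totals()
  expect_equal(rowSums(tot$energy_mj),
               setNames(tot$totals$energy_mj_per_day, tot$person_ids),
               tolerance = 1e-9)
  expect_equal(rowSums(tot$grams),
               setNames(tot$totals$grams_per_day, tot$person_ids),
               tolerance = 1e-9)
  expect_equal(rowSums(tot$nutrient_ug),
               setNames(tot$totals$nutrient_ug_per_day, tot$person_ids),
               tolerance = 1e-9)

  sv <- shared_survey()
  perm <- sample(nrow(sv$records))
  tot2 <- compute_person_group_totals(sv$records[perm, ], sv$food_table,
                                      sv$persons)
  expect_equal(tot2$grams, tot$grams)
  expect_equal(tot2$totals, tot$totals)
})

test_that("stratum medians are order statistics over all persons including non-consumers", {
  # stratum grams {0, 100, 200} -> median 100
  persons <- data.frame(person_id = c("A", "B", "C"), sex = "M",
                        age_years = 30L, stringsAsFactors = FALSE)
  records <- data.frame(person_id = c("B", "C"), food_code = "0001",
                        grams_per_day = c(100, 200), stringsAsFactors = FALSE)
  strata <- data.frame(stratum_id = "all", sexes = "MF",
                       age_min = 4L, age_max = 75L, stringsAsFactors = FALSE)
  tot <- compute_person_group_totals(records, tiny_food_table(), persons)
  agg <- aggregate_strata(tot, persons, strata)
  expect_equal(agg$median_group_grams["all", "milk"], 100)

  # stratum of one person -> that person's values
  one <- persons[1, ]
  r1 <- data.frame(person_id = "A", food_code = "0002", grams_per_day = 50,
                   stringsAsFactors = FALSE)
  agg1 <- aggregate_strata(compute_person_group_totals(r1, tiny_food_table(), one),
                           one, strata)
  expect_equal(agg1$median_group_grams["all", "cereals"], 50)
  expect_equal(agg1$strata$median_background_nutrient_ug, 0)
})

test_that("stratum aggregation matches an independent sort-based recomputation", {
  sv <- shared_survey()
  tot <- shared_totals()
  strata <- default_strata()
  agg <- aggregate_strata(tot, sv$persons, strata,
                          groups = food_groups(sv$food_table))
  sid <- assign_strata(sv$persons, strata)
  for (s in sample(strata$stratum_id, 4)) {
    rows <- which(sid == s)
    for (g in sample(colnames(tot$energy_mj), 5)) {
      v <- sort(unname(tot$energy_mj[rows, g]))
      n <- length(v)
      mid <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
      expect_equal(agg$median_group_energy_mj[s, g], mid)
    }
    expect_equal(agg$strata$median_background_nutrient_ug[match(s, agg$strata$stratum_id)],
                 manual_percentile(tot$totals$nutrient_ug_per_day[rows], 50))
  }
  # empty stratum is a hard error
  ghost <- rbind(strata,
                 data.frame(stratum_id = "ghost", sexes = "MF",
                            age_min = 76L, age_max = 80L))
  expect_error(aggregate_strata(tot, sv$persons, ghost), "ghost")
})

test_that("food table and aggregates round-trip through their CSV dialects", {
  sv <- shared_survey()
  dir <- withr::local_tempdir()
  paths <- write_survey(sv, dir)
  ft2 <- read_food_table(paths["food_table"], groups_path = paths["food_groups"])
  expect_equal(as.data.frame(ft2), as.data.frame(sv$food_table))
  expect_equal(food_groups(ft2), food_groups(sv$food_table))
  # write -> read -> write is byte-stable
  p2 <- file.path(dir, "ft2.csv")
  write_food_table(ft2, p2)
  expect_identical(readLines(p2), readLines(paths[["food_table"]]))

  agg <- aggregate_strata(shared_totals(), sv$persons, default_strata(),
                          groups = food_groups(sv$food_table))
  pa <- file.path(dir, "agg.csv")
  write_aggregates_csv(agg, pa)
  agg2 <- read_aggregates_csv(pa)
  expect_equal(agg2$median_group_energy_mj, agg$median_group_energy_mj)
  expect_equal(agg2$strata, agg$strata)
  expect_equal(agg2$groups$fortifiable, agg$groups$fortifiable)
})
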