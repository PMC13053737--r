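test_that("a toy two-file cohort reads, validates and round-trips", {
  dir <- withr::local_tempdir()
  writeLines(c("person_id,pair_id,zygosity,sex,birth_year,study_label",
               "A1,P1,MZ,female,1930,TOY",
               "A2,P1,MZ,female,1931,TOY"),
             file.path(dir, "toy_persons.csv"))
  writeLines(c("person_id,age_years,grip",
               "A1,70,31.5", "A1,74,29.0", "A2,70,33.1", "A2,74,"),
             file.path(dir, "toy_visits.csv"))
  co <- read_cohort(file.path(dir, "toy"))
  expect_s3_class(co, "cohort_table")
  expect_equal(nrow(co$persons), 2L)
  expect_equal(nrow(co$visits), 4L)
  expect_true(is.na(co$visits$grip[co$visits$person_id == "A2" &
                                     co$visits$age_years == 74]))

  out <- file.path(dir, "copy")
  write_cohort(co, out)
  back <- read_cohort(out)
  expect_identical(back$persons, co$persons)
  expect_identical(back$visits, co$visits)
})

test_that("tab-separated input is sniffed and schema mapping renames columns", {
  dir <- withr::local_tempdir()
  writeLines(c("id\tfam\tzyg\tgender",
               "A1\tP1\tDZ\tmale", "A2\tP1\tDZ\tfemale"),
             file.path(dir, "m_persons.csv"))
  writeLines(c("id\tage", "A1\t70", "A2\t71"),
             file.path(dir, "m_visits.csv"))
  schema <- list(persons = c(person_id = "id", pair_id = "fam",
                             zygosity = "zyg", sex = "gender"),
                 visits = c(person_id = "id", age_years = "age"))
  co <- read_cohort(file.path(dir, "m"), schema = schema)
  expect_equal(co$persons$person_id, c("A1", "A2"))
  expect_equal(co$visits$age_years, c(70, 71))
})

test_that("validation rejects exactly the enumerated violations", {
  p <- toy_persons(2)
  v <- toy_visits(p)
  expect_silent(validate_cohort(cohort_table(p, v, validate = FALSE)))

  # MZ pair of discordant sex, error names the pair
  p2 <- p
  p2$zygosity <- "MZ"
  p2$sex <- c("male", "female", "male", "male")
  err <- expect_error(cohort_table(p2, v), "discordant sex")
  expect_match(conditionMessage(err), "PR01")

  # discordant zygosity within a pair
  p3 <- p
  p3$zygosity <- c("MZ", "DZ", "DZ", "DZ")
  p3$sex <- c("male", "male", "male", "female")
  expect_error(cohort_table(p3, v), "zygosity")

  # duplicated visit
  v2 <- rbind(v, v[1, ])
  expect_error(cohort_table(p, v2), "duplicated \\(person_id, age_years\\)")

  # orphan visit
  v3 <- v
  v3$person_id[1] <- "GHOST"
  expect_error(cohort_table(p, v3), "unknown person_id")

  # missing mandatory column
  expect_error(cohort_table(p[, -2], v), "mandatory column")

  # three persons in one pair
  p4 <- rbind(p, data.frame(person_id = "T999", pair_id = "PR01",
                            zygosity = "DZ", sex = "male",
                            birth_year = 1930L, study_label = "TOY"))
  expect_error(cohort_table(p4, v), "more than 2")
})

test_that("validation never rejects simulator output", {
  for (seed in 1:5) {
    co <- simulate_cohort(sim_config(n_pairs = c(MZ = 20, DZ = 30),
                                     emit_components = TRUE,
                                     emit_isced = TRUE,
                                     n_waves = 3),
                          seed = seed)
    expect_silent(validate_cohort(co))
  }
})

test_that("simulated cohorts with missing biomarkers round-trip exactly", {
  co <- simulate_cohort(sim_config(n_pairs = c(MZ = 5, DZ = 5),
                                   emit_components = TRUE, n_waves = 2),
                        seed = 3)
  co$visits$grip[c(2, 5)] <- NA
  co$visits$gait[3] <- NA
  dir <- withr::local_tempdir()
  write_cohort(co, file.path(dir, "sim"))
  back <- read_cohort(file.path(dir, "sim"))
  co_sorted <- co
  co_sorted$visits <- co$visits[order(co$visits$person_id,
                                      co$visits$age_years), ]
  rownames(co_sorted$visits) <- NULL
  for (col in names(co$visits))
    expect_equal(back$visits[[col]], co_sorted$visits[[col]],
                 tolerance = 1e-12, info = col)
  for (col in names(co$persons))
    expect_equal(back$persons[[col]], co$persons[[col]], tolerance = 1e-12)
})

test_that("an empty cohort writes header-only files", {
  p <- toy_persons(1)[0, ]
  v <- data.frame(person_id = character(0), age_years = numeric(0))
  dir <- withr::local_tempdir()
  write_cohort(cohort_table(p, v, validate = FALSE), file.path(dir, "e"))
  lines <- readLines(file.path(dir, "e_persons.csv"))
  expect_length(lines, 1L)
  expect_match(lines, "person_id")
})

test_that("complete_pairs keeps exactly the pairs complete on the variable", {
  p <- toy_persons(3)
  p$isei <- c(40, 45, 50, NA, 60, 65)  # pair 2 has one missing ISEI
  co <- cohort_table(p, toy_visits(p))
  cc <- complete_pairs(co, require = "isei")
  expect_equal(sort(unique(cc$persons$pair_id)), c("PR01", "PR03"))
  expect_equal(nrow(cc$persons), 4L)

  # all complete -> identity on persons
  p$isei <- 40
  co <- cohort_table(p, toy_visits(p))
  expect_equal(complete_pairs(co, "isei")$persons$person_id,
               p$person_id)

  # singletons only -> empty
  ps <- toy_persons(0, singletons = 3)
  cos <- cohort_table(ps, toy_visits(ps))
  expect_equal(nrow(complete_pairs(cos)$persons), 0L)
})

test_that("complete_pairs output has an even person count, pairs of two", {
  for (seed in 1:3) {
    co <- simulate_cohort(sim_config(n_pairs = c(MZ = 15, DZ = 25),
                                     n_waves = 2), seed = seed)
    # knock out some persons to create singletons
    drop <- sample(nrow(co$persons), 7)
    co2 <- cohort_table(co$persons[-drop, ],
                        co$visits[co$visits$person_id %in%
                                    co$persons$person_id[-drop], ],
                        validate = FALSE)
    cc <- complete_pairs(co2)
    expect_equal(nrow(cc$persons) %% 2L, 0L)
    expect_true(all(table(cc$persons$pair_id) == 2L))
  }
})
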