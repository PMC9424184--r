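test_that("configuration invariants are enforced with informative errors", {
  expect_error(cohort_config(wave_years = c(2000, 1999)), "strictly increasing")
  bad <- default_stratum_proportions()
  bad$prop <- bad$prop * 2
  expect_error(cohort_config(stratum_proportions = bad), "sum to 1")
})

test_that("negative spreads and misplaced blood wave are rejected", {
  expect_error(flat_config(sd_within = c(sbp = -1, dbp = 5, bmi = 1)),
               "sd_within")
  cfg <- default_cohort_config()
  cfg$blood$wave <- 1990
  expect_error(ckdburden:::validate_cohort_config(cfg), "blood")
})

test_that("the generator is reproducible under a fixed seed", {
  cfg <- flat_config(n = 300)
  a <- simulate_cohort(cfg, seed = 11)
  b <- simulate_cohort(cfg, seed = 11)
  expect_identical(a, b)
  c <- simulate_cohort(cfg, seed = 12)
  expect_false(identical(a, c))
})

test_that("zero noise and zero slopes pin every exposure to its stratum baseline", {
  cfg <- flat_config(n = 200, sbp = 120, dbp = 75, bmi = 22,
                     sd_within = c(sbp = 0, dbp = 0, bmi = 0),
                     sd_intercept = c(sbp = 0, dbp = 0, bmi = 0),
                     sd_slope = c(sbp = 0, dbp = 0, bmi = 0))
  survey <- simulate_cohort(cfg, seed = 3)
  expect_true(all(survey$sbp == 120))
  expect_true(all(survey$dbp == 75))
  expect_true(all(survey$bmi == 22))
})

test_that("survey rows satisfy the structural invariants", {
  fx <- calibrated_fixture()
  survey <- fx$survey
  expect_true(all(survey$age >= 18))
  expect_true(all(survey$sbp > survey$dbp))
  expect_true(all(survey$bmi > 0))
  blood_rows <- !is.na(survey$tg)
  expect_true(all(survey$wave[blood_rows] == fx$config$blood$wave))
  expect_identical(blood_rows, !is.na(survey$glucose))
  # ages advance by exactly the inter-wave gap
  gap_ok <- tapply(seq_len(nrow(survey)), survey$id, function(i) {
    d <- survey[i, ]
    all(diff(d$age) == diff(d$wave))
  })
  expect_true(all(unlist(gap_ok)))
})

test_that("the open cohort retains individuals across three or more waves", {
  fx <- calibrated_fixture()
  n_waves <- table(fx$survey$id)
  expect_gt(mean(n_waves >= 3), 0.3)
  closed <- flat_config(n = 150, retention = 1)
  s <- simulate_cohort(closed, seed = 5)
  expect_true(all(table(s$id) == length(closed$wave_years)))
})

test_that("realized stratum means converge to configured targets", {
  cfg <- flat_config(n = 5000, sbp = 116,
                     waves = c(1991, 1993))
  survey <- simulate_cohort(cfg, seed = 21)
  d <- survey[survey$wave == 1991 & survey$sex == "male", ]
  se <- stats::sd(d$sbp) / sqrt(nrow(d))
  expect_lt(abs(mean(d$sbp) - 116), 3 * se)
})

test_that("moment recovery holds across seeds", {
  cfg <- flat_config(n = 1200, sbp = 120, waves = c(1991, 1993))
  hits <- vapply(1:20, function(s) {
    d <- simulate_cohort(cfg, seed = 100 + s)
    d <- d[d$wave == 1991, ]
    se <- stats::sd(d$sbp) / sqrt(nrow(d))
    abs(mean(d$sbp) - 120) < 3 * se
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("the default census reproduces the national adult total", {
  cen <- generate_census(default_cohort_config())
  expect_identical(sum(cen$count), 846662309)
  expect_equal(nrow(cen), 16)
  expect_setequal(paste(cen$age_group, cen$sex, cen$residence, sep = "|"),
                  ckdburden:::all_strata()$stratum)
  custom <- generate_census(default_cohort_config(), total = 1000)
  expect_identical(sum(custom$count), 1000)
})

test_that("census counts translate into proportional standardization weights", {
  w <- ckdburden:::census_weights(mini_census(c(1, 3)))
  expect_equal(unname(w[order(names(w))]), c(0.25, 0.75))
})

test_that("the calibrated defaults encode the published trajectories", {
  cfg <- default_cohort_config()
  expect_equal(unname(cfg$smoking$current["male", 1]), 0.667)
  # census-weighted BMI target in 2011: baseline + 20 years of slope
  w <- ckdburden:::census_weights(generate_census(cfg))
  bmi <- cfg$continuous$bmi
  target_2011 <- sum(w * (bmi$baseline[names(w)] + 20 * bmi$slope[names(w)]))
  expect_equal(target_2011, 23.92, tolerance = 1e-9)
  sbp <- cfg$continuous$sbp
  expect_equal(sum(w * sbp$baseline[names(w)]), 115, tolerance = 1e-9)
  expect_equal(sum(w * (sbp$baseline[names(w)] + 20 * sbp$slope[names(w)])),
               125, tolerance = 1e-9)
  expect_silent(ckdburden:::validate_cohort_config(cfg))
})

test_that("survey and census tables round-trip through delimited text", {
  fx <- calibrated_fixture()
  dir <- withr::local_tempdir()
  paths <- write_cohort_tables(utils::head(fx$survey, 50), fx$census, dir)
  survey2 <- read_cohort_table(paths["survey"])
  expect_equal(survey2$sbp, utils::head(fx$survey, 50)$sbp, tolerance = 1e-12)
  expect_true(all(is.na(survey2$tg) == is.na(utils::head(fx$survey, 50)$tg)))
})
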