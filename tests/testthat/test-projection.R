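test_that("identical noise-free lines are recovered exactly", {
  waves <- c(1991, 1995, 1999, 2003)
  survey <- do.call(rbind, lapply(1:10, function(i)
    data.frame(id = i, wave = waves, age = 30, sex = "male",
               residence = "urban", y = 2 + 0.4 * (waves - 1991),
               stringsAsFactors = FALSE)))
  fit <- fit_stratum_trend(survey, "y", "18-39|male|urban")
  expect_equal(fit$slope, 0.4, tolerance = 1e-12)
  expect_equal(fit$tau2, 0)
  expect_equal(fit$se, 0)
  expect_equal(fit$n_individuals, 10)
})

test_that("individuals below the wave threshold are excluded", {
  waves <- c(1991, 1995, 1999)
  long <- do.call(rbind, lapply(1:5, function(i)
    data.frame(id = i, wave = waves, age = 30, sex = "male",
               residence = "urban", y = stats::rnorm(3),
               stringsAsFactors = FALSE)))
  short <- do.call(rbind, lapply(6:10, function(i)
    data.frame(id = i, wave = waves[1:2], age = 30, sex = "male",
               residence = "urban", y = stats::rnorm(2),
               stringsAsFactors = FALSE)))
  fit <- fit_stratum_trend(rbind(long, short), "y", "18-39|male|urban")
  expect_equal(fit$n_individuals, 5)
  expect_error(fit_stratum_trend(short, "y", "18-39|male|urban"),
               "18-39\\|male\\|urban")
})

test_that("the two-stage estimator recovers a known random-slope truth", {
  set.seed(55)
  waves <- c(1991, 1995, 1999, 2003, 2007)
  hits <- vapply(1:200, function(r) {
    survey <- make_panel(80, waves, intercept_sd = 1, slope_mean = 0.5,
                         slope_sd = 0.2, noise_sd = 1)
    fit <- fit_stratum_trend(survey, "y", "18-39|male|urban")
    abs(fit$slope - 0.5) <= 2 * fit$se
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("the pooled slope agrees with an independent DL meta-analysis", {
  skip_if_not_installed("metafor")
  set.seed(66)
  waves <- c(1991, 1995, 1999, 2003)
  survey <- make_panel(30, waves, intercept_sd = 1, slope_mean = 0.3,
                       slope_sd = 0.15, noise_sd = 1)
  fit <- fit_stratum_trend(survey, "y", "18-39|male|urban")
  yi <- sxx <- rss <- numeric(30)
  for (i in 1:30) {
    d <- survey[survey$id == i, ]
    m <- stats::lm(y ~ wave, data = d)
    yi[i] <- stats::coef(m)["wave"]
    sxx[i] <- sum((d$wave - mean(d$wave))^2)
    rss[i] <- sum(stats::resid(m)^2)
  }
  vi <- (sum(rss) / (30 * (length(waves) - 2))) / sxx
  rma <- metafor::rma(yi, vi, method = "DL")
  expect_equal(fit$slope, as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(fit$se, as.numeric(rma$se), tolerance = 1e-8)
  expect_equal(fit$tau2, rma$tau2, tolerance = 1e-8)
})

test_that("projection arithmetic is linear and anchored", {
  model <- list(slope = 0.5)
  expect_equal(project_mean(model, 2031, 125, 2011), 135)
  expect_equal(project_mean(list(slope = 0), 2031, 125, 2011), 125)
  # doubling the horizon doubles the change
  expect_equal(project_mean(model, 2051, 125, 2011) - 125,
               2 * (project_mean(model, 2031, 125, 2011) - 125))
  expect_error(project_mean(model, 2001, 125, 2011), "anchor")
  # smoking-style proportion with the published decline
  smk <- list(slope = (0.204 - 0.265) / 20)
  expect_equal(project_mean(smk, 2031, 0.265, 2011, proportion = TRUE), 0.204,
               tolerance = 1e-12)
  expect_equal(project_mean(list(slope = -0.1), 2031, 0.265, 2011,
                            proportion = TRUE), 0)
})

test_that("distribution projection is a pure location shift", {
  set.seed(7)
  x <- stats::rnorm(1000, 125, 10)
  d <- structure(list(values = x, weights = rep(1e-3, 1000), factor = "sbp",
                      wave = 2011), class = "standardized_distribution")
  same <- project_distribution(d, distribution_mean(d))
  expect_equal(same$values, d$values)
  shifted <- project_distribution(d, distribution_mean(d) + 10)
  expect_equal(distribution_mean(shifted), distribution_mean(d) + 10,
               tolerance = 1e-10)
  expect_equal(distribution_var(shifted), distribution_var(d),
               tolerance = 1e-10)
  # a higher projected mean strictly raises the continuous PAF
  spec <- ckd_risk_factors()$sbp
  expect_gt(paf_continuous(shifted, spec), paf_continuous(d, spec))
})

test_that("projected standardized means equal census-weighted stratum projections", {
  fx <- calibrated_fixture()
  spec <- ckd_risk_factors()["sbp"]
  proj <- projected_burden(fx$survey, fx$census, spec, years = c(2021, 2031),
                           total = 9e7, n_draws = 50, seed = 2)
  w <- ckdburden:::census_weights(fx$census)
  anchor_year <- max(fx$survey$wave)
  slopes <- vapply(names(w), function(s)
    fit_stratum_trend(fx$survey, "sbp", s)$slope, numeric(1))
  manual <- standardized_mean(fx$survey, fx$census, "sbp", anchor_year)$mean +
    sum(w * slopes) * (2031 - anchor_year)
  expect_equal(proj$exposure[proj$year == 2031], manual, tolerance = 1e-10)
  # linearity of the projected change
  d21 <- proj$exposure[proj$year == 2021] -
    standardized_mean(fx$survey, fx$census, "sbp", anchor_year)$mean
  d31 <- proj$exposure[proj$year == 2031] -
    standardized_mean(fx$survey, fx$census, "sbp", anchor_year)$mean
  expect_equal(d31 / d21, 2, tolerance = 1e-8)
})

test_that("zero slopes freeze the projected burden", {
  waves <- c(2007, 2009, 2011)
  set.seed(9)
  strata <- ckdburden:::all_strata()[rep(1:16, each = 3), ]
  survey <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    s <- strata[i, ]
    age0 <- c(`18-39` = 25, `40-59` = 45, `60-69` = 62, `70+` = 72)[s$age_group]
    data.frame(id = i, wave = waves, age = age0 + (waves - waves[1]),
               sex = s$sex, residence = s$residence,
               sbp = 125, stringsAsFactors = FALSE)
  }))
  cen <- generate_census(default_cohort_config())
  proj <- projected_burden(survey, cen, ckd_risk_factors()["sbp"],
                           years = c(2021, 2031), total = 9e7,
                           n_draws = 20, seed = 1)
  expect_equal(proj$exposure[1], proj$exposure[2], tolerance = 1e-12)
  expect_equal(proj$attributable[1], proj$attributable[2], tolerance = 1e-9)
})
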