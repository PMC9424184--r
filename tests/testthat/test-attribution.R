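specs <- ckd_risk_factors()

test_that("the categorical PAF follows the closed form", {
  expect_equal(paf_categorical(c(0.5, 0.5), c(1, 3)), 0.5)
  expect_equal(paf_categorical(c(0.2, 0.3, 0.5), c(1, 1, 1)), 0)
  expect_error(paf_categorical(c(0.5, 0.6), c(1, 2)), "sum to 1")
  expect_error(paf_categorical(c(-0.1, 1.1), c(1, 2)), ">= 0")
  expect_error(paf_categorical(c(0.5, 0.5), c(1, -2)), "> 0")
})

test_that("the categorical PAF matches an individual-level simulation", {
  set.seed(19)
  prev <- c(0.735, 0.265)
  rr <- c(1, 1.34)
  oracle <- sim_paf_oracle(prev, rr, n = 1e6)
  expect_lt(abs(paf_categorical(prev, rr) - oracle$paf), 3 * oracle$se)
})

test_that("PAF is monotone in relative risks and exposure shift", {
  p <- c(0.6, 0.3, 0.1)
  base <- paf_categorical(p, c(1, 1.3, 1.6))
  expect_gt(paf_categorical(p, c(1, 1.3, 1.9)), base)
  expect_gt(paf_categorical(p, c(1, 1.5, 1.6)), base)
  # continuous: shifting P1 upward increases PAF
  set.seed(2)
  x <- stats::rnorm(5000, 125, 12)
  d <- structure(list(values = x, weights = rep(1 / 5000, 5000),
                      factor = "sbp", wave = 2011),
                 class = "standardized_distribution")
  d_hi <- d; d_hi$values <- d_hi$values + 5
  expect_gt(paf_continuous(d_hi, specs$sbp), paf_continuous(d, specs$sbp))
  expect_lt(paf_continuous(d_hi, specs$sbp), 1)
})

test_that("continuous PAF vanishes when exposure sits at the counterfactual", {
  set.seed(3)
  n <- 50000
  x <- stats::rnorm(n, 115, 6)
  x <- x[x > 0]
  d <- structure(list(values = x, weights = rep(1 / length(x), length(x)),
                      factor = "sbp", wave = 2011),
                 class = "standardized_distribution")
  paf <- suppressWarnings(paf_continuous(d, specs$sbp))
  expect_lt(abs(paf), 0.01)
})

test_that("a point mass at the TMRED mean flags a non-positive PAF", {
  d <- structure(list(values = 115, weights = 1, factor = "sbp", wave = 2011),
                 class = "standardized_distribution")
  paf <- suppressWarnings(paf_continuous(d, specs$sbp))
  expect_lte(paf, 0)
})

test_that("continuous PAF matches the Monte-Carlo integration oracle", {
  d <- structure(list(values = 125, weights = 1, factor = "sbp", wave = 2011),
                 class = "standardized_distribution")
  paf <- paf_continuous(d, specs$sbp)
  set.seed(12)
  # point mass: factual integral is exactly RR(125) = 1.08
  x2 <- stats::rnorm(3e6, 115, 6)
  x2 <- x2[x2 >= 0 & x2 <= 125][1:1e6]
  e2 <- mean(rr_continuous(specs$sbp, x2))
  se <- stats::sd(rr_continuous(specs$sbp, x2)) / sqrt(1e6) / 1.08
  expect_lt(abs(paf - (1.08 - e2) / 1.08), 3 * se)
})

test_that("quadrature on a kernel-smoothed P1 agrees with the weighted mean", {
  set.seed(5)
  x <- stats::rnorm(20000, 125, 10)
  w <- rep(1 / 20000, 20000)
  e1 <- sum(w * rr_continuous(specs$sbp, x))
  kde <- stats::density(x, n = 4096)
  dx <- diff(kde$x[1:2])
  e1_kde <- sum(rr_continuous(specs$sbp, kde$x) * kde$y) * dx
  expect_lt(abs(e1 - e1_kde), 1e-2)
})

test_that("binned categorical PAF converges to the continuous PAF", {
  set.seed(6)
  x <- stats::rnorm(200000, 125, 12)
  x <- x[x > 0]
  d <- structure(list(values = x, weights = rep(1 / length(x), length(x)),
                      factor = "sbp", wave = 2011),
                 class = "standardized_distribution")
  cont <- paf_continuous(d, specs$sbp)
  expect_lt(abs(binned_paf(d, specs$sbp, 1000) - cont), 1e-3)
  # and the error shrinks with finer bins
  expect_lt(abs(binned_paf(d, specs$sbp, 1000) - cont),
            abs(binned_paf(d, specs$sbp, 20) - cont) + 1e-6)
})

test_that("total and attributable case arithmetic is exact", {
  expect_equal(total_cases(0.108, 846662309), 0.108 * 846662309)
  expect_equal(total_cases(0, 1e6), 0)
  expect_equal(total_cases(1, 1e6), 1e6)
  expect_error(total_cases(1.2, 1e6), "prevalence")
  total <- total_cases(0.108, 846662309)
  expect_equal(attributable_cases(0.087, total) / 1e6, 7.9, tolerance = 0.1)
  expect_equal(attributable_cases(0.074, total) / 1e6, 6.8, tolerance = 0.1)
  expect_equal(attributable_cases(0, total), 0)
  expect_error(attributable_cases(1, total), "< 1")
  expect_warning(attributable_cases(-0.05, total), "negative")
})

test_that("Monte-Carlo intervals collapse, reproduce and cover", {
  fx <- calibrated_fixture()
  spec0 <- ckd_risk_factors()$smoking
  spec0$rr_low <- spec0$rr
  spec0$rr_high <- spec0$rr
  b0 <- burden_with_ci(fx$survey, fx$census, spec0, prevalence = 0.108,
                       prevalence_ci = c(0.108, 0.108),
                       population = sum(fx$census$count), wave = 2011,
                       n_draws = 200, seed = 1)
  expect_equal(unname(b0$paf["q2.5"]), unname(b0$paf["point"]), tolerance = 1e-12)
  expect_equal(unname(b0$attributable["q97.5"]),
               unname(b0$attributable["point"]), tolerance = 1e-6)
  spec <- ckd_risk_factors()$smoking
  b1 <- burden_with_ci(fx$survey, fx$census, spec, 0.108, c(0.102, 0.113),
                       sum(fx$census$count), 2011, n_draws = 300, seed = 7)
  b2 <- burden_with_ci(fx$survey, fx$census, spec, 0.108, c(0.102, 0.113),
                       sum(fx$census$count), 2011, n_draws = 300, seed = 7)
  expect_identical(b1$paf, b2$paf)
  expect_lte(b1$paf["q2.5"], b1$paf["point"])
  expect_gte(b1$paf["q97.5"], b1$paf["point"])
})

test_that("the interval covers a known true PAF at the nominal rate", {
  set.seed(23)
  prev <- c(never = 0.7, current = 0.3)
  true_rr <- 1.4
  true_paf <- paf_categorical(prev, c(1, true_rr))
  sigma <- 0.06  # log-RR standard error driving both truth and draws
  covered <- vapply(1:150, function(r) {
    rr_hat <- exp(stats::rnorm(1, log(true_rr), sigma))
    draws <- exp(stats::rnorm(600, log(rr_hat), sigma))
    pafs <- vapply(draws, function(g) paf_categorical(prev, c(1, g)), numeric(1))
    ci <- stats::quantile(pafs, c(0.025, 0.975))
    ci[1] <= true_paf && true_paf <= ci[2]
  }, logical(1))
  expect_gt(mean(covered), 0.88)
  expect_lt(mean(covered), 0.99)
})

test_that("the attributable series is linear in the PAFs", {
  pafs <- data.frame(wave = c(1991, 2011), paf = c(0.10, 0.07))
  out <- attributable_series(pafs, 9e7)
  expect_equal(out$attributable, c(0.10, 0.07) * 9e7)
  expect_equal(diff(out$attributable), (0.07 - 0.10) * 9e7)
  flat <- attributable_series(data.frame(wave = 1:3, paf = 0.05), 1e6)
  expect_true(all(flat$attributable == 5e4))
})
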