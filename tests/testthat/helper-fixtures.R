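# Fixtures and independent oracles used across the suite. Everything is
# generated in code; nothing is read from disk.

constant_named <- function(value) {
  s <- ckdburden:::all_strata()$stratum
  stats::setNames(rep(value, length(s)), s)
}

# Small generator config with flat stratum targets; noise and slopes settable.
flat_config <- function(n = 800,
                        waves = c(1991, 1993, 1997, 2000, 2004, 2006, 2009, 2011),
                        sbp = 120, dbp = 75, bmi = 22,
                        slope = c(sbp = 0, dbp = 0, bmi = 0),
                        sd_within = c(sbp = 8, dbp = 5, bmi = 1),
                        sd_intercept = c(sbp = 10, dbp = 7, bmi = 2.5),
                        sd_slope = c(sbp = 0.15, dbp = 0.1, bmi = 0.04),
                        retention = 0.88, confounding = NULL) {
  base <- c(sbp = sbp, dbp = dbp, bmi = bmi)
  cont <- lapply(c(sbp = "sbp", dbp = "dbp", bmi = "bmi"), function(f)
    list(baseline = constant_named(base[f]), slope = constant_named(slope[f]),
         sd_within = unname(sd_within[f]),
         sd_intercept = unname(sd_intercept[f]),
         sd_slope = unname(sd_slope[f])))
  smoking <- list(current = rbind(male = rep(0.3, length(waves)),
                                  female = rep(0.04, length(waves))),
                  ever = c(male = 0.4, female = 0.06))
  args <- list(wave_years = waves, n_individuals = n, continuous = cont,
               smoking = smoking, blood = list(
                 wave = waves[length(waves)],
                 tg = list(sdlog = 0.45, p_high = 0.25, threshold = 1.7),
                 glucose = list(sdlog = 0.08, p_high = 0.0384, threshold = 5.6),
                 hdl = list(sd = 0.30, p_low = c(male = 0.2, female = 0.05),
                            threshold = c(male = 1.1, female = 0.9))),
               participation = list(retention = retention, replenish = TRUE))
  if (!is.null(confounding)) args$confounding <- confounding
  do.call(cohort_config, args)
}

# Two-stratum census for arithmetic unit tests.
mini_census <- function(counts = c(1, 3)) {
  data.frame(age_group = c("18-39", "40-59"), sex = "male",
             residence = "urban", count = counts, stringsAsFactors = FALSE)
}

# Minimal person-wave panel for trend machinery: one response column `y`,
# demographics constant so the stratum is well defined.
make_panel <- function(n_id, waves, intercept_sd = 1, slope_mean = 0,
                       slope_sd = 0, noise_sd = 1, age = 30, sex = "male",
                       residence = "urban") {
  a <- stats::rnorm(n_id, 0, intercept_sd)
  b <- stats::rnorm(n_id, slope_mean, slope_sd)
  nw <- length(waves)
  idx <- rep(seq_len(n_id), each = nw)
  t <- rep(waves - waves[1], n_id)
  data.frame(id = idx, wave = rep(waves, n_id), age = age, sex = sex,
             residence = residence,
             y = a[idx] + b[idx] * t + stats::rnorm(n_id * nw, 0, noise_sd),
             stringsAsFactors = FALSE)
}

# Shared moderate cohort from the calibrated defaults (built once per run).
calibrated_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- default_cohort_config(n_individuals = 2500)
      cache <<- list(config = cfg,
                     survey = simulate_cohort(cfg, seed = 42),
                     census = generate_census(cfg))
    }
    cache
  }
})

# Independent brute-force standardized mean: explicit loop over strata.
brute_standardized_mean <- function(survey, census, factor, wave) {
  d <- survey[survey$wave == wave & !is.na(survey[[factor]]), ]
  total <- sum(census$count)
  acc <- 0
  for (i in seq_len(nrow(census))) {
    lo <- c(`18-39` = 18, `40-59` = 40, `60-69` = 60, `70+` = 70)
    hi <- c(`18-39` = 40, `40-59` = 60, `60-69` = 70, `70+` = Inf)
    g <- census$age_group[i]
    rows <- d$age >= lo[g] & d$age < hi[g] & d$sex == census$sex[i] &
      d$residence == census$residence[i]
    acc <- acc + (census$count[i] / total) * mean(d[[factor]][rows])
  }
  acc
}

# Individual-level simulation oracle for the categorical PAF: assign
# categories, draw cases with probability proportional to RR, and compare
# realized cases with the all-reference counterfactual.
sim_paf_oracle <- function(prevalence, rr, n = 1e6, p0 = 0.05) {
  idx <- sample.int(length(prevalence), n, replace = TRUE, prob = prevalence)
  p_case <- p0 * rr[idx]
  cases <- sum(stats::rbinom(n, 1, p_case))
  counter <- sum(stats::rbinom(n, 1, p0))
  paf <- (cases - counter) / cases
  var_c <- sum(p_case * (1 - p_case))
  var_b <- n * p0 * (1 - p0)
  se <- (counter / cases) * sqrt(var_b / counter^2 + var_c / cases^2)
  list(paf = paf, se = se)
}

# Monte-Carlo integration oracle for the continuous PAF: fresh draws from
# P1 (normal) and from the truncated TMRED counterfactual P2 on [0, m].
mc_paf_oracle <- function(spec, p1_mean, p1_sd, m, n = 1e6) {
  x1 <- stats::rnorm(n, p1_mean, p1_sd)
  x1 <- x1[x1 >= 0 & x1 <= m]
  r1 <- rr_continuous(spec, x1)
  x2 <- stats::rnorm(ceiling(2.5 * n), spec$tmred_mean, spec$tmred_sd)
  x2 <- x2[x2 >= 0 & x2 <= m][seq_len(n)]
  r2 <- rr_continuous(spec, x2)
  e1 <- mean(r1); e2 <- mean(r2)
  paf <- (e1 - e2) / e1
  rel_se <- sqrt(stats::var(r1) / (length(r1) * e1^2) +
                 stats::var(r2) / (n * e2^2))
  list(paf = paf, se = (e2 / e1) * rel_se)
}

# Discretized PAF over K bins of [0, m]: both the factual sample and the
# truncated-normal counterfactual are binned and the Levin form is applied
# to each (identity: PAF = 1 - (1 - paf_cat(P1)) / (1 - paf_cat(P2))).
binned_paf <- function(dist, spec, k) {
  m <- max(dist$values)
  breaks <- seq(0, m, length.out = k + 1)
  mids <- (breaks[-1] + breaks[-(k + 1)]) / 2
  rr <- rr_continuous(spec, mids)
  p1 <- tapply(dist$weights,
               cut(dist$values, breaks, include.lowest = TRUE), sum)
  p1[is.na(p1)] <- 0
  mass <- stats::pnorm(breaks, spec$tmred_mean, spec$tmred_sd)
  p2 <- diff(mass) / (mass[k + 1] - mass[1])
  f1 <- paf_categorical(as.numeric(p1) / sum(p1), rr)
  f2 <- paf_categorical(p2, rr)
  1 - (1 - f1) / (1 - f2)
}
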