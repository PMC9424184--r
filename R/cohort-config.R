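## Calibrated trajectory margins for the three continuous factors, 1991 -> 2011:
## published sex / age-group / residence values and the census-standardized
## adult endpoints. Joint stratum targets are built additively from the margins
## and recentred so the census-weighted overall mean hits the endpoint path.

.margin_weights <- list(
  sex = c(male = 0.4725, female = 0.5275),
  age = c(`18-39` = 0.45, `40-59` = 0.37, `60-69` = 0.11, `70+` = 0.07),
  residence = c(urban = 0.5, rural = 0.5)
)

.trajectory_margins <- list(
  sbp = list(
    overall = c(115, 125),
    sex = rbind(`1991` = c(116, 112), `2011` = c(124, 119)),
    age = rbind(`1991` = c(109, 117, 127, 133), `2011` = c(116, 123, 129, 129)),
    residence = rbind(`1991` = c(115, 113), `2011` = c(121, 122))
  ),
  dbp = list(
    overall = c(74, 79),
    sex = rbind(`1991` = c(76, 73), `2011` = c(80, 77)),
    age = rbind(`1991` = c(72, 76, 79, 81), `2011` = c(76, 80, 80, 77)),
    residence = rbind(`1991` = c(74, 74), `2011` = c(78, 79))
  ),
  bmi = list(
    overall = c(21.67, 23.92),
    sex = rbind(`1991` = c(21.8, 22.3), `2011` = c(24.0, 23.6)),
    age = rbind(`1991` = c(21.8, 22.5, 22.1, 21.4), `2011` = c(23.1, 24.2, 23.3, 23.8)),
    residence = rbind(`1991` = c(22.2, 21.9), `2011` = c(23.7, 23.8))
  )
)

## Per-wave current-smoking prevalence by sex (published trajectories) and the
## assumed ever-smoking fractions; former = ever - current, never = 1 - ever.
.smoking_current <- rbind(
  male   = c(0.667, 0.644, 0.584, 0.586, 0.560, 0.535, 0.546, 0.527),
  female = c(0.043, 0.044, 0.042, 0.045, 0.040, 0.035, 0.036, 0.029)
)
.smoking_ever <- c(male = 0.75, female = 0.055)

## Additive stratum targets from marginal trajectories, recentred so the
## census-weighted overall baseline/slope equal the stated endpoint path.
calibrate_strata <- function(margins, span = 20) {
  w <- .margin_weights
  strata <- all_strata()
  base_ov <- margins$overall[1]
  slope_ov <- (margins$overall[2] - margins$overall[1]) / span
  eff <- function(m) {
    b91 <- m["1991", ]
    sl <- (m["2011", ] - m["1991", ]) / span
    list(b = b91, s = sl)
  }
  sx <- eff(margins$sex); ag <- eff(margins$age); rs <- eff(margins$residence)
  names(sx$b) <- names(sx$s) <- names(w$sex)
  names(ag$b) <- names(ag$s) <- names(w$age)
  names(rs$b) <- names(rs$s) <- names(w$residence)
  center <- function(v, wt) v - sum(wt * v)
  sx$b <- center(sx$b, w$sex); ag$b <- center(ag$b, w$age); rs$b <- center(rs$b, w$residence)
  sx$s <- center(sx$s, w$sex); ag$s <- center(ag$s, w$age); rs$s <- center(rs$s, w$residence)
  baseline <- base_ov + sx$b[strata$sex] + ag$b[strata$age_group] + rs$b[strata$residence]
  slope <- slope_ov + sx$s[strata$sex] + ag$s[strata$age_group] + rs$s[strata$residence]
  names(baseline) <- names(slope) <- strata$stratum
  list(baseline = baseline, slope = slope)
}

#' Default joint stratum proportions
#'
#' Product of the marginal sex, age-group and residence shares used for both
#' cohort sampling and the synthetic census, over the 16 joint strata.
#'
#' @return data.frame with `age_group`, `sex`, `residence`, `prop`.
#' @export
default_stratum_proportions <- function() {
  strata <- all_strata()
  w <- .margin_weights
  strata$prop <- w$sex[strata$sex] * w$age[strata$age_group] *
    w$residence[strata$residence]
  rownames(strata) <- NULL
  strata
}

#' Cohort generator configuration
#'
#' Bundles every parameter of the synthetic open-cohort generator. The
#' defaults are the calibrated study conditions: eight survey waves 1991-2011;
#' joint stratum targets built from the published sex, age-group and residence
#' trajectories, recentred so the census-standardized adult means follow
#' 115 to 125 mm Hg (SBP), 74 to 79 mm Hg (DBP), 21.67 to 23.92 kg/m^2 (BMI)
#' and current smoking follows the published per-wave sex-specific
#' trajectories (overall 33.7% down to about 26.5%); a blood panel (TG,
#' HDL-C, glucose) measured in one wave only (2009); and an open-cohort
#' participation process with per-wave retention 0.88.
#'
#' @param wave_years survey calendar years, strictly increasing.
#' @param n_individuals target panel size per wave.
#' @param stratum_proportions data.frame (`age_group`, `sex`, `residence`,
#'   `prop`) with the 16 joint strata; `prop` sums to 1.
#' @param continuous named list (`sbp`, `dbp`, `bmi`) of
#'   `list(baseline, slope, sd_within, sd_intercept, sd_slope)`; `baseline`
#'   and `slope` are per-stratum named vectors (exposure units and units/year),
#'   the SDs are the within-person noise and the between-person random
#'   intercept/slope spreads.
#' @param smoking list with `current` (sex x wave matrix of current-smoking
#'   prevalence) and `ever` (per-sex ever-smoking fraction, constant over
#'   waves; former = ever - current, never = 1 - ever).
#' @param blood single-wave blood panel settings: measurement `wave`, and for
#'   TG / glucose (log-normal) and HDL-C (normal, sex-specific) the spread
#'   plus the target threshold-exceedance fractions from which the location
#'   parameters are solved.
#' @param participation list with per-wave `retention` probability and
#'   `replenish` (recruit new entrants to keep the panel size).
#' @param confounding optional covariate effects: `education` named vector of
#'   per-level effects on continuous factors (default zero) and `drift`
#'   (education distribution shifts across entry waves) so covariate
#'   adjustment is testable.
#' @param seed default seed used by [simulate_cohort()].
#' @return object of class `cohort_config`.
#' @seealso [simulate_cohort()], [generate_census()], [default_cohort_config()]
#' @export
cohort_config <- function(
    wave_years = c(1991, 1993, 1997, 2000, 2004, 2006, 2009, 2011),
    n_individuals = 5000,
    stratum_proportions = default_stratum_proportions(),
    continuous = list(
      sbp = c(calibrate_strata(.trajectory_margins$sbp),
              list(sd_within = 8, sd_intercept = 10, sd_slope = 0.15)),
      dbp = c(calibrate_strata(.trajectory_margins$dbp),
              list(sd_within = 5, sd_intercept = 7, sd_slope = 0.10)),
      bmi = c(calibrate_strata(.trajectory_margins$bmi),
              list(sd_within = 1.0, sd_intercept = 2.5, sd_slope = 0.04))
    ),
    smoking = list(current = .smoking_current, ever = .smoking_ever),
    blood = list(
      wave = 2009,
      tg = list(sdlog = 0.45, p_high = 0.25, threshold = 1.7),
      glucose = list(sdlog = 0.08, p_high = 0.0384, threshold = 5.6),
      hdl = list(sd = 0.30, p_low = c(male = 0.202, female = 0.0548),
                 threshold = c(male = 1.1, female = 0.9))
    ),
    participation = list(retention = 0.88, replenish = TRUE),
    confounding = list(education = c(sbp = 0, dbp = 0, bmi = 0), drift = FALSE),
    seed = 20100L) {
  config <- structure(
    list(wave_years = wave_years, n_individuals = n_individuals,
         stratum_proportions = stratum_proportions, continuous = continuous,
         smoking = smoking, blood = blood, participation = participation,
         confounding = confounding, seed = seed),
    class = "cohort_config")
  validate_cohort_config(config)
  config
}

#' Default calibrated generator configuration
#'
#' Returns the [cohort_config()] defaults: the study conditions the synthetic
#' cohort is calibrated to (published stratum trajectories 1991-2011, single
#' blood-panel wave 2009, open-cohort retention 0.88).
#'
#' @param n_individuals target panel size per wave.
#' @return object of class `cohort_config`.
#' @export
default_cohort_config <- function(n_individuals = 5000) {
  cohort_config(n_individuals = n_individuals)
}

validate_cohort_config <- function(config) {
  w <- config$wave_years
  if (length(w) < 2 || any(diff(w) <= 0))
    stop("wave_years must be strictly increasing")
  if (config$n_individuals < 1) stop("n_individuals must be >= 1")
  sp <- config$stratum_proportions
  if (!is.data.frame(sp) || nrow(sp) != 16 ||
      !setequal(paste(sp$age_group, sp$sex, sp$residence, sep = "|"),
                all_strata()$stratum))
    stop("stratum_proportions must contain each of the 16 joint strata once")
  if (abs(sum(sp$prop) - 1) > 1e-9)
    stop("stratum_proportions: prop must sum to 1")
  if (any(sp$prop < 0)) stop("stratum_proportions: prop must be >= 0")
  for (f in names(config$continuous)) {
    fc <- config$continuous[[f]]
    for (s in c("sd_within", "sd_intercept", "sd_slope"))
      if (fc[[s]] < 0) stop(sprintf("continuous$%s$%s must be >= 0", f, s))
    for (v in c("baseline", "slope"))
      if (!all(all_strata()$stratum %in% names(fc[[v]])))
        stop(sprintf("continuous$%s$%s must name all 16 strata", f, v))
  }
  sm <- config$smoking
  if (ncol(sm$current) != length(w))
    stop("smoking$current must have one column per wave")
  if (any(sm$current < 0 | sm$current > 1))
    stop("smoking$current must lie in [0, 1]")
  if (any(sm$ever[rownames(sm$current)] < apply(sm$current, 1, max)))
    stop("smoking$ever must be >= current prevalence in every wave")
  if (!(config$blood$wave %in% w))
    stop("blood$wave must be one of wave_years")
  ret <- config$participation$retention
  if (ret < 0 || ret > 1) stop("participation$retention must lie in [0, 1]")
  invisible(config)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic open-cohort configuration\n")
  cat("  waves:", paste(x$wave_years, collapse = ", "), "\n")
  cat("  panel size per wave:", x$n_individuals, "\n")
  cat("  continuous factors:", paste(names(x$continuous), collapse = ", "), "\n")
  cat("  blood-panel wave:", x$blood$wave, "\n")
  cat("  per-wave retention:", x$participation$retention, "\n")
  invisible(x)
}
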