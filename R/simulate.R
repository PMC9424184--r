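## Synthetic open-cohort generator. Individual-level model for continuous
## exposures:
##   x(i, t) = baseline[stratum(i, t)] + slope[stratum(i, t)] * (t - t0)
##             + u_i + v_i * (t - t0) + within-person noise,
## with u_i, v_i normal random intercept/slope and stratum taken at the age
## attained at each wave. Smoking is categorical with quitting-only
## transitions calibrated to per-sex prevalence targets; the blood panel is
## generated in a single wave.

.provinces <- paste0("province_", 1:9)
.educations <- c("primary", "lower_middle", "upper_middle", "college")
.occupations <- c("farmer", "worker", "service", "office", "other")

sample_entry_age <- function(groups) {
  lo <- c(`18-39` = 18, `40-59` = 40, `60-69` = 60, `70+` = 70)
  hi <- c(`18-39` = 39, `40-59` = 59, `60-69` = 69, `70+` = 89)
  lo[groups] + floor(stats::runif(length(groups)) * (hi[groups] - lo[groups] + 1))
}

education_probs <- function(wave_idx, drift) {
  if (isTRUE(drift)) {
    w <- exp(0.12 * (wave_idx - 1) * seq_along(.educations))
    w / sum(w)
  } else c(0.30, 0.35, 0.25, 0.10)
}

#' Simulate an open longitudinal cohort
#'
#' Generates person-wave survey records with the statistical structure the
#' burden analysis assumes: per-stratum linear exposure trajectories with
#' person-level random intercepts and slopes, categorical smoking with
#' quitting-only transitions tracking per-sex prevalence targets, a blood
#' panel (TG, HDL-C, glucose) observed in a single wave, and an open-cohort
#' participation process (per-wave dropout, replenishing entrants). Ages
#' advance deterministically between waves; all participants are adults.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; defaults to `config$seed`. Identical
#'   (config, seed) pairs give identical tables.
#' @return data.frame with one row per person-wave: `id`, `wave`, `age`,
#'   `sex`, `residence`, `province`, `education`, `occupation`, `sbp`, `dbp`
#'   (mm Hg), `bmi` (kg/m^2), `smoking` (never/former/current), and `tg`,
#'   `hdl`, `glucose` (mmol/L; `NA` outside the blood-panel wave).
#' @examples
#' survey <- simulate_cohort(default_cohort_config(n_individuals = 300), seed = 1)
#' head(survey)
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  validate_cohort_config(config)
  set.seed(seed)
  waves <- config$wave_years
  t0 <- waves[1]
  n_target <- config$n_individuals
  sp <- config$stratum_proportions
  facs <- names(config$continuous)
  conf <- config$confounding

  ## growing person registry
  sex <- residence <- province <- occupation <- smoking <- character(0)
  education <- integer(0)
  entry_year <- age_entry <- numeric(0)
  ranef_u <- ranef_v <- matrix(numeric(0), 0, length(facs),
                               dimnames = list(NULL, facs))
  active <- logical(0)

  recruit <- function(k, wave_idx) {
    si <- sample.int(nrow(sp), k, replace = TRUE, prob = sp$prop)
    sx <- sp$sex[si]
    p_cur <- config$smoking$current[sx, wave_idx]
    p_ever <- config$smoking$ever[sx]
    urand <- stats::runif(k)
    smk <- ifelse(urand < p_cur, "current",
                  ifelse(urand < p_ever, "former", "never"))
    u <- v <- matrix(0, k, length(facs), dimnames = list(NULL, facs))
    for (f in facs) {
      fc <- config$continuous[[f]]
      u[, f] <- stats::rnorm(k, 0, fc$sd_intercept)
      v[, f] <- stats::rnorm(k, 0, fc$sd_slope)
    }
    list(sex = sx, residence = sp$residence[si],
         province = sample(.provinces, k, replace = TRUE),
         education = sample.int(length(.educations), k, replace = TRUE,
                                prob = education_probs(wave_idx, conf$drift)),
         occupation = sample(.occupations, k, replace = TRUE),
         smoking = smk,
         entry_year = rep(waves[wave_idx], k),
         age_entry = sample_entry_age(sp$age_group[si]),
         u = u, v = v)
  }

  add_people <- function(p) {
    sex <<- c(sex, p$sex); residence <<- c(residence, p$residence)
    province <<- c(province, p$province); education <<- c(education, p$education)
    occupation <<- c(occupation, p$occupation); smoking <<- c(smoking, p$smoking)
    entry_year <<- c(entry_year, p$entry_year)
    age_entry <<- c(age_entry, p$age_entry)
    ranef_u <<- rbind(ranef_u, p$u); ranef_v <<- rbind(ranef_v, p$v)
    active <<- c(active, rep(TRUE, length(p$sex)))
  }

  add_people(recruit(n_target, 1L))

  blood <- config$blood
  tg_meanlog <- log(blood$tg$threshold) -
    blood$tg$sdlog * stats::qnorm(1 - blood$tg$p_high)
  glu_meanlog <- log(blood$glucose$threshold) -
    blood$glucose$sdlog * stats::qnorm(1 - blood$glucose$p_high)
  hdl_mean <- blood$hdl$threshold - blood$hdl$sd * stats::qnorm(blood$hdl$p_low)

  rows <- vector("list", length(waves))
  for (j in seq_along(waves)) {
    yr <- waves[j]
    idx <- which(active)
    k <- length(idx)
    age <- age_entry[idx] + (yr - entry_year[idx])
    strat <- paste(as.character(age_group(age)), sex[idx], residence[idx],
                   sep = "|")
    rec <- data.frame(id = idx, wave = yr, age = age, sex = sex[idx],
                      residence = residence[idx], province = province[idx],
                      education = .educations[education[idx]],
                      occupation = occupation[idx],
                      stringsAsFactors = FALSE)
    for (f in facs) {
      fc <- config$continuous[[f]]
      val <- fc$baseline[strat] + fc$slope[strat] * (yr - t0) +
        ranef_u[idx, f] + ranef_v[idx, f] * (yr - t0) +
        stats::rnorm(k, 0, fc$sd_within)
      eff <- conf$education[f]
      if (!is.na(eff) && eff != 0)
        val <- val + eff * (education[idx] - mean(seq_along(.educations)))
      rec[[f]] <- unname(val)
    }
    ## physiological ordering of the two pressures
    if (all(c("sbp", "dbp") %in% facs))
      rec$dbp <- pmin(rec$dbp, rec$sbp - 5)
    rec$smoking <- smoking[idx]
    if (yr == blood$wave) {
      rec$tg <- stats::rlnorm(k, tg_meanlog, blood$tg$sdlog)
      rec$hdl <- stats::rnorm(k, hdl_mean[sex[idx]], blood$hdl$sd)
      rec$glucose <- stats::rlnorm(k, glu_meanlog, blood$glucose$sdlog)
    } else {
      rec$tg <- rec$hdl <- rec$glucose <- NA_real_
    }
    rows[[j]] <- rec

    if (j < length(waves)) {
      ## quitting-only smoking transitions toward the next wave's targets
      cur_now <- config$smoking$current[, j]
      cur_next <- config$smoking$current[, j + 1]
      hazard <- pmax(0, 1 - cur_next / pmax(cur_now, 1e-12))
      names(hazard) <- rownames(config$smoking$current)
      is_cur <- active & smoking == "current"
      if (any(is_cur)) {
        quit <- stats::runif(sum(is_cur)) < hazard[sex[is_cur]]
        smoking[which(is_cur)[quit]] <- "former"
      }
      ## open-cohort participation: dropout, then replenishment
      stay <- stats::runif(k) < config$participation$retention
      active[idx[!stay]] <- FALSE
      if (isTRUE(config$participation$replenish)) {
        short <- n_target - sum(active)
        if (short > 0) add_people(recruit(short, j + 1L))
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$id, out$wave), ]
  rownames(out) <- NULL
  out
}

#' Write the survey and census tables as delimited text
#'
#' @param survey person-wave table from [simulate_cohort()].
#' @param census reference table from [generate_census()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (`survey.csv`, `census.csv`).
#' @export
write_cohort_tables <- function(survey, census, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(survey = file.path(dir, "survey.csv"),
             census = file.path(dir, "census.csv"))
  utils::write.csv(survey, paths["survey"], row.names = FALSE, na = "")
  utils::write.csv(census, paths["census"], row.names = FALSE, na = "")
  invisible(paths)
}

#' Read a survey or census table written by [write_cohort_tables()]
#'
#' @param path path to the CSV file (empty fields are missing values).
#' @return data.frame.
#' @export
read_cohort_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
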