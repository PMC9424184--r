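## Population-attributable fractions and attributable case counts.
##
## Categorical exposure (Levin form over n categories):
##   PAF = sum_i P_i (RR_i - 1) / (sum_i P_i (RR_i - 1) + 1)
## Continuous exposure, against the TMRED counterfactual P2:
##   PAF = (int RR(x) P1(x) dx - int RR(x) P2(x) dx) / int RR(x) P1(x) dx
## with the integrals over [0, m], m the maximum observed exposure. P1 is the
## standardized empirical sample (exact weighted sum); P2 is the TMRED normal
## truncated to [0, m], integrated by adaptive quadrature.

#' PAF for a categorical exposure
#'
#' @param prevalence per-category population fractions (must sum to 1).
#' @param rr per-category relative risks, aligned with `prevalence`; the
#'   reference category has RR 1.
#' @return PAF point value in (-1, 1).
#' @examples
#' paf_categorical(c(0.5, 0.5), c(1, 3))  # 0.5
#' @export
paf_categorical <- function(prevalence, rr) {
  if (length(prevalence) != length(rr))
    stop("prevalence and rr must have the same length")
  if (any(prevalence < 0)) stop("prevalences must be >= 0")
  if (abs(sum(prevalence) - 1) > 1e-8) stop("prevalences must sum to 1")
  if (any(rr <= 0)) stop("relative risks must be > 0")
  excess <- sum(prevalence * (rr - 1))
  excess / (excess + 1)
}

## Mean RR under the counterfactual TMRED distribution, truncated to [0, m].
counterfactual_mean_rr <- function(spec, m, rr = spec$rr,
                                   rel_tol = 1e-10) {
  mu <- spec$tmred_mean; s <- spec$tmred_sd
  if (m <= 0) stop("maximum exposure level must be > 0")
  mass <- stats::pnorm(m, mu, s) - stats::pnorm(0, mu, s)
  if (mass <= 0) stop("counterfactual distribution has no mass on [0, m]")
  below <- stats::pnorm(min(mu, m), mu, s) - stats::pnorm(0, mu, s)
  above <- if (m > mu)
    stats::integrate(function(x) rr^((x - mu) / spec$unit_increment) *
                       stats::dnorm(x, mu, s),
                     mu, m, rel.tol = rel_tol)$value
  else 0
  (below + above) / mass
}

#' PAF for a continuous exposure against its TMRED
#'
#' The factual integral is the exact weighted mean of RR(x) over the
#' standardized empirical sample; the counterfactual integral is adaptive
#' quadrature of RR(x) against the TMRED normal truncated to [0, m], with m
#' the maximum observed exposure. A non-positive PAF (exposure distribution
#' no worse than the counterfactual) is returned with a warning.
#'
#' @param p1 a `standardized_distribution` from [standardized_sample()].
#' @param spec a continuous [risk_factor_spec()].
#' @param rr optional per-increment RR override (uncertainty draws).
#' @return PAF point value (< 1).
#' @export
paf_continuous <- function(p1, spec, rr = spec$rr) {
  if (spec$kind != "continuous")
    stop(spec$name, " is categorical; use paf_categorical()")
  w <- p1$weights
  if (sum(w) <= 0) stop("distribution weights must have positive total")
  w <- w / sum(w)
  e1 <- sum(w * rr_continuous(spec, p1$values, rr = rr))
  e2 <- counterfactual_mean_rr(spec, max(p1$values), rr = rr)
  paf <- (e1 - e2) / e1
  if (paf < 0)
    warning(spec$name, ": non-positive PAF (exposure below the counterfactual)")
  paf
}

#' Total disease cases from prevalence and population
#'
#' @param prevalence disease prevalence in the population, in `[0, 1]`.
#' @param population number of persons.
#' @return expected case count (unrounded persons).
#' @examples
#' total_cases(0.108, 846662309) / 1e6  # 91.44 million
#' @export
total_cases <- function(prevalence, population) {
  if (prevalence < 0 || prevalence > 1) stop("prevalence must lie in [0, 1]")
  if (population < 0) stop("population must be >= 0")
  prevalence * population
}

#' Attributable cases from a PAF
#'
#' @param paf population-attributable fraction (< 1; negative allowed for a
#'   protective exposure pattern, returned with a warning).
#' @param total total case count.
#' @return attributable case count (persons).
#' @examples
#' attributable_cases(0.087, total_cases(0.108, 846662309)) / 1e6  # ~ 7.96
#' @export
attributable_cases <- function(paf, total) {
  if (any(paf >= 1)) stop("PAF must be < 1")
  if (any(total < 0)) stop("total cases must be >= 0")
  out <- paf * total
  if (any(out < 0)) warning("negative attributable cases (protective pattern)")
  out
}

## Exposure input for a spec at one wave: a standardized_distribution for
## continuous factors, a named prevalence vector (spec category order) for
## categorical ones. Blood measurements are classified by threshold first.
exposure_input <- function(survey, census, spec, wave) {
  if (spec$kind == "continuous")
    return(standardized_sample(survey, census, spec$exposure, wave))
  if (is.null(spec$threshold)) {
    prev <- standardized_prevalence(survey, census, spec$exposure, wave,
                                    categories = names(spec$rr))
  } else {
    survey$.category <- exposure_category(spec, survey[[spec$exposure]],
                                          survey$sex)
    prev <- standardized_prevalence(survey, census, ".category", wave,
                                    categories = names(spec$rr))
  }
  stats::setNames(prev$prevalence, prev$category)
}

## PAF for either kind from a prepared exposure input and an RR draw.
paf_from_input <- function(input, spec, rr) {
  if (spec$kind == "continuous") paf_continuous(input, spec, rr = rr)
  else paf_categorical(input[names(spec$rr)], rr)
}

#' Attributable burden with Monte-Carlo confidence intervals
#'
#' Computes the PAF and attributable case count for one risk factor at one
#' wave, with uncertainty propagated by Monte Carlo: each draw samples the
#' relative risks from their CIs ([rr_draw()]) and the disease prevalence
#' from a normal on the logit scale matched to its CI, then recomputes the
#' PAF and the case count. The reported interval is the 2.5/97.5 percentile
#' range; the point estimate uses the point inputs, not the draw mean.
#'
#' @inheritParams standardized_mean
#' @param spec a [risk_factor_spec()].
#' @param prevalence disease prevalence point estimate.
#' @param prevalence_ci length-2 vector, 95% CI of the prevalence.
#' @param population reference population size (persons).
#' @param wave survey year the exposure is taken from.
#' @param n_draws Monte-Carlo draws (>= 1000 recommended).
#' @param seed seed for the draw stream.
#' @return object of class `burden_estimate`: list with `factor`, `wave`,
#'   `paf` (point, lower, upper), `total` and `attributable` case counts with
#'   intervals, `n_draws`, `seed`.
#' @export
burden_with_ci <- function(survey, census, spec, prevalence,
                           prevalence_ci = c(prevalence, prevalence),
                           population, wave, n_draws = 1000, seed = 1L) {
  if (prevalence_ci[1] > prevalence || prevalence_ci[2] < prevalence)
    stop("prevalence CI must bracket the point estimate")
  input <- exposure_input(survey, census, spec, wave)
  paf_point <- suppressWarnings(paf_from_input(input, spec, spec$rr))
  total_point <- total_cases(prevalence, population)

  set.seed(seed)
  rrs <- rr_draw(spec, n_draws)
  prev_draws <- if (diff(prevalence_ci) == 0) rep(prevalence, n_draws) else
    stats::plogis(stats::rnorm(n_draws, stats::qlogis(prevalence),
                               (stats::qlogis(prevalence_ci[2]) -
                                stats::qlogis(prevalence_ci[1])) /
                                 (2 * stats::qnorm(0.975))))
  paf_draws <- if (spec$kind == "continuous")
    vapply(rrs, function(r) suppressWarnings(
      paf_from_input(input, spec, r)), numeric(1))
  else
    vapply(seq_len(n_draws), function(i) suppressWarnings(
      paf_from_input(input, spec, rrs[i, ])), numeric(1))
  case_draws <- paf_draws * prev_draws * population
  q <- function(v) unname(stats::quantile(v, c(0.025, 0.975)))
  structure(
    list(factor = spec$name, wave = wave,
         paf = c(point = paf_point, q2.5 = q(paf_draws)[1],
                 q97.5 = q(paf_draws)[2]),
         total = c(point = total_point,
                   q2.5 = q(prev_draws * population)[1],
                   q97.5 = q(prev_draws * population)[2]),
         attributable = c(point = attributable_cases(paf_point, total_point),
                          q2.5 = q(case_draws)[1], q97.5 = q(case_draws)[2]),
         n_draws = n_draws, seed = seed),
    class = "burden_estimate")
}

#' @export
print.burden_estimate <- function(x, ...) {
  cat(sprintf("%s, wave %s\n", x$factor, x$wave))
  cat(sprintf("  PAF %.1f%% (95%% CI %.1f-%.1f)\n", 100 * x$paf["point"],
              100 * x$paf["q2.5"], 100 * x$paf["q97.5"]))
  cat(sprintf("  attributable cases %.1f (95%% CI %.1f-%.1f) million\n",
              x$attributable["point"] / 1e6, x$attributable["q2.5"] / 1e6,
              x$attributable["q97.5"] / 1e6))
  invisible(x)
}

#' Attributable-case series across waves at a fixed case total
#'
#' Applies one total case count (the 2011 total) to the PAF of every wave, so
#' the series reflects exposure change only — the stated convention of the
#' time-trend analysis, which ignores aging and population growth and is
#' known to overstate early-period burden.
#'
#' @param pafs data.frame with columns `wave` and `paf` (optionally
#'   `paf_lower`, `paf_upper`).
#' @param total total case count applied to all waves.
#' @return `pafs` with attributable-case columns added.
#' @export
attributable_series <- function(pafs, total) {
  pafs$attributable <- attributable_cases(pafs$paf, total)
  if (all(c("paf_lower", "paf_upper") %in% names(pafs))) {
    pafs$attributable_lower <- pafs$paf_lower * total
    pafs$attributable_upper <- pafs$paf_upper * total
  }
  pafs
}
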