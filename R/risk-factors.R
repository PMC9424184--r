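## Risk-factor registry: theoretical minimum risk exposure distributions
## (TMREDs) and relative risks with 95% CIs, plus the dose-response and
## sampling rules used by the attribution stage.

#' Construct a risk-factor specification
#'
#' A risk factor is either continuous — a TMRED mean (SD) in exposure units
#' and a relative risk per `unit_increment` above the TMRED — or categorical,
#' with per-category RRs and one reference category at RR 1. Categorical
#' blood factors carry the threshold that classifies the continuous
#' measurement; for HDL-C the threshold is sex-specific.
#'
#' @param name short factor name; must match the survey column via `exposure`.
#' @param kind `"continuous"` or `"categorical"`.
#' @param exposure survey column holding the measurement.
#' @param label human-readable description.
#' @param tmred_mean,tmred_sd TMRED mean and SD (continuous only).
#' @param unit_increment exposure increment the RR refers to (continuous only).
#' @param rr,rr_low,rr_high relative risk and 95% CI: scalars per increment
#'   (continuous) or named per-category vectors including the reference at 1
#'   (categorical).
#' @param reference reference category name (categorical only).
#' @param threshold classification threshold for blood factors: scalar, or a
#'   named per-sex vector; `direction` says which side is the exposed
#'   category.
#' @param direction `"above"` or `"below"` (categorical blood factors).
#' @return object of class `risk_factor_spec`.
#' @export
risk_factor_spec <- function(name, kind, exposure = name, label = name,
                             tmred_mean = NULL, tmred_sd = NULL,
                             unit_increment = NULL,
                             rr, rr_low, rr_high,
                             reference = NULL, threshold = NULL,
                             direction = NULL) {
  kind <- match.arg(kind, c("continuous", "categorical"))
  spec <- structure(
    list(name = name, kind = kind, exposure = exposure, label = label,
         tmred_mean = tmred_mean, tmred_sd = tmred_sd,
         unit_increment = unit_increment,
         rr = rr, rr_low = rr_low, rr_high = rr_high,
         reference = reference, threshold = threshold, direction = direction),
    class = "risk_factor_spec")
  validate_risk_factor_spec(spec)
  spec
}

validate_risk_factor_spec <- function(spec) {
  if (any(spec$rr <= 0)) stop(spec$name, ": relative risks must be > 0")
  if (any(spec$rr_low > spec$rr | spec$rr > spec$rr_high))
    stop(spec$name, ": CI must bracket the point RR")
  if (spec$kind == "continuous") {
    if (is.null(spec$tmred_sd) || spec$tmred_sd <= 0)
      stop(spec$name, ": tmred_sd must be > 0")
    if (is.null(spec$unit_increment) || spec$unit_increment <= 0)
      stop(spec$name, ": unit_increment must be > 0")
  } else {
    if (is.null(spec$reference) || !spec$reference %in% names(spec$rr))
      stop(spec$name, ": reference category must be among the RR names")
    if (spec$rr[spec$reference] != 1)
      stop(spec$name, ": the reference category must have RR 1")
  }
  invisible(spec)
}

#' Built-in CKD risk-factor registry
#'
#' The seven modifiable risk factors with their TMREDs and meta-analytic
#' relative risks: high BMI (TMRED 21 (1) kg/m^2, RR 1.02 per kg/m^2), high
#' SBP (115 (6) mm Hg, RR 1.08 per 10 mm Hg), high DBP (75 (6) mm Hg, RR
#' 1.12 per 10 mm Hg), smoking (current 1.34, former/ever 1.27 vs never),
#' high TG (>1.7 mmol/L, RR 1.32), low HDL-C (<1.1 male / <0.9 female
#' mmol/L, RR 1.24), and high plasma glucose (>5.6 mmol/L, RR 1.89).
#'
#' @param smoking `"two"` (default) contrasts current smoking against
#'   not currently smoking (former smokers grouped with the reference),
#'   the contrast behind the published current-smoking burden; `"three"`
#'   additionally assigns the ever-smoking RR 1.27 to former smokers.
#' @return named list of seven [risk_factor_spec()] objects.
#' @export
ckd_risk_factors <- function(smoking = c("two", "three")) {
  smoking <- match.arg(smoking)
  smk <- if (smoking == "three")
    list(rr = c(never = 1, former = 1.27, current = 1.34),
         rr_low = c(never = 1, former = 1.19, current = 1.23),
         rr_high = c(never = 1, former = 1.35, current = 1.47))
  else
    list(rr = c(never = 1, former = 1, current = 1.34),
         rr_low = c(never = 1, former = 1, current = 1.23),
         rr_high = c(never = 1, former = 1, current = 1.47))
  list(
    bmi = risk_factor_spec("bmi", "continuous", label = "High body mass index",
                           tmred_mean = 21, tmred_sd = 1, unit_increment = 1,
                           rr = 1.02, rr_low = 1.01, rr_high = 1.03),
    sbp = risk_factor_spec("sbp", "continuous",
                           label = "High systolic blood pressure",
                           tmred_mean = 115, tmred_sd = 6, unit_increment = 10,
                           rr = 1.08, rr_low = 1.04, rr_high = 1.11),
    dbp = risk_factor_spec("dbp", "continuous",
                           label = "High diastolic blood pressure",
                           tmred_mean = 75, tmred_sd = 6, unit_increment = 10,
                           rr = 1.12, rr_low = 1.04, rr_high = 1.20),
    smoking = risk_factor_spec("smoking", "categorical", label = "Smoking",
                               rr = smk$rr, rr_low = smk$rr_low,
                               rr_high = smk$rr_high, reference = "never"),
    tg = risk_factor_spec("tg", "categorical", label = "High triglycerides",
                          rr = c(normal = 1, high = 1.32),
                          rr_low = c(normal = 1, high = 1.15),
                          rr_high = c(normal = 1, high = 1.51),
                          reference = "normal", threshold = 1.7,
                          direction = "above"),
    hdl = risk_factor_spec("hdl", "categorical", label = "Low HDL cholesterol",
                           rr = c(normal = 1, low = 1.24),
                           rr_low = c(normal = 1, low = 1.04),
                           rr_high = c(normal = 1, low = 1.47),
                           reference = "normal",
                           threshold = c(male = 1.1, female = 0.9),
                           direction = "below"),
    glucose = risk_factor_spec("glucose", "categorical",
                               label = "High plasma glucose",
                               rr = c(normal = 1, high = 1.89),
                               rr_low = c(normal = 1, high = 1.51),
                               rr_high = c(normal = 1, high = 2.37),
                               reference = "normal", threshold = 5.6,
                               direction = "above")
  )
}

#' Relative risk at a continuous exposure level
#'
#' Log-linear dose-response: RR(x) = rr^((x - tmred_mean) / unit_increment)
#' above the TMRED mean, floored at 1 at or below it (no protective
#' extrapolation below the minimum-risk level).
#'
#' @param spec a continuous [risk_factor_spec()].
#' @param x exposure values.
#' @param rr optional per-increment RR overriding the point estimate (used
#'   for uncertainty draws).
#' @return relative risks, same length as `x`.
#' @export
rr_continuous <- function(spec, x, rr = spec$rr) {
  if (spec$kind != "continuous")
    stop(spec$name, " is categorical; use rr_category()")
  if (any(!is.finite(x))) stop("exposure values must be finite")
  ifelse(x <= spec$tmred_mean, 1,
         rr^((x - spec$tmred_mean) / spec$unit_increment))
}

#' Relative risk of an exposure category
#'
#' @param spec a categorical [risk_factor_spec()].
#' @param category category labels (e.g. `"current"`).
#' @param sex unused for the RR itself (categorical RRs are sex-invariant);
#'   accepted so classification helpers can share a signature.
#' @return relative risks.
#' @export
rr_category <- function(spec, category, sex = NULL) {
  if (spec$kind != "categorical")
    stop(spec$name, " is continuous; use rr_continuous()")
  category <- as.character(category)
  if (!all(category %in% names(spec$rr)))
    stop(spec$name, ": unknown category ",
         paste(setdiff(category, names(spec$rr)), collapse = ", "))
  unname(spec$rr[category])
}

#' Classify a continuous blood measurement into spec categories
#'
#' Applies the spec's threshold (sex-specific for HDL-C): `direction =
#' "above"` marks values above the threshold as the exposed category,
#' `"below"` marks values below it.
#'
#' @param spec a categorical [risk_factor_spec()] with a threshold.
#' @param value measurements (mmol/L).
#' @param sex per-observation sex; required when the threshold is sex-specific.
#' @return character vector of categories (`NA` where value is missing).
#' @export
exposure_category <- function(spec, value, sex = NULL) {
  if (is.null(spec$threshold))
    stop(spec$name, " has no classification threshold")
  thr <- if (length(spec$threshold) > 1) {
    if (is.null(sex)) stop(spec$name, ": sex needed for sex-specific threshold")
    spec$threshold[as.character(sex)]
  } else rep(spec$threshold, length(value))
  exposed <- setdiff(names(spec$rr), spec$reference)
  out <- rep(NA_character_, length(value))
  ok <- !is.na(value)
  hit <- if (spec$direction == "above") value > thr else value < thr
  out[ok] <- ifelse(hit[ok], exposed, spec$reference)
  out
}

#' Sample relative risks from their confidence intervals
#'
#' Draws log-normal relative risks: log RR ~ Normal(log rr,
#' (log rr_high - log rr_low) / (2 * 1.96)). The reference category (RR 1
#' with a zero-width CI) stays at 1 in every draw.
#'
#' @param spec a [risk_factor_spec()].
#' @param n number of draws.
#' @return for continuous specs a numeric vector of per-increment RRs; for
#'   categorical specs an `n` x categories matrix.
#' @export
rr_draw <- function(spec, n = 1) {
  sigma <- (log(spec$rr_high) - log(spec$rr_low)) / (2 * stats::qnorm(0.975))
  if (spec$kind == "continuous") {
    exp(stats::rnorm(n, log(spec$rr), sigma))
  } else {
    draws <- vapply(seq_along(spec$rr), function(j) {
      if (sigma[j] == 0) rep(spec$rr[j], n)
      else exp(stats::rnorm(n, log(spec$rr[j]), sigma[j]))
    }, numeric(n))
    if (n == 1) draws <- matrix(draws, nrow = 1)
    colnames(draws) <- names(spec$rr)
    draws
  }
}

#' @export
print.risk_factor_spec <- function(x, ...) {
  cat(sprintf("Risk factor: %s (%s, %s)\n", x$name, x$label, x$kind))
  if (x$kind == "continuous") {
    cat(sprintf("  TMRED %s (%s), RR %.2f (%.2f-%.2f) per %s unit(s)\n",
                x$tmred_mean, x$tmred_sd, x$rr, x$rr_low, x$rr_high,
                x$unit_increment))
  } else {
    for (cc in names(x$rr))
      cat(sprintf("  %s: RR %.2f (%.2f-%.2f)%s\n", cc, x$rr[cc],
                  x$rr_low[cc], x$rr_high[cc],
                  if (cc == x$reference) " [reference]" else ""))
  }
  invisible(x)
}
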