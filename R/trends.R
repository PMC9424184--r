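## Wave means adjusted for covariates, and the linear trend test with
## calendar year as a scored (numeric) regressor. Both are fixed-effects
## least-squares fits; the trend test uses cluster-robust standard errors by
## person to respect the repeated measures (a documented simplification of a
## mixed model, validated by simulation).

default_covariates <- c("age", "sex", "residence", "education",
                        "occupation", "province")

prepare_covariates <- function(d, covariates) {
  covariates <- intersect(covariates, names(d))
  keep <- vapply(covariates, function(v) length(unique(d[[v]])) > 1, logical(1))
  covariates[keep]
}

trend_response <- function(d, factor) {
  x <- d[[factor]]
  if (is.numeric(x)) x else as.numeric(as.character(x) == "current")
}

#' Covariate-adjusted wave means
#'
#' Least-squares means of an exposure per survey wave, adjusted for
#' demographic and socioeconomic covariates with a fixed-effects linear
#' model. The adjusted mean for wave w is the average model prediction over
#' the pooled covariate distribution with the wave set to w (G-computation),
#' so waves are compared at a common covariate profile. With no confounding
#' the adjusted means coincide with the crude wave means.
#'
#' @inheritParams standardized_mean
#' @param covariates covariate columns to adjust for; constants are dropped.
#' @return data.frame with `wave`, `mean`, `se`.
#' @export
adjusted_means <- function(survey, factor,
                           covariates = default_covariates) {
  d <- survey[!is.na(survey[[factor]]), , drop = FALSE]
  waves <- sort(unique(d$wave))
  if (length(waves) < 2) stop("adjusted_means needs at least 2 waves")
  covariates <- prepare_covariates(d, covariates)
  d$.wave <- base::factor(d$wave, levels = waves)
  fml <- stats::reformulate(c(".wave", covariates), response = factor)
  fit <- stats::lm(fml, data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("collinear covariates in adjustment model: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  V <- stats::vcov(fit)
  tt <- stats::delete.response(stats::terms(fit))
  out <- lapply(waves, function(w) {
    nd <- d
    nd$.wave <- base::factor(w, levels = waves)
    L <- colMeans(stats::model.matrix(tt, nd, xlev = fit$xlevels))
    data.frame(wave = w, mean = sum(L * cf),
               se = sqrt(drop(t(L) %*% V %*% L)))
  })
  do.call(rbind, out)
}

#' Linear trend test with year as a scored variable
#'
#' Tests for a secular trend in an exposure by regressing it on calendar year
#' (numeric) with covariate adjustment, in the full cohort or within one
#' joint stratum. Standard errors are cluster-robust by person id to account
#' for repeated measures; the p-value uses a t reference with
#' (clusters - 1) degrees of freedom. For smoking the response is the
#' current-smoking indicator (linear probability model), so the slope is in
#' prevalence units per year.
#'
#' @inheritParams adjusted_means
#' @param stratum `NULL` for the whole cohort, or one stratum label such as
#'   `"18-39|male|urban"` (see [assign_stratum()]); sex-only or
#'   residence-only subsets can be requested as e.g. `"male"` or `"rural"`.
#' @return object of class `trend_result`: data.frame with `factor`,
#'   `stratum`, `slope` (exposure units per year), `se`, `statistic`,
#'   `p_value`, `n_individuals`, `n_obs`.
#' @export
trend_test <- function(survey, factor, stratum = NULL,
                       covariates = default_covariates) {
  d <- survey[!is.na(survey[[factor]]), , drop = FALSE]
  if (!is.null(stratum)) {
    s <- assign_stratum(d$age, d$sex, d$residence)
    keep <- if (stratum %in% all_strata()$stratum) s$stratum == stratum
            else if (stratum %in% .sexes) d$sex == stratum
            else if (stratum %in% .residences) d$residence == stratum
            else if (stratum %in% .age_groups) s$age_group == stratum
            else stop("unknown stratum: ", stratum)
    d <- d[keep, , drop = FALSE]
  }
  if (length(unique(d$wave)) < 3)
    stop("trend_test needs data in at least 3 waves",
         if (!is.null(stratum)) paste0(" (stratum ", stratum, ")") else "")
  d$.y <- trend_response(d, factor)
  d$.year <- d$wave
  covariates <- prepare_covariates(d, covariates)
  fml <- stats::reformulate(c(".year", covariates), response = ".y")
  fit <- stats::lm(fml, data = d)
  vc <- sandwich::vcovCL(fit, cluster = d$id)
  slope <- stats::coef(fit)[".year"]
  se <- sqrt(vc[".year", ".year"])
  g <- length(unique(d$id))
  stat <- slope / se
  res <- data.frame(factor = factor,
                    stratum = if (is.null(stratum)) "overall" else stratum,
                    slope = unname(slope), se = unname(se),
                    statistic = unname(stat),
                    p_value = 2 * stats::pt(-abs(stat), df = g - 1),
                    n_individuals = g, n_obs = nrow(d),
                    stringsAsFactors = FALSE)
  class(res) <- c("trend_result", "data.frame")
  res
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Trend in %s (%s): %+.4g per year (SE %.3g), p = %.3g\n",
              x$factor, x$stratum, x$slope, x$se, x$p_value))
  invisible(x)
}
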