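## Exposure projection: a two-stage random-effects trend per joint stratum
## among participants observed in at least three waves. Stage one fits an
## ordinary least-squares slope per individual; stage two pools the
## individual slopes with inverse-variance weights and a DerSimonian-Laird
## between-individual variance component.

#' Fit a per-stratum random-effects exposure trend
#'
#' Two-stage estimator: for every individual with at least `min_waves`
#' measurements inside the stratum, an OLS slope of exposure on calendar year
#' is fitted; the stratum slope is the inverse-variance-weighted mean of the
#' individual slopes with a DerSimonian-Laird (method-of-moments)
#' between-individual slope variance. Slope sampling variances use the
#' stratum-pooled residual variance scaled by each individual's year spread:
#' individual fits have 1-3 residual degrees of freedom, and constant
#' trajectories (e.g. lifelong never-smokers) would otherwise report zero
#' variance and receive infinite weight. For smoking the response is the
#' current-smoking indicator, so the slope is prevalence per year.
#'
#' @inheritParams standardized_mean
#' @param stratum stratum label, e.g. `"40-59|male|rural"`.
#' @param min_waves minimum number of waves per eligible individual.
#' @return object of class `stratum_trend`: list with `factor`, `stratum`,
#'   `slope` (units/year), `se`, `tau2` (between-individual slope variance),
#'   `n_individuals`.
#' @export
fit_stratum_trend <- function(survey, factor, stratum, min_waves = 3) {
  d <- survey[!is.na(survey[[factor]]), , drop = FALSE]
  s <- assign_stratum(d$age, d$sex, d$residence)
  d <- d[s$stratum == stratum, , drop = FALSE]
  d$.y <- trend_response(d, factor)
  pieces <- split(d[, c("wave", ".y")], d$id)
  est <- lapply(pieces, function(p) {
    p <- p[!duplicated(p$wave), , drop = FALSE]
    if (nrow(p) < min_waves) return(NULL)
    t <- p$wave - mean(p$wave)
    sxx <- sum(t^2)
    b <- sum(t * p$.y) / sxx
    res <- p$.y - mean(p$.y) - b * t
    c(b = b, sxx = sxx, rss = sum(res^2), df = max(0, nrow(p) - 2))
  })
  est <- do.call(rbind, Filter(Negate(is.null), est))
  if (is.null(est) || nrow(est) < 2)
    stop("fewer than 2 individuals with >= ", min_waves,
         " waves in stratum ", stratum)
  b <- est[, "b"]
  k <- length(b)
  ## sampling variance of each slope from the stratum-pooled residual
  ## variance (individual fits have too few degrees of freedom to estimate
  ## their own), scaled by each individual's year spread
  s2p <- if (sum(est[, "df"]) > 0) sum(est[, "rss"]) / sum(est[, "df"]) else 0
  v <- s2p / est[, "sxx"]
  if (max(v) < 1e-12) {
    ## noise-free trajectories: slopes are exact
    vb <- stats::var(b)
    tau2 <- if (vb > 1e-24) vb else 0
    slope <- mean(b)
    se <- sqrt(tau2 / k)
  } else {
    w <- 1 / v
    bw <- sum(w * b) / sum(w)
    q <- sum(w * (b - bw)^2)
    tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    wstar <- 1 / (v + tau2)
    slope <- sum(wstar * b) / sum(wstar)
    se <- sqrt(1 / sum(wstar))
  }
  structure(list(factor = factor, stratum = stratum, slope = slope, se = se,
                 tau2 = tau2, n_individuals = k),
            class = "stratum_trend")
}

#' @export
print.stratum_trend <- function(x, ...) {
  cat(sprintf(
    "Stratum trend, %s in %s: %+.4g per year (SE %.3g), tau^2 = %.3g, n = %d\n",
    x$factor, x$stratum, x$slope, x$se, x$tau2, x$n_individuals))
  invisible(x)
}

#' Project an exposure mean forward
#'
#' Linear extrapolation from the last observed (standardized) value:
#' `anchor_value + slope * (target_year - anchor_year)`. Proportions are
#' clipped to `[0, 1]`.
#'
#' @param model a `stratum_trend` (or any list with a `slope`).
#' @param target_year year to project to (>= `anchor_year`).
#' @param anchor_value last observed standardized mean (or prevalence).
#' @param anchor_year year of the anchor value.
#' @param proportion clip the projection to `[0, 1]`?
#' @return projected mean.
#' @export
project_mean <- function(model, target_year, anchor_value, anchor_year,
                         proportion = FALSE) {
  if (any(target_year < anchor_year))
    stop("target_year must be >= anchor_year")
  out <- anchor_value + model$slope * (target_year - anchor_year)
  if (proportion) out <- pmin(1, pmax(0, out))
  out
}

#' Shift a standardized distribution to a projected mean
#'
#' Location shift: every exposure value moves by (projected mean - current
#' weighted mean); weights, shape and variance are unchanged. This supplies
#' the full projected population distribution P1 that the continuous PAF
#' integral needs, under the assumption that the distribution translates
#' with its mean.
#'
#' @param base a `standardized_distribution`.
#' @param projected_mean target weighted mean.
#' @return a shifted `standardized_distribution`.
#' @export
project_distribution <- function(base, projected_mean) {
  base$values <- base$values + (projected_mean - distribution_mean(base))
  base
}

## Census-weighted overall slope from the 16 per-stratum trend fits.
overall_slope <- function(survey, factor, census, min_waves = 3) {
  w <- census_weights(census)
  fits <- lapply(names(w), function(s)
    fit_stratum_trend(survey, factor, s, min_waves = min_waves))
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  ses <- vapply(fits, `[[`, numeric(1), "se")
  list(slope = sum(w * slopes), se = sqrt(sum(w^2 * ses^2)), fits = fits)
}

#' Projected attributable burden
#'
#' Projects each trend factor's exposure forward with the per-stratum
#' random-effects slopes (census-weighted to an overall slope), recomputes
#' the PAF each year — via a location-shifted standardized distribution for
#' continuous factors, via extrapolated current-smoking prevalence (clipped
#' to `[0, 1]`, never-smoking held fixed) for smoking — and multiplies by the
#' anchor-year total case count. Intervals come from relative-risk draws as
#' in [burden_with_ci()].
#'
#' @inheritParams standardized_mean
#' @param specs named list of [risk_factor_spec()]s; only the longitudinal
#'   factors (`sbp`, `dbp`, `bmi`, `smoking`) are projected.
#' @param years projection years (default 2013-2031, biennial).
#' @param total total case count applied to every projected year.
#' @param min_waves eligibility threshold for the trend fits.
#' @param n_draws,seed Monte-Carlo settings for the intervals.
#' @return data.frame with one row per factor-year: projected `exposure`
#'   (mean or current-smoking prevalence), `paf` with interval, and
#'   `attributable` cases with interval.
#' @export
projected_burden <- function(survey, census, specs = ckd_risk_factors(),
                             years = seq(2013, 2031, by = 2), total,
                             min_waves = 3, n_draws = 1000, seed = 1L) {
  anchor_year <- max(survey$wave)
  facs <- intersect(names(specs), c("sbp", "dbp", "bmi", "smoking"))
  if (!length(facs)) stop("no projectable factors in specs")
  set.seed(seed)
  out <- list()
  for (f in facs) {
    spec <- specs[[f]]
    ov <- overall_slope(survey, f, census, min_waves = min_waves)
    rrs <- rr_draw(spec, n_draws)
    if (spec$kind == "continuous") {
      anchor <- standardized_mean(survey, census, f, anchor_year)$mean
      base <- standardized_sample(survey, census, f, anchor_year)
      for (y in years) {
        pm <- project_mean(ov, y, anchor, anchor_year)
        p1 <- project_distribution(base, pm)
        paf <- suppressWarnings(paf_continuous(p1, spec))
        draws <- vapply(rrs, function(r) suppressWarnings(
          paf_continuous(p1, spec, rr = r)), numeric(1))
        out[[length(out) + 1]] <- data.frame(
          factor = f, year = y, exposure = pm, paf = paf,
          paf_lower = unname(stats::quantile(draws, 0.025)),
          paf_upper = unname(stats::quantile(draws, 0.975)),
          stringsAsFactors = FALSE)
      }
    } else {
      prev <- standardized_prevalence(survey, census, f, anchor_year,
                                      categories = names(spec$rr))
      p <- stats::setNames(prev$prevalence, prev$category)
      never <- p[spec$reference]
      for (y in years) {
        cur <- project_mean(ov, y, p["current"], anchor_year,
                            proportion = TRUE)
        cur <- min(cur, 1 - never)
        proj <- c(never = unname(never), former = unname(1 - never - cur),
                  current = unname(cur))[names(spec$rr)]
        paf <- paf_categorical(proj, spec$rr)
        draws <- vapply(seq_len(n_draws), function(i)
          paf_categorical(proj, rrs[i, names(spec$rr)]), numeric(1))
        out[[length(out) + 1]] <- data.frame(
          factor = f, year = y, exposure = unname(cur), paf = paf,
          paf_lower = unname(stats::quantile(draws, 0.025)),
          paf_upper = unname(stats::quantile(draws, 0.975)),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  attributable_series(res, total)
}
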