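## Direct standardization of exposure distributions to the census strata.
## Every statistic is a census-share-weighted combination of within-stratum
## sample statistics; empty strata with positive census weight are a hard
## error (no silent renormalization).

wave_subset <- function(survey, factor, wave) {
  if (!factor %in% names(survey)) stop("unknown factor column: ", factor)
  if (!wave %in% survey$wave) stop("wave ", wave, " not present in survey")
  d <- survey[survey$wave == wave & !is.na(survey[[factor]]), , drop = FALSE]
  if (nrow(d) == 0) stop("no non-missing observations of ", factor,
                         " in wave ", wave)
  d$`.stratum` <- assign_stratum(d$age, d$sex, d$residence)$stratum
  d
}

check_strata_covered <- function(d, weights) {
  missing <- setdiff(names(weights), unique(d$`.stratum`))
  if (length(missing))
    stop("census strata with positive weight but no observations: ",
         paste(missing, collapse = ", "))
}

#' Census-standardized mean of a continuous exposure
#'
#' Directly standardizes the wave-specific exposure distribution to the
#' reference census: mean = sum over strata of (census share) x (stratum
#' sample mean). The standard error follows from the weighted combination of
#' independent stratum means, `sqrt(sum(W_s^2 var_s / n_s))`. Missing
#' exposure values are dropped (complete case) before standardization.
#'
#' @param survey person-wave table (see [simulate_cohort()] for columns).
#' @param census reference table (see [generate_census()]).
#' @param factor name of a numeric exposure column (e.g. `"sbp"`).
#' @param wave survey year.
#' @return list with `mean`, `se` and `n` (observations used).
#' @export
standardized_mean <- function(survey, census, factor, wave) {
  d <- wave_subset(survey, factor, wave)
  w <- census_weights(census)
  check_strata_covered(d, w)
  x <- d[[factor]]
  g <- factor(d$`.stratum`, levels = names(w))
  m <- tapply(x, g, mean)
  v <- tapply(x, g, stats::var)
  n <- tapply(x, g, length)
  v[is.na(v)] <- 0  # singleton stratum: no variance contribution
  list(mean = sum(w * m), se = sqrt(sum(w^2 * v / n)), n = nrow(d))
}

#' Census-standardized category prevalences
#'
#' Applies direct standardization to category indicators of a categorical
#' exposure (e.g. smoking status): each category's prevalence is the
#' census-weighted mean of the within-stratum indicator means. Prevalences
#' sum to 1 across categories.
#'
#' @inheritParams standardized_mean
#' @param factor name of a categorical exposure column (e.g. `"smoking"`).
#' @param categories optional category order; defaults to the sorted observed
#'   categories.
#' @return data.frame with `category`, `prevalence`, `se`.
#' @export
standardized_prevalence <- function(survey, census, factor, wave,
                                    categories = NULL) {
  d <- wave_subset(survey, factor, wave)
  w <- census_weights(census)
  check_strata_covered(d, w)
  obs <- as.character(d[[factor]])
  if (is.null(categories)) categories <- sort(unique(obs))
  if (!all(obs %in% categories))
    stop("observed categories outside 'categories': ",
         paste(setdiff(obs, categories), collapse = ", "))
  out <- lapply(categories, function(cc) {
    ind <- as.numeric(obs == cc)
    g <- factor(d$`.stratum`, levels = names(w))
    m <- tapply(ind, g, mean)
    v <- tapply(ind, g, stats::var)
    n <- tapply(ind, g, length)
    v[is.na(v)] <- 0
    data.frame(category = cc, prevalence = sum(w * m),
               se = sqrt(sum(w^2 * v / n)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Census-standardized empirical exposure distribution
#'
#' Builds the standardized population distribution of exposure P1(x) as a
#' weighted empirical sample: each observation in stratum s carries weight
#' W_s / n_s (census share over stratum sample size), so weights sum to 1 and
#' the weighted mean equals [standardized_mean()] exactly.
#'
#' @inheritParams standardized_mean
#' @return object of class `standardized_distribution`: list with `values`,
#'   `weights`, `factor`, `wave`.
#' @export
standardized_sample <- function(survey, census, factor, wave) {
  d <- wave_subset(survey, factor, wave)
  w <- census_weights(census)
  check_strata_covered(d, w)
  n_s <- table(factor(d$`.stratum`, levels = names(w)))
  wt <- as.numeric(w[d$`.stratum`] / n_s[d$`.stratum`])
  structure(list(values = d[[factor]], weights = wt,
                 factor = factor, wave = wave),
            class = "standardized_distribution")
}

#' @export
print.standardized_distribution <- function(x, ...) {
  cat("Standardized exposure distribution:", x$factor, "in wave", x$wave, "\n")
  cat(sprintf("  n = %d, weighted mean = %.4f, weighted SD = %.4f\n",
              length(x$values), distribution_mean(x),
              sqrt(distribution_var(x))))
  invisible(x)
}

#' Weighted mean of a standardized distribution
#' @param dist a `standardized_distribution`.
#' @return numeric scalar.
#' @export
distribution_mean <- function(dist) sum(dist$weights * dist$values)

#' Weighted variance of a standardized distribution
#' @param dist a `standardized_distribution`.
#' @return numeric scalar.
#' @export
distribution_var <- function(dist) {
  m <- distribution_mean(dist)
  sum(dist$weights * (dist$values - m)^2)
}
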