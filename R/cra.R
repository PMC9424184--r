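#' Comparative risk assessment of CKD burden
#'
#' Fits the full attribution analysis on a longitudinal survey: census-
#' standardized exposure trajectories and trend tests for the longitudinal
#' factors (SBP, DBP, BMI, current smoking), population-attributable
#' fractions for all seven risk factors against their TMREDs, total and
#' attributable CKD case counts with Monte-Carlo intervals, and the
#' attributable-case series across waves at the anchor-year case total.
#' Blood-panel factors (TG, HDL-C, glucose) are evaluated at their single
#' measurement wave and carried forward to the anchor year.
#'
#' @inheritParams standardized_mean
#' @param specs risk-factor registry, default [ckd_risk_factors()].
#' @param prevalence,prevalence_ci CKD prevalence with 95% CI
#'   (default 10.8%, 10.2-11.3%).
#' @param population reference adult population; defaults to the census total.
#' @param blood_wave wave carrying the blood panel (default 2009).
#' @param n_draws Monte-Carlo draws for the intervals.
#' @param seed integer seed controlling every random stream.
#' @return object of class `cra` with components `trajectories`, `trends`,
#'   `burden` (per-factor [burden_with_ci()] results), `burden_table`,
#'   `series`, `total`, and the inputs needed by [predict.cra()].
#' @seealso [predict.cra()] for the 20-year projection, [run_pipeline()] for
#'   file-based output.
#' @examples
#' \donttest{
#' cfg <- default_cohort_config(n_individuals = 1500)
#' survey <- simulate_cohort(cfg, seed = 7)
#' census <- generate_census(cfg)
#' fit <- cra(survey, census, n_draws = 200, seed = 7)
#' print(fit)
#' coef(fit)
#' }
#' @export
cra <- function(survey, census, specs = ckd_risk_factors(),
                prevalence = 0.108, prevalence_ci = c(0.102, 0.113),
                population = sum(census$count), blood_wave = 2009,
                n_draws = 1000, seed = 1L) {
  waves <- sort(unique(survey$wave))
  anchor_year <- max(waves)
  trend_facs <- intersect(names(specs), c("sbp", "dbp", "bmi", "smoking"))
  blood_facs <- intersect(names(specs), c("tg", "hdl", "glucose"))

  trajectories <- do.call(rbind, lapply(trend_facs, function(f) {
    do.call(rbind, lapply(waves, function(w) {
      if (specs[[f]]$kind == "continuous") {
        m <- standardized_mean(survey, census, f, w)
        data.frame(factor = f, wave = w, mean = m$mean, se = m$se,
                   stringsAsFactors = FALSE)
      } else {
        p <- standardized_prevalence(survey, census, f, w,
                                     categories = names(specs[[f]]$rr))
        cur <- p[p$category == "current", ]
        data.frame(factor = f, wave = w, mean = cur$prevalence, se = cur$se,
                   stringsAsFactors = FALSE)
      }
    }))
  }))

  trends <- do.call(rbind, lapply(trend_facs, function(f)
    trend_test(survey, f)))

  total <- total_cases(prevalence, population)

  burden <- list()
  for (i in seq_along(names(specs))) {
    f <- names(specs)[i]
    w <- if (f %in% blood_facs) blood_wave else anchor_year
    burden[[f]] <- burden_with_ci(survey, census, specs[[f]], prevalence,
                                  prevalence_ci, population, wave = w,
                                  n_draws = n_draws, seed = seed + i)
  }
  burden_table <- do.call(rbind, lapply(burden, function(b)
    data.frame(factor = b$factor, exposure_wave = b$wave,
               paf = b$paf["point"], paf_lower = b$paf["q2.5"],
               paf_upper = b$paf["q97.5"],
               attributable = b$attributable["point"],
               attributable_lower = b$attributable["q2.5"],
               attributable_upper = b$attributable["q97.5"],
               row.names = NULL, stringsAsFactors = FALSE)))
  burden_table <- burden_table[order(-burden_table$attributable), ]

  series <- do.call(rbind, lapply(trend_facs, function(f) {
    pafs <- do.call(rbind, lapply(waves, function(w) {
      input <- exposure_input(survey, census, specs[[f]], w)
      data.frame(factor = f, wave = w,
                 paf = suppressWarnings(paf_from_input(input, specs[[f]],
                                                       specs[[f]]$rr)),
                 stringsAsFactors = FALSE)
    }))
    attributable_series(pafs, total)
  }))

  structure(
    list(trajectories = trajectories, trends = trends, burden = burden,
         burden_table = burden_table, series = series, total = total,
         prevalence = prevalence, prevalence_ci = prevalence_ci,
         population = population, waves = waves, anchor_year = anchor_year,
         blood_wave = blood_wave, specs = specs, n_draws = n_draws,
         seed = seed, survey = survey, census = census),
    class = "cra")
}

#' @export
print.cra <- function(x, ...) {
  cat("Comparative risk assessment of CKD burden\n")
  cat(sprintf("  cohort: %d person-waves, %d individuals, waves %s-%s\n",
              nrow(x$survey), length(unique(x$survey$id)),
              min(x$waves), max(x$waves)))
  cat(sprintf("  CKD prevalence %.1f%% (95%% CI %.1f-%.1f), population %s\n",
              100 * x$prevalence, 100 * x$prevalence_ci[1],
              100 * x$prevalence_ci[2],
              format(x$population, big.mark = ",")))
  cat(sprintf("  total CKD cases: %.1f million\n", x$total / 1e6))
  cat(sprintf("  attributable burden in %d (leading factors):\n",
              x$anchor_year))
  top <- utils::head(x$burden_table, 3)
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-8s PAF %.1f%%, %.1f million cases\n", top$factor[i],
                100 * top$paf[i], top$attributable[i] / 1e6))
  invisible(x)
}

#' @export
summary.cra <- function(object, ...) {
  structure(list(fit = object), class = "summary.cra")
}

#' @export
print.summary.cra <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nAttributable burden by factor:\n")
  bt <- fit$burden_table
  bt$paf <- sprintf("%.1f%% (%.1f-%.1f)", 100 * bt$paf, 100 * bt$paf_lower,
                    100 * bt$paf_upper)
  bt$attributable <- sprintf("%.1f (%.1f-%.1f) million",
                             bt$attributable / 1e6,
                             bt$attributable_lower / 1e6,
                             bt$attributable_upper / 1e6)
  print(bt[, c("factor", "exposure_wave", "paf", "attributable")],
        row.names = FALSE)
  cat("\nSecular trends (year as scored variable, cluster-robust):\n")
  tr <- fit$trends
  tr$p_value <- format.pval(tr$p_value, digits = 3)
  print(as.data.frame(tr)[, c("factor", "slope", "se", "p_value")],
        row.names = FALSE)
  invisible(x)
}

#' PAF point estimates of a fitted comparative risk assessment
#'
#' @param object a [cra()] fit.
#' @param ... unused.
#' @return named numeric vector of per-factor PAFs at the anchor year.
#' @export
coef.cra <- function(object, ...) {
  stats::setNames(object$burden_table$paf, object$burden_table$factor)
}

#' Project a fitted comparative risk assessment forward
#'
#' Runs the two-stage random-effects projection ([projected_burden()]) for
#' the longitudinal factors, anchored at the fit's last observed
#' standardized values and its total case count.
#'
#' @param object a [cra()] fit.
#' @param years projection years (default 2013-2031, biennial).
#' @param min_waves eligibility threshold for the per-individual trend fits.
#' @param n_draws,seed Monte-Carlo settings; default to the fit's.
#' @param ... unused.
#' @return data.frame of projected exposure, PAF and attributable cases per
#'   factor-year.
#' @export
predict.cra <- function(object, years = seq(2013, 2031, by = 2),
                        min_waves = 3, n_draws = object$n_draws,
                        seed = object$seed, ...) {
  projected_burden(object$survey, object$census, object$specs, years = years,
                   total = object$total, min_waves = min_waves,
                   n_draws = n_draws, seed = seed)
}

#' Plot exposure trajectories and attributable burden
#'
#' Two base-graphics panels: the census-standardized trajectory of each
#' longitudinal factor across waves, and the attributable cases per factor
#' at the anchor year with their intervals.
#'
#' @param x a [cra()] fit.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.cra <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  facs <- unique(x$trajectories$factor)
  graphics::plot(NULL, xlim = range(x$waves), ylim = c(0, 1.05),
                 xlab = "wave", ylab = "scaled exposure",
                 main = "Standardized trajectories")
  for (i in seq_along(facs)) {
    tr <- x$trajectories[x$trajectories$factor == facs[i], ]
    y <- (tr$mean - min(tr$mean)) / max(diff(range(tr$mean)), 1e-12)
    graphics::lines(tr$wave, y, col = i, type = "b", pch = 16)
  }
  graphics::legend("bottomleft", legend = facs, col = seq_along(facs),
                   lty = 1, pch = 16, cex = 0.8, bty = "n")
  bt <- x$burden_table
  bp <- graphics::barplot(bt$attributable / 1e6, names.arg = bt$factor,
                          las = 2, ylab = "attributable cases (millions)",
                          main = sprintf("Burden in %d", x$anchor_year),
                          ylim = c(0, 1.1 * max(bt$attributable_upper) / 1e6))
  graphics::arrows(bp, bt$attributable_lower / 1e6, bp,
                   bt$attributable_upper / 1e6, angle = 90, code = 3,
                   length = 0.03)
  invisible(x)
}
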