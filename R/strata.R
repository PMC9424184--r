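#' @keywords internal
"_PACKAGE"

## Joint standardization strata: 4 age groups x 2 sexes x 2 residences = 16.
.age_groups <- c("18-39", "40-59", "60-69", "70+")
.sexes <- c("male", "female")
.residences <- c("urban", "rural")

#' Age group of an adult age
#'
#' Maps an age in years to the four standardization age groups
#' `18-39`, `40-59`, `60-69`, `70+`. Ages below 18 are outside the study
#' population and raise an error.
#'
#' @param age numeric vector of ages in years.
#' @return factor with levels `18-39`, `40-59`, `60-69`, `70+`.
#' @export
age_group <- function(age) {
  if (any(!is.finite(age)) || any(age < 18))
    stop("age must be finite and >= 18 (participants under 18 are excluded)")
  cut(age, breaks = c(18, 40, 60, 70, Inf), right = FALSE, labels = .age_groups)
}

#' Assign joint census strata
#'
#' Deterministically maps (age, sex, residence) to the joint stratum used for
#' direct standardization: age group x sex x urban/rural residence.
#'
#' @param age ages in years (>= 18).
#' @param sex `"male"` or `"female"`.
#' @param residence `"urban"` or `"rural"`.
#' @return data.frame with columns `age_group`, `sex`, `residence` and the
#'   combined `stratum` label.
#' @examples
#' assign_stratum(c(39, 70), c("male", "female"), c("urban", "rural"))
#' @export
assign_stratum <- function(age, sex, residence) {
  sex <- as.character(sex)
  residence <- as.character(residence)
  if (!all(sex %in% .sexes)) stop("sex must be 'male' or 'female'")
  if (!all(residence %in% .residences)) stop("residence must be 'urban' or 'rural'")
  ag <- as.character(age_group(age))
  data.frame(age_group = ag, sex = sex, residence = residence,
             stratum = paste(ag, sex, residence, sep = "|"),
             stringsAsFactors = FALSE)
}

## All 16 stratum labels in canonical order.
all_strata <- function() {
  g <- expand.grid(age_group = .age_groups, sex = .sexes, residence = .residences,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$stratum <- paste(g$age_group, g$sex, g$residence, sep = "|")
  g[order(g$stratum), , drop = FALSE]
}

## Census stratum weights (shares of the reference population), named by stratum.
census_weights <- function(census) {
  stopifnot(all(c("age_group", "sex", "residence", "count") %in% names(census)))
  if (any(census$count <= 0)) stop("census counts must be > 0")
  key <- paste(census$age_group, census$sex, census$residence, sep = "|")
  if (anyDuplicated(key)) stop("duplicated census strata")
  w <- census$count / sum(census$count)
  names(w) <- key
  w
}

## Apportion a population total over shares, largest-remainder, exact total.
apportion <- function(total, shares) {
  raw <- total * shares / sum(shares)
  out <- floor(raw)
  rem <- total - sum(out)
  if (rem > 0) {
    idx <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1
  }
  out
}

#' Generate the reference census table
#'
#' Builds the reference population used for direct standardization: counts for
#' the 16 joint strata (age group x sex x residence). The default reproduces
#' the adult population total of the 2010 Chinese census, 846,662,309, spread
#' over the strata with the generator's stratum proportions. The table is
#' synthetic: joint counts are modelled as the product of marginal shares.
#'
#' @param config a [cohort_config()]; its `stratum_proportions` become the
#'   census shares.
#' @param total total adult population (persons).
#' @return data.frame with columns `age_group`, `sex`, `residence`, `count`.
#' @examples
#' cen <- generate_census(default_cohort_config())
#' sum(cen$count)  # 846662309
#' @export
generate_census <- function(config = default_cohort_config(),
                            total = 846662309) {
  props <- config$stratum_proportions
  cen <- props[, c("age_group", "sex", "residence")]
  cen$count <- apportion(total, props$prop)
  cen
}
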