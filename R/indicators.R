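#' Indicator and domain metadata for the child social exclusion index
#'
#' The index is built from 13 small-area indicators grouped into five domains.
#' Eleven indicators are census-style proportions of dependent children aged
#' 0-15 exposed to a risk factor (sole-parent family, bottom income quintile,
#' jobless family, no family member with Year 12, low early-development score,
#' no internet, no parent volunteering, no motor vehicle, rental stress,
#' overcrowding), where larger values already mean higher risk. Three are
#' access ratios (GPs per 1,000 population, dentists per 1,000 population, and
#' an area-to-national ratio of Year 5 literacy/numeracy scores) where larger
#' raw values mean *better* circumstances; they are re-oriented before scoring
#' so that larger always means higher risk.
#'
#' @return A data frame with one row per indicator and columns
#'   \code{indicator}, \code{domain} (one of Socio-economic, Education,
#'   Connectedness, Housing, Health services) and \code{orientation}
#'   (\code{"proportion_risk"} or \code{"ratio_inverted"}).
#' @export
#' @examples
#' table(cse_indicators()$domain)
cse_indicators <- function() {
  data.frame(
    indicator = c(
      "sole_parent", "low_income", "no_parent_working",
      "no_year12", "naplan_ratio", "aedi_low",
      "no_internet", "no_volunteer", "no_motor_vehicle",
      "housing_stress", "overcrowding",
      "gp_ratio", "dentist_ratio"
    ),
    domain = rep(
      c("Socio-economic", "Education", "Connectedness", "Housing",
        "Health services"),
      times = c(3L, 3L, 3L, 2L, 2L)
    ),
    orientation = c(
      "proportion_risk", "proportion_risk", "proportion_risk",
      "proportion_risk", "ratio_inverted", "proportion_risk",
      "proportion_risk", "proportion_risk", "proportion_risk",
      "proportion_risk", "proportion_risk",
      "ratio_inverted", "ratio_inverted"
    ),
    stringsAsFactors = FALSE
  )
}

#' Remoteness categories, least to most remote
#' @return Character vector of the five category labels.
#' @export
remoteness_levels <- function() {
  c("Major cities", "Inner regional", "Outer regional", "Remote",
    "Very remote")
}

#' Domain labels in scoring order
#' @return Character vector of the five domain labels.
#' @export
cse_domains <- function() {
  c("Socio-economic", "Education", "Connectedness", "Housing",
    "Health services")
}

# age groups used for rate standardisation (children 0-14)
age_groups <- function() c("0-4", "5-9", "10-14")
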