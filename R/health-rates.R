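#' Standard population age shares for direct standardisation
#'
#' Direct age standardisation weights each age group's event rate by a fixed
#' standard population's share of that age group, so areas with different age
#' structures are comparable. The true 2001 Australian standard-population
#' shares must be supplied by the user; the default here is a synthetic
#' placeholder (roughly equal thirds across 0-4, 5-9 and 10-14) intended for
#' simulation and testing only, and is labelled as such.
#'
#' @param shares Named numeric vector of shares for age groups \code{0-4},
#'   \code{5-9}, \code{10-14}; must be positive and sum to 1.
#' @param label Description of the standard used.
#' @return An object of class \code{standard_population}.
#' @export
standard_population <- function(shares = c("0-4" = 0.32, "5-9" = 0.33,
                                           "10-14" = 0.35),
                                label = "synthetic placeholder standard") {
  if (!all(age_groups() %in% names(shares)))
    stop("shares must be named with age groups ",
         paste(age_groups(), collapse = ", "), call. = FALSE)
  shares <- shares[age_groups()]
  if (any(shares <= 0) || abs(sum(shares) - 1) > 1e-9)
    stop("shares must be positive and sum to 1", call. = FALSE)
  structure(list(shares = shares, label = label),
            class = "standard_population")
}

#' December population by interpolation of June estimates
#'
#' Mid-financial-year (December) populations are estimated as the arithmetic
#' mean of the preceding and subsequent June estimated resident populations.
#'
#' @param june_before,june_after Nonnegative population counts (vectorised).
#' @return The interpolated December population(s).
#' @export
#' @examples
#' december_population(100, 120)  # 110
december_population <- function(june_before, june_after) {
  if (any(june_before < 0) || any(june_after < 0))
    stop("populations must be nonnegative", call. = FALSE)
  (june_before + june_after) / 2
}

#' Directly age-standardised event rate per 1,000 children
#'
#' Computes \code{1000 * sum(shares[g] * counts[g] / pops[g])} over age
#' groups: the rate a population with the standard age structure would
#' experience at the area's age-specific rates.
#'
#' @param counts Named event counts per age group.
#' @param pops Named person-years at risk per age group.
#' @param std A [standard_population()].
#' @param area_id Optional label used in error messages.
#' @return Standardised rate per 1,000.
#' @export
age_standardised_rate <- function(counts, pops, std = standard_population(),
                                  area_id = NULL) {
  stopifnot(inherits(std, "standard_population"))
  g <- age_groups()
  if (!all(g %in% names(counts)) || !all(g %in% names(pops)))
    stop("counts and pops must be named by age group", call. = FALSE)
  counts <- counts[g]; pops <- pops[g]
  bad <- counts > 0 & pops <= 0
  if (any(bad))
    stop("events with zero population",
         if (!is.null(area_id)) paste0(" in area ", area_id),
         " for age group ", paste(g[bad], collapse = ", "), call. = FALSE)
  ratio <- ifelse(pops > 0, counts / pops, 0)
  1000 * sum(std$shares * ratio)
}

#' Mean annual age-standardised hospitalisation rates per area
#'
#' For each area and financial year, the December population of each age group
#' is interpolated from the adjacent June estimates and the yearly
#' age-standardised rate computed; the area's rate is the unweighted mean of
#' the yearly rates (an "average annual rate"), damping stochastic
#' year-to-year variation in small areas. Areas with no recorded events get a
#' rate of zero.
#'
#' @param events Data frame with columns \code{area_id}, \code{year}
#'   (financial-year start), \code{age_group}, \code{events}. Missing
#'   area-year-age combinations count as zero events.
#' @param june_pops Data frame with columns \code{area_id}, \code{june_year},
#'   \code{age_group}, \code{pop}. Each financial year \code{y} needs June
#'   estimates for \code{y} and \code{y + 1}.
#' @param std A [standard_population()].
#' @param years Financial years to use; defaults to the years present in
#'   \code{events}.
#' @return A data frame (\code{area_id}, \code{pph_rate}, per 1,000 children
#'   0-14 per year) with attribute \code{years_used}.
#' @export
mean_annual_pph_rate <- function(events, june_pops,
                                 std = standard_population(), years = NULL) {
  stopifnot(all(c("area_id", "year", "age_group", "events") %in% names(events)),
            all(c("area_id", "june_year", "age_group", "pop") %in%
                  names(june_pops)))
  if (is.null(years)) years <- sort(unique(events$year))
  if (length(years) < 1) stop("at least one year required", call. = FALSE)
  ids <- sort(unique(june_pops$area_id))
  g <- age_groups()

  pop_mat <- function(yr) {
    sel <- june_pops[june_pops$june_year == yr, ]
    if (nrow(sel) == 0) stop("no June populations for year ", yr, call. = FALSE)
    m <- matrix(0, length(ids), length(g), dimnames = list(ids, g))
    m[cbind(match(sel$area_id, ids), match(sel$age_group, g))] <- sel$pop
    missing <- setdiff(ids, unique(sel$area_id))
    if (length(missing))
      stop("areas missing June ", yr, " populations: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    m
  }
  ev_mat <- function(yr) {
    sel <- events[events$year == yr, ]
    unknown <- setdiff(sel$area_id, ids)
    if (length(unknown))
      stop("event areas missing population data: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    m <- matrix(0, length(ids), length(g), dimnames = list(ids, g))
    if (nrow(sel))
      m[cbind(match(sel$area_id, ids), match(sel$age_group, g))] <- sel$events
    m
  }

  yearly <- sapply(years, function(yr) {
    dec <- december_population(pop_mat(yr), pop_mat(yr + 1))
    ev <- ev_mat(yr)
    vapply(seq_along(ids), function(i)
      age_standardised_rate(ev[i, ], dec[i, ], std, area_id = ids[i]),
      numeric(1))
  })
  yearly <- matrix(yearly, nrow = length(ids))
  out <- data.frame(area_id = ids, pph_rate = rowMeans(yearly),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "years_used") <- years
  out
}

#' Avoidable-death rates and estimated deaths per quintile
#'
#' Pools deaths and 0-14 populations over the areas of each quintile to get a
#' quintile-level death rate, then applies that rate to the quintile's 0-15
#' population (the population on which the quintiles were built) to estimate
#' the number of deaths among 0-15 year olds. The unrounded estimate is
#' retained alongside the integer-rounded value used for reporting.
#'
#' @param deaths Named vector of death counts per area (one year).
#' @param pops_0_14 Named vector of 0-14 populations per area.
#' @param quintiles A [weighted_quintiles()] assignment.
#' @param pops_0_15 Named vector of 0-15 populations per area.
#' @return Data frame with one row per quintile: \code{quintile},
#'   \code{deaths}, \code{pop_0_14}, \code{rate} (deaths per person),
#'   \code{pop_0_15}, \code{est_deaths}, \code{est_deaths_rounded}.
#' @export
quintile_death_rates <- function(deaths, pops_0_14, quintiles, pops_0_15) {
  q <- as_quintile_vector(quintiles)
  ids <- names(q)
  for (nm in c("deaths", "pops_0_14", "pops_0_15")) {
    v <- get(nm)
    if (!all(ids %in% names(v)))
      stop("areas missing from '", nm, "': ",
           paste(utils::head(setdiff(ids, names(v)), 5), collapse = ", "),
           call. = FALSE)
  }
  res <- do.call(rbind, lapply(sort(unique(q)), function(k) {
    sel <- ids[q == k]
    p14 <- sum(pops_0_14[sel])
    if (p14 <= 0) stop("quintile ", k, " has zero population", call. = FALSE)
    d <- sum(deaths[sel])
    p15 <- sum(pops_0_15[sel])
    rate <- d / p14
    data.frame(quintile = k, deaths = d, pop_0_14 = p14, rate = rate,
               pop_0_15 = p15, est_deaths = rate * p15,
               est_deaths_rounded = round(rate * p15))
  }))
  rownames(res) <- NULL
  res
}
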