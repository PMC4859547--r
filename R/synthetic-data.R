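#' Configuration for the synthetic small-area generator
#'
#' Defines the data-generating process used to emulate the analysis inputs:
#' a single latent area-disadvantage factor \code{z ~ Normal(0, latent_sd)}
#' that loads positively on all 13 social-exclusion indicators, right-skewed
#' (log-normal) child populations, a five-level remoteness classification,
#' Poisson hospitalisation counts whose log rate rises with \code{z} and
#' carries an additive excess in remote categories, and rare Poisson
#' avoidable-death counts whose rate rises with \code{z}.
#'
#' Proportion-type indicators are generated as
#' \code{plogis(intercept + loading * z + noise)}; access-ratio indicators
#' (GP, dentist, literacy/numeracy score ratios) as
#' \code{base * exp(-(loading * z + noise))}, so higher disadvantage means a
#' lower (better-is-higher) ratio, matching their field orientation.
#'
#' @param n_areas Number of small areas. Default 1154, the national count of
#'   analysable areas after exclusions.
#' @param seed Integer seed; the generator is fully reproducible.
#' @param latent_sd Standard deviation of the latent disadvantage factor.
#' @param indicator_loadings Numeric vector of 13 positive loadings.
#' @param indicator_noise_sd Standard deviation of per-indicator noise on the
#'   latent scale.
#' @param child_pop_log_mean,child_pop_log_sd Log-normal parameters for the
#'   resident child (0-15) population of an area.
#' @param remoteness_probs Probabilities of the five remoteness categories
#'   (least to most remote); must sum to 1.
#' @param pph_baseline_log_rate Log hospitalisation events per child-year at
#'   \code{z = 0} in non-remote areas.
#' @param pph_disadvantage_slope Increase in log hospitalisation rate per unit
#'   of latent disadvantage.
#' @param pph_remote_excess Additive log-rate excess for each remoteness
#'   category; by default nonzero only for Remote and Very remote.
#' @param death_rate_per_100k Baseline avoidable-death rate per 100,000
#'   children 0-14 per year.
#' @param death_disadvantage_slope Increase in log death rate per unit of
#'   latent disadvantage.
#' @param n_years Number of financial years of hospitalisation data.
#' @param age_group_shares Shares of the child population in age groups 0-4,
#'   5-9, 10-14; must sum to 1.
#' @param nonresponse_shape1,nonresponse_shape2 Beta parameters for simulated
#'   per-indicator census non-response fractions.
#' @param n_force_low_pop Number of areas forced below 30 resident children
#'   (to exercise area filtering).
#' @param n_force_both Number of additional areas forced to fail both the
#'   population and the non-response rule.
#' @param first_year First financial year label (start year).
#' @return An object of class \code{cse_sim_config}.
#' @seealso [simulate_cse_data()]
#' @export
sim_config <- function(n_areas = 1154L,
                       seed = 1L,
                       latent_sd = 1,
                       indicator_loadings = rep(1, 13),
                       indicator_noise_sd = 0.5,
                       child_pop_log_mean = 8,
                       child_pop_log_sd = 0.8,
                       remoteness_probs = c(0.34, 0.24, 0.26, 0.08, 0.08),
                       pph_baseline_log_rate = log(0.024),
                       pph_disadvantage_slope = 0.35,
                       pph_remote_excess = c(0, 0, 0, 0.5, 0.5),
                       death_rate_per_100k = 23,
                       death_disadvantage_slope = 0.3,
                       n_years = 3L,
                       age_group_shares = c(0.32, 0.33, 0.35),
                       nonresponse_shape1 = 0.8,
                       nonresponse_shape2 = 30,
                       n_force_low_pop = 0L,
                       n_force_both = 0L,
                       first_year = 2006L) {
  cfg <- list(
    n_areas = as.integer(n_areas), seed = as.integer(seed),
    latent_sd = latent_sd,
    indicator_loadings = indicator_loadings,
    indicator_noise_sd = indicator_noise_sd,
    child_pop_log_mean = child_pop_log_mean,
    child_pop_log_sd = child_pop_log_sd,
    remoteness_probs = remoteness_probs,
    pph_baseline_log_rate = pph_baseline_log_rate,
    pph_disadvantage_slope = pph_disadvantage_slope,
    pph_remote_excess = pph_remote_excess,
    death_rate_per_100k = death_rate_per_100k,
    death_disadvantage_slope = death_disadvantage_slope,
    n_years = as.integer(n_years),
    age_group_shares = age_group_shares,
    nonresponse_shape1 = nonresponse_shape1,
    nonresponse_shape2 = nonresponse_shape2,
    n_force_low_pop = as.integer(n_force_low_pop),
    n_force_both = as.integer(n_force_both),
    first_year = as.integer(first_year)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "cse_sim_config")
}

validate_sim_config <- function(cfg) {
  for (f in names(cfg)) {
    v <- cfg[[f]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      stop("sim_config field '", f, "' must be finite numeric", call. = FALSE)
    }
  }
  if (cfg$n_areas < 1) stop("sim_config field 'n_areas' must be positive", call. = FALSE)
  for (f in c("latent_sd", "indicator_noise_sd", "child_pop_log_sd",
              "death_rate_per_100k", "nonresponse_shape1",
              "nonresponse_shape2")) {
    if (cfg[[f]] < 0 || (f %in% c("latent_sd", "child_pop_log_sd",
                                  "death_rate_per_100k") && cfg[[f]] <= 0)) {
      stop("sim_config field '", f, "' must be positive", call. = FALSE)
    }
  }
  if (length(cfg$indicator_loadings) != 13)
    stop("sim_config field 'indicator_loadings' must have length 13", call. = FALSE)
  if (length(cfg$remoteness_probs) != 5 ||
      abs(sum(cfg$remoteness_probs) - 1) > 1e-9)
    stop("sim_config field 'remoteness_probs' must be 5 probabilities summing to 1",
         call. = FALSE)
  if (length(cfg$age_group_shares) != 3 ||
      abs(sum(cfg$age_group_shares) - 1) > 1e-9)
    stop("sim_config field 'age_group_shares' must be 3 shares summing to 1",
         call. = FALSE)
  if (length(cfg$pph_remote_excess) != 5)
    stop("sim_config field 'pph_remote_excess' must have length 5", call. = FALSE)
  if (cfg$n_years < 1) stop("sim_config field 'n_years' must be >= 1", call. = FALSE)
  invisible(cfg)
}

# baseline levels giving realistic marginal indicator values at z = 0
indicator_baselines <- function() {
  c(sole_parent = 0.20, low_income = 0.20, no_parent_working = 0.15,
    no_year12 = 0.30, naplan_ratio = 1.00, aedi_low = 0.10,
    no_internet = 0.25, no_volunteer = 0.60, no_motor_vehicle = 0.05,
    housing_stress = 0.10, overcrowding = 0.06,
    gp_ratio = 1.10, dentist_ratio = 0.45)
}

#' Generate a synthetic small-area dataset
#'
#' Draws a complete set of analysis inputs under the model described in
#' [sim_config()]: an area table (child population, remoteness, per-indicator
#' non-response fractions), the 13-indicator table, June population estimates
#' by age group and year, hospitalisation event counts per area, financial
#' year and age group, and avoidable-death counts per area and year. The
#' latent disadvantage factor is retained so recovery of the composite index
#' can be tested against ground truth.
#'
#' @param config A [sim_config()] object.
#' @return An object of class \code{cse_sim}: a list with elements
#'   \code{areas}, \code{indicators}, \code{age_pops}, \code{pph_counts},
#'   \code{death_counts}, \code{latent} and \code{config}.
#' @export
#' @examples
#' sim <- simulate_cse_data(sim_config(n_areas = 50, seed = 7))
#' head(sim$areas)
simulate_cse_data <- function(config = sim_config()) {
  stopifnot(inherits(config, "cse_sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_areas
  meta <- cse_indicators()
  base <- indicator_baselines()

  area_id <- sprintf("A%04d", seq_len(n))
  z <- stats::rnorm(n, 0, config$latent_sd)

  # indicators: logistic proportions, or declining positive ratios
  ind <- matrix(NA_real_, n, 13, dimnames = list(area_id, meta$indicator))
  for (j in seq_len(13)) {
    eta <- config$indicator_loadings[j] * z +
      stats::rnorm(n, 0, config$indicator_noise_sd)
    nm <- meta$indicator[j]
    if (meta$orientation[j] == "proportion_risk") {
      ind[, j] <- stats::plogis(stats::qlogis(base[[nm]]) + eta)
    } else {
      ind[, j] <- base[[nm]] * exp(-eta)
    }
  }

  child_pop <- pmax(1L, as.integer(round(stats::rlnorm(
    n, config$child_pop_log_mean, config$child_pop_log_sd))))
  n_forced <- config$n_force_low_pop + config$n_force_both
  if (n_forced > n) stop("forced exclusion counts exceed n_areas", call. = FALSE)
  if (n_forced > 0) {
    child_pop[seq_len(n_forced)] <- sample(5:29, n_forced, replace = TRUE)
  }

  remoteness <- sample(remoteness_levels(), n, replace = TRUE,
                       prob = config$remoteness_probs)

  nr <- matrix(stats::rbeta(n * 13, config$nonresponse_shape1,
                            config$nonresponse_shape2),
               n, 13, dimnames = list(area_id, paste0("nr_", meta$indicator)))
  nr <- pmin(nr, 0.79)  # default dataset passes the response filter
  if (config$n_force_both > 0) {
    rows <- config$n_force_low_pop + seq_len(config$n_force_both)
    nr[rows, 1] <- stats::runif(config$n_force_both, 0.80, 0.95)
  }

  # base age-group split of the 0-15 population, remainder to the youngest
  shares <- config$age_group_shares
  base_age <- t(vapply(child_pop, function(p) {
    a <- floor(p * shares)
    a[1] <- a[1] + (p - sum(a))
    a
  }, numeric(3)))
  colnames(base_age) <- age_groups()

  years <- config$first_year + 0:config$n_years  # June snapshots
  age_pops <- do.call(rbind, lapply(seq_along(years), function(k) {
    jitter <- matrix(exp(stats::rnorm(n * 3, 0, 0.01)), n, 3)
    data.frame(
      area_id = rep(area_id, 3),
      june_year = years[k],
      age_group = rep(age_groups(), each = n),
      pop = as.integer(round(base_age * jitter)),
      stringsAsFactors = FALSE
    )
  }))

  rem_idx <- match(remoteness, remoteness_levels())
  log_rate <- config$pph_baseline_log_rate +
    config$pph_disadvantage_slope * z + config$pph_remote_excess[rem_idx]

  pop_lookup <- function(yr) {
    sel <- age_pops[age_pops$june_year == yr, ]
    m <- matrix(sel$pop, n, 3, dimnames = list(sel$area_id[seq_len(n)],
                                               age_groups()))
    m[area_id, , drop = FALSE]
  }
  june_mats <- lapply(years, pop_lookup)
  names(june_mats) <- as.character(years)

  fin_years <- config$first_year + seq_len(config$n_years) - 1L
  pph_counts <- do.call(rbind, lapply(seq_along(fin_years), function(t) {
    dec_pop <- (june_mats[[t]] + june_mats[[t + 1]]) / 2
    lambda <- dec_pop * exp(log_rate)
    ev <- matrix(stats::rpois(n * 3, as.vector(lambda)), n, 3)
    data.frame(
      area_id = rep(area_id, 3),
      year = fin_years[t],
      age_group = rep(age_groups(), each = n),
      events = as.integer(ev),
      stringsAsFactors = FALSE
    )
  }))

  death_years <- config$first_year + seq_len(config$n_years)
  death_rate <- config$death_rate_per_100k / 1e5 *
    exp(config$death_disadvantage_slope * z)
  death_counts <- do.call(rbind, lapply(death_years, function(yr) {
    pop014 <- rowSums(june_mats[[as.character(yr)]])
    data.frame(area_id = area_id, year = yr,
               deaths = stats::rpois(n, pop014 * death_rate),
               stringsAsFactors = FALSE)
  }))

  areas <- data.frame(area_id = area_id, child_pop_0_15 = child_pop,
                      remoteness = remoteness, stringsAsFactors = FALSE)
  areas <- cbind(areas, as.data.frame(nr))
  rownames(areas) <- NULL

  structure(list(
    areas = areas,
    indicators = data.frame(area_id = area_id, as.data.frame(ind),
                            row.names = NULL, stringsAsFactors = FALSE),
    age_pops = age_pops,
    pph_counts = pph_counts,
    death_counts = death_counts,
    latent = stats::setNames(z, area_id),
    config = config
  ), class = "cse_sim")
}

#' @export
print.cse_sim <- function(x, ...) {
  cat("Synthetic small-area dataset:", nrow(x$areas), "areas,",
      x$config$n_years, "years (seed", x$config$seed, ")\n")
  cat("  total children 0-15:", sum(x$areas$child_pop_0_15), "\n")
  cat("  hospitalisation events:", sum(x$pph_counts$events),
      "| avoidable deaths (all years):", sum(x$death_counts$deaths), "\n")
  invisible(x)
}

#' Write a synthetic dataset to delimited text files
#'
#' Writes \code{areas.csv}, \code{indicators.csv}, \code{age_pops.csv},
#' \code{pph_counts.csv}, \code{death_counts.csv} and \code{latent.csv} plus a
#' \code{manifest.json} recording the generator configuration and seed.
#'
#' @param sim A \code{cse_sim} object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cse_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "cse_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    areas = file.path(dir, "areas.csv"),
    indicators = file.path(dir, "indicators.csv"),
    age_pops = file.path(dir, "age_pops.csv"),
    pph_counts = file.path(dir, "pph_counts.csv"),
    death_counts = file.path(dir, "death_counts.csv"),
    latent = file.path(dir, "latent.csv")
  )
  utils::write.csv(sim$areas, paths["areas"], row.names = FALSE)
  utils::write.csv(sim$indicators, paths["indicators"], row.names = FALSE)
  utils::write.csv(sim$age_pops, paths["age_pops"], row.names = FALSE)
  utils::write.csv(sim$pph_counts, paths["pph_counts"], row.names = FALSE)
  utils::write.csv(sim$death_counts, paths["death_counts"], row.names = FALSE)
  utils::write.csv(data.frame(area_id = names(sim$latent), z = sim$latent,
                              row.names = NULL),
                   paths["latent"], row.names = FALSE)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(config = unclass(sim$config),
                            files = as.list(basename(paths))),
                       manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, manifest = manifest))
}
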