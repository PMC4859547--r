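#' Run the full small-area analysis pipeline
#'
#' Orchestrates the five stages — \code{simulate} (write a synthetic dataset),
#' \code{index} (build the social-exclusion index), \code{rates}
#' (age-standardised hospitalisation rates), \code{associate} (correlations,
#' concordance cross-tabs, quintile summaries, gradient tests) and
#' \code{model} (polynomial fit, residuals by remoteness, mortality
#' chi-squares) — as one reproducible run. Each stage reads its inputs from
#' the output directory, writes its results as CSV, and records a JSON
#' manifest (parameters, input/output file hashes, package version, seed). A
#' plain-text \code{report.txt} reproducing the standard table layout is
#' written after the last stage.
#'
#' @param config Either a list or the path to a YAML file with any of:
#'   \code{out} (output directory, required), \code{seed}, \code{stages}
#'   (subset of the five stage names, in pipeline order), \code{sim} (list of
#'   [sim_config()] overrides), \code{min_children}, \code{max_nonresponse},
#'   \code{alpha}, \code{std_shares} (named age-group shares).
#' @return Invisibly, a list with the per-stage outputs that were computed.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out))
  all_stages <- c("simulate", "index", "rates", "associate", "model")
  stages <- if (is.null(config$stages)) all_stages else
    match.arg(config$stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out <- config$out
  dir.create(file.path(out, "manifests"), recursive = TRUE,
             showWarnings = FALSE)
  unlink(file.path(out, "FAILED"))

  results <- list()
  for (stage in stages) {
    results[[stage]] <- tryCatch(
      run_stage(stage, config, seed, out),
      error = function(e) {
        writeLines(paste("stage:", stage, "-", conditionMessage(e)),
                   file.path(out, "FAILED"))
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }
    )
  }
  if ("model" %in% stages || "associate" %in% stages) {
    write_report(out)
  }
  invisible(results)
}

run_stage <- function(stage, config, seed, out) {
  switch(stage,
         simulate = stage_simulate(config, seed, out),
         index = stage_index(config, out),
         rates = stage_rates(config, out),
         associate = stage_associate(config, out),
         model = stage_model(config, out))
}

write_manifest <- function(out, stage, params, inputs, outputs) {
  manifest <- list(
    stage = stage,
    params = params,
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(outputs)),
    package_version = as.character(utils::packageVersion("csehealth"))
  )
  jsonlite::write_json(manifest,
                       file.path(out, "manifests", paste0(stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

read_stage_csv <- function(out, name) {
  path <- file.path(out, "data", name)
  if (!file.exists(path))
    stop("required input '", name, "' not found; run the producing stage first",
         call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

stage_simulate <- function(config, seed, out) {
  args <- config$sim
  if (is.null(args)) args <- list()
  args$seed <- seed
  cfg <- do.call(sim_config, args)
  sim <- simulate_cse_data(cfg)
  paths <- write_cse_dataset(sim, file.path(out, "data"))
  write_manifest(out, "simulate",
                 params = unclass(cfg), inputs = character(),
                 outputs = unname(paths))
  sim
}

stage_index <- function(config, out) {
  areas <- read_stage_csv(out, "areas.csv")
  indicators <- read_stage_csv(out, "indicators.csv")
  idx <- cse_index(indicators, areas,
                   min_children = config$min_children %||% 30L,
                   max_nonresponse = config$max_nonresponse %||% 0.80)
  path <- file.path(out, "data", "index.csv")
  utils::write.csv(as.data.frame(idx), path, row.names = FALSE)
  excl_path <- file.path(out, "data", "excluded_areas.csv")
  utils::write.csv(idx$excluded, excl_path, row.names = FALSE)
  message("index: ", length(idx$area_id), " areas included, ",
          nrow(idx$excluded), " excluded")
  write_manifest(out, "index",
                 params = list(min_children = config$min_children %||% 30L,
                               max_nonresponse = config$max_nonresponse %||% 0.80),
                 inputs = file.path(out, "data",
                                    c("areas.csv", "indicators.csv")),
                 outputs = c(path, excl_path))
  idx
}

pipeline_std <- function(config) {
  if (is.null(config$std_shares)) standard_population()
  else standard_population(unlist(config$std_shares))
}

stage_rates <- function(config, out) {
  events <- read_stage_csv(out, "pph_counts.csv")
  pops <- read_stage_csv(out, "age_pops.csv")
  rates <- mean_annual_pph_rate(events, pops, pipeline_std(config))
  path <- file.path(out, "data", "rates.csv")
  df <- rates
  df$years_used <- paste(attr(rates, "years_used"), collapse = ";")
  utils::write.csv(df, path, row.names = FALSE)
  write_manifest(out, "rates",
                 params = list(std = pipeline_std(config)$shares),
                 inputs = file.path(out, "data",
                                    c("pph_counts.csv", "age_pops.csv")),
                 outputs = path)
  rates
}

`%||%` <- function(a, b) if (is.null(a)) b else a

index_bases <- function() c("composite", cse_domains())

stage_associate <- function(config, out) {
  idx_df <- read_stage_csv(out, "index.csv")
  rates <- read_stage_csv(out, "rates.csv")
  r <- stats::setNames(rates$pph_rate, rates$area_id)
  ids <- idx_df$area_id
  if (!all(ids %in% names(r)))
    stop("rates missing for some indexed areas", call. = FALSE)
  w <- stats::setNames(idx_df$child_pop_0_15, ids)
  pph_q <- weighted_quintiles(r[ids], w, ids, label = "PPH rate")

  base_cols <- c(composite = "composite",
                 stats::setNames(paste0("index_",
                                        gsub("[^A-Za-z]+", "_",
                                             tolower(cse_domains()))),
                                 cse_domains()))
  cors <- vapply(base_cols, function(cl)
    weighted_pearson(idx_df[[cl]], r[ids], w), numeric(1))
  utils::write.csv(data.frame(basis = names(base_cols),
                              weighted_pearson = cors, row.names = NULL),
                   file.path(out, "data", "correlations.csv"),
                   row.names = FALSE)

  crosstabs <- lapply(names(base_cols), function(b) {
    qcol <- paste0("quintile_", gsub("[^A-Za-z]+", "_", tolower(b)))
    iq <- weighted_quintiles(idx_df[[base_cols[[b]]]], w, ids, label = b)
    ct <- crosstab_shares(pph_q, iq, w)
    utils::write.csv(as.data.frame(ct$shares),
                     file.path(out, "data",
                               paste0("crosstab_",
                                      gsub("[^A-Za-z]+", "_", tolower(b)),
                                      ".csv")))
    ct
  })
  names(crosstabs) <- names(base_cols)

  comp_q <- weighted_quintiles(idx_df$composite, w, ids, label = "composite")
  qs <- quintile_summary(r[ids], comp_q)
  utils::write.csv(qs, file.path(out, "data", "quintile_summary.csv"),
                   row.names = FALSE)
  gt <- gradient_tests(r[ids], comp_q)
  utils::write.csv(gt$welch_pairs,
                   file.path(out, "data", "welch_pairs.csv"),
                   row.names = FALSE)

  outputs <- file.path(out, "data",
                       c("correlations.csv", "quintile_summary.csv",
                         "welch_pairs.csv",
                         paste0("crosstab_",
                                gsub("[^A-Za-z]+", "_",
                                     tolower(names(base_cols))), ".csv")))
  write_manifest(out, "associate", params = list(),
                 inputs = file.path(out, "data", c("index.csv", "rates.csv")),
                 outputs = outputs)
  res <- list(correlations = cors, crosstabs = crosstabs,
              quintile_summary = qs, gradient_tests = gt, pph_q = pph_q)
  saveRDS_free_report(res, out, "associate")
  res
}

stage_model <- function(config, out) {
  idx_df <- read_stage_csv(out, "index.csv")
  rates <- read_stage_csv(out, "rates.csv")
  areas <- read_stage_csv(out, "areas.csv")
  deaths <- read_stage_csv(out, "death_counts.csv")
  pops <- read_stage_csv(out, "age_pops.csv")

  ids <- idx_df$area_id
  r <- stats::setNames(rates$pph_rate, rates$area_id)[ids]
  comp <- stats::setNames(idx_df$composite, ids)
  w <- stats::setNames(idx_df$child_pop_0_15, ids)

  fit <- fit_polynomial(comp, r, alpha = config$alpha %||% 0.05)
  fit_df <- data.frame(term = names(coef(fit)), coefficient = coef(fit),
                       p_value = fit$p_values, row.names = NULL)
  utils::write.csv(fit_df, file.path(out, "data", "fit_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(area_id = names(residuals(fit)),
                              residual = residuals(fit), row.names = NULL),
                   file.path(out, "data", "residuals.csv"), row.names = FALSE)

  cat_ <- stats::setNames(areas$remoteness, areas$area_id)
  rem <- residuals_by_remoteness(fit, cat_)
  utils::write.csv(rem$table,
                   file.path(out, "data", "residuals_by_remoteness.csv"),
                   row.names = FALSE)

  # mortality: first death year; 0-14 populations from that June
  death_year <- min(deaths$year)
  d1 <- deaths[deaths$year == death_year, ]
  dvec <- stats::setNames(d1$deaths, d1$area_id)
  p14 <- tapply(pops$pop[pops$june_year == death_year],
                pops$area_id[pops$june_year == death_year], sum)
  p14 <- stats::setNames(as.numeric(p14), names(p14))

  base_cols <- c(composite = "composite",
                 stats::setNames(paste0("index_",
                                        gsub("[^A-Za-z]+", "_",
                                             tolower(cse_domains()))),
                                 cse_domains()))
  contingency <- lapply(names(base_cols), function(b) {
    iq <- weighted_quintiles(idx_df[[base_cols[[b]]]], w, ids, label = b)
    qdr <- quintile_death_rates(dvec[ids], p14[ids], iq, w)
    mortality_chi_square(qdr$est_deaths_rounded, round(qdr$pop_0_15))
  })
  names(contingency) <- names(base_cols)
  chi_df <- data.frame(
    basis = names(contingency),
    chi2 = vapply(contingency, `[[`, numeric(1), "chi2"),
    df = vapply(contingency, `[[`, numeric(1), "df"),
    p = vapply(contingency, `[[`, numeric(1), "p"), row.names = NULL)
  utils::write.csv(chi_df, file.path(out, "data", "mortality_chi_square.csv"),
                   row.names = FALSE)

  outputs <- file.path(out, "data",
                       c("fit_summary.csv", "residuals.csv",
                         "residuals_by_remoteness.csv",
                         "mortality_chi_square.csv"))
  write_manifest(out, "model",
                 params = list(alpha = config$alpha %||% 0.05,
                               death_year = death_year),
                 inputs = file.path(out, "data",
                                    c("index.csv", "rates.csv", "areas.csv",
                                      "death_counts.csv", "age_pops.csv")),
                 outputs = outputs)
  res <- list(fit = fit, remoteness = rem, contingency = contingency)
  saveRDS_free_report(res, out, "model")
  res
}

# keep latest stage results in memory for report assembly without binary files
report_cache <- new.env(parent = emptyenv())
saveRDS_free_report <- function(res, out, stage) {
  assign(paste0(out, ":", stage), res, envir = report_cache)
  invisible(NULL)
}

write_report <- function(out) {
  lines <- c("Small-area child social exclusion and health outcomes: run report",
             strrep("=", 66), "")
  assoc <- mget(paste0(out, ":associate"), envir = report_cache,
                ifnotfound = list(NULL))[[1]]
  model <- mget(paste0(out, ":model"), envir = report_cache,
                ifnotfound = list(NULL))[[1]]
  if (!is.null(assoc)) {
    lines <- c(lines, "Weighted Pearson correlations (index basis vs PPH rate):",
               utils::capture.output(print(round(assoc$correlations, 3))), "")
    for (b in names(assoc$crosstabs)) {
      lines <- c(lines, paste0("Cross-tab: PPH quintile by ", b, " quintile"),
                 utils::capture.output(print(assoc$crosstabs[[b]])), "")
    }
    lines <- c(lines, "PPH rates by composite quintile:",
               utils::capture.output(print(assoc$quintile_summary,
                                           row.names = FALSE)), "",
               utils::capture.output(print(assoc$gradient_tests)), "")
  }
  if (!is.null(model)) {
    lines <- c(lines, utils::capture.output(print(model$fit)), "",
               utils::capture.output(print(model$remoteness)), "")
    for (b in names(model$contingency)) {
      lines <- c(lines, paste0("Avoidable deaths by ", b, " quintile:"),
                 utils::capture.output(print(model$contingency[[b]])), "")
    }
  }
  writeLines(lines, file.path(out, "report.txt"))
  invisible(file.path(out, "report.txt"))
}
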