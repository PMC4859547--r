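test_that("noise-free quadratic truth is recovered exactly by backward elimination", {
  ids <- sprintf("A%03d", 1:80)
  x <- setNames(seq(2, 98, length.out = 80), ids)
  r <- setNames(0.0071 * x^2 + 21.74, ids)
  fit <- fit_polynomial(x, r)
  expect_setequal(fit$terms, c("intercept", "index^2"))
  expect_equal(unname(coef(fit)[["index^2"]]), 0.0071, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[["intercept"]]), 21.74, tolerance = 1e-6)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-8)
  expect_equal(unname(predict(fit, 50)), 0.0071 * 2500 + 21.74,
               tolerance = 1e-8)
})

test_that("noise-free linear truth keeps only the linear term", {
  ids <- sprintf("A%03d", 1:40)
  x <- setNames(seq(5, 95, length.out = 40), ids)
  fit <- fit_polynomial(x, setNames(2 * x + 5, ids))
  expect_setequal(fit$terms, c("intercept", "index"))
  expect_equal(unname(coef(fit)[["index"]]), 2, tolerance = 1e-8)
  expect_equal(unname(coef(fit)[["intercept"]]), 5, tolerance = 1e-8)
})

test_that("pure-noise rates usually collapse to the intercept-only model", {
  # backward elimination over three collinear raw powers retains some term in
  # roughly 13% of replicates at alpha = 0.05; the large majority collapse
  eliminated <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    ids <- sprintf("A%03d", 1:500)
    x <- setNames(runif(500, 0, 100), ids)
    r <- setNames(rnorm(500, 25, 5), ids)
    fit <- fit_polynomial(x, r)
    identical(fit$terms, "intercept")
  }, logical(1))
  expect_gte(mean(eliminated), 0.7)
  # intercept-only residuals are deviations from the mean
  set.seed(1001)
  ids <- sprintf("A%03d", 1:500)
  x <- setNames(runif(500, 0, 100), ids)
  r <- setNames(rnorm(500, 25, 5), ids)
  fit <- fit_polynomial(x, r)
  if (identical(fit$terms, "intercept"))
    expect_equal(unname(residuals(fit)), unname(r - mean(r)))
})

test_that("no retained term has p >= alpha and residuals sum to zero", {
  set.seed(55)
  for (rep in 1:10) {
    ids <- sprintf("A%03d", 1:200)
    x <- setNames(runif(200, 0, 100), ids)
    r <- setNames(20 + 0.005 * x^2 + rnorm(200, 0, 8), ids)
    fit <- fit_polynomial(x, r, alpha = 0.05)
    pv <- fit$p_values[setdiff(fit$terms, "intercept")]
    if (length(pv)) expect_true(all(pv < 0.05))
    expect_equal(sum(residuals(fit)), 0, tolerance = 1e-6)
    expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  }
})

test_that("collinear and undersized designs are rejected", {
  ids <- sprintf("A%d", 1:4)
  expect_error(fit_polynomial(setNames(1:4, ids), setNames(rnorm(4), ids)),
               "areas")
  ids6 <- sprintf("A%d", 1:6)
  expect_error(fit_polynomial(setNames(rep(3, 6), ids6),
                              setNames(rnorm(6), ids6)), "collinear")
})

test_that("remoteness assignment follows the population majority with remote-ward ties", {
  expect_equal(assign_remoteness(sub_populations =
                                   c("Major cities" = 900,
                                     "Inner regional" = 100)),
               "Major cities")
  expect_equal(assign_remoteness(category = "Remote"), "Remote")
  expect_warning(
    got <- assign_remoteness(sub_populations = c("Remote" = 500,
                                                 "Very remote" = 500)),
    "more remote")
  expect_equal(got, "Very remote")
  expect_error(assign_remoteness(sub_populations = numeric()), "positive")
  expect_error(assign_remoteness(category = "Suburbia"), "one of")
})

test_that("zero residuals give zero category means and F = 0", {
  res <- setNames(rep(0, 20), sprintf("A%02d", 1:20))
  cats <- setNames(rep(remoteness_levels(), 4), names(res))
  out <- residuals_by_remoteness(res, cats)
  expect_equal(out$table$mean, rep(0, 5))
  expect_equal(out$anova$F, 0)
  expect_equal(out$anova$p, 1)
})

test_that("injected remote excess yields positive remote residual means separated by Tukey", {
  sim <- simulate_cse_data(sim_config(n_areas = 1000, seed = 61))
  idx <- cse_index(sim$indicators, sim$areas)
  rates <- mean_annual_pph_rate(sim$pph_counts, sim$age_pops)
  r <- setNames(rates$pph_rate, rates$area_id)[idx$area_id]
  fit <- fit_polynomial(idx$composite, r)
  out <- residuals_by_remoteness(
    fit, setNames(sim$areas$remoteness, sim$areas$area_id))

  tab <- out$table
  remote <- tab$remoteness %in% c("Remote", "Very remote")
  expect_true(all(tab$mean[remote] > 0))
  expect_equal(sum(tab$mean * tab$n) / sum(tab$n), 0, tolerance = 1e-6)
  expect_lt(out$anova$p, 0.001)

  pairs_needed <- as.vector(outer(c("Remote", "Very remote"),
                                  c("Major cities", "Inner regional",
                                    "Outer regional"), paste, sep = "-"))
  tk <- out$tukey
  key <- function(p) {
    parts <- strsplit(p, "-(?=[A-Z])", perl = TRUE)[[1]]
    paste(sort(parts), collapse = "|")
  }
  tk_keys <- vapply(tk$pair, key, character(1))
  for (p in pairs_needed) {
    hit <- tk[tk_keys == key(p), ]
    expect_equal(nrow(hit), 1)
    expect_lt(hit$p_adj, 0.05)
  }
})

test_that("two balanced groups: Tukey adjusted p equals the pooled t-test p", {
  set.seed(66)
  res <- setNames(c(rnorm(12, 0, 1), rnorm(12, 1.2, 1)), sprintf("A%02d", 1:24))
  cats <- setNames(rep(c("Major cities", "Remote"), each = 12), names(res))
  out <- residuals_by_remoteness(res, cats)
  tt <- t.test(res[1:12], res[13:24], var.equal = TRUE)
  # with 2 groups the studentised range q = sqrt(2)|t|, so p values coincide
  expect_equal(out$tukey$p_adj, tt$p.value, tolerance = 1e-9)
  expect_equal(abs(out$tukey$diff),
               abs(unname(diff(tapply(res, cats, mean)))), tolerance = 1e-12)
})

test_that("singleton categories are excluded from Tukey with a warning", {
  set.seed(67)
  res <- setNames(rnorm(11), sprintf("A%02d", 1:11))
  cats <- setNames(c(rep("Major cities", 5), rep("Remote", 5), "Very remote"),
                   names(res))
  expect_warning(out <- residuals_by_remoteness(res, cats), "Very remote")
  expect_false(any(grepl("Very remote", out$tukey$pair)))
  expect_equal(sum(out$table$n), 11)
})

test_that("mortality chi-square matches the direct Pearson formula and its invariances", {
  deaths <- c(240, 175, 189, 163, 114)
  pops <- c(747511, 759398, 752010, 756553, 757980)
  got <- mortality_chi_square(deaths, pops)
  tab <- cbind(deaths, pops - deaths)
  expect_equal(got$chi2, oracle_chi_square(tab), tolerance = 1e-9)
  expect_equal(got$df, 4)
  # swapping the deaths and survivors columns changes nothing
  swapped <- mortality_chi_square(pops - deaths, pops)
  expect_equal(swapped$chi2, got$chi2, tolerance = 1e-9)
  # deaths proportional to population: exact homogeneity
  expect_equal(mortality_chi_square(c(10, 20, 30, 40, 50),
                                    c(1000, 2000, 3000, 4000, 5000))$chi2,
               0, tolerance = 1e-9)
  expect_error(mortality_chi_square(c(5, 1), c(4, 10)), "exceed")
})
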