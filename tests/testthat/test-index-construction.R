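test_that("area filtering applies both exclusion rules with recorded reasons", {
  a <- tiny_areas(4, pops = c(29L, 30L, 500L, 10L))
  a$nr_sole_parent <- c(0, 0.80, 0.10, 0.85)
  flt <- filter_areas(a)
  expect_setequal(flt$included$area_id, "T03")
  excl <- flt$excluded[order(flt$excluded$area_id), ]
  # 29 children: below the "fewer than 30" rule
  expect_equal(excl$reason[excl$area_id == "T01"], "low_population")
  # exactly 0.80 non-response: the threshold is inclusive
  expect_equal(excl$reason[excl$area_id == "T02"], "low_response")
  expect_equal(excl$reason[excl$area_id == "T04"],
               "low_population;low_response")

  expect_error(filter_areas(a[0, ]), "non-empty")
  expect_error(filter_areas(tiny_areas(3, pops = c(1L, 2L, 3L))),
               "min_children")
})

test_that("orientation reverses access ratios and leaves proportions bit-identical", {
  ind <- tiny_indicators(8)
  oriented <- orient_indicators(ind)
  meta <- cse_indicators()
  for (j in seq_len(nrow(meta))) {
    nm <- meta$indicator[j]
    rho <- cor(ind[[nm]], oriented[[nm]], method = "spearman")
    if (meta$orientation[j] == "proportion_risk") {
      expect_identical(oriented[[nm]], ind[[nm]])
      expect_equal(rho, 1)
    } else {
      expect_equal(rho, -1)
    }
  }
  # GP ratios 2.0 > 1.0 > 0.5 become lowest > middle > highest risk
  ind3 <- tiny_indicators(3)
  ind3$gp_ratio <- c(2.0, 1.0, 0.5)
  o3 <- orient_indicators(ind3)
  expect_equal(order(o3$gp_ratio), c(1, 2, 3))  # ascending risk order

  ind$dentist_ratio[2] <- Inf
  expect_error(orient_indicators(ind), "dentist_ratio.*T02")
})

test_that("PCA domain scores match a brute-force eigen decomposition", {
  # 4-area, 2-indicator worked fixture scored against an explicit eigen oracle
  ind <- tiny_indicators(4, seed = 1)
  oriented <- orient_indicators(ind)
  x <- as.matrix(oriented[, c("housing_stress", "overcrowding")])
  # reuse the Housing pair as a 2-indicator PCA fixture via Health services
  x2 <- as.matrix(oriented[, c("gp_ratio", "dentist_ratio")])
  got <- score_domain_pca(oriented, "Health services")
  expect_equal(unname(got), oracle_pca_score(x2), tolerance = 1e-9)

  # larger random domains against the same oracle
  for (d in c("Socio-economic", "Education", "Connectedness")) {
    o <- orient_indicators(tiny_indicators(30, seed = 99))
    cols <- cse_indicators()$indicator[cse_indicators()$domain == d]
    expect_equal(unname(score_domain_pca(o, d)),
                 oracle_pca_score(as.matrix(o[, cols])), tolerance = 1e-9)
  }
})

test_that("PCA score sign always points toward higher risk and mean is zero", {
  o <- orient_indicators(tiny_indicators(25, seed = 3))
  s <- score_domain_pca(o, "Education")
  expect_equal(mean(s), 0, tolerance = 1e-12)
  cols <- cse_indicators()$indicator[cse_indicators()$domain == "Education"]
  expect_gt(cor(s, rowMeans(scale(as.matrix(o[, cols])))), 0)

  # two perfectly correlated indicators: score proportional to either
  o2 <- tiny_indicators(10, seed = 6)
  o2$gp_ratio <- o2$dentist_ratio * 2
  o2 <- orient_indicators(o2)
  s2 <- score_domain_pca(o2, "Health services")
  expect_equal(abs(cor(s2, o2$dentist_ratio)), 1, tolerance = 1e-12)
  expect_gt(cor(s2, o2$dentist_ratio), 0)  # oriented: higher = higher risk
})

test_that("PCA errors on Housing, zero variance and too few areas", {
  o <- orient_indicators(tiny_indicators(10))
  expect_error(score_domain_pca(o, "Housing"), "score_domain_mean")
  o$no_internet <- 0.3
  expect_error(score_domain_pca(o, "Connectedness"), "no_internet")
  expect_error(score_domain_pca(orient_indicators(tiny_indicators(2)),
                                "Education"), "3 areas")
})

test_that("housing score is the symmetric arithmetic mean of two proportions", {
  o <- tiny_indicators(3)
  o$housing_stress <- c(0.30, 0, 1)
  o$overcrowding <- c(0.10, 0, 1)
  expect_equal(unname(score_domain_mean(orient_indicators(o))),
               c(0.20, 0, 1))
  # symmetry under swapping the two indicators
  o2 <- o
  o2$housing_stress <- o$overcrowding
  o2$overcrowding <- o$housing_stress
  expect_equal(score_domain_mean(orient_indicators(o2)),
               score_domain_mean(orient_indicators(o)))
  o$housing_stress[1] <- NA
  expect_error(score_domain_mean(orient_indicators(o)), "missing")
})

test_that("exponential rank transform matches its closed form and boundary", {
  tr <- exponential_rank_transform(c(a = 5, b = 1, c = 3))
  expect_equal(unname(tr$R[order(tr$R)]), (1:3) / 3)
  expect_equal(unname(tr$X[["a"]]), 100, tolerance = 1e-9)  # R = 1 -> exactly 100
  # R = 0.5 against a direct high-precision evaluation of the formula
  tr2 <- exponential_rank_transform(setNames(1:2, c("lo", "hi")))
  expect_equal(unname(tr2$X[["lo"]]),
               -23 * log(1 - 0.5 * (1 - exp(-100 / 23))), tolerance = 1e-12)
  # strictly increasing in R, positive everywhere, 0 at the R -> 0 limit
  tr3 <- exponential_rank_transform(rnorm(200))
  ord <- order(tr3$R)
  expect_true(all(diff(tr3$X[ord]) > 0))
  expect_true(all(tr3$X > 0 & tr3$X <= 100))
  expect_equal(-23 * log(1 - 0 * (1 - exp(-100 / 23))), 0)
  expect_error(exponential_rank_transform(c(1, NA)), "finite")
})

test_that("tied scores get consecutive ranks in stable id order", {
  tr <- exponential_rank_transform(c(z = 1, y = 1, x = 1))
  expect_equal(tr$R[c("x", "y", "z")], c(x = 1/3, y = 2/3, z = 1))
  expect_equal(unname(max(tr$X)), 100, tolerance = 1e-9)
})

test_that("composite index is the symmetric row mean of the five domain indices", {
  X <- matrix(runif(20, 1, 100), 4, 5, dimnames = list(NULL, cse_domains()))
  comp <- composite_index(X)
  expect_equal(comp, rowMeans(X))
  expect_true(all(comp >= apply(X, 1, min) & comp <= apply(X, 1, max)))
  expect_equal(composite_index(X[, sample(5)]), comp)  # column order irrelevant
  expect_equal(unname(composite_index(matrix(100, 1, 5,
    dimnames = list(NULL, cse_domains())))), 100)
  expect_error(composite_index(X[, -2]), colnames(X)[2])
})

test_that("weighted quintiles follow the cumulative-midpoint rule", {
  # equal weights, distinct values: 2 areas per quintile, largest in quintile 1
  q <- weighted_quintiles(10:1, rep(1, 10), letters[1:10])
  qv <- quintile_of(q)
  expect_equal(as.integer(table(qv)), rep(2L, 5))
  expect_equal(unname(qv[c("a", "b")]), c(1L, 1L))

  # one dominant area spans quintiles 1-3 by the midpoint rule
  basis <- c(9, 5, 4, 3)
  w <- c(60, 15, 15, 10)
  got <- quintile_of(weighted_quintiles(basis, w, letters[1:4]))
  expect_equal(got, oracle_weighted_quintiles(basis, w, letters[1:4]))
  expect_equal(unname(got["a"]), 2L)  # midpoint 0.30 lies in (1/5, 2/5]

  expect_error(weighted_quintiles(1:3, rep(0, 3), letters[1:3]), "positive")
  expect_error(weighted_quintiles(c(1, Inf, 2), rep(1, 3), letters[1:3]),
               "finite")
})

test_that("quintile shares deviate from 20% by at most the largest area", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    basis <- rnorm(n)
    w <- rlnorm(n, 5, 1)
    ids <- sprintf("r%02d", seq_len(n))
    q <- weighted_quintiles(basis, w, ids)
    shares <- tapply(q$assignment$weight, q$assignment$quintile, sum) / sum(w)
    expect_true(all(abs(shares - 0.2) <= max(w) / sum(w) + 1e-12))
  }
})

test_that("end-to-end: noise-free composite is a strictly monotone map of the latent factor", {
  sim <- simulate_cse_data(sim_config(n_areas = 150, seed = 17,
                                      indicator_noise_sd = 0))
  idx <- cse_index(sim$indicators, sim$areas)
  z <- sim$latent[idx$area_id]
  expect_equal(cor(idx$composite, z, method = "spearman"), 1)
})

test_that("rescaling one oriented indicator changes no PCA score or quintile", {
  sim <- simulate_cse_data(sim_config(n_areas = 120, seed = 23))
  idx1 <- cse_index(sim$indicators, sim$areas)
  ind2 <- sim$indicators
  ind2$no_internet <- ind2$no_internet * 7.3  # positive rescale
  idx2 <- cse_index(ind2, sim$areas)
  expect_equal(idx2$domain_scores[, "Connectedness"],
               idx1$domain_scores[, "Connectedness"], tolerance = 1e-9)
  expect_equal(quintile_of(idx2$quintiles$composite),
               quintile_of(idx1$quintiles$composite))
})

test_that("transformed domain indices always lie in (0, 100]", {
  sim <- simulate_cse_data(sim_config(n_areas = 90, seed = 29))
  idx <- cse_index(sim$indicators, sim$areas)
  expect_true(all(idx$X > 0 & idx$X <= 100))
  expect_true(all(idx$composite > 0 & idx$composite <= 100))
})
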