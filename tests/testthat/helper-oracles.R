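# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each quantity from its defining formula and
# never call the package function they check.

oracle_weighted_pearson <- function(x, y, w) {
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  num <- 0; vx <- 0; vy <- 0
  for (i in seq_along(x)) {
    num <- num + w[i] * (x[i] - mx) * (y[i] - my)
    vx <- vx + w[i] * (x[i] - mx)^2
    vy <- vy + w[i] * (y[i] - my)^2
  }
  num / sqrt(vx * vy)
}

# enumerate cumulative-weight intervals and place each area's midpoint
oracle_weighted_quintiles <- function(basis, weights, ids) {
  ord <- order(-basis, ids)
  total <- sum(weights)
  lo <- 0
  q <- integer(length(basis))
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    hi <- lo + weights[i]
    mid5 <- 5 * (lo + hi) / 2
    k <- NA_integer_
    for (kk in 1:5) {
      if (mid5 > (kk - 1) * total && mid5 <= kk * total) { k <- kk; break }
    }
    if (is.na(k)) k <- if (mid5 <= 0) 1L else 5L
    q[i] <- k
    lo <- hi
  }
  stats::setNames(q, ids)
}

oracle_age_standardised_rate <- function(counts, pops, shares) {
  g <- names(shares)
  total <- 0
  for (a in g) {
    r <- if (pops[[a]] > 0) counts[[a]] / pops[[a]] else 0
    total <- total + shares[[a]] * r
  }
  1000 * total
}

oracle_welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_chi_square <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- rs[i] * cs[j] / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  unname(stat)
}

# first-principal-component domain score from an explicit eigen decomposition
oracle_pca_score <- function(x) {
  xs <- scale(x)
  ev <- eigen(stats::cor(x))$vectors[, 1]
  s <- as.numeric(xs %*% ev)
  if (cor(s, rowMeans(xs)) < 0) s <- -s
  s
}

# small synthetic area/indicator tables for unit tests
tiny_areas <- function(n = 6, pops = NULL, nr = 0) {
  meta <- cse_indicators()
  a <- data.frame(area_id = sprintf("T%02d", seq_len(n)),
                  child_pop_0_15 = if (is.null(pops)) rep(100L, n) else pops,
                  remoteness = rep("Major cities", n),
                  stringsAsFactors = FALSE)
  for (ind in meta$indicator) a[[paste0("nr_", ind)]] <- nr
  a
}

tiny_indicators <- function(n = 6, seed = 42) {
  set.seed(seed)
  meta <- cse_indicators()
  out <- data.frame(area_id = sprintf("T%02d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(nrow(meta))) {
    out[[meta$indicator[j]]] <- if (meta$orientation[j] == "proportion_risk")
      runif(n, 0.02, 0.6) else runif(n, 0.3, 2)
  }
  out
}
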