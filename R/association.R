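#' Population-weighted Pearson correlation
#'
#' Pearson correlation with observations weighted by child population, so
#' populous areas contribute proportionally more:
#' \deqn{r = \frac{\sum w (x - \bar x_w)(y - \bar y_w)}
#'             {\sqrt{\sum w (x - \bar x_w)^2 \sum w (y - \bar y_w)^2}}}
#' with weighted means \eqn{\bar x_w, \bar y_w}.
#'
#' @param x,y Numeric vectors.
#' @param w Nonnegative weights (child populations).
#' @return Correlation in \code{[-1, 1]}.
#' @export
weighted_pearson <- function(x, y, w) {
  stopifnot(length(x) == length(y), length(x) == length(w))
  keep <- w > 0
  if (sum(keep) < 3) stop("need at least 3 areas with positive weight",
                          call. = FALSE)
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0)
    stop("zero weighted variance in x or y", call. = FALSE)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

new_crosstab <- function(shares) {
  shares <- as.matrix(shares)
  stopifnot(nrow(shares) == 5, ncol(shares) == 5)
  d <- row(shares) - col(shares)
  structure(list(
    shares = shares,
    row_totals = rowSums(shares),
    col_totals = colSums(shares),
    diagonal_pct = sum(shares[d == 0]),
    diagonal_adjacent_pct = sum(shares[abs(d) <= 1])
  ), class = "cse_crosstab")
}

#' Concordance cross-tabulation from a percentage matrix
#'
#' Wraps an existing 5x5 matrix of percentages of children (rows = outcome
#' quintile, columns = index quintile) and computes the diagonal and
#' diagonal-plus-adjacent concordance sums. Used when the cell shares are
#' already available, e.g. from a published table.
#'
#' @param shares 5x5 numeric matrix of percentages (grand total ~100).
#' @return An object of class \code{cse_crosstab}.
#' @export
as_crosstab <- function(shares) new_crosstab(shares)

#' Quintile concordance cross-tabulation
#'
#' Cross-tabulates two quintile assignments over the same areas, with each
#' cell holding the percentage of all children living in areas with that
#' combination of outcome and index quintile. The diagonal sum is the share of
#' children whose outcome quintile coincides with their index quintile; the
#' diagonal-plus-adjacent sum allows a one-quintile discrepancy.
#'
#' @param outcome_q,index_q [weighted_quintiles()] objects (e.g. built from
#'   hospitalisation rates and from the index) covering the same areas.
#' @param weights Named child populations per area; defaults to the weights
#'   stored in \code{outcome_q}.
#' @return An object of class \code{cse_crosstab} with elements
#'   \code{shares}, \code{row_totals}, \code{col_totals},
#'   \code{diagonal_pct} and \code{diagonal_adjacent_pct}.
#' @export
crosstab_shares <- function(outcome_q, index_q, weights = NULL) {
  qo <- quintile_of(outcome_q)
  qi <- quintile_of(index_q)
  if (!setequal(names(qo), names(qi)))
    stop("quintile assignments cover different areas", call. = FALSE)
  ids <- names(qo)
  if (is.null(weights))
    weights <- stats::setNames(outcome_q$assignment$weight,
                               outcome_q$assignment$area_id)
  if (!all(ids %in% names(weights)))
    stop("weights missing for some areas", call. = FALSE)
  w <- weights[ids]
  m <- matrix(0, 5, 5, dimnames = list(outcome = 1:5, index = 1:5))
  for (i in seq_along(ids)) {
    m[qo[i], qi[ids[i]]] <- m[qo[i], qi[ids[i]]] + w[i]
  }
  new_crosstab(100 * m / sum(w))
}

#' @export
print.cse_crosstab <- function(x, digits = 1, ...) {
  m <- cbind(x$shares, Total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, 100))
  print(round(m, digits))
  cat(sprintf("Diagonal: %.1f%% of children; diagonal + adjacent: %.1f%%\n",
              x$diagonal_pct, x$diagonal_adjacent_pct))
  invisible(x)
}

#' Per-quintile summary of area rates
#'
#' Unweighted mean, sample standard deviation, minimum and maximum of the
#' area-level rates in each quintile (dispersion across areas, not across
#' children).
#'
#' @param rates Data frame (\code{area_id}, \code{pph_rate}) as returned by
#'   [mean_annual_pph_rate()], or a named numeric vector.
#' @param quintiles A [weighted_quintiles()] assignment.
#' @return Data frame with \code{quintile}, \code{mean}, \code{sd},
#'   \code{min}, \code{max}, \code{n}.
#' @export
quintile_summary <- function(rates, quintiles) {
  r <- rate_vector(rates)
  q <- as_quintile_vector(quintiles)
  if (!all(names(q) %in% names(r)))
    stop("rates missing for some quintiled areas", call. = FALSE)
  r <- r[names(q)]
  out <- do.call(rbind, lapply(sort(unique(q)), function(k) {
    v <- r[q == k]
    if (length(v) == 0) stop("empty quintile ", k, call. = FALSE)
    data.frame(quintile = k, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               min = min(v), max = max(v), n = length(v))
  }))
  rownames(out) <- NULL
  out
}

# accept either a weighted_quintiles() object or a named integer vector
as_quintile_vector <- function(quintiles) {
  if (inherits(quintiles, "cse_quintiles")) return(quintile_of(quintiles))
  if (is.null(names(quintiles)))
    stop("quintile assignment must be a cse_quintiles object or named vector",
         call. = FALSE)
  quintiles
}

rate_vector <- function(rates) {
  if (is.data.frame(rates)) {
    stopifnot(all(c("area_id", "pph_rate") %in% names(rates)))
    stats::setNames(rates$pph_rate, rates$area_id)
  } else {
    if (is.null(names(rates))) stop("rates must be named by area", call. = FALSE)
    rates
  }
}

#' Tests for a gradient in rates across quintiles
#'
#' One-way ANOVA of area rates by quintile, a Kruskal-Wallis rank test (robust
#' to the strongly unequal variances typical of the most disadvantaged
#' quintile) and Welch two-sample t-tests for all quintile pairs
#' (Welch-Satterthwaite degrees of freedom, no equal-variance assumption).
#'
#' @param rates Rates as in [quintile_summary()].
#' @param quintiles A [weighted_quintiles()] assignment.
#' @return An object of class \code{cse_gradient_tests}: list with
#'   \code{anova} (F, df_between, df_within, p), \code{kruskal_wallis}
#'   (chi2, df, p) and \code{welch_pairs} (data frame of all pairs).
#' @export
gradient_tests <- function(rates, quintiles) {
  r <- rate_vector(rates)
  q <- as_quintile_vector(quintiles)
  r <- r[names(q)]
  grp <- factor(q)
  sizes <- table(grp)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("each quintile needs at least 2 areas", call. = FALSE)

  av <- stats::anova(stats::aov(r ~ grp))
  kw <- stats::kruskal.test(r, grp)

  pairs <- utils::combn(sort(unique(q)), 2)
  welch <- do.call(rbind, apply(pairs, 2, function(p) {
    tt <- stats::t.test(r[q == p[1]], r[q == p[2]], var.equal = FALSE)
    data.frame(q_i = p[1], q_j = p[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))

  structure(list(
    anova = list(F = av$`F value`[1], df_between = av$Df[1],
                 df_within = av$Df[2], p = av$`Pr(>F)`[1]),
    kruskal_wallis = list(chi2 = unname(kw$statistic),
                          df = unname(kw$parameter), p = kw$p.value),
    welch_pairs = welch
  ), class = "cse_gradient_tests")
}

#' @export
print.cse_gradient_tests <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.2f, p = %.3g\n",
              x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p))
  cat(sprintf("Kruskal-Wallis: chi2 = %.2f, df = %d, p = %.3g\n",
              x$kruskal_wallis$chi2, x$kruskal_wallis$df, x$kruskal_wallis$p))
  cat("Welch pairwise t-tests:\n")
  print(transform(x$welch_pairs, t = round(t, 2), df = round(df, 1),
                  p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}
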