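#' Polynomial regression of hospitalisation rate on the index, with backward
#' elimination
#'
#' Fits ordinary least squares of the area rate on raw polynomial terms of the
#' composite index (index, index^2, index^3 up to \code{max_degree}), then
#' repeatedly drops the non-intercept term with the largest p-value at or
#' above \code{alpha} and refits, until every remaining term is significant.
#' The intercept is always retained. Raw (non-orthogonal) powers are used so
#' coefficients are on the natural scale of the index.
#'
#' When the model fits the data exactly (residual sum of squares numerically
#' zero relative to the total), t-based p-values are undefined; elimination
#' then falls back to an exact-fit comparison: a term is dropped if and only
#' if the model without it still fits exactly.
#'
#' @param index Named numeric vector of composite index values per area (or a
#'   \code{cse_index} object, whose composite is used).
#' @param rates Rates as in [quintile_summary()].
#' @param max_degree Highest power explored (default 3).
#' @param alpha Significance level for retention (default 0.05).
#' @return An object of class \code{cse_pph_fit}: list with \code{fit} (the
#'   underlying \code{lm}), \code{terms}, \code{coefficients},
#'   \code{p_values}, \code{r_squared}, \code{residuals} (named by area) and
#'   \code{alpha}.
#' @export
#' @examples
#' x <- stats::setNames(seq(5, 95, length.out = 50), sprintf("A%02d", 1:50))
#' r <- 0.0071 * x^2 + 21.74
#' fit <- fit_polynomial(x, stats::setNames(r, names(x)))
#' coef(fit)
fit_polynomial <- function(index, rates, max_degree = 3L, alpha = 0.05) {
  if (inherits(index, "cse_index")) index <- index$composite
  r <- rate_vector(rates)
  ids <- intersect(names(index), names(r))
  if (length(ids) < max_degree + 2)
    stop("need at least max_degree + 2 areas", call. = FALSE)
  df <- data.frame(rate = r[ids], x = index[ids])
  term_names <- paste0("I(x^", seq_len(max_degree), ")")
  term_names[1] <- "x"
  labels <- c("index", "index^2", "index^3")[seq_len(max_degree)]

  active <- seq_len(max_degree)
  if (stats::var(df$rate) == 0) active <- integer(0)  # degenerate: constant rates
  if (length(active) == 0) {
    fit <- stats::lm(rate ~ 1, data = df)
  } else repeat {
    form <- stats::reformulate(term_names[active], response = "rate")
    fit <- stats::lm(form, data = df)
    if (anyNA(stats::coef(fit)))
      stop("collinear design: polynomial terms are linearly dependent",
           call. = FALSE)
    rss <- sum(stats::residuals(fit)^2)
    tss <- sum((df$rate - mean(df$rate))^2)
    exact <- tss > 0 && rss / tss < 1e-10
    if (length(active) == 0) break
    if (exact) {
      # p-values are undefined at zero residual variance: a term is
      # removable iff the model without it still fits exactly
      droppable <- vapply(seq_along(active), function(j) {
        rest <- active[-j]
        f2 <- if (length(rest)) {
          stats::lm(stats::reformulate(term_names[rest], response = "rate"),
                    data = df)
        } else stats::lm(rate ~ 1, data = df)
        sum(stats::residuals(f2)^2) / tss < 1e-10
      }, logical(1))
      if (!any(droppable)) break
      active <- active[-max(which(droppable))]  # drop highest removable power
    } else {
      pv <- summary(fit)$coefficients[-1, "Pr(>|t|)"]
      if (all(pv < alpha)) break
      active <- active[-which.max(pv)]
    }
    if (length(active) == 0) {
      fit <- stats::lm(rate ~ 1, data = df)
      break
    }
  }

  smry <- summary(fit)
  cf <- stats::coef(fit)
  names(cf) <- vapply(names(cf), function(nm) {
    if (nm == "(Intercept)") "intercept" else labels[match(nm, term_names)]
  }, character(1), USE.NAMES = FALSE)
  pv_all <- smry$coefficients[, "Pr(>|t|)"]
  names(pv_all) <- names(cf)
  res <- stats::setNames(stats::residuals(fit), ids)

  structure(list(
    fit = fit,
    terms = names(cf),
    coefficients = cf,
    p_values = pv_all,
    r_squared = smry$r.squared,
    residuals = res,
    alpha = alpha,
    n = length(ids)
  ), class = "cse_pph_fit")
}

#' @export
print.cse_pph_fit <- function(x, ...) {
  eq <- paste(sprintf("%.4g * %s", x$coefficients[-1],
                      names(x$coefficients)[-1]), collapse = " + ")
  if (eq == "") eq <- "(intercept only)"
  cat("Hospitalisation rate model (backward elimination, alpha =", x$alpha,
      "):\n  rate =", eq, "+", sprintf("%.4g", x$coefficients[["intercept"]]),
      "\n")
  cat(sprintf("  r^2 = %.3f on %d areas\n", x$r_squared, x$n))
  invisible(x)
}

#' @export
summary.cse_pph_fit <- function(object, ...) summary(object$fit, ...)

#' @export
coef.cse_pph_fit <- function(object, ...) object$coefficients

#' @export
residuals.cse_pph_fit <- function(object, ...) object$residuals

#' @export
fitted.cse_pph_fit <- function(object, ...)
  stats::setNames(stats::fitted(object$fit), names(object$residuals))

#' @export
predict.cse_pph_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  if (is.numeric(newdata)) newdata <- data.frame(x = newdata)
  stats::predict(object$fit, newdata = newdata, ...)
}

#' Assign an area to a single remoteness category
#'
#' Areas spanning several remoteness categories are placed in the category
#' where the majority of their population lives; ties go to the more remote
#' category (with a warning), reflecting that service access is limited by the
#' remoter part.
#'
#' @param category The area's category, if it lies wholly in one.
#' @param sub_populations Named population counts by category for areas that
#'   span several.
#' @return One of [remoteness_levels()].
#' @export
assign_remoteness <- function(category = NULL, sub_populations = NULL) {
  lv <- remoteness_levels()
  if (is.null(sub_populations)) {
    if (is.null(category) || !category %in% lv)
      stop("category must be one of: ", paste(lv, collapse = ", "),
           call. = FALSE)
    return(category)
  }
  sub_populations <- sub_populations[sub_populations > 0]
  if (length(sub_populations) == 0 || sum(sub_populations) <= 0)
    stop("sub_populations must contain positive counts", call. = FALSE)
  if (!all(names(sub_populations) %in% lv))
    stop("unknown remoteness categories: ",
         paste(setdiff(names(sub_populations), lv), collapse = ", "),
         call. = FALSE)
  mx <- max(sub_populations)
  top <- names(sub_populations)[sub_populations == mx]
  if (length(top) > 1) {
    top <- top[which.max(match(top, lv))]
    warning("remoteness tie resolved to the more remote category: ", top,
            call. = FALSE)
  }
  top
}

#' Residual rates summarised by remoteness
#'
#' Summarises model residuals (observed minus predicted rate) within each
#' remoteness category, tests for differences with a one-way ANOVA, and runs
#' Tukey-Kramer all-pairs comparisons (honest significant differences with
#' unequal group sizes). Positive mean residuals mark categories whose areas
#' have systematically worse outcomes than their social-exclusion risk
#' predicts.
#'
#' @param fit A [fit_polynomial()] result (or a named residual vector).
#' @param categories Named character vector of remoteness categories covering
#'   every fitted area.
#' @return An object of class \code{cse_remoteness_residuals}: list with
#'   \code{table} (per-category mean, sd, min, max, n), \code{anova} (F,
#'   df_between, df_within, p) and \code{tukey} (data frame of pairwise
#'   differences and adjusted p-values).
#' @export
residuals_by_remoteness <- function(fit, categories) {
  res <- if (inherits(fit, "cse_pph_fit")) fit$residuals else fit
  if (is.null(names(res))) stop("residuals must be named by area", call. = FALSE)
  if (!all(names(res) %in% names(categories)))
    stop("remoteness category missing for some fitted areas", call. = FALSE)
  cat_ <- factor(categories[names(res)],
                 levels = intersect(remoteness_levels(),
                                    unique(categories[names(res)])))

  tab <- do.call(rbind, lapply(levels(cat_), function(lv) {
    v <- res[cat_ == lv]
    data.frame(remoteness = lv, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               min = min(v), max = max(v), n = length(v),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL

  if (stats::var(res) == 0) {
    anova_res <- list(F = 0, df_between = nlevels(cat_) - 1L,
                      df_within = length(res) - nlevels(cat_), p = 1)
    tukey <- data.frame(pair = character(), diff = numeric(),
                        p_adj = numeric())
  } else {
    av <- stats::anova(stats::aov(res ~ cat_))
    anova_res <- list(F = av$`F value`[1], df_between = av$Df[1],
                      df_within = av$Df[2], p = av$`Pr(>F)`[1])
    small <- tab$remoteness[tab$n < 2]
    keep <- !(as.character(cat_) %in% small)
    if (length(small)) {
      warning("categories with < 2 areas excluded from Tukey comparisons: ",
              paste(small, collapse = ", "), call. = FALSE)
    }
    sub_cat <- droplevels(cat_[keep])
    hsd <- stats::TukeyHSD(stats::aov(res[keep] ~ sub_cat))$sub_cat
    tukey <- data.frame(pair = rownames(hsd), diff = hsd[, "diff"],
                        p_adj = hsd[, "p adj"], row.names = NULL,
                        stringsAsFactors = FALSE)
  }

  structure(list(table = tab, anova = anova_res, tukey = tukey),
            class = "cse_remoteness_residuals")
}

#' @export
print.cse_remoteness_residuals <- function(x, ...) {
  cat("Residual rate by remoteness:\n")
  print(transform(x$table, mean = round(mean, 1), sd = round(sd, 1),
                  min = round(min, 1), max = round(max, 1)),
        row.names = FALSE)
  cat(sprintf("ANOVA: F(%d, %d) = %.2f, p = %.3g\n", x$anova$df_between,
              x$anova$df_within, x$anova$F, x$anova$p))
  if (nrow(x$tukey)) {
    cat("Tukey-Kramer pairs with adjusted p < 0.05:\n")
    sig <- x$tukey[x$tukey$p_adj < 0.05, ]
    if (nrow(sig)) print(transform(sig, diff = round(diff, 1),
                                   p_adj = signif(p_adj, 2)),
                         row.names = FALSE)
    else cat("  (none)\n")
  }
  invisible(x)
}

#' Chi-square test of death rates across quintiles
#'
#' Builds the 5x2 contingency table of avoidable deaths and survivors
#' (population minus deaths) per quintile and applies Pearson's chi-square
#' test without continuity correction (df = quintiles - 1). A significant
#' statistic indicates that the avoidable-death rate differs across quintiles.
#'
#' @param deaths Integer death counts per quintile (length 5 in the standard
#'   analysis).
#' @param populations Child populations per quintile, each at least the
#'   corresponding death count.
#' @return An object of class \code{cse_contingency}: list with \code{table}
#'   (deaths, survivors), \code{chi2}, \code{df} and \code{p}.
#' @export
#' @examples
#' mortality_chi_square(c(240, 175, 189, 163, 114),
#'                      c(747511, 759398, 752010, 756553, 757980))
mortality_chi_square <- function(deaths, populations) {
  stopifnot(length(deaths) == length(populations))
  if (any(deaths < 0) || any(populations < 0))
    stop("counts must be nonnegative", call. = FALSE)
  if (any(deaths > populations))
    stop("deaths exceed population in some quintile", call. = FALSE)
  if (sum(populations > 0) < 2)
    stop("need at least 2 quintiles with positive population", call. = FALSE)
  tab <- cbind(deaths = deaths, survivors = populations - deaths)
  rownames(tab) <- paste0("Q", seq_along(deaths))
  ct <- stats::chisq.test(tab, correct = FALSE)
  structure(list(table = tab, chi2 = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value),
            class = "cse_contingency")
}

#' @export
print.cse_contingency <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi2 = %.1f, df = %d, p = %.3g\n", x$chi2, x$df, x$p))
  invisible(x)
}
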