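#' Filter small areas by child population and census response
#'
#' Areas with fewer than \code{min_children} resident children aged 0-15, or
#' with a non-response fraction at or above \code{max_nonresponse} for any
#' indicator, are excluded from index construction. An area can fail both
#' rules; both reasons are recorded.
#'
#' @param areas Data frame with columns \code{area_id}, \code{child_pop_0_15}
#'   and one \code{nr_<indicator>} column per indicator.
#' @param min_children Minimum resident children 0-15 (default 30; the rule is
#'   "fewer than", so an area with exactly 30 is kept).
#' @param max_nonresponse Non-response threshold in (0, 1] (default 0.80; the
#'   rule is inclusive, so a fraction of exactly 0.80 excludes).
#' @return A list with \code{included} (the retained rows of \code{areas}) and
#'   \code{excluded}, a data frame with \code{area_id}, logical columns
#'   \code{low_population} and \code{low_response}, and a combined
#'   \code{reason} string.
#' @export
filter_areas <- function(areas, min_children = 30L, max_nonresponse = 0.80) {
  if (!is.data.frame(areas) || nrow(areas) == 0)
    stop("'areas' must be a non-empty data frame", call. = FALSE)
  stopifnot(min_children >= 0, max_nonresponse > 0, max_nonresponse <= 1)
  nr_cols <- grep("^nr_", names(areas), value = TRUE)
  low_pop <- areas$child_pop_0_15 < min_children
  low_resp <- if (length(nr_cols)) {
    apply(as.matrix(areas[, nr_cols, drop = FALSE]) >= max_nonresponse, 1, any)
  } else rep(FALSE, nrow(areas))
  out <- low_pop | low_resp
  if (all(out)) {
    stop("all areas excluded (min_children = ", min_children,
         ", max_nonresponse = ", max_nonresponse, ")", call. = FALSE)
  }
  excl <- data.frame(
    area_id = areas$area_id[out],
    low_population = low_pop[out],
    low_response = low_resp[out],
    stringsAsFactors = FALSE
  )
  excl$reason <- apply(excl[, c("low_population", "low_response")], 1,
                       function(r) paste(c("low_population", "low_response")[r],
                                         collapse = ";"))
  list(included = areas[!out, , drop = FALSE], excluded = excl)
}

#' Orient all indicators so larger means higher risk
#'
#' Proportion-type indicators are returned unchanged. Access-ratio indicators
#' (GP ratio, dentist ratio, literacy/numeracy score ratio), where larger raw
#' values mean better circumstances, are negated so that larger always means a
#' higher risk of social exclusion. Negation exactly reverses the ordering and
#' is absorbed by the standardisation applied before principal-component
#' scoring.
#'
#' @param indicators Data frame with \code{area_id} and one column per
#'   indicator named as in [cse_indicators()].
#' @param meta Indicator metadata; defaults to [cse_indicators()].
#' @return The indicator data frame with inverted columns negated.
#' @export
orient_indicators <- function(indicators, meta = cse_indicators()) {
  missing_cols <- setdiff(meta$indicator, names(indicators))
  if (length(missing_cols))
    stop("indicator columns missing: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- indicators
  for (nm in meta$indicator[meta$orientation == "ratio_inverted"]) {
    v <- out[[nm]]
    if (any(!is.finite(v))) {
      bad <- out$area_id[!is.finite(v)]
      stop("non-finite values in inverted indicator '", nm, "' for areas: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    out[[nm]] <- -v
  }
  attr(out, "oriented") <- TRUE
  out
}

#' Domain score by first principal component
#'
#' Standardises each of the domain's oriented indicators to mean 0 and
#' variance 1 over the included areas and extracts the first principal
#' component of their correlation structure. The component sign is fixed so
#' the score correlates positively with the unweighted mean of the domain's
#' oriented indicators, guaranteeing that a higher score always means higher
#' risk. Scores have mean 0 by construction.
#'
#' @param oriented Oriented indicator data frame (see [orient_indicators()]).
#' @param domain One of the four multi-indicator domains; the Housing domain
#'   uses [score_domain_mean()] instead.
#' @param meta Indicator metadata.
#' @return Numeric vector of raw domain scores, named by \code{area_id}.
#' @export
score_domain_pca <- function(oriented, domain, meta = cse_indicators()) {
  if (identical(domain, "Housing"))
    stop("Housing is scored by score_domain_mean(), not PCA", call. = FALSE)
  cols <- meta$indicator[meta$domain == domain]
  if (length(cols) < 2) stop("unknown or single-indicator domain: ", domain,
                             call. = FALSE)
  x <- as.matrix(oriented[, cols, drop = FALSE])
  if (nrow(x) < 3) stop("PCA needs at least 3 areas", call. = FALSE)
  vars <- apply(x, 2, stats::var)
  if (any(vars <= 0))
    stop("zero-variance indicator in domain ", domain, ": ",
         paste(cols[vars <= 0], collapse = ", "), call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  score <- pc$x[, 1]
  if (stats::cor(score, rowMeans(scale(x))) < 0) score <- -score
  stats::setNames(as.numeric(score), oriented$area_id)
}

#' Housing domain score by arithmetic mean
#'
#' The two housing indicators (rental stress and overcrowding) are weakly
#' correlated, so the domain score is their plain arithmetic mean rather than
#' a principal component.
#'
#' @param oriented Oriented indicator data frame.
#' @param meta Indicator metadata.
#' @return Numeric vector in \code{[0, 1]}, named by \code{area_id}.
#' @export
score_domain_mean <- function(oriented, meta = cse_indicators()) {
  cols <- meta$indicator[meta$domain == "Housing"]
  stopifnot(length(cols) == 2)
  x <- as.matrix(oriented[, cols, drop = FALSE])
  if (anyNA(x)) stop("missing housing indicator values", call. = FALSE)
  if (any(x < 0 | x > 1))
    stop("housing indicators must be proportions in [0, 1]", call. = FALSE)
  stats::setNames(rowMeans(x), oriented$area_id)
}

#' Exponential transformation of domain ranks
#'
#' Areas are ranked in ascending order of risk: the least deprived area gets
#' rank 1 and scaled rank \code{R = 1/N}, the most deprived gets \code{R = 1}.
#' Ties take consecutive ranks in stable id order so that \code{R} always
#' equals \code{k/N}. The transformed index is
#' \deqn{X = -23 \log\{1 - R (1 - e^{-100/23})\}}
#' which maps \code{(0, 1]} onto \code{(0, 100]} with \code{X = 100} exactly
#' at \code{R = 1}, stretching the deprived tail so the most excluded areas
#' are separated more finely than the rest.
#'
#' @param scores Numeric vector of raw domain scores (higher = higher risk).
#' @param ids Optional ids used to break ties deterministically; defaults to
#'   the names of \code{scores} or element order.
#' @return A list with \code{R} (scaled ranks in \code{(0, 1]}) and \code{X}
#'   (transformed index in \code{(0, 100]}), both named like \code{scores}.
#' @export
#' @examples
#' exponential_rank_transform(c(a = 0.1, b = 2.5, c = 1.0))
exponential_rank_transform <- function(scores, ids = NULL) {
  if (length(scores) < 1 || any(!is.finite(scores)))
    stop("scores must be finite and non-empty", call. = FALSE)
  if (is.null(ids)) ids <- names(scores)
  if (is.null(ids)) ids <- seq_along(scores)
  n <- length(scores)
  ord <- order(scores, ids)          # ascending risk, ties by id
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  R <- rank / n
  X <- -23 * log(1 - R * (1 - exp(-100 / 23)))
  names(R) <- names(X) <- names(scores)
  list(R = R, X = X)
}

#' Composite index as the mean of the five transformed domain indices
#'
#' @param X Matrix or data frame of transformed domain indices with one column
#'   per domain (all five of [cse_domains()] must be present), values in
#'   \code{(0, 100]}.
#' @return Numeric vector of composite scores in \code{(0, 100]}.
#' @export
composite_index <- function(X) {
  X <- as.matrix(X)
  missing_dom <- setdiff(cse_domains(), colnames(X))
  if (length(missing_dom))
    stop("missing domain columns: ", paste(missing_dom, collapse = ", "),
         call. = FALSE)
  X <- X[, cse_domains(), drop = FALSE]
  if (any(!is.finite(X)) || any(X <= 0 | X > 100))
    stop("domain indices must lie in (0, 100]", call. = FALSE)
  rowMeans(X)
}

#' Child-population weighted quintiles
#'
#' Areas are sorted by the basis value in descending order (highest risk or
#' highest rate first; ties broken by area id) and the cumulative child
#' population computed. An area belongs to quintile \code{k} when the midpoint
#' of its cumulative-weight interval falls in \code{((k-1)/5, k/5]} of the
#' total weight, so each quintile holds as close to 20\% of all children as
#' the atomicity of areas allows and quintile 1 always holds the areas with
#' the largest basis values.
#'
#' @param basis Numeric vector (index score or rate), named by area id or
#'   accompanied by \code{ids}.
#' @param weights Child populations, same length as \code{basis}.
#' @param ids Area identifiers; defaults to \code{names(basis)}.
#' @param label Name of the basis (e.g. \code{"composite"}), kept for
#'   reporting.
#' @return An object of class \code{cse_quintiles}: a list with
#'   \code{assignment} (data frame of \code{area_id}, \code{quintile},
#'   \code{weight}, \code{basis}) and \code{label}.
#' @export
weighted_quintiles <- function(basis, weights, ids = names(basis),
                               label = "basis") {
  if (is.null(ids)) ids <- as.character(seq_along(basis))
  ids <- as.character(ids)
  stopifnot(length(basis) == length(weights), length(ids) == length(basis))
  if (any(!is.finite(basis))) stop("basis values must be finite", call. = FALSE)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  total <- sum(weights)
  if (total <= 0) stop("total weight must be positive", call. = FALSE)
  ord <- order(-basis, ids)
  w <- weights[ord]
  # area k in quintile q iff (q-1)*total < 5*midpoint_k <= q*total; comparing
  # in the unscaled weight space keeps integer weights exact at boundaries
  m5 <- 5 * (cumsum(w) - w / 2)
  q <- rowSums(outer(m5, total * (1:4), ">")) + 1L
  q <- pmin(pmax(q, 1L), 5L)
  assignment <- data.frame(
    area_id = ids[ord], quintile = as.integer(q),
    weight = w, basis = basis[ord],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(assignment = assignment, label = label),
            class = "cse_quintiles")
}

#' @export
print.cse_quintiles <- function(x, ...) {
  shares <- tapply(x$assignment$weight, x$assignment$quintile, sum)
  shares <- 100 * shares / sum(x$assignment$weight)
  cat("Population-weighted quintiles of", x$label, "(1 = highest):\n")
  print(round(shares, 2))
  invisible(x)
}

#' Extract a named quintile vector from a \code{cse_quintiles} object
#' @param q A \code{cse_quintiles} object.
#' @return Integer vector of quintiles named by area id.
#' @export
quintile_of <- function(q) {
  stopifnot(inherits(q, "cse_quintiles"))
  stats::setNames(q$assignment$quintile, q$assignment$area_id)
}

#' Build the child social exclusion index
#'
#' Runs the full index pipeline: filter areas, orient indicators, score the
#' five domains (principal components for Socio-economic, Education,
#' Connectedness and Health services; the arithmetic mean for Housing), apply
#' the exponential rank transformation to each domain, average the five
#' transformed indices into the composite, and assign child-population
#' weighted quintiles for the composite and every domain (quintile 1 = highest
#' risk).
#'
#' @param indicators Data frame of raw indicator values (see
#'   [cse_indicators()] for the expected columns).
#' @param areas Area table with \code{area_id}, \code{child_pop_0_15} and
#'   \code{nr_*} non-response columns.
#' @param min_children,max_nonresponse Filtering thresholds; see
#'   [filter_areas()].
#' @param meta Indicator metadata.
#' @return An object of class \code{cse_index} with elements \code{area_id},
#'   \code{domain_scores} (raw scores), \code{R}, \code{X} (scaled ranks and
#'   transformed indices per domain), \code{composite}, \code{weights} (child
#'   populations), \code{quintiles} (named list of [weighted_quintiles()]
#'   results for \code{composite} and each domain) and \code{excluded}.
#' @export
#' @examples
#' sim <- simulate_cse_data(sim_config(n_areas = 120, seed = 3))
#' idx <- cse_index(sim$indicators, sim$areas)
#' summary(idx)
cse_index <- function(indicators, areas, min_children = 30L,
                      max_nonresponse = 0.80, meta = cse_indicators()) {
  flt <- filter_areas(areas, min_children, max_nonresponse)
  keep <- flt$included$area_id
  ind <- indicators[match(keep, indicators$area_id), , drop = FALSE]
  if (anyNA(ind$area_id))
    stop("areas missing from the indicator table: ",
         paste(utils::head(setdiff(keep, indicators$area_id), 5),
               collapse = ", "), call. = FALSE)
  oriented <- orient_indicators(ind, meta)

  domains <- cse_domains()
  raw <- sapply(domains, function(d) {
    if (d == "Housing") score_domain_mean(oriented, meta)
    else score_domain_pca(oriented, d, meta)
  })
  rownames(raw) <- keep

  tr <- lapply(domains, function(d)
    exponential_rank_transform(raw[, d], ids = keep))
  names(tr) <- domains
  R <- sapply(tr, `[[`, "R")
  X <- sapply(tr, `[[`, "X")
  rownames(R) <- rownames(X) <- keep
  composite <- composite_index(X)

  weights <- stats::setNames(flt$included$child_pop_0_15, keep)
  quintiles <- c(
    list(composite = weighted_quintiles(composite, weights, keep,
                                        label = "composite")),
    stats::setNames(lapply(domains, function(d)
      weighted_quintiles(X[, d], weights, keep, label = d)), domains)
  )

  structure(list(
    area_id = keep, domain_scores = raw, R = R, X = X,
    composite = stats::setNames(composite, keep),
    weights = weights, quintiles = quintiles,
    excluded = flt$excluded,
    thresholds = c(min_children = min_children,
                   max_nonresponse = max_nonresponse)
  ), class = "cse_index")
}

#' @export
print.cse_index <- function(x, ...) {
  cat("Child social exclusion index:", length(x$area_id), "areas",
      sprintf("(%d excluded)\n", nrow(x$excluded)))
  cat("Composite score: median", round(stats::median(x$composite), 1),
      "range", paste(round(range(x$composite), 1), collapse = "-"), "\n")
  invisible(x)
}

#' @export
summary.cse_index <- function(object, ...) {
  q <- quintile_of(object$quintiles$composite)[object$area_id]
  out <- list(
    n_areas = length(object$area_id),
    n_excluded = nrow(object$excluded),
    composite = summary(object$composite),
    children_by_quintile = tapply(object$weights, q, sum)
  )
  class(out) <- "summary.cse_index"
  out
}

#' @export
print.summary.cse_index <- function(x, ...) {
  cat("Areas included:", x$n_areas, "| excluded:", x$n_excluded, "\n")
  cat("Composite index:\n")
  print(x$composite)
  cat("Children 0-15 per composite quintile (1 = highest risk):\n")
  print(x$children_by_quintile)
  invisible(x)
}

#' @export
as.data.frame.cse_index <- function(x, ...) {
  df <- data.frame(area_id = x$area_id, child_pop_0_15 = x$weights,
                   row.names = NULL, stringsAsFactors = FALSE)
  raw <- as.data.frame(x$domain_scores)
  names(raw) <- paste0("score_", gsub("[^A-Za-z]+", "_", tolower(names(raw))))
  Xd <- as.data.frame(x$X)
  names(Xd) <- paste0("index_", gsub("[^A-Za-z]+", "_", tolower(names(Xd))))
  df <- cbind(df, raw, Xd)
  df$composite <- as.numeric(x$composite)
  for (nm in names(x$quintiles)) {
    qv <- quintile_of(x$quintiles[[nm]])
    df[[paste0("quintile_", gsub("[^A-Za-z]+", "_", tolower(nm)))]] <-
      as.integer(qv[x$area_id])
  }
  df
}

#' @export
plot.cse_index <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(x$composite, breaks = 30, main = "Composite index",
                 xlab = "Index score (0-100)", col = "grey80")
  q <- quintile_of(x$quintiles$composite)[x$area_id]
  shares <- tapply(x$weights, q, sum) / sum(x$weights) * 100
  graphics::barplot(shares, main = "Children per quintile",
                    xlab = "Quintile (1 = highest risk)", ylab = "% of children")
  invisible(x)
}
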