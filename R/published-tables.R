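#' Published national quintile-level results shipped with the package
#'
#' Two small reference tables from the published national analysis of
#' Australian children aged 0-14 are shipped as plain-text CSV so the
#' concordance and contingency machinery can be validated against real
#' aggregate results: the 5x5 percentage cross-tabulations of hospitalisation
#' quintile by index/domain quintile, and the 2007 quintile-level estimated
#' avoidable deaths and 0-15 populations.
#'
#' @param basis One of \code{"composite"}, \code{"socioeconomic"},
#'   \code{"education"}, \code{"connectedness"}, \code{"housing"},
#'   \code{"health_services"}.
#' @return \code{published_concordance()}: a \code{cse_crosstab} built from
#'   the published cell percentages. \code{published_mortality()}: a data
#'   frame with \code{quintile}, \code{est_deaths}, \code{population_0_15}.
#' @name published-tables
NULL

published_bases <- function() {
  c("composite", "socioeconomic", "education", "connectedness", "housing",
    "health_services")
}

#' @rdname published-tables
#' @export
published_concordance <- function(basis = "composite") {
  basis <- match.arg(basis, published_bases())
  path <- system.file("extdata", "pph_concordance_shares.csv",
                      package = "csehealth", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  sel <- tab[tab$basis == basis, ]
  m <- as.matrix(sel[order(sel$pph_quintile), paste0("q", 1:5)])
  dimnames(m) <- list(outcome = 1:5, index = 1:5)
  as_crosstab(m)
}

#' @rdname published-tables
#' @export
published_mortality <- function(basis = "composite") {
  basis <- match.arg(basis, published_bases())
  path <- system.file("extdata", "avoidable_deaths_by_quintile_2007.csv",
                      package = "csehealth", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  sel <- tab[tab$basis == basis, c("quintile", "est_deaths",
                                   "population_0_15")]
  rownames(sel) <- NULL
  sel[order(sel$quintile), ]
}
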