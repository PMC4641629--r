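#' Published fuzzy membership table of the 33 reference outcrops
#'
#' The printed membership grades (FKM_A, FKM_B, FKM_C, two decimals) and
#' expert habitat labels of the 33 northern Adriatic outcrops used to verify
#' the expert typology. Ships with the package as a plain TSV.
#'
#' @return data.frame: station, typ, FKM_A, FKM_B, FKM_C (33 rows).
#' @export
reference_memberships <- function() {
  path <- system.file("extdata", "table3_memberships.tsv", package = "reefhab")
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Published variation-partitioning fractions of the reference model
#'
#' Adjusted R squared fractions of the reference final model over the four
#' predictor groups (Surface, Bottom, Hydro, Depth): marginals for every
#' union of groups plus the published conditional fractions. Used for
#' arithmetic-identity regression tests of the partitioning.
#'
#' @return named numeric vector keyed by term (e.g. `"Surface+Bottom"`,
#'   `"Hydro|Depth"`).
#' @export
reference_partition <- function() {
  path <- system.file("extdata", "table4_adjr2.tsv", package = "reefhab")
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(d$adj_r2, d$term)
}

#' Membership matrix of the reference table
#'
#' @return 33 x 3 numeric matrix with station rownames and FKM_* colnames.
#' @export
reference_membership_matrix <- function() {
  d <- reference_memberships()
  m <- as.matrix(d[, c("FKM_A", "FKM_B", "FKM_C")])
  rownames(m) <- d$station
  m
}
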