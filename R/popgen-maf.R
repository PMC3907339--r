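#' Folded minor-allele frequency per variant
#'
#' The minor-allele count folds the alternative-allele count over the
#' non-missing chromosomes: `MAC = min(alt, 2 n_nonmissing - alt)` and
#' `MAF = MAC / (2 n_nonmissing)`. All-missing sites get `NA` and are
#' flagged.
#'
#' @param G Dosage matrix (individuals x variants; `NA` = missing) or a
#'   single dosage vector.
#' @return Tibble with `variant_id`, `mac`, `maf`, `n_nonmissing`,
#'   `all_missing`.
#' @export
compute_maf <- function(G) {
  if (is.vector(G)) G <- matrix(G, ncol = 1, dimnames = list(NULL, "v1"))
  alt <- colSums(G, na.rm = TRUE)
  n_nm <- colSums(!is.na(G))
  mac <- pmin(alt, 2 * n_nm - alt)
  maf <- ifelse(n_nm > 0, mac / (2 * n_nm), NA_real_)
  tibble::tibble(variant_id = colnames(G) %||% sprintf("v%d", seq_along(alt)),
                 mac = as.integer(unname(ifelse(n_nm > 0, mac, NA))),
                 maf = unname(maf), n_nonmissing = as.integer(unname(n_nm)),
                 all_missing = unname(n_nm == 0))
}

#' Minor-allele frequency from a printed minor-allele count
#'
#' Convenience for recomputing reported MAFs from reported MACs:
#' `MAF = MAC / (2 n_individuals)`.
#'
#' @param mac Minor-allele count(s).
#' @param n_individuals Number of diploid individuals.
#' @return Numeric MAF(s).
#' @export
maf_from_mac <- function(mac, n_individuals) {
  stopifnot(all(mac >= 0), n_individuals > 0)
  mac / (2 * n_individuals)
}
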