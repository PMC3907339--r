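#' Per-individual sample quality control
#'
#' An individual passes when their fraction of target base pairs covered at
#' >= 20x depth is at least 0.70 and their genotype concordance with the
#' array check SNPs is at least 0.90 (both thresholds inclusive).
#' Concordance is the fraction of check SNPs, non-missing in both sources,
#' at which the sequence-derived genotype equals the array genotype.
#'
#' @param coverage Tibble with columns `id` and `coverage_fraction`.
#' @param array_checks Dosage matrix of array genotypes at the check SNPs
#'   (individuals x SNPs, rownames = ids).
#' @param sequence_genotypes Dosage matrix of sequence-derived genotypes at
#'   the same SNPs (same dimnames).
#' @return Tibble sorted by `id` with `coverage_fraction`, `concordance`,
#'   `pass` and `reason`. Individuals absent from the coverage table fail
#'   with reason `"no coverage record"`.
#' @export
sample_qc <- function(coverage, array_checks, sequence_genotypes) {
  if (ncol(array_checks) == 0) abort("check-SNP set is empty")
  stopifnot(identical(dimnames(array_checks), dimnames(sequence_genotypes)))
  ids <- rownames(array_checks)
  ok <- !is.na(array_checks) & !is.na(sequence_genotypes)
  agree <- ok & array_checks == sequence_genotypes
  conc <- rowSums(agree) / pmax(rowSums(ok), 1)
  conc[rowSums(ok) == 0] <- NA_real_
  cov <- coverage$coverage_fraction[match(ids, coverage$id)]
  pass <- !is.na(cov) & !is.na(conc) & cov >= 0.70 & conc >= 0.90
  reason <- dplyr::case_when(
    is.na(cov) ~ "no coverage record",
    is.na(conc) ~ "no check-SNP comparisons",
    cov < 0.70 & conc < 0.90 ~ "low coverage; low concordance",
    cov < 0.70 ~ "low coverage",
    conc < 0.90 ~ "low concordance",
    TRUE ~ "pass")
  tibble::tibble(id = ids, coverage_fraction = unname(cov),
                 concordance = unname(conc),
                 pass = unname(pass), reason = reason) |>
    dplyr::arrange(.data$id)
}
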