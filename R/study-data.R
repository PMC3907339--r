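#' Bundled published study input tables
#'
#' Small printed tables from the targeted re-sequencing study of Finnish
#' metabolic cohorts that this pipeline reproduces, shipped as plain-text
#' inputs for the worked examples: the 17 target-locus regions of interest
#' (kb sequenced per locus), the validation-campaign counts, the variant
#' consequence-class counts, and the reported minor-allele counts for the
#' multivariate-model variants at the two burden/variance-component
#' exemplar genes. The study genotyped 6,123 individuals.
#'
#' @return `study_target_regions()`, `study_variant_class_counts()` and
#'   `study_reported_variants()` return tibbles; `study_validation_counts()`
#'   returns a named list suitable for [validation_ledger()].
#' @name study_tables
NULL

study_file <- function(name) {
  path <- system.file("extdata", name, package = "rarelocus")
  if (path == "") abort(paste("bundled table not found:", name))
  path
}

#' @rdname study_tables
#' @export
study_target_regions <- function() {
  readr::read_tsv(study_file("study_target_regions.tsv"),
                  show_col_types = FALSE) |>
    dplyr::mutate(length_kb = .data$roi_kb)
}

#' @rdname study_tables
#' @export
study_validation_counts <- function() {
  jsonlite::read_json(study_file("study_validation_counts.json"),
                      simplifyVector = TRUE)
}

#' @rdname study_tables
#' @export
study_variant_class_counts <- function() {
  readr::read_tsv(study_file("study_variant_class_counts.tsv"),
                  show_col_types = FALSE)
}

#' @rdname study_tables
#' @export
study_reported_variants <- function() {
  readr::read_tsv(study_file("study_reported_variants.tsv"),
                  show_col_types = FALSE)
}

#' Count predicted-deleterious variants from consequence-class counts
#'
#' Predicted-deleterious means nonsense or probably-damaging missense.
#'
#' @param class_counts Tibble with `consequence` and `n_sites`.
#' @return Integer count.
#' @export
count_predicted_deleterious <- function(class_counts) {
  sum(class_counts$n_sites[class_counts$consequence %in%
                             c("nonsense", "missense_probably")])
}
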