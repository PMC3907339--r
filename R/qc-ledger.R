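#' Validation bookkeeping for low-count variant sites
#'
#' Reproduces the arithmetic of a validation campaign over all sites
#' observed at most three times: the singleton stratum is the remainder
#' after removing tripleton and doubleton sites from the attempted total;
#' retained singletons are the singletons surviving removal of WGA-only
#' validations and of refuted / not-covered / WGA-artifact sites; the
#' retained total combines the validated tripletons and doubletons with the
#' retained singletons; the analysis site count replaces the attempted
#' stratum of the initial inventory with the retained total, and re-included
#' external-database sites are added on top.
#'
#' When `retained_total_printed` is supplied and differs from the derived
#' sum, the derived value is kept in the ledger, the printed value is used
#' for the downstream totals, and a warning surfaces the discrepancy (it is
#' never silently reconciled).
#'
#' @param sites_initial Sites in the initial inventory.
#' @param attempted Low-count sites where validation was attempted.
#' @param tripleton_sites,doubleton_sites Stratum sizes within `attempted`.
#' @param tripleton_validated,doubleton_validated Validated site counts in
#'   those strata.
#' @param wga_only_singletons Singletons validated only in whole-genome-
#'   amplified DNA (excluded conservatively).
#' @param refuted,not_covered,wga_artifact Failed singleton counts.
#' @param homalt_reclassified Singletons reclassified as homozygous
#'   alternative on validation (recorded; already inside the retained
#'   arithmetic).
#' @param reincluded_dbsnp Non-refuted sites re-included after appearing in
#'   a later external database release.
#' @param retained_total_printed Optional externally stated retained total.
#' @return An `rl_ledger` list of the input and derived counts; see
#'   [tidy.rl_ledger()].
#' @export
validation_ledger <- function(sites_initial = 0, attempted = 0,
                              tripleton_sites = 0, doubleton_sites = 0,
                              tripleton_validated = 0,
                              doubleton_validated = 0,
                              wga_only_singletons = 0, refuted = 0,
                              not_covered = 0, wga_artifact = 0,
                              homalt_reclassified = 0,
                              reincluded_dbsnp = 0,
                              retained_total_printed = NULL) {
  inputs <- c(sites_initial, attempted, tripleton_sites, doubleton_sites,
              tripleton_validated, doubleton_validated, wga_only_singletons,
              refuted, not_covered, wga_artifact, homalt_reclassified,
              reincluded_dbsnp)
  if (any(inputs < 0) || any(inputs != round(inputs))) {
    abort("ledger inputs must be non-negative integers")
  }
  singleton_sites <- attempted - tripleton_sites - doubleton_sites
  retained_singletons <- singleton_sites - wga_only_singletons -
    (refuted + not_covered + wga_artifact)
  retained_total_derived <- tripleton_validated + doubleton_validated +
    retained_singletons
  if (singleton_sites < 0 || retained_singletons < 0 ||
      retained_total_derived < 0) {
    abort("ledger arithmetic produced a negative count: inputs inconsistent")
  }
  retained_total <- retained_total_derived
  if (!is.null(retained_total_printed)) {
    if (retained_total_printed != retained_total_derived) {
      warn(sprintf(paste0(
        "stated retained total (%d) differs from derived ",
        "tripleton + doubleton + singleton sum (%d); using the stated ",
        "value for downstream totals"),
        retained_total_printed, retained_total_derived))
    }
    retained_total <- retained_total_printed
  }
  analysis_sites <- sites_initial - attempted + retained_total
  if (analysis_sites < 0) abort("analysis site count negative")
  structure(list(
    sites_initial = sites_initial, attempted = attempted,
    tripleton_sites = tripleton_sites, doubleton_sites = doubleton_sites,
    singleton_sites = singleton_sites,
    tripleton_validated = tripleton_validated,
    doubleton_validated = doubleton_validated,
    wga_only_singletons = wga_only_singletons, refuted = refuted,
    not_covered = not_covered, wga_artifact = wga_artifact,
    homalt_reclassified = homalt_reclassified,
    retained_singletons = retained_singletons,
    retained_total_derived = retained_total_derived,
    retained_total = retained_total,
    reincluded_dbsnp = reincluded_dbsnp,
    analysis_sites = analysis_sites,
    final_site_count = analysis_sites + reincluded_dbsnp),
    class = "rl_ledger")
}

#' Tidy a validation ledger into a two-column tibble
#' @param x An `rl_ledger`.
#' @param ... Unused.
#' @return Tibble with `quantity` and `count`.
#' @export
tidy.rl_ledger <- function(x, ...) {
  tibble::tibble(quantity = names(unclass(x)),
                 count = unlist(unclass(x), use.names = FALSE))
}

#' @exportS3Method base::print
print.rl_ledger <- function(x, ...) {
  cat("Validation ledger\n")
  print(tidy(x), n = Inf)
  invisible(x)
}
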