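#' Classify variants by frequency and predicted function
#'
#' Assigns each variant a frequency class partition (`singleton`,
#' `doubleton`, `rare` for other sites below the rare cutoff, `common`),
#' overlay flags `is_rare` (MAF strictly below `rare_cutoff`),
#' `is_goldilocks` (MAF in `[0.005, 0.02]`, rare enough to be founder-
#' enriched but common enough for single-variant tests) and `is_functional`
#' (nonsense or probably-damaging missense), plus `is_ns` for any
#' non-synonymous class.
#'
#' @param annotations Tibble with `variant_id` and `consequence` (one of
#'   [consequence_classes()]).
#' @param mafs Tibble from [compute_maf()] (needs `variant_id`, `mac`,
#'   `maf`).
#' @param rare_cutoff MAF threshold below which a variant is rare
#'   (default 0.01; 0.005 is the convention used in cross-study
#'   comparisons).
#' @return Tibble: variant_id, mac, maf, consequence, freq_class, is_rare,
#'   is_goldilocks, is_ns, is_functional.
#' @export
classify_variants <- function(annotations, mafs, rare_cutoff = 0.01) {
  unknown <- setdiff(unique(annotations$consequence), consequence_classes())
  if (length(unknown)) {
    abort(paste("unknown consequence classes:",
                paste(unknown, collapse = ", ")))
  }
  missing_ann <- setdiff(mafs$variant_id, annotations$variant_id)
  if (length(missing_ann)) {
    abort(paste("variants without annotation:",
                paste(head(missing_ann, 5), collapse = ", ")))
  }
  ns_classes <- c("nonsense", "missense_probably", "missense_possibly",
                  "missense_benign")
  dplyr::inner_join(mafs, annotations, by = "variant_id") |>
    dplyr::mutate(
      is_rare = .data$maf < rare_cutoff,
      freq_class = dplyr::case_when(
        .data$mac == 1 ~ "singleton",
        .data$mac == 2 ~ "doubleton",
        .data$is_rare ~ "rare",
        TRUE ~ "common"),
      is_goldilocks = .data$maf >= 0.005 & .data$maf <= 0.02,
      is_ns = .data$consequence %in% ns_classes,
      is_functional = .data$consequence %in% c("nonsense",
                                               "missense_probably")) |>
    dplyr::select("variant_id", "mac", "maf", "consequence", "freq_class",
                  "is_rare", "is_goldilocks", "is_ns", "is_functional")
}

#' Odds ratio that predicted-functional variants are rare
#'
#' Builds the 2x2 functional-by-rare table and reports the cross-product
#' odds ratio with a Woolf (log-OR normal) 95% confidence interval. Zero
#' cells trigger the Haldane-Anscombe 0.5 continuity correction, flagged in
#' the output.
#'
#' @param classes Tibble from [classify_variants()] (uses `is_functional`
#'   and `maf`).
#' @param rare_cutoff MAF cutoff defining "rare" for the table (default
#'   0.005, the cross-study convention).
#' @return Tibble: or, ci_lo, ci_hi, corrected, and the four cell counts.
#' @export
functional_rare_odds_ratio <- function(classes, rare_cutoff = 0.005) {
  rare <- classes$maf < rare_cutoff
  a <- sum(classes$is_functional & rare)      # functional, rare
  b <- sum(classes$is_functional & !rare)     # functional, common
  c_ <- sum(!classes$is_functional & rare)    # non-functional, rare
  d <- sum(!classes$is_functional & !rare)    # non-functional, common
  cells <- c(a, b, c_, d)
  if (sum(cells > 0) < 2) abort("functional-by-rare table is degenerate")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  tibble::tibble(or = or,
                 ci_lo = exp(log(or) - 1.96 * se),
                 ci_hi = exp(log(or) + 1.96 * se),
                 corrected = corrected,
                 n_functional_rare = a, n_functional_common = b,
                 n_other_rare = c_, n_other_common = d)
}
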