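#' Per-variant carrier direction summary for a gene set
#'
#' For each variant, compares the mean trait residual of carriers (dosage
#' >= 1) against non-carriers and counts how many variants push the trait
#' up versus down — the annotation used to read burden-versus-variance-
#' component contrasts.
#'
#' @param set An `rl_gene_set`.
#' @param residuals Tibble from [residualize()].
#' @return Tibble with one row per variant (`variant_id`, `n_carriers`,
#'   `carrier_mean`, `noncarrier_mean`, `direction`) and attributes `n_up`,
#'   `n_down`.
#' @export
direction_summary <- function(set, residuals) {
  d <- gene_set_data(set, residuals, NULL)
  rows <- purrr::map(colnames(d$G), function(vid) {
    carrier <- d$G[, vid] >= 1
    cm <- mean(d$y[carrier])
    nm <- mean(d$y[!carrier])
    tibble::tibble(variant_id = vid, n_carriers = sum(carrier),
                   carrier_mean = cm, noncarrier_mean = nm,
                   direction = ifelse(is.na(cm), NA_character_,
                                      ifelse(cm > nm, "up", "down")))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_up") <- sum(out$direction == "up", na.rm = TRUE)
  attr(out, "n_down") <- sum(out$direction == "down", na.rm = TRUE)
  out
}

#' Run both gene-level tests over a list of gene sets
#'
#' Applies [cmc_test()] (permutation p-values) and [skat_test()] (asymptotic
#' p-values) to every gene set for one trait and assembles the combined
#' result table, including the carrier-direction counts.
#'
#' @param gene_sets List from [build_gene_sets()].
#' @param residuals Tibble from [residualize()].
#' @param pcs `rl_pca` or score matrix, or `NULL`.
#' @param B Permutations for the burden test.
#' @param seed Seed for the permutation streams.
#' @param ... Passed on to [cmc_test()] (e.g. `escalate`).
#' @return Tibble: gene, trait, n, n_variants, cmc_stat, cmc_p, skat_Q,
#'   skat_p, n_up, n_down, B.
#' @export
gene_level_tests <- function(gene_sets, residuals, pcs = NULL, B = 10000,
                             seed = NULL, ...) {
  trait <- attr(residuals, "trait") %||% NA_character_
  rows <- purrr::imap(gene_sets, function(set, nm) {
    cmc <- cmc_test(set, residuals, pcs, B = B, seed = seed, ...)
    skat <- skat_test(set, residuals, pcs)
    dirs <- direction_summary(set, residuals)
    tibble::tibble(gene = set$gene, trait = trait, n = cmc$n,
                   n_variants = cmc$n_variants, cmc_stat = cmc$cmc_stat,
                   cmc_p = cmc$cmc_p, skat_Q = skat$skat_Q,
                   skat_p = skat$skat_p, n_up = attr(dirs, "n_up"),
                   n_down = attr(dirs, "n_down"), B = cmc$B)
  })
  dplyr::bind_rows(rows)
}
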