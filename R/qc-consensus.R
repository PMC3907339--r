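#' Merge replicate center call sets into a consensus genotype matrix
#'
#' Sites are excluded outright when the centers disagree on the alternative
#' allele or when any center reports a multi-allelic ALT. At retained sites
#' each genotype is the 2-of-3 majority value: a genotype is non-missing in
#' the consensus only when at least two centers agree on it; fully
#' discordant triples (and entries with fewer than two non-missing calls)
#' are set missing. Pairwise inter-center concordance is reported overall
#' and by genotype class, where a comparison is assigned to the class of the
#' consensus genotype at that entry.
#'
#' @param callsets List of at least two `rl_center_callset` objects with
#'   identically ordered individuals.
#' @return An `rl_consensus` list: `genotypes` (consensus matrix; excluded
#'   sites dropped), `sites` (tibble: variant_id, excluded, reason),
#'   `discordant_missing` (logical matrix flagging genotypes set missing by
#'   discordance among >= 2 non-missing calls), `concordance` (tibble by
#'   class plus overall).
#' @export
merge_consensus <- function(callsets) {
  if (length(callsets) < 2) abort("need at least two center call sets")
  ids <- lapply(callsets, function(cs) rownames(cs$genotypes))
  for (k in seq_along(ids)[-1]) {
    if (!identical(ids[[1]], ids[[k]])) {
      d1 <- setdiff(ids[[1]], ids[[k]])
      d2 <- setdiff(ids[[k]], ids[[1]])
      abort(paste0(
        "individual IDs differ between centers 1 and ", k,
        "; only in center 1: ", paste(head(d1, 5), collapse = ","),
        "; only in center ", k, ": ", paste(head(d2, 5), collapse = ",")))
    }
  }
  vids <- callsets[[1]]$alleles$variant_id
  alts <- vapply(callsets, function(cs) cs$alleles$alt, character(length(vids)))
  alts <- matrix(alts, nrow = length(vids))
  multi <- apply(alts, 1, function(a) any(grepl(",", a)))
  mismatch <- apply(alts, 1, function(a) length(unique(a)) > 1) & !multi
  reason <- dplyr::case_when(multi ~ "multi-allelic",
                             mismatch ~ "alt-mismatch",
                             TRUE ~ "none")
  sites <- tibble::tibble(variant_id = vids, excluded = reason != "none",
                          reason = reason)
  keep <- !sites$excluded
  Gs <- lapply(callsets, function(cs) cs$genotypes[, keep, drop = FALSE])
  n <- nrow(Gs[[1]]); m <- ncol(Gs[[1]])
  cons <- matrix(NA_integer_, n, m, dimnames = dimnames(Gs[[1]]))
  # count, per entry, how many centers support each dosage value
  support <- lapply(0:2, function(v) {
    Reduce(`+`, lapply(Gs, function(X) !is.na(X) & X == v))
  })
  for (v in 0:2) cons[support[[v + 1]] >= 2] <- v
  n_called <- Reduce(`+`, lapply(Gs, function(X) !is.na(X)))
  discordant_missing <- n_called >= 2 & is.na(cons)
  # pairwise concordance, assigned to the consensus genotype class
  pairs <- utils::combn(length(Gs), 2)
  n_pair <- matrix(0, n, m); n_agree <- matrix(0, n, m)
  for (j in seq_len(ncol(pairs))) {
    A <- Gs[[pairs[1, j]]]; B <- Gs[[pairs[2, j]]]
    ok <- !is.na(A) & !is.na(B)
    n_pair <- n_pair + ok
    n_agree <- n_agree + (ok & A == B)
  }
  class_names <- c("hom_ref", "het", "hom_alt")
  by_class <- purrr::map_dfr(0:2, function(v) {
    sel <- !is.na(cons) & cons == v
    tibble::tibble(class = class_names[v + 1],
                   n_comparisons = sum(n_pair[sel]),
                   n_concordant = sum(n_agree[sel]),
                   rate = ifelse(sum(n_pair[sel]) > 0,
                                 sum(n_agree[sel]) / sum(n_pair[sel]),
                                 NA_real_))
  })
  overall <- tibble::tibble(class = "overall",
                            n_comparisons = sum(n_pair),
                            n_concordant = sum(n_agree),
                            rate = ifelse(sum(n_pair) > 0,
                                          sum(n_agree) / sum(n_pair),
                                          NA_real_))
  structure(list(genotypes = cons, sites = sites,
                 discordant_missing = discordant_missing,
                 concordance = dplyr::bind_rows(by_class, overall)),
            class = "rl_consensus")
}

#' @exportS3Method base::print
print.rl_consensus <- function(x, ...) {
  cat("Consensus call set:", ncol(x$genotypes), "retained sites,",
      sum(x$sites$excluded), "excluded\n")
  ov <- x$concordance$rate[x$concordance$class == "overall"]
  cat(sprintf("  overall pairwise concordance: %.4f%%\n", 100 * ov))
  invisible(x)
}
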