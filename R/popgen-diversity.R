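#' Watterson's per-bp nucleotide diversity estimator
#'
#' `theta_W = S / (a_n L)` with `a_n = sum_{i=1}^{n-1} 1/i`, `S` the number
#' of segregating sites, `L` the number of base pairs surveyed and `n` the
#' number of chromosomes.
#'
#' @param S Segregating sites.
#' @param L Base pairs sequenced.
#' @param n Chromosomes sampled.
#' @return Per-bp theta_W.
#' @export
watterson_theta <- function(S, L, n) {
  if (n < 2 || L <= 0) abort("need n >= 2 chromosomes and L > 0 bp")
  if (S < 0 || S > L * n) abort("segregating-site count impossible for L, n")
  a_n <- sum(1 / seq_len(n - 1))
  S / (a_n * L)
}

#' Mean pairwise-difference per-bp diversity from genotypes
#'
#' The per-site unbiased estimator from folded allele counts,
#' `2 c (n_s - c) / (n_s (n_s - 1))`, summed over sites and divided by the
#' surveyed length; `c` is the site's minor-allele count and `n_s` its
#' non-missing chromosome count. Genotype-level, so no phasing is required.
#'
#' @param G Dosage matrix.
#' @param L Base pairs sequenced.
#' @return Per-bp theta_pi.
#' @export
pairwise_theta <- function(G, L) {
  if (L <= 0) abort("L must be positive")
  maf_tab <- compute_maf(G)
  ok <- !maf_tab$all_missing & maf_tab$n_nonmissing >= 1
  c_i <- maf_tab$mac[ok]
  n_s <- 2 * maf_tab$n_nonmissing[ok]
  usable <- n_s >= 2
  sum(2 * c_i[usable] * (n_s[usable] - c_i[usable]) /
        (n_s[usable] * (n_s[usable] - 1))) / L
}

#' Per-bp and diversity summary for a genotype matrix
#'
#' @param G Dosage matrix.
#' @param L Base pairs sequenced.
#' @return Tibble with `S`, `L`, `n_chromosomes`, `theta_w`, `theta_pi`.
#' @export
diversity_estimates <- function(G, L) {
  maf_tab <- compute_maf(G)
  S <- sum(maf_tab$mac > 0, na.rm = TRUE)
  n <- 2 * nrow(G)
  tibble::tibble(S = S, L = L, n_chromosomes = n,
                 theta_w = watterson_theta(S, L, n),
                 theta_pi = pairwise_theta(G, L))
}

#' Base pairs sequenced per variant site
#'
#' Total targeted length divided by the number of variant sites, rounded to
#' the nearest integer ("one variant site in every X bp").
#'
#' @param total_sites Number of variant sites.
#' @param regions Tibble of target regions with either a `length_bp` column
#'   or `start`/`end` half-open coordinates; a `length_kb` column is also
#'   accepted.
#' @return Integer bp-per-variant.
#' @export
variants_per_bp <- function(total_sites, regions) {
  if (nrow(regions) == 0) abort("regions table is empty")
  if (total_sites <= 0) abort("variant site count must be positive")
  bp <- if ("length_bp" %in% names(regions)) {
    sum(regions$length_bp)
  } else if ("length_kb" %in% names(regions)) {
    sum(regions$length_kb) * 1000
  } else if (all(c("start", "end") %in% names(regions))) {
    sum(regions$end - regions$start)
  } else {
    abort("regions needs length_bp, length_kb or start/end columns")
  }
  round(bp / total_sites)
}
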