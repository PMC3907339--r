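#' Simulate a genotype dosage matrix under Hardy-Weinberg sampling
#'
#' Each variant's genotypes are drawn as Binomial(2, p) allele counts. When
#' `config$substructure_fst > 0` the sample is split into two equal latent
#' subpopulations whose per-variant frequencies are perturbed around the
#' population value by the Balding-Nichols model
#' `p_k ~ Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`,
#' creating the mild stratification that genotype PCA must detect.
#'
#' @param freqs Population minor-allele frequencies from
#'   [simulate_allele_frequencies()].
#' @param config An [sim_config()] object.
#' @param variant_ids Optional column names for the result.
#' @return Integer matrix of dosages in `{0, 1, 2}` with individuals in rows
#'   (named `I000001`, ...) and variants in columns; attribute `subpop`
#'   records the latent subpopulation labels.
#' @export
simulate_genotypes <- function(freqs, config, variant_ids = NULL) {
  stopifnot(inherits(config, "rl_sim_config"), all(freqs > 0), all(freqs <= 0.5))
  n <- config$n_individuals
  m <- length(freqs)
  fst <- config$substructure_fst
  with_stage_seed(config$seed, "genotypes", {
    subpop <- rep(1:2, length.out = n)
    G <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      if (fst > 0) {
        a <- freqs[j] * (1 - fst) / fst
        b <- (1 - freqs[j]) * (1 - fst) / fst
        pk <- pmin(pmax(rbeta(2, a, b), 0), 1)
        G[, j] <- rbinom(n, 2L, pk[subpop])
      } else {
        G[, j] <- rbinom(n, 2L, freqs[j])
      }
    }
    rownames(G) <- sprintf("I%06d", seq_len(n))
    colnames(G) <- variant_ids %||% sprintf("v%05d", seq_len(m))
    attr(G, "subpop") <- subpop
    G
  })
}

# assemble the per-variant metadata table for a set of loci; the array SNP
# (when present) is the first position of the locus span for determinism
build_variant_table <- function(config, freqs) {
  loci <- config$loci
  rows <- list()
  k <- 0L
  for (l in loci) {
    n_v <- l$n_variants
    has_array <- !is.null(l$array_snp)
    pos <- sort(sample.int(l$length_bp, n_v)) + l$start
    cons <- sample(consequence_classes(), n_v, replace = TRUE,
                   prob = l$consequence_probs)
    is_array <- rep(FALSE, n_v)
    p <- numeric(n_v)
    if (has_array) {
      ia <- sample.int(n_v, 1)
      is_array[ia] <- TRUE
      cons[ia] <- "intron"
      p[is_array] <- l$array_snp$maf
      p[!is_array] <- freqs[k + seq_len(n_v - 1L)]
      k <- k + n_v - 1L
    } else {
      p <- freqs[k + seq_len(n_v)]
      k <- k + n_v
    }
    alleles <- t(vapply(seq_len(n_v), function(i) {
      sample(c("A", "C", "G", "T"), 2)
    }, character(2)))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variant_id = paste0("chr", l$chrom, ":", pos),
      gene = l$gene, chrom = l$chrom, pos = pos,
      ref = alleles[, 1], alt = alleles[, 2],
      consequence = cons, is_array_snp = is_array, pop_maf = p
    )
  }
  dplyr::bind_rows(rows)
}
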