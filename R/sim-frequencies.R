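#' Draw population minor-allele frequencies under a founder bottleneck
#'
#' Generates one population MAF per (non-array) variant site. The default
#' parametric mode re-weights the standard neutral frequency spectrum
#' (density proportional to 1/p, the continuous analogue of the 1/i site
#' count spectrum) in two ways that together emulate a recent population
#' bottleneck: a fraction `goldilocks_weight` of sites is drawn from the
#' 0.5-2% "Goldilocks" band, and the rare tail is truncated at
#' `min_maf_factor` times the neutral minimum (drift through the bottleneck
#' removes the very rarest alleles). The `wright_fisher` mode runs an
#' explicit two-epoch forward simulation instead; `mode = "none"` gives the
#' untruncated neutral spectrum. All returned frequencies are folded to the
#' minor allele, i.e. lie in (0, 0.5].
#'
#' @param config An [sim_config()] object (only `bottleneck`,
#'   `n_individuals` and `seed` are consulted).
#' @param n_sites Number of frequencies to draw; defaults to the total
#'   non-array variant count implied by `config$loci`.
#' @return Numeric vector of population MAFs in (0, 0.5].
#' @export
simulate_allele_frequencies <- function(config, n_sites = NULL) {
  stopifnot(inherits(config, "rl_sim_config"))
  if (is.null(n_sites)) {
    n_sites <- sum(vapply(config$loci, function(l) {
      l$n_variants - !is.null(l$array_snp)
    }, numeric(1)))
  }
  bn <- config$bottleneck
  mode <- bn$mode %||% "parametric"
  # the rarest frequency a site segregating in the sample can plausibly have
  p_min <- 0.5 / (2 * config$n_individuals)
  with_stage_seed(config$seed, "frequencies", {
    p <- switch(
      mode,
      none = draw_neutral_maf(n_sites, p_min),
      parametric = {
        w <- bn$goldilocks_weight %||% 0.12
        fac <- bn$min_maf_factor %||% 4
        from_band <- runif(n_sites) < w
        out <- draw_neutral_maf(n_sites, min(p_min * fac, 0.004))
        out[from_band] <- exp(runif(sum(from_band), log(0.005), log(0.02)))
        out
      },
      wright_fisher = draw_wf_maf(n_sites, bn, p_min),
      abort(paste0("unknown bottleneck mode: ", mode))
    )
    pmin(p, 0.5)
  })
}

# inverse-CDF draw from density proportional to 1/p on (p_min, 0.5]
draw_neutral_maf <- function(n, p_min) {
  u <- runif(n)
  p_min * (0.5 / p_min)^u
}

# two-epoch forward Wright-Fisher: neutral ancestral frequencies drift for
# generations_post generations at 2*bottleneck_size chromosomes; fixed and
# lost sites are redrawn so every returned site segregates.
draw_wf_maf <- function(n, bn, p_min) {
  n_b <- bn$bottleneck_size
  gens <- bn$generations_post %||% 0
  if (n_b < 2) abort("bottleneck_size must be >= 2")
  chrom <- 2L * as.integer(n_b)
  out <- numeric(0)
  guard <- 0L
  while (length(out) < n && guard < 200L) {
    guard <- guard + 1L
    p <- draw_neutral_maf(2L * n, p_min)
    if (gens > 0) {
      for (g in seq_len(gens)) {
        seg <- p > 0 & p < 1
        p[seg] <- rbinom(sum(seg), chrom, p[seg]) / chrom
      }
    }
    p <- p[p > 0 & p < 1]
    p <- pmin(p, 1 - p)
    out <- c(out, p)
  }
  if (length(out) < n) abort("bottleneck parameters fix or lose all sites")
  out[seq_len(n)]
}
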