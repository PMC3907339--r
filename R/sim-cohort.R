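#' Simulate a complete targeted re-sequencing study
#'
#' End-to-end generator: draws bottleneck-shaped allele frequencies, builds
#' the variant table over the configured loci, samples genotypes under HWE,
#' plants the true genetic model, simulates covariate-structured phenotypes,
#' and produces three noisy per-center replicate call sets. Every stage uses
#' a named sub-stream of the master seed, so repeated calls with the same
#' configuration are byte-identical.
#'
#' @param config An [sim_config()] object.
#' @return An `rl_cohort` list with elements `genotypes` (truth dosage
#'   matrix), `variants` (metadata tibble), `phenotypes` (tibble),
#'   `true_model` (`rl_true_model`), `centers` (list of three call sets)
#'   and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "rl_sim_config"))
  freqs <- simulate_allele_frequencies(config)
  variants <- with_stage_seed(config$seed, "variant_table",
                              build_variant_table(config, freqs))
  G <- simulate_genotypes(variants$pop_maf, config,
                          variant_ids = variants$variant_id)
  true_model <- build_true_model(G, variants, config)
  phenotypes <- simulate_phenotypes(G, true_model, config)
  centers <- simulate_center_callsets(G, config, variants)
  structure(list(genotypes = G, variants = variants,
                 phenotypes = phenotypes, true_model = true_model,
                 centers = centers, config = config),
            class = "rl_cohort")
}

#' @exportS3Method base::print
print.rl_cohort <- function(x, ...) {
  cat("Simulated re-sequencing cohort\n")
  cat("  individuals:", nrow(x$genotypes), "\n")
  cat("  variant sites:", ncol(x$genotypes), "over",
      length(x$config$loci), "loci\n")
  cat("  planted effects:", nrow(x$true_model$effects), "\n")
  invisible(x)
}
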