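#' Specify one targeted locus for the cohort simulator
#'
#' A locus is a contiguous targeted region containing one gene's coding
#' span, a designated common "array SNP" (the genotyping-array variant that
#' carries the known GWAS signal at the locus), and optionally one or more
#' sets of rare causal variants planted on a trait.
#'
#' @param gene Gene symbol used to label variants.
#' @param chrom Chromosome label.
#' @param start Start coordinate (bp) of the targeted span.
#' @param length_bp Length of the targeted span in bp.
#' @param n_variants Number of variant sites to generate (including the
#'   array SNP).
#' @param consequence_probs Named probabilities over the consequence classes
#'   `nonsense`, `missense_probably`, `missense_possibly`, `missense_benign`,
#'   `synonymous`, `utr5`, `utr3`, `intron`; must sum to 1.
#' @param array_snp List with `maf` (population minor-allele frequency in
#'   (0, 0.5]) and `beta`, a named numeric vector of per-trait additive
#'   effects in trait-residual-SD units.
#' @param rare_effects List of rare causal effect sets; each element is a
#'   list with `trait`, `n_causal`, `maf_max`, `beta_sd` (effect size per
#'   allele copy in residual-SD units) and `direction` (`"same"` or
#'   `"mixed"`).
#' @return A `rl_locus_spec` list.
#' @export
locus_spec <- function(gene, chrom = "1", start = 1e6, length_bp = 15000,
                       n_variants = 60,
                       consequence_probs = default_consequence_probs(),
                       array_snp = list(maf = 0.3, beta = c(HDLC = 0)),
                       rare_effects = list()) {
  consequence_probs <- consequence_probs[consequence_classes()]
  if (anyNA(consequence_probs)) {
    abort("consequence_probs must name every consequence class")
  }
  if (abs(sum(consequence_probs) - 1) > 1e-8) {
    abort("consequence_probs must sum to 1")
  }
  if (!is.null(array_snp)) {
    if (array_snp$maf <= 0 || array_snp$maf > 0.5) {
      abort("array_snp$maf must lie in (0, 0.5]")
    }
  }
  for (re in rare_effects) {
    stopifnot(re$maf_max > 0, re$maf_max <= 0.5,
              re$direction %in% c("same", "mixed"))
  }
  structure(list(gene = gene, chrom = as.character(chrom), start = start,
                 length_bp = length_bp, n_variants = n_variants,
                 consequence_probs = consequence_probs,
                 array_snp = array_snp, rare_effects = rare_effects),
            class = "rl_locus_spec")
}

#' Consequence classes recognised by the annotation tables
#' @return Character vector of the eight consequence classes.
#' @export
consequence_classes <- function() {
  c("nonsense", "missense_probably", "missense_possibly", "missense_benign",
    "synonymous", "utr5", "utr3", "intron")
}

#' Default consequence-class mix
#'
#' Mirrors a targeted coding design: ~37% non-synonymous, ~23% synonymous,
#' ~40% UTR/intron, with the non-synonymous mass split across PolyPhen-2
#' categories so that nonsense plus probably-damaging missense make up a
#' realistic predicted-deleterious fraction (~13%).
#' @return Named probability vector over [consequence_classes()].
#' @export
default_consequence_probs <- function() {
  c(nonsense = 0.012, missense_probably = 0.115, missense_possibly = 0.080,
    missense_benign = 0.163, synonymous = 0.230, utr5 = 0.060,
    utr3 = 0.100, intron = 0.240)
}

#' Per-trait generative parameters for the phenotype simulator
#'
#' Six fasting metabolic traits. `log_scale` traits (TG, FG, FI) are
#' generated so that the natural log of the trait is linear in the
#' covariates and genotype effects; units are mmol/L (TG, FG, TC, LDLC,
#' HDLC) and mU/L (FI) on the natural scale. Covariate coefficients and
#' residual SDs are on the analysis (possibly log) scale. Means and SDs are
#' free parameters of the generator, chosen to sit in the physiological
#' range for an adult northern-European cohort.
#' @return A tibble with one row per trait.
#' @export
default_trait_params <- function() {
  tibble::tribble(
    ~trait, ~log_scale, ~intercept, ~b_age, ~b_age2, ~b_sex, ~b_oc, ~b_preg,
    ~b_cohort, ~b_case, ~residual_sd,
    "TG",   TRUE,  -0.90, 0.012, 0e+0, -0.25, 0.10, 0.15, 0.05, 0.10, 0.45,
    "HDLC", FALSE,  1.20, 0.002, 0e+0,  0.25, 0.05, 0.05, 0.02, 0.00, 0.33,
    "LDLC", FALSE,  1.80, 0.022, 1e-4, -0.15, 0.10, 0.10, 0.05, 0.00, 0.85,
    "TC",   FALSE,  3.60, 0.025, 1e-4, -0.10, 0.15, 0.20, 0.05, 0.00, 0.95,
    "FG",   TRUE,   1.50, 0.002, 0e+0, -0.03, 0.00, -0.02, 0.02, 0.30, 0.07,
    "FI",   TRUE,   1.60, 0.005, 0e+0, -0.05, 0.05, 0.10, 0.05, 0.40, 0.50
  )
}

#' Default locus architectures
#'
#' Two planted architectures spanning the qualitative contrast the pipeline
#' must resolve: a locus whose rare non-synonymous variants all push the
#' trait the same way (burden-favourable) and a locus whose rare variants
#' push in both directions (variance-component-favourable). Both carry a
#' common array-SNP signal on HDL-C.
#' @return List of [locus_spec()] objects.
#' @export
default_loci <- function() {
  list(
    locus_spec("ABCA1", chrom = "9", start = 107543376, length_bp = 11176,
               n_variants = 73,
               array_snp = list(maf = 0.30, beta = c(HDLC = -0.08)),
               rare_effects = list(list(trait = "HDLC", n_causal = 6,
                                        maf_max = 0.01, beta_sd = 0.6,
                                        direction = "same"))),
    locus_spec("CETP", chrom = "16", start = 56733941, length_bp = 16686,
               n_variants = 148,
               array_snp = list(maf = 0.27, beta = c(HDLC = 0.27)),
               rare_effects = list(list(trait = "HDLC", n_causal = 8,
                                        maf_max = 0.01, beta_sd = 0.6,
                                        direction = "mixed")))
  )
}

#' Build a validated simulation configuration
#'
#' The configuration fixes every condition of the emulated study design:
#' a population cohort plus an overlapping case-control cohort, a
#' bottleneck-skewed allele-frequency spectrum, covariate-driven traits,
#' and three noisy per-center replicate call sets.
#'
#' @param n_individuals Total sample size (>= 50). The default matches a
#'   full-scale combined cohort of 6,123.
#' @param cohort_fractions Named proportions over `cohortA`,
#'   `cohortB_control`, `cohortB_case`; must sum to 1.
#' @param loci List of [locus_spec()] objects.
#' @param bottleneck List describing the frequency model. `mode` is
#'   `"parametric"` (default; mixture re-weighting of the neutral 1/i
#'   spectrum, with `goldilocks_weight` mass moved into MAF 0.5-2% and the
#'   rare tail truncated at `min_maf_factor` times the neutral minimum),
#'   `"wright_fisher"` (two-epoch forward simulation; needs
#'   `ancestral_size`, `bottleneck_size` >= 2, `generations_post`), or
#'   `"none"` (standard neutral spectrum).
#' @param trait_params Tibble as returned by [default_trait_params()].
#' @param substructure_fst Balding-Nichols divergence between two latent
#'   subpopulations, in `[0, 0.1]`; 0 disables substructure.
#' @param center_error_rate Per-genotype independent flip probability in
#'   each center call set.
#' @param center_missing_rate Per-genotype missingness probability in each
#'   center call set.
#' @param center_artifact_sites Number of planted alt-allele-discordant
#'   sites per run (consensus merging must exclude them).
#' @param seed Master integer seed fanned out to named sub-streams.
#' @return A validated `rl_sim_config` list.
#' @export
sim_config <- function(n_individuals = 6123,
                       cohort_fractions = c(cohortA = 4447 / 6123,
                                            cohortB_control = 836 / 6123,
                                            cohortB_case = 840 / 6123),
                       loci = default_loci(),
                       bottleneck = list(mode = "parametric",
                                         goldilocks_weight = 0.12,
                                         min_maf_factor = 4),
                       trait_params = default_trait_params(),
                       substructure_fst = 0,
                       center_error_rate = 0.001,
                       center_missing_rate = 0.005,
                       center_artifact_sites = 2,
                       seed = 1L) {
  if (n_individuals < 50) abort("n_individuals must be >= 50")
  need <- c("cohortA", "cohortB_control", "cohortB_case")
  if (!setequal(names(cohort_fractions), need)) {
    abort("cohort_fractions must be named cohortA/cohortB_control/cohortB_case")
  }
  cohort_fractions <- cohort_fractions[need]
  if (abs(sum(cohort_fractions) - 1) > 1e-8) {
    abort("cohort_fractions must sum to 1")
  }
  rates <- c(center_error_rate, center_missing_rate, substructure_fst)
  if (any(rates < 0) || any(c(center_error_rate, center_missing_rate) > 1)) {
    abort("rates must lie in [0, 1]")
  }
  if (substructure_fst > 0.1) abort("substructure_fst must lie in [0, 0.1]")
  if (identical(bottleneck$mode, "wright_fisher") &&
      (is.null(bottleneck$bottleneck_size) || bottleneck$bottleneck_size < 2)) {
    abort("wright_fisher bottleneck requires bottleneck_size >= 2")
  }
  loci <- lapply(loci, function(l) {
    if (!inherits(l, "rl_locus_spec")) abort("loci must be locus_spec objects")
    l
  })
  structure(list(n_individuals = as.integer(n_individuals),
                 cohort_fractions = cohort_fractions, loci = loci,
                 bottleneck = bottleneck, trait_params = trait_params,
                 substructure_fst = substructure_fst,
                 center_error_rate = center_error_rate,
                 center_missing_rate = center_missing_rate,
                 center_artifact_sites = as.integer(center_artifact_sites),
                 seed = as.integer(seed)),
            class = "rl_sim_config")
}
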