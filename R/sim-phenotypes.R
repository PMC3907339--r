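#' Plant the true genetic model for a simulated cohort
#'
#' Selects causal variants for every rare-effect set in the configuration
#' (variants of the right gene with sample MAF below the set's ceiling and
#' at least one observed copy, excluding the array SNP) and assigns betas in
#' residual-SD units: all positive under `direction = "same"`, alternating
#' signs under `"mixed"`. Array-SNP effects from each locus spec are added
#' as common-variant signals. Per-signal variance explained is the additive
#' closed form `2 p (1 - p) beta^2` relative to the trait's genetic-plus-
#' residual variance.
#'
#' @param G Dosage matrix from [simulate_genotypes()].
#' @param variants Variant metadata tibble (needs `variant_id`, `gene`,
#'   `is_array_snp`).
#' @param config An [sim_config()] object.
#' @return A `rl_true_model` list with `effects` (tibble: variant_id, trait,
#'   beta, source) and `variance_explained` (tibble per signal).
#' @export
build_true_model <- function(G, variants, config) {
  tp <- config$trait_params
  maf <- colMeans(G) / 2
  maf <- pmin(maf, 1 - maf)
  eff <- list()
  with_stage_seed(config$seed, "true_model", {
    for (l in config$loci) {
      in_gene <- variants$gene == l$gene
      if (!is.null(l$array_snp)) {
        aid <- variants$variant_id[in_gene & variants$is_array_snp]
        for (tr in names(l$array_snp$beta)) {
          b <- l$array_snp$beta[[tr]]
          if (b != 0) {
            sd_r <- tp$residual_sd[tp$trait == tr]
            eff[[length(eff) + 1L]] <- tibble::tibble(
              variant_id = aid, trait = tr, beta = b * sd_r,
              source = "array_snp")
          }
        }
      }
      for (re in l$rare_effects) {
        # rare causal architecture: non-synonymous sites below the MAF ceiling
        ns <- variants$consequence %in% c("nonsense", "missense_probably",
                                          "missense_possibly",
                                          "missense_benign")
        pool <- variants$variant_id[in_gene & ns & !variants$is_array_snp]
        pool <- pool[maf[pool] > 0 & maf[pool] < re$maf_max]
        if (length(pool) == 0) next
        ids <- sample(pool, min(re$n_causal, length(pool)))
        sgn <- if (re$direction == "same") {
          rep(1, length(ids))
        } else {
          rep_len(c(1, -1), length(ids))
        }
        sd_r <- tp$residual_sd[tp$trait == re$trait]
        eff[[length(eff) + 1L]] <- tibble::tibble(
          variant_id = ids, trait = re$trait,
          beta = sgn * re$beta_sd * sd_r, source = "rare_set")
      }
    }
  })
  effects <- if (length(eff)) dplyr::bind_rows(eff) else {
    tibble::tibble(variant_id = character(), trait = character(),
                   beta = numeric(), source = character())
  }
  ve <- effects |>
    dplyr::mutate(p = maf[.data$variant_id]) |>
    dplyr::group_by(.data$trait) |>
    dplyr::mutate(
      genetic_var = sum(2 * .data$p * (1 - .data$p) * .data$beta^2),
      resid_var = tp$residual_sd[match(.data$trait[1], tp$trait)]^2,
      variance_explained = 2 * .data$p * (1 - .data$p) * .data$beta^2 /
        (.data$genetic_var + .data$resid_var)) |>
    dplyr::ungroup() |>
    dplyr::select("variant_id", "trait", "beta", "p", "variance_explained")
  structure(list(effects = effects, variance_explained = ve,
                 monomorphic_sites = names(maf)[maf == 0]),
            class = "rl_true_model")
}

#' Simulate covariate-structured metabolic traits
#'
#' Each trait (or its natural log, for the log-scale traits TG, FG and FI)
#' is a linear combination of age, age squared, sex, oral-contraceptive use,
#' pregnancy, cohort indicator and case status, plus the planted additive
#' genotype effects and Gaussian noise. Oral-contraceptive use and pregnancy
#' occur only in females; ages are uniform on 31-62 years; T2D cases occur
#' only in cohort B.
#'
#' @param G Dosage matrix.
#' @param model A `rl_true_model` from [build_true_model()].
#' @param config An [sim_config()] object.
#' @return Phenotype tibble with columns `id`, `cohort`, `case_status`,
#'   `age`, `sex` (1 = female), `oc_use`, `pregnant` and the six traits
#'   `TG`, `HDLC`, `LDLC`, `TC`, `FG`, `FI` on their natural scales.
#' @export
simulate_phenotypes <- function(G, model, config) {
  stopifnot(inherits(config, "rl_sim_config"),
            inherits(model, "rl_true_model"))
  tp <- config$trait_params
  if (any(tp$residual_sd < 0)) abort("residual_sd must be non-negative")
  missing_ids <- setdiff(model$effects$variant_id, colnames(G))
  if (length(missing_ids)) {
    abort(paste("causal variants absent from genotype matrix:",
                paste(missing_ids, collapse = ", ")))
  }
  n <- nrow(G)
  with_stage_seed(config$seed, "phenotypes", {
    fr <- config$cohort_fractions
    n_a <- round(n * fr[["cohortA"]])
    n_bcase <- round(n * fr[["cohortB_case"]])
    cohort <- rep(c("A", "B"), c(n_a, n - n_a))
    case_status <- as.integer(seq_len(n) > n - n_bcase)
    age <- runif(n, 31, 62)
    sex <- rbinom(n, 1, 0.5) # 1 = female
    oc_use <- ifelse(sex == 1, rbinom(n, 1, 0.25), 0L)
    pregnant <- ifelse(sex == 1 & oc_use == 0, rbinom(n, 1, 0.03), 0L)
    out <- tibble::tibble(id = rownames(G), cohort = cohort,
                          case_status = case_status, age = age, sex = sex,
                          oc_use = as.integer(oc_use),
                          pregnant = as.integer(pregnant))
    for (i in seq_len(nrow(tp))) {
      row <- tp[i, ]
      y <- row$intercept + row$b_age * age + row$b_age2 * age^2 +
        row$b_sex * sex + row$b_oc * oc_use + row$b_preg * pregnant +
        row$b_cohort * (cohort == "B") + row$b_case * case_status +
        rnorm(n, 0, row$residual_sd)
      ids <- model$effects$variant_id[model$effects$trait == row$trait]
      if (length(ids)) {
        betas <- model$effects$beta[model$effects$trait == row$trait]
        y <- y + as.numeric(G[, ids, drop = FALSE] %*% betas)
      }
      out[[row$trait]] <- if (row$log_scale) exp(y) else y
    }
    out
  })
}
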