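code_genotype <- function(g, model) {
  switch(model,
         additive = g,
         dominant = as.numeric(g >= 1),
         recessive = as.numeric(g == 2),
         abort(paste("unknown genetic model:", model)))
}

align_scores <- function(pcs, ids) {
  if (is.null(pcs)) return(NULL)
  S <- if (inherits(pcs, "rl_pca")) pcs$scores else as.matrix(pcs)
  idx <- match(ids, rownames(S))
  if (anyNA(idx)) abort("principal-component scores missing for some ids")
  S[idx, , drop = FALSE]
}

#' Single-variant association tests of trait residuals
#'
#' For each variant, ordinary least squares of the phenotype residuals on
#' the coded genotype plus the principal-component covariates, per-variant
#' complete case, with a two-sided t test on the genotype coefficient.
#' Variants below the MAF floor or monomorphic after missingness are
#' reported with a `note` and `NA` statistics. Optionally conditions on
#' additional dosage covariates (see [conditional_test()]).
#'
#' @param residuals Tibble from [residualize()] (`id`, `residual`).
#' @param G Dosage matrix (rownames = ids).
#' @param pcs `rl_pca` object or score matrix, or `NULL` for no adjustment.
#' @param model Genetic model: `"additive"` (default), `"dominant"`,
#'   `"recessive"`.
#' @param maf_min Minimum MAF tested (default 0.001, i.e. MAF > 0.1%).
#' @param condition_on Character vector of variant ids whose dosages enter
#'   as covariates; a tested variant with squared correlation > 0.99 with a
#'   conditioning dosage is flagged non-estimable.
#' @param variants Optional subset of variant ids to test.
#' @return Tibble: variant_id, trait, model, beta, se, p, maf, n,
#'   conditioned_on, note.
#' @export
single_variant_test <- function(residuals, G, pcs = NULL,
                                model = "additive", maf_min = 0.001,
                                condition_on = character(0),
                                variants = NULL) {
  ids <- intersect(residuals$id, rownames(G))
  y_all <- residuals$residual[match(ids, residuals$id)]
  Gm <- G[ids, , drop = FALSE]
  S <- align_scores(pcs, ids)
  test_ids <- variants %||% setdiff(colnames(G), condition_on)
  cond_mat <- if (length(condition_on)) {
    Gm[, condition_on, drop = FALSE]
  } else NULL
  trait <- attr(residuals, "trait") %||% NA_character_
  cond_label <- paste(condition_on, collapse = ",")
  rows <- purrr::map(test_ids, function(vid) {
    g <- Gm[, vid]
    keep <- !is.na(g) & !is.na(y_all)
    if (!is.null(cond_mat)) keep <- keep & complete.cases(cond_mat)
    g <- g[keep]
    n <- sum(keep)
    maf <- if (n > 0) min(mean(g) / 2, 1 - mean(g) / 2) else NA_real_
    base <- tibble::tibble(variant_id = vid, trait = trait, model = model,
                           beta = NA_real_, se = NA_real_, p = NA_real_,
                           maf = maf, n = n, conditioned_on = cond_label,
                           note = "")
    if (n < 3 || is.na(maf) || maf == 0) {
      base$note <- "monomorphic"
      return(base)
    }
    if (maf <= maf_min) {
      base$note <- "below MAF floor"
      return(base)
    }
    if (!is.null(cond_mat)) {
      for (cid in condition_on) {
        r2 <- suppressWarnings(cor(g, cond_mat[keep, cid]))^2
        if (!is.na(r2) && r2 > 0.99) {
          base$note <- "collinear with conditioning variant"
          return(base)
        }
      }
    }
    x <- code_genotype(g, model)
    if (var(x) == 0) {
      base$note <- "monomorphic under coding"
      return(base)
    }
    covar <- cbind(if (!is.null(S)) S[keep, , drop = FALSE],
                   if (!is.null(cond_mat)) cond_mat[keep, , drop = FALSE])
    fit <- ols_term_test(y_all[keep], x, covar)
    if (!fit$estimable) {
      base$note <- "non-estimable"
      return(base)
    }
    base$beta <- fit$beta; base$se <- fit$se; base$p <- fit$p
    base
  })
  dplyr::bind_rows(rows)
}

#' Single-variant tests conditional on the array SNP
#'
#' Re-tests each variant with the array SNP's dosage appended to the
#' covariates, assessing whether its signal is independent of the known
#' common GWAS signal at the locus.
#'
#' @inheritParams single_variant_test
#' @param array_variant Variant id of the array SNP.
#' @return As [single_variant_test()], with `conditioned_on` recorded.
#' @export
conditional_test <- function(residuals, G, array_variant, pcs = NULL,
                             model = "additive", maf_min = 0.001,
                             variants = NULL) {
  if (!array_variant %in% colnames(G)) {
    abort(paste("array variant not in genotype matrix:", array_variant))
  }
  single_variant_test(residuals, G, pcs = pcs, model = model,
                      maf_min = maf_min, condition_on = array_variant,
                      variants = setdiff(variants %||% colnames(G),
                                         array_variant))
}

#' Pick the array SNP at a locus
#'
#' The array-designated variant with the smallest single-variant p-value;
#' exact ties break by genomic position, then id.
#'
#' @param results Tibble with `variant_id` and `p`.
#' @param array_ids Variant ids genotyped on the array.
#' @param positions Optional named vector of genomic positions for
#'   tie-breaking.
#' @return The selected variant id.
#' @export
select_array_snp <- function(results, array_ids, positions = NULL) {
  cand <- results[results$variant_id %in% array_ids & !is.na(results$p), ]
  if (nrow(cand) == 0) abort("no array-designated variant was tested")
  pos <- if (!is.null(positions)) {
    positions[cand$variant_id]
  } else {
    rep(0, nrow(cand))
  }
  ord <- order(cand$p, pos, cand$variant_id)
  cand$variant_id[ord[1]]
}

#' Squared dosage correlation between two variants
#'
#' @param a,b Dosage vectors over the same individuals.
#' @param min_n Minimum shared non-missing individuals (default 30).
#' @return r-squared, or `NA` when either variant is monomorphic on the
#'   shared set.
#' @export
ld_r2 <- function(a, b, min_n = 30) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < min_n) abort("fewer than min_n shared non-missing genotypes")
  if (var(a[ok]) == 0 || var(b[ok]) == 0) return(NA_real_)
  cor(a[ok], b[ok])^2
}

#' Are two variants effectively independent?
#'
#' Independence rule: r-squared strictly below 0.20.
#' @param r2 Squared correlation from [ld_r2()].
#' @return Logical.
#' @export
is_independent <- function(r2) {
  !is.na(r2) & r2 < 0.20
}

#' Logistic case-control test per variant
#'
#' Wald test of the additive dosage in a logistic regression of case status
#' on genotype plus principal components. Betas are log odds ratios.
#' Quasi-separation (divergent estimates) is flagged.
#'
#' @param case_labels Named 0/1 vector (names = ids) or tibble with `id`,
#'   `case_status`.
#' @param G Dosage matrix.
#' @param pcs `rl_pca` or score matrix, or `NULL`.
#' @param maf_min Minimum MAF tested (default 0.01).
#' @return Tibble: variant_id, beta, se, p, maf, n, note.
#' @export
case_control_test <- function(case_labels, G, pcs = NULL, maf_min = 0.01) {
  if (is.data.frame(case_labels)) {
    case_labels <- setNames(case_labels$case_status, case_labels$id)
  }
  ids <- intersect(names(case_labels), rownames(G))
  yy <- case_labels[ids]
  Gm <- G[ids, , drop = FALSE]
  S <- align_scores(pcs, ids)
  rows <- purrr::map(colnames(Gm), function(vid) {
    g <- Gm[, vid]
    keep <- !is.na(g) & !is.na(yy)
    g <- g[keep]
    n <- sum(keep)
    maf <- if (n > 0) min(mean(g) / 2, 1 - mean(g) / 2) else NA_real_
    base <- tibble::tibble(variant_id = vid, beta = NA_real_, se = NA_real_,
                           p = NA_real_, maf = maf, n = n, note = "")
    if (is.na(maf) || maf == 0) {
      base$note <- "monomorphic"
      return(base)
    }
    if (maf <= maf_min) {
      base$note <- "below MAF floor"
      return(base)
    }
    df <- data.frame(g = g)
    if (!is.null(S)) df <- cbind(df, as.data.frame(S[keep, , drop = FALSE]))
    fit <- suppressWarnings(glm(yy[keep] ~ ., data = df,
                                family = binomial()))
    sm <- summary(fit)$coefficients
    row <- sm[rownames(sm) == "g", , drop = FALSE]
    if (nrow(row) == 0) {
      base$note <- "non-estimable"
      return(base)
    }
    if (abs(row[1, 1]) > 10 || row[1, 2] > 10) {
      base$note <- "quasi-separation"
      return(base)
    }
    base$beta <- row[1, 1]; base$se <- row[1, 2]
    base$p <- 2 * pnorm(abs(row[1, 3]), lower.tail = FALSE)
    base
  })
  dplyr::bind_rows(rows)
}
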