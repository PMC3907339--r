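#' Build per-gene rare-variant sets for gene-level testing
#'
#' Filters to non-synonymous variants (nonsense plus all missense
#' categories) that segregate with folded MAF strictly below `maf_max`,
#' keeps genes with at least two qualifying sites, and restricts each gene's
#' genotype submatrix to individuals with complete genotype data across all
#' of its included sites.
#'
#' @param G Dosage matrix.
#' @param annotations Tibble with `variant_id` and `consequence`.
#' @param maf_max Strict MAF ceiling (default 0.01).
#' @return Named list of `rl_gene_set` objects (fields `gene`,
#'   `variant_ids`, `genotypes`, `maf`); genes with fewer than two
#'   qualifying sites are dropped.
#' @export
build_gene_sets <- function(G, annotations, maf_max = 0.01) {
  ns_classes <- c("nonsense", "missense_probably", "missense_possibly",
                  "missense_benign")
  maf_tab <- compute_maf(G)
  qualifying <- annotations |>
    dplyr::inner_join(maf_tab, by = "variant_id") |>
    dplyr::filter(.data$consequence %in% ns_classes,
                  .data$mac > 0, .data$maf < maf_max)
  sets <- qualifying |>
    dplyr::group_by(.data$gene) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::group_split()
  out <- lapply(sets, function(df) {
    sub <- G[, df$variant_id, drop = FALSE]
    complete <- complete.cases(sub)
    structure(list(gene = df$gene[1], variant_ids = df$variant_id,
                   genotypes = sub[complete, , drop = FALSE],
                   maf = setNames(df$maf, df$variant_id)),
              class = "rl_gene_set")
  })
  setNames(out, vapply(out, function(s) s$gene, character(1)))
}

#' Construct a gene set directly from a genotype submatrix
#'
#' Escape hatch around the filters of [build_gene_sets()] (e.g. to force a
#' single-variant set through the gene-level tests). Individuals with any
#' missing genotype are dropped.
#'
#' @param gene Gene label.
#' @param genotypes Dosage matrix restricted to the gene's variants.
#' @return An `rl_gene_set`.
#' @export
gene_set <- function(gene, genotypes) {
  complete <- complete.cases(genotypes)
  sub <- genotypes[complete, , drop = FALSE]
  maf <- compute_maf(sub)
  structure(list(gene = gene, variant_ids = colnames(sub), genotypes = sub,
                 maf = setNames(maf$maf, maf$variant_id)),
            class = "rl_gene_set")
}

# align residuals and PC scores to a gene set's complete-case individuals
gene_set_data <- function(set, residuals, pcs) {
  ids <- intersect(rownames(set$genotypes), residuals$id)
  list(ids = ids,
       y = residuals$residual[match(ids, residuals$id)],
       G = set$genotypes[ids, , drop = FALSE],
       S = align_scores(pcs, ids))
}
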