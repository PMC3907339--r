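#' Simulate three noisy per-center replicate call sets
#'
#' Each center's call set equals the truth except for independent
#' per-genotype errors (a flip to one of the other two dosages with
#' probability `center_error_rate`) and missingness (`NA` with probability
#' `center_missing_rate`). A configurable number of sites is planted as
#' alt-allele-discordant across centers (each center reports a different
#' ALT allele); consensus merging must exclude these.
#'
#' @param G Truth dosage matrix.
#' @param config An [sim_config()] object.
#' @param variants Variant metadata tibble with `ref`/`alt` columns; when
#'   `NULL`, arbitrary fixed alleles are assigned.
#' @return List of three `rl_center_callset` objects (fields `center`,
#'   `genotypes`, `alleles`), with attribute `artifact_sites` naming the
#'   planted discordant-ALT sites.
#' @export
simulate_center_callsets <- function(G, config, variants = NULL) {
  stopifnot(inherits(config, "rl_sim_config"))
  m <- ncol(G)
  if (is.null(variants)) {
    variants <- tibble::tibble(variant_id = colnames(G), ref = "A", alt = "G")
  }
  e <- config$center_error_rate
  miss <- config$center_missing_rate
  with_stage_seed(config$seed, "center_callsets", {
    n_art <- min(config$center_artifact_sites, m)
    artifact <- if (n_art > 0) sample(colnames(G), n_art) else character(0)
    centers <- lapply(c("center1", "center2", "center3"), function(cid) {
      X <- G
      if (e > 0) {
        flip <- which(runif(length(X)) < e)
        if (length(flip)) {
          # replace by one of the two other dosage values, uniformly
          X[flip] <- (X[flip] + sample(1:2, length(flip), replace = TRUE)) %% 3L
        }
      }
      if (miss > 0) X[runif(length(X)) < miss] <- NA_integer_
      alleles <- tibble::tibble(variant_id = variants$variant_id,
                                ref = variants$ref, alt = variants$alt)
      structure(list(center = cid, genotypes = X, alleles = alleles),
                class = "rl_center_callset")
    })
    # plant discordant ALT alleles: each center reports a different ALT
    for (vid in artifact) {
      base <- centers[[1]]$alleles
      i <- match(vid, base$variant_id)
      others <- setdiff(c("A", "C", "G", "T"), base$ref[i])
      for (k in 1:3) centers[[k]]$alleles$alt[i] <- others[k]
    }
    attr(centers, "artifact_sites") <- artifact
    centers
  })
}
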