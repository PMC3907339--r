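#' Greedy LD pruning of common variants
#'
#' Slides a window of `window` SNPs in steps of `step`; within each window,
#' SNP pairs with squared dosage correlation above `r2_max` lose their
#' right-hand member, so no retained pair exceeds the threshold. Only
#' variants at or above `maf_min` enter (PCA uses common SNPs).
#'
#' @param G Dosage matrix.
#' @param r2_max Maximum retained pairwise r-squared (default 0.5).
#' @param maf_min Minimum MAF for eligibility (default 0.01).
#' @param window,step Window size and slide step, in SNPs.
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(G, r2_max = 0.5, maf_min = 0.01, window = 50, step = 5) {
  maf_tab <- compute_maf(G)
  elig <- maf_tab$variant_id[!is.na(maf_tab$maf) & maf_tab$maf >= maf_min &
                               maf_tab$mac > 0]
  Gc <- G[, elig, drop = FALSE]
  m <- ncol(Gc)
  if (m <= 1) return(colnames(Gc))
  keep <- rep(TRUE, m)
  start <- 1L
  repeat {
    idx <- which(keep & seq_len(m) >= start &
                   seq_len(m) < start + window)
    if (length(idx) > 1) {
      r2 <- suppressWarnings(cor(Gc[, idx, drop = FALSE],
                                 use = "pairwise.complete.obs")^2)
      r2[is.na(r2)] <- 0
      for (a in seq_along(idx)) {
        if (!keep[idx[a]]) next
        hits <- which(r2[a, ] >= r2_max)
        hits <- hits[hits > a & keep[idx[hits]]]
        keep[idx[hits]] <- FALSE
      }
    }
    if (start + window > m) break
    start <- start + step
  }
  colnames(Gc)[keep]
}

#' Genotype principal components for stratification control
#'
#' Standardizes each SNP by its estimated allele frequency (centering at
#' `2 p` and scaling by `sqrt(p (1 - p))`, missing dosages mean-imputed) and
#' extracts the top `K` components of the individual-by-individual
#' covariance, the standard normalization for genotype PCA.
#'
#' @param G Dosage matrix, typically pre-filtered with [ld_prune()].
#' @param K Number of components (default 5).
#' @return An `rl_pca` list: `scores` (n x K matrix, rownames = ids),
#'   `eigenvalues`, `snps` used.
#' @export
genotype_pca <- function(G, K = 5) {
  p <- colMeans(G, na.rm = TRUE) / 2
  ok <- p > 0 & p < 1
  X <- G[, ok, drop = FALSE]
  p <- p[ok]
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    xj[is.na(xj)] <- 2 * p[j]
    X[, j] <- (xj - 2 * p[j]) / sqrt(p[j] * (1 - p[j]))
  }
  if (K > min(dim(X)) - 1) abort("K exceeds the rank of the genotype matrix")
  pc <- prcomp(X, center = FALSE, scale. = FALSE, rank. = K)
  scores <- pc$x[, seq_len(K), drop = FALSE]
  rownames(scores) <- rownames(G)
  structure(list(scores = scores, eigenvalues = pc$sdev[seq_len(K)]^2,
                 snps = colnames(X)), class = "rl_pca")
}

#' Tidy genotype-PCA scores
#' @param x An `rl_pca`.
#' @param ... Unused.
#' @return Tibble with `id` and one column per component.
#' @export
tidy.rl_pca <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(id = rownames(x$scores)),
                   tibble::as_tibble(x$scores))
}
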