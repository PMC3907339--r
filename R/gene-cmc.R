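madsen_browning_weights <- function(G) {
  n <- nrow(G)
  # smoothed folded frequency so monomorphic-in-subset sites keep finite weight
  p <- (colSums(G) + 1) / (2 * n + 2)
  p <- pmin(p, 1 - p)
  1 / sqrt(n * p * (1 - p))
}

#' Weighted-sum burden (CMC-style) test with permutation p-value
#'
#' Collapses a gene's rare variants into a per-individual weighted sum score
#' `b_i = sum_j w_j g_ij` (default Madsen-Browning inverse-SD weights,
#' `w_j = 1 / sqrt(n p_j (1 - p_j))`; `"flat"` gives the unweighted 0/1
#' collapse of dosages), then tests the burden coefficient in an OLS of the
#' trait residuals on the burden score plus principal components. The
#' statistic is the squared t of the burden coefficient; its p-value comes
#' from `B` permutations of the residual vector:
#' `p = (1 + #\{perm stat >= observed\}) / (1 + B)`.
#' When `escalate = TRUE` and the estimate hits the resolution floor
#' (`p < 10 / B`), the permutation count is multiplied by 10 repeatedly up
#' to `max_B`.
#'
#' @param set An `rl_gene_set` from [build_gene_sets()].
#' @param residuals Tibble from [residualize()].
#' @param pcs `rl_pca` or score matrix, or `NULL`.
#' @param B Number of permutations (>= 100).
#' @param weights `"madsen_browning"` (default) or `"flat"`.
#' @param seed Optional seed for the permutation stream.
#' @param escalate,max_B Permutation escalation rule.
#' @return Tibble: gene, cmc_stat, cmc_p, B, n, n_variants, note.
#' @export
cmc_test <- function(set, residuals, pcs = NULL, B = 10000,
                     weights = c("madsen_browning", "flat"), seed = NULL,
                     escalate = FALSE, max_B = 1e6) {
  weights <- match.arg(weights)
  if (B < 100) abort("B must be >= 100")
  d <- gene_set_data(set, residuals, pcs)
  n <- length(d$ids)
  w <- if (weights == "madsen_browning") {
    madsen_browning_weights(d$G)
  } else {
    rep(1, ncol(d$G))
  }
  b <- as.numeric(d$G %*% w)
  out <- tibble::tibble(gene = set$gene, cmc_stat = NA_real_,
                        cmc_p = NA_real_, B = B, n = n,
                        n_variants = ncol(d$G), note = "")
  if (var(b) == 0) {
    out$cmc_p <- 1
    out$note <- "zero-variance burden score"
    return(out)
  }
  repeat {
    res <- burden_perm_stat(d$y, b, d$S, B, seed)
    if (!escalate || res$p >= 10 / B || B >= max_B) break
    B <- min(B * 10, max_B)
  }
  out$cmc_stat <- res$stat
  out$cmc_p <- res$p
  out$B <- B
  out
}

# squared-t burden statistic and its permutation distribution, vectorized:
# both burden and (permuted) residuals are projected off the covariates once
burden_perm_stat <- function(y, b, S, B, seed = NULL) {
  X <- cbind(rep(1, length(y)), S)
  qx <- qr(X)
  bp <- as.numeric(b - qr.fitted(qx, b))
  df <- length(y) - ncol(X) - 1L
  bb <- sum(bp^2)
  stat_of <- function(Y) {
    Yp <- Y - qr.fitted(qx, Y)
    cross <- as.numeric(crossprod(bp, Yp))
    yty <- if (is.matrix(Yp)) colSums(Yp^2) else sum(Yp^2)
    num <- cross^2 / bb
    num / ((yty - num) / df)
  }
  obs <- stat_of(y)
  run <- function() {
    perms <- matrix(0L, length(y), B)
    for (k in seq_len(B)) perms[, k] <- sample.int(length(y))
    Y <- matrix(y[perms], length(y), B)
    stat_of(Y)
  }
  perm_stats <- if (is.null(seed)) run() else with_stage_seed(seed, "cmc", run())
  list(stat = obs, p = (1 + sum(perm_stats >= obs)) / (1 + B))
}
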