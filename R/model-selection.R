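bic_of_fit <- function(y, X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(NA_real_) # singular design: move is skipped
  rss <- sum((y - qr.fitted(qx, y))^2)
  n <- length(y)
  n * log(rss / n) + ncol(X) * log(n)
}

#' Greedy BIC stepwise selection of locus variants
#'
#' Both-directions stepwise search over all non-singleton variants at a
#' locus: starting from the base model (intercept plus the principal
#' components, which are never dropped), at each step the single addition or
#' deletion giving the largest BIC decrease is taken; the search stops when
#' no move decreases BIC. `BIC = n log(RSS / n) + k log(n)` with `k` the
#' number of free coefficients including the intercept and PCs. Moves that
#' would make the design singular are skipped, and exact BIC ties break by
#' genomic position, then id. Only individuals with complete genotype data
#' across all candidate variants are used.
#'
#' @param residuals Tibble from [residualize()].
#' @param G_locus Dosage matrix of the locus's variants.
#' @param pcs `rl_pca` or score matrix, or `NULL`.
#' @param positions Optional named position vector for tie-breaking
#'   (defaults to positions parsed from `chr:pos` ids, else input order).
#' @param exclude_singletons Drop MAC-1 variants from candidacy (default
#'   TRUE; a single carrier cannot support effect inference).
#' @return An `rl_selection` list: `selected` (tibble with beta/se/p from
#'   the final joint model), `bic_trace` (tibble: step, move, variant_id,
#'   bic), `base_bic`, `final_bic`, `n`, `trait`, `candidates`.
#' @export
greedy_bic_select <- function(residuals, G_locus, pcs = NULL,
                              positions = NULL, exclude_singletons = TRUE) {
  ids <- intersect(residuals$id, rownames(G_locus))
  Gm <- G_locus[ids, , drop = FALSE]
  complete <- complete.cases(Gm)
  ids <- ids[complete]
  Gm <- Gm[complete, , drop = FALSE]
  y <- residuals$residual[match(ids, residuals$id)]
  S <- align_scores(pcs, ids)
  n <- length(y)
  maf_tab <- compute_maf(Gm)
  cand <- maf_tab$variant_id[maf_tab$mac >= if (exclude_singletons) 2 else 1]
  if (is.null(positions)) {
    parsed <- suppressWarnings(as.integer(sub("^.*:", "", cand)))
    positions <- setNames(ifelse(is.na(parsed), seq_along(cand), parsed), cand)
  }
  cand <- cand[order(positions[cand], cand)]
  base_X <- cbind(`(Intercept)` = rep(1, n), S)
  base_bic <- bic_of_fit(y, base_X)
  selected <- character(0)
  trace <- list(tibble::tibble(step = 0L, move = "base",
                               variant_id = NA_character_, bic = base_bic))
  current_bic <- base_bic
  step <- 0L
  repeat {
    adds <- setdiff(cand, selected)
    drops <- selected
    best <- list(bic = current_bic, move = NULL, id = NULL)
    for (vid in adds) {
      bic <- bic_of_fit(y, cbind(base_X, Gm[, c(selected, vid), drop = FALSE]))
      if (!is.na(bic) && bic < best$bic - 1e-9) {
        best <- list(bic = bic, move = "add", id = vid)
      }
    }
    for (vid in drops) {
      keep <- setdiff(selected, vid)
      bic <- bic_of_fit(y, cbind(base_X, Gm[, keep, drop = FALSE]))
      if (!is.na(bic) && bic < best$bic - 1e-9) {
        best <- list(bic = bic, move = "drop", id = vid)
      }
    }
    if (is.null(best$move)) break
    selected <- if (best$move == "add") {
      c(selected, best$id)
    } else {
      setdiff(selected, best$id)
    }
    current_bic <- best$bic
    step <- step + 1L
    trace[[length(trace) + 1L]] <- tibble::tibble(
      step = step, move = best$move, variant_id = best$id, bic = current_bic)
  }
  sel_tab <- if (length(selected)) {
    fit <- lm(y ~ cbind(base_X[, -1, drop = FALSE],
                        Gm[, selected, drop = FALSE]))
    sm <- summary(fit)$coefficients
    # coefficient rows for the selected variants are the trailing ones
    k <- length(selected)
    rows <- sm[seq(nrow(sm) - k + 1, nrow(sm)), , drop = FALSE]
    tibble::tibble(variant_id = selected, beta = rows[, 1], se = rows[, 2],
                   p = rows[, 4])
  } else {
    tibble::tibble(variant_id = character(), beta = numeric(),
                   se = numeric(), p = numeric())
  }
  structure(list(selected = sel_tab,
                 bic_trace = dplyr::bind_rows(trace),
                 base_bic = base_bic, final_bic = current_bic, n = n,
                 trait = attr(residuals, "trait") %||% NA_character_,
                 candidates = cand),
            class = "rl_selection")
}

#' Tidy the selected variants of a stepwise search
#' @param x An `rl_selection`.
#' @param ... Unused.
#' @return Tibble of selected variants with beta, se, p.
#' @export
tidy.rl_selection <- function(x, ...) x$selected

#' One-row summary of a stepwise search
#' @param x An `rl_selection`.
#' @param ... Unused.
#' @return Tibble: n, n_candidates, n_selected, base_bic, final_bic, steps.
#' @export
glance.rl_selection <- function(x, ...) {
  tibble::tibble(n = x$n, n_candidates = length(x$candidates),
                 n_selected = nrow(x$selected), base_bic = x$base_bic,
                 final_bic = x$final_bic,
                 steps = max(x$bic_trace$step))
}

#' @exportS3Method base::print
print.rl_selection <- function(x, ...) {
  cat("Greedy BIC selection:", nrow(x$selected), "of",
      length(x$candidates), "candidates selected",
      sprintf("(BIC %.1f -> %.1f)\n", x$base_bic, x$final_bic))
  if (nrow(x$selected)) print(x$selected)
  invisible(x)
}

#' Plot the BIC trace of a stepwise search
#' @param object An `rl_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rl_selection <- function(object, ...) {
  ggplot2::ggplot(object$bic_trace,
                  ggplot2::aes(x = .data$step, y = .data$bic)) +
    ggplot2::geom_step() + ggplot2::geom_point() +
    ggplot2::labs(x = "accepted move", y = "BIC",
                  title = "Greedy stepwise BIC trace") +
    ggplot2::theme_minimal()
}

#' Variance explained by the array SNP alone versus the selected model
#'
#' Partials the principal components out of the trait residuals and of every
#' dosage involved, then reports the ordinary R-squared (as a percent) of
#' the array SNP alone and of the array SNP plus the selected sequence
#' variants, over the shared complete-case individuals.
#'
#' @param residuals Tibble from [residualize()].
#' @param G Dosage matrix.
#' @param model_variants Variant ids of the selected sequence variants.
#' @param array_snp Array SNP variant id.
#' @param pcs `rl_pca` or score matrix, or `NULL`.
#' @return Tibble: r2_array_pct, r2_full_pct, n.
#' @export
variance_explained <- function(residuals, G, model_variants, array_snp,
                               pcs = NULL) {
  vars <- unique(c(array_snp, model_variants))
  missing_v <- setdiff(vars, colnames(G))
  if (length(missing_v)) {
    abort(paste("variants not in genotype matrix:",
                paste(missing_v, collapse = ", ")))
  }
  ids <- intersect(residuals$id, rownames(G))
  Gm <- G[ids, vars, drop = FALSE]
  keep <- complete.cases(Gm)
  ids <- ids[keep]
  y <- residuals$residual[match(ids, residuals$id)]
  S <- align_scores(pcs, ids)
  X0 <- if (is.null(S)) matrix(nrow = length(ids), ncol = 0) else S
  yp <- project_out(y, X0)
  Gp <- project_out(Gm[keep, , drop = FALSE], X0)
  r2 <- function(cols) {
    Z <- Gp[, cols, drop = FALSE]
    fit <- lm.fit(cbind(1, Z), yp)
    1 - sum(fit$residuals^2) / sum((yp - mean(yp))^2)
  }
  tibble::tibble(r2_array_pct = 100 * r2(array_snp),
                 r2_full_pct = 100 * r2(vars), n = length(ids))
}
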