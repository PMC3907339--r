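#' Benjamini-Hochberg step-up threshold over a test inventory
#'
#' Step-up rule: with ordered p-values `p_(1) <= ... <= p_(m)`, the cutoff
#' is `p_(k*)` for the largest `k` with `p_(k) <= k q / m`; with no such
#' `k`, the cutoff is 0 and nothing is rejected. Built on
#' [stats::p.adjust()]: the rejections are exactly the tests whose BH-
#' adjusted p-value is at most `q`.
#'
#' @param p_values Numeric p-values in (0, 1].
#' @param q FDR level in (0, 1).
#' @param ids Optional test ids (defaults to indices).
#' @return Tibble: method, level, m, cutoff, n_significant, plus a
#'   list-column `significant` of rejected ids.
#' @export
bh_threshold <- function(p_values, q = 0.05, ids = NULL) {
  if (length(p_values) < 1) abort("need at least one p-value")
  if (q <= 0 || q >= 1) abort("q must lie in (0, 1)")
  ids <- ids %||% as.character(seq_along(p_values))
  adj <- p.adjust(p_values, method = "BH")
  sig <- adj <= q
  cutoff <- if (any(sig)) max(p_values[sig]) else 0
  tibble::tibble(method = "BH", level = q, m = length(p_values),
                 cutoff = cutoff, n_significant = sum(sig),
                 significant = list(ids[sig]))
}

#' Bonferroni threshold
#'
#' @param alpha Family-wise level.
#' @param m Number of tests.
#' @return The per-test cutoff `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1) {
  if (m < 1) abort("m must be >= 1")
  alpha / m
}

#' Assemble per-locus-trait association report tables
#'
#' For each locus-trait combination: the array-SNP row, followed by the
#' sequence variants whose conditional p-value falls below the fixed
#' threshold and whose LD with the array SNP satisfies the independence
#' rule (r-squared < 0.20). The fixed default threshold of 0.001 is the
#' operating rule of the study design this pipeline reproduces; a
#' BH-derived cutoff may be supplied instead via `threshold`.
#'
#' @param marginal Tibble from [single_variant_test()] (unconditional).
#' @param conditional Tibble from [conditional_test()].
#' @param G Dosage matrix (for LD with the array SNP).
#' @param array_snp Array SNP id for the locus.
#' @param annotations Tibble with `variant_id`, `gene`, `consequence`.
#' @param threshold Fixed p-value threshold for independence (default
#'   0.001).
#' @param variance Optional tibble from [variance_explained()] whose columns
#'   are appended to the independent-variant rows.
#' @return Tibble: one array-SNP row (`role = "array_snp"`) plus one row per
#'   independent variant (`role = "independent"`), with beta, se, p, maf,
#'   gene, consequence, r2_with_array.
#' @export
build_report <- function(marginal, conditional, G, array_snp, annotations,
                         threshold = 0.001, variance = NULL) {
  if (nrow(marginal) == 0) abort("marginal association results are empty")
  arr <- marginal[marginal$variant_id == array_snp, ]
  if (nrow(arr) == 0) abort(paste("array SNP missing from results:", array_snp))
  ann <- function(v) {
    i <- match(v, annotations$variant_id)
    list(gene = annotations$gene[i], consequence = annotations$consequence[i])
  }
  a <- ann(array_snp)
  out <- tibble::tibble(role = "array_snp", variant_id = array_snp,
                        gene = a$gene, consequence = "array SNP",
                        beta = arr$beta, se = arr$se, p = arr$p,
                        maf = arr$maf, r2_with_array = NA_real_)
  hits <- conditional[!is.na(conditional$p) & conditional$p < threshold, ]
  if (nrow(hits) > 0) {
    r2 <- vapply(hits$variant_id, function(v) {
      ld_r2(G[, v], G[, array_snp])
    }, numeric(1))
    keep <- is_independent(r2)
    hits <- hits[keep, ]
    r2 <- r2[keep]
    if (nrow(hits) > 0) {
      h <- ann(hits$variant_id)
      out <- dplyr::bind_rows(out, tibble::tibble(
        role = "independent", variant_id = hits$variant_id, gene = h$gene,
        consequence = h$consequence, beta = hits$beta, se = hits$se,
        p = hits$p, maf = hits$maf, r2_with_array = unname(r2)))
    }
  }
  if (!is.null(variance)) {
    out$r2_array_pct <- variance$r2_array_pct
    out$r2_full_pct <- variance$r2_full_pct
  }
  out
}

#' Per-locus association scatter plot
#'
#' -log10 p-values by position, with the array SNP highlighted; the simple
#' per-locus view used to inspect marginal versus conditional signals.
#'
#' @param results Tibble from [single_variant_test()].
#' @param positions Named positions (defaults to parsing `chr:pos` ids).
#' @param array_snp Optional array-SNP id to highlight.
#' @param threshold Horizontal reference line (default 0.001).
#' @return A ggplot.
#' @export
plot_locus_association <- function(results, positions = NULL,
                                   array_snp = NULL, threshold = 0.001) {
  df <- results[!is.na(results$p), ]
  pos <- if (!is.null(positions)) {
    positions[df$variant_id]
  } else {
    suppressWarnings(as.integer(sub("^.*:", "", df$variant_id)))
  }
  df$pos <- pos
  df$is_array <- df$variant_id %in% (array_snp %||% character(0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_array), size = 2) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "purple"),
                                 guide = "none") +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
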