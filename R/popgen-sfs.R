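#' Folded site-frequency spectrum of a genotype matrix
#'
#' Counts variant sites by folded minor-allele count. Sites with missing
#' genotypes have fewer non-missing chromosomes than `2 n`; they enter the
#' spectrum only after hypergeometric projection to a common chromosome
#' count `m` (defaulting to the largest count shared by every polymorphic
#' site), so that the spectrum is defined at a single stated sample size.
#'
#' @param G Dosage matrix with `NA` for missing genotypes.
#' @param m Common chromosome count to project to; `NULL` uses the minimum
#'   non-missing chromosome count over polymorphic sites.
#' @return An `rl_sfs` list: `n_chromosomes`, `counts` (vector indexed by
#'   minor-allele count `1..floor(n/2)`; expectation-valued when projection
#'   was applied), `total_sites`.
#' @export
compute_sfs <- function(G, m = NULL) {
  maf_tab <- compute_maf(G)
  poly <- maf_tab$mac > 0 & !maf_tab$all_missing
  if (!any(poly)) {
    m <- m %||% (2L * nrow(G))
    return(new_sfs(numeric(floor(m / 2)), m))
  }
  macs <- maf_tab$mac[poly]
  ns <- 2L * maf_tab$n_nonmissing[poly]
  m <- m %||% min(ns)
  if (m < 2) abort("target chromosome count must be >= 2")
  counts <- numeric(floor(m / 2))
  for (i in seq_along(macs)) {
    if (ns[i] == m) {
      j <- min(macs[i], m - macs[i])
      if (j >= 1) counts[j] <- counts[j] + 1
    } else {
      counts <- counts + project_site_mass(macs[i], ns[i], m)
    }
  }
  new_sfs(counts, m)
}

new_sfs <- function(counts, n_chromosomes) {
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 counts = counts, total_sites = sum(counts)),
            class = "rl_sfs")
}

#' Construct a site-frequency spectrum from explicit counts
#' @param counts Numeric vector indexed by minor-allele count 1..floor(n/2).
#' @param n_chromosomes Chromosome count the spectrum refers to.
#' @return An `rl_sfs`.
#' @export
sfs <- function(counts, n_chromosomes) {
  if (any(counts < 0)) abort("SFS counts must be non-negative")
  if (length(counts) != floor(n_chromosomes / 2)) {
    counts <- c(counts, numeric(floor(n_chromosomes / 2) - length(counts)))
  }
  new_sfs(counts, n_chromosomes)
}

# expected folded spectrum contribution of one site with i minor alleles
# among n chromosomes, down-sampled to m chromosomes without replacement
project_site_mass <- function(i, n, m, unit = 1) {
  j <- 0:min(i, m)
  mass <- dhyper(j, i, n - i, m)
  out <- numeric(floor(m / 2))
  for (idx in seq_along(j)) {
    jf <- min(j[idx], m - j[idx])
    if (jf >= 1) out[jf] <- out[jf] + mass[idx] * unit
  }
  out
}

#' Hypergeometric down-sampling projection of a site-frequency spectrum
#'
#' Computes the expected folded spectrum at a smaller chromosome count `m`:
#' each source class with `i` minor alleles among `n` chromosomes spreads
#' its sites over target counts `j` with the hypergeometric probability of
#' drawing `j` minor alleles in `m` draws without replacement; draws of all
#' or none of the minor alleles leave the site monomorphic (mass lost), and
#' counts above `m/2` are refolded. Projected counts are expectations and
#' need not be integers.
#'
#' @param x An `rl_sfs`.
#' @param m Target chromosome count, `2 <= m <= n`.
#' @return An `rl_sfs` at `m` chromosomes.
#' @export
project_sfs <- function(x, m) {
  stopifnot(inherits(x, "rl_sfs"))
  if (m > x$n_chromosomes) abort("cannot project to a larger sample")
  if (m < 2) abort("target chromosome count must be >= 2")
  if (m == x$n_chromosomes) return(x)
  counts <- numeric(floor(m / 2))
  for (i in seq_along(x$counts)) {
    if (x$counts[i] > 0) {
      counts <- counts + project_site_mass(i, x$n_chromosomes, m,
                                           unit = x$counts[i])
    }
  }
  new_sfs(counts, m)
}

#' Tidy a site-frequency spectrum
#' @param x An `rl_sfs`.
#' @param ... Unused.
#' @return Tibble with `mac`, `n_sites`, `proportion`.
#' @export
tidy.rl_sfs <- function(x, ...) {
  tibble::tibble(mac = seq_along(x$counts), n_sites = x$counts,
                 proportion = if (x$total_sites > 0) {
                   x$counts / x$total_sites
                 } else {
                   rep(NA_real_, length(x$counts))
                 })
}

#' @exportS3Method base::print
print.rl_sfs <- function(x, ...) {
  cat("Folded site-frequency spectrum at", x$n_chromosomes, "chromosomes;",
      format(x$total_sites), "sites\n")
  invisible(x)
}

#' Plot a site-frequency spectrum as proportions by minor-allele count
#' @param object An `rl_sfs`.
#' @param max_mac Largest minor-allele count shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rl_sfs <- function(object, max_mac = 20, ...) {
  df <- tidy(object) |> dplyr::filter(.data$mac <= max_mac)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mac, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "minor allele count", y = "proportion of variant sites",
                  title = paste0("Folded SFS at ", object$n_chromosomes,
                                 " chromosomes")) +
    ggplot2::theme_minimal()
}
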