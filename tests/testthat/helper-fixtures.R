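# shared in-code fixtures; everything is generated at test time

tiny_config <- function(n = 300, seed = 11, ...) {
  sim_config(n_individuals = n, seed = seed, ...)
}

# one small cohort reused across files (built once per test run)
.fixture_env <- new.env(parent = emptyenv())
tiny_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(tiny_config())
  }
  .fixture_env$cohort
}

# dosage matrix with given columns and ids
dosage_matrix <- function(..., ids = NULL) {
  cols <- list(...)
  G <- do.call(cbind, cols)
  rownames(G) <- ids %||% sprintf("I%03d", seq_len(nrow(G)))
  G
}

# a center call set wrapping a dosage matrix
make_callset <- function(center, G, alt = NULL) {
  structure(list(center = center, genotypes = G,
                 alleles = tibble::tibble(
                   variant_id = colnames(G), ref = "A",
                   alt = alt %||% rep("G", ncol(G)))),
            class = "rl_center_callset")
}

# residuals tibble from a plain numeric vector
residuals_of <- function(y, ids = NULL, trait = "HDLC") {
  out <- tibble::tibble(id = ids %||% sprintf("I%03d", seq_along(y)),
                        residual = y - mean(y))
  attr(out, "trait") <- trait
  out
}

# draw a dosage column at frequency p for n individuals
dosage_at <- function(n, p) rbinom(n, 2, p)

`%||%` <- function(a, b) if (is.null(a)) b else a
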