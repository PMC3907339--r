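make_gene_matrix <- function(n, mafs, prefix = "g") {
  G <- vapply(mafs, function(p) dosage_at(n, p), integer(n))
  dimnames(G) <- list(sprintf("I%04d", seq_len(n)),
                      paste0(prefix, seq_along(mafs)))
  G
}

test_that("gene sets apply the NS/MAF/site-count filters exactly", {
  n <- 2000
  withr::with_seed(3, {
    G <- cbind(make_gene_matrix(n, c(0.004, 0.006, 0.02)),     # A: g1..g3
               make_gene_matrix(n, c(0.003, 0.005), "h"))      # B: h1..h2
  })
  ann <- tibble::tibble(
    variant_id = colnames(G),
    gene = rep(c("A", "B"), c(3, 2)),
    consequence = c("missense_benign", "nonsense", "missense_probably",
                    "synonymous", "missense_possibly"))
  sets <- build_gene_sets(G, ann, maf_max = 0.01)
  # gene A keeps its two NS sites under 1%; gene B has only one NS site
  expect_named(sets, "A")
  expect_setequal(sets$A$variant_ids, c("g1", "g2"))
  # brute-force filter oracle
  maf <- compute_maf(G)
  brute <- ann$variant_id[ann$consequence != "synonymous" &
                            maf$maf < 0.01 & maf$mac > 0]
  expect_setequal(unlist(lapply(sets, `[[`, "variant_ids")),
                  intersect(brute, c("g1", "g2", "g3")))
  # a variant at exactly 1% is excluded (strict <)
  G2 <- cbind(v1 = rep(c(0L, 1L), c(90, 10)), v2 = rep(c(0L, 1L), c(90, 10)),
              v3 = dosage_at(100, 0.004))
  rownames(G2) <- sprintf("I%03d", 1:100)
  ann2 <- tibble::tibble(variant_id = c("v1", "v2", "v3"), gene = "C",
                         consequence = "missense_benign")
  expect_equal(compute_maf(G2)$maf[1], 0.05)
  sets2 <- build_gene_sets(G2, ann2, maf_max = 0.05)
  expect_false("v1" %in% unlist(lapply(sets2, `[[`, "variant_ids")))
})

test_that("gene sets keep only individuals with complete genotype data", {
  G <- dosage_matrix(a = c(1L, 0L, NA, 0L, 0L, 0L),
                     b = c(0L, 1L, 0L, NA, 0L, 0L))
  ann <- tibble::tibble(variant_id = c("a", "b"), gene = "G1",
                        consequence = "nonsense")
  sets <- build_gene_sets(G, ann, maf_max = 0.5)
  expect_equal(nrow(sets$G1$genotypes), 4)
  expect_false(anyNA(sets$G1$genotypes))
})

test_that("burden permutation p has the correct floor and flags degenerate scores", {
  n <- 500
  withr::with_seed(7, {
    G <- make_gene_matrix(n, rep(0.01, 4))
    y <- 2 * rowSums(G) + rnorm(n) # overwhelming same-direction signal
  })
  set <- gene_set("X", G)
  res <- cmc_test(set, residuals_of(y, ids = rownames(G)), B = 100, seed = 1)
  expect_equal(res$cmc_p, 1 / 101)
  mono <- gene_set("M", matrix(0L, n, 2,
                               dimnames = list(rownames(G), c("a", "b"))))
  res0 <- cmc_test(mono, residuals_of(rnorm(n), ids = rownames(G)),
                   B = 100, seed = 1)
  expect_equal(res0$cmc_p, 1)
  expect_match(res0$note, "zero-variance")
})

test_that("permutation escalation refines small p-values", {
  n <- 500
  withr::with_seed(8, {
    G <- make_gene_matrix(n, rep(0.01, 4))
    y <- 1.5 * rowSums(G) + rnorm(n)
  })
  set <- gene_set("X", G)
  r <- residuals_of(y, ids = rownames(G))
  res <- cmc_test(set, r, B = 100, seed = 2, escalate = TRUE, max_B = 10000)
  expect_equal(res$B, 10000)
  expect_lte(res$cmc_p, 10 / 100)
})

test_that("both gene-level tests are invariant to individual and variant order", {
  n <- 400
  withr::with_seed(15, {
    G <- make_gene_matrix(n, c(0.01, 0.008, 0.005))
    y <- rnorm(n) + 0.5 * G[, 1]
  })
  r <- residuals_of(y, ids = rownames(G))
  set1 <- gene_set("X", G)
  set2 <- gene_set("X", G[rev(seq_len(n)), c(3, 1, 2)])
  c1 <- cmc_test(set1, r, B = 500, seed = 9)
  c2 <- cmc_test(set2, r, B = 500, seed = 9)
  expect_equal(c1$cmc_stat, c2$cmc_stat, tolerance = 1e-10)
  expect_equal(c1$cmc_p, c2$cmc_p)
  s1 <- skat_test(set1, r)
  s2 <- skat_test(set2, r)
  expect_equal(s1$skat_Q, s2$skat_Q, tolerance = 1e-8)
  expect_equal(s1$skat_p, s2$skat_p, tolerance = 1e-8)
})

test_that("a single-variant set reduces SKAT to the squared score test", {
  n <- 1500
  withr::with_seed(25, {
    g <- dosage_at(n, 0.05)
    y <- 0.15 * g + rnorm(n)
  })
  G <- matrix(g, ncol = 1, dimnames = list(sprintf("I%04d", 1:n), "v"))
  set <- gene_set("X", G)
  r <- residuals_of(y, ids = rownames(G))
  res <- skat_test(set, r, weights = "flat")
  # score test: U^2 / (sigma2 * g'Pg) ~ chi2_1 under the null
  yc <- r$residual - mean(r$residual)
  gc <- g - mean(g)
  sigma2 <- sum(yc^2) / (n - 1)
  stat <- sum(gc * yc)^2 / (sigma2 * sum(gc^2))
  expect_equal(res$skat_p, pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("mixture-of-chi-square tail probabilities match simulation", {
  lambda <- c(3, 1.5, 0.5, 0.25)
  withr::with_seed(31, {
    draws <- colSums(lambda * matrix(rchisq(4 * 2e5, 1), 4))
  })
  for (q in c(2, 8, 20)) {
    mc <- mean(draws > q)
    p <- mixture_chisq_pvalue(q, lambda)$p
    expect_lt(abs(p - mc), 3 * sqrt(mc * (1 - mc) / 2e5) + 1e-4)
  }
  # Liu fallback stays close to Imhof in the moderate tail
  p_liu <- mixture_chisq_pvalue(20, lambda, method = "liu")$p
  p_imhof <- mixture_chisq_pvalue(20, lambda, method = "imhof")$p
  expect_lt(abs(log10(p_liu) - log10(p_imhof)), 0.3)
})

test_that("direction summaries recover planted signs and split evenly under the null", {
  n <- 3000
  withr::with_seed(37, {
    G <- make_gene_matrix(n, rep(0.008, 6))
    y_up <- rowSums(G) * 1.5 + rnorm(n)
  })
  set <- gene_set("X", G)
  d_up <- direction_summary(set, residuals_of(y_up, ids = rownames(G)))
  with_carriers <- d_up$n_carriers >= 5
  expect_gte(mean(d_up$direction[with_carriers] == "up"), 0.9)

  withr::with_seed(38, {
    splits <- replicate(60, {
      d0 <- direction_summary(set, residuals_of(rnorm(n), ids = rownames(G)))
      attr(d0, "n_up")
    })
  })
  # binomial(6, 1/2) mean under the null
  expect_lt(abs(mean(splits) - 3), 3 * sqrt(6 * 0.25 / 60))

  one <- gene_set("O", matrix(c(1L, rep(0L, 9)), ncol = 1,
                              dimnames = list(sprintf("I%02d", 1:10), "v")))
  y1 <- c(5, rnorm(9))
  d1 <- direction_summary(one, residuals_of(y1, ids = sprintf("I%02d", 1:10)))
  expect_equal(d1$direction, "up")
})

test_that("the combined gene-level runner assembles the full result schema", {
  co <- tiny_cohort()
  ann <- dplyr::select(co$variants, variant_id, gene, consequence)
  sets <- build_gene_sets(co$genotypes, ann)
  r <- residualize(co$phenotypes, "HDLC")
  res <- gene_level_tests(sets, r, B = 200, seed = 12)
  expect_named(res, c("gene", "trait", "n", "n_variants", "cmc_stat",
                      "cmc_p", "skat_Q", "skat_p", "n_up", "n_down", "B"))
  expect_true(all(res$cmc_p >= 1 / 201))
  expect_true(all(res$skat_Q >= 0))
  expect_true(all(res$n_up + res$n_down <= res$n_variants))
})
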