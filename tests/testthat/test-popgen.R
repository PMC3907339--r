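test_that("MAF computation folds to the minor allele over non-missing genotypes", {
  G <- dosage_matrix(v1 = c(2L, 2L, 1L), v2 = c(0L, 0L, 0L),
                     v3 = c(2L, NA, 1L))
  tab <- compute_maf(G)
  expect_equal(tab$mac, c(1L, 0L, 1L)) # v1 folds: alt count 5 of 6
  expect_equal(tab$maf, c(1 / 6, 0, 1 / 4))
  expect_equal(tab$n_nonmissing, c(3L, 3L, 2L))
  allNA <- compute_maf(matrix(NA_integer_, 3, 1))
  expect_true(allNA$all_missing)
  expect_true(is.na(allNA$maf))
})

test_that("printed MAFs are recovered from printed MACs at the study sample size", {
  # reported multivariate-model rows at the two exemplar genes, n = 6,123;
  # array-SNP rows carry array-genotyped MAFs (different denominator) and
  # are excluded from the sequence-based identity
  rep_tab <- dplyr::filter(study_reported_variants(), !is_array)
  maf <- maf_from_mac(rep_tab$mac, 6123)
  expect_equal(signif(maf, 2), signif(rep_tab$maf_printed, 2))
  expect_equal(signif(maf_from_mac(674, 6123), 2), 0.055)
  expect_equal(signif(maf_from_mac(7, 6123), 2), 0.00057)
})

test_that("SFS tallies match a brute-force histogram and handle edge cases", {
  withr::with_seed(10, {
    G <- sapply(c(0.01, 0.05, 0.2, 0.4, 0.003), function(p) dosage_at(200, p))
  })
  rownames(G) <- sprintf("I%03d", 1:200)
  colnames(G) <- paste0("v", 1:5)
  s <- compute_sfs(G)
  macs <- compute_maf(G)$mac
  brute <- tabulate(macs[macs > 0], nbins = 200)
  expect_equal(s$counts, brute)
  expect_equal(s$total_sites, sum(macs > 0))

  one <- compute_sfs(dosage_matrix(v1 = c(1L, 0L, 0L)))
  expect_equal(one$counts[1], 1)
  empty <- compute_sfs(matrix(0L, 4, 0))
  expect_equal(empty$total_sites, 0)
})

test_that("hypergeometric projection matches enumeration and Monte-Carlo subsampling", {
  s <- sfs(c(0, 1), 20) # one doubleton among 20 chromosomes
  proj <- project_sfs(s, 10)
  # enumeration: j successes among 10 draws from 2 minor / 18 major
  expect_equal(proj$counts[1], dhyper(1, 2, 18, 10))
  expect_equal(proj$counts[2], dhyper(2, 2, 18, 10))
  # projection to self is the identity; m out of range is fatal
  expect_identical(project_sfs(s, 20), s)
  expect_error(project_sfs(s, 21), "larger")
  expect_error(project_sfs(s, 1), ">= 2")

  # Monte-Carlo oracle: subsample chromosomes of a constructed site
  chroms <- c(rep(1, 2), rep(0, 18))
  withr::with_seed(12, {
    draws <- replicate(1e5, {
      j <- sum(sample(chroms, 10))
      min(j, 10 - j)
    })
  })
  p1 <- mean(draws == 1)
  se <- sqrt(p1 * (1 - p1) / 1e5)
  expect_lt(abs(proj$counts[1] - p1), 3 * se)

  # mass is only lost through monomorphic draws
  withr::with_seed(13, {
    big <- sfs(rpois(25, 3), 50)
  })
  expect_lte(project_sfs(big, 12)$total_sites, big$total_sites)
})

test_that("diversity estimators reproduce hand-computed values", {
  expect_equal(watterson_theta(S = 2, L = 100, n = 4),
               2 / ((1 + 1 / 2 + 1 / 3) * 100))
  # one site with minor count 2 among 4 chromosomes: all-pairs brute force
  haps <- c(1, 1, 0, 0)
  pairs <- combn(4, 2)
  pi_brute <- mean(haps[pairs[1, ]] != haps[pairs[2, ]])
  G <- dosage_matrix(v1 = c(2L, 0L)) # two diploids carrying those haplotypes
  expect_equal(pairwise_theta(G, L = 100), pi_brute / 100)
  expect_equal(pairwise_theta(G, 100), 2 * 2 * 2 / (4 * 3) / 100)
  # no segregating sites
  expect_equal(watterson_theta(0, 100, 4), 0)
  expect_equal(pairwise_theta(dosage_matrix(v1 = c(0L, 0L)), 100), 0)
  expect_error(watterson_theta(1000, 10, 4), "impossible")
})

test_that("theta_W and theta_pi agree in expectation under neutral sampling", {
  # sites drawn from the neutral spectrum P(i) ~ 1/i over unfolded counts
  n_chrom <- 20
  a_n <- sum(1 / seq_len(n_chrom - 1))
  theta_site <- 0.004 # per-bp theta fixed by construction
  L <- 50000
  withr::with_seed(77, {
    est <- replicate(500, {
      S <- rpois(1, theta_site * a_n * L)
      i <- sample(seq_len(n_chrom - 1), S, replace = TRUE,
                  prob = 1 / seq_len(n_chrom - 1))
      G <- vapply(i, function(cnt) {
        hap <- sample(c(rep(1L, cnt), rep(0L, n_chrom - cnt)))
        hap[seq(1, n_chrom, 2)] + hap[seq(2, n_chrom, 2)]
      }, integer(n_chrom / 2))
      rownames(G) <- sprintf("I%03d", seq_len(n_chrom / 2))
      c(w = watterson_theta(S, L, n_chrom), p = pairwise_theta(G, L))
    })
  })
  expect_lt(abs(mean(est["w", ]) - mean(est["p", ])) / mean(est["w", ]), 0.1)
  expect_lt(abs(mean(est["w", ]) - theta_site) / theta_site, 0.1)
})

test_that("variant classification matches a brute-force filter and stated cutoffs", {
  ann <- tibble::tibble(variant_id = paste0("v", 1:6),
                        consequence = c("missense_probably", "nonsense",
                                        "synonymous", "intron",
                                        "missense_benign", "utr3"))
  mafs <- tibble::tibble(variant_id = paste0("v", 1:6),
                         mac = c(60L, 1L, 2L, 10L, 200L, 5L),
                         maf = c(0.005, 0.0001, 0.0002, 0.0009, 0.02, 0.0005),
                         n_nonmissing = 6000L, all_missing = FALSE)
  cls <- classify_variants(ann, mafs)
  v1 <- cls[cls$variant_id == "v1", ]
  # 0.5% is inside both the rare and goldilocks ranges, and probably-damaging
  expect_true(v1$is_rare && v1$is_goldilocks && v1$is_functional)
  expect_equal(cls$freq_class[cls$variant_id == "v2"], "singleton")
  expect_equal(cls$freq_class[cls$variant_id == "v3"], "doubleton")
  expect_equal(cls$freq_class[cls$variant_id == "v5"], "common")
  # partition consistency: singleton + doubleton + other rare = all rare
  expect_equal(sum(cls$freq_class %in% c("singleton", "doubleton", "rare")),
               sum(cls$is_rare))
  # brute-force flag check
  expect_equal(cls$is_functional,
               ann$consequence %in% c("nonsense", "missense_probably"))
  expect_error(classify_variants(dplyr::mutate(ann, consequence = "odd"),
                                 mafs), "unknown")
})

test_that("predicted-deleterious bookkeeping reproduces the published count", {
  expect_equal(count_predicted_deleterious(study_variant_class_counts()), 236)
  expect_equal(sum(study_variant_class_counts()$n_sites), 1852)
})

test_that("functional-by-rare odds ratio follows the Woolf construction", {
  mk <- function(a, b, c_, d) {
    tibble::tibble(
      is_functional = rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c_, d)),
      maf = rep(c(0.001, 0.1, 0.001, 0.1), c(a, b, c_, d)))
  }
  expect_equal(functional_rare_odds_ratio(mk(10, 10, 10, 10))$or, 1)
  res <- functional_rare_odds_ratio(mk(10, 10, 10, 40))
  expect_equal(res$or, 4)
  se <- sqrt(1 / 10 + 1 / 10 + 1 / 10 + 1 / 40)
  expect_equal(res$ci_lo, exp(log(4) - 1.96 * se))
  expect_equal(res$ci_hi, exp(log(4) + 1.96 * se))
  dbl <- functional_rare_odds_ratio(mk(20, 20, 20, 80))
  expect_equal(dbl$or, 4)
  expect_lt(dbl$ci_hi - dbl$ci_lo, res$ci_hi - res$ci_lo)
  zero <- functional_rare_odds_ratio(mk(10, 0, 10, 40))
  expect_true(zero$corrected)
})

test_that("sequence density reproduces the published one-variant-per-147-bp", {
  regions <- study_target_regions()
  expect_equal(nrow(regions), 17)
  expect_equal(variants_per_bp(1852, regions), 147)
  expect_equal(variants_per_bp(10, tibble::tibble(length_bp = 1000)), 100)
  expect_equal(variants_per_bp(20, tibble::tibble(length_bp = 2000)), 100)
  expect_error(variants_per_bp(0, regions), "positive")
})
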