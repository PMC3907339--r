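test_that("residualization removes the covariate signal and centers residuals", {
  co <- tiny_cohort()
  r <- residualize(co$phenotypes, "HDLC")
  expect_lt(abs(mean(r$residual)), 1e-10)
  expect_identical(attr(r, "transformation"), "none")
  rtg <- residualize(co$phenotypes, "TG")
  expect_identical(attr(rtg, "transformation"), "log")
  # residuals are orthogonal to every covariate
  ph <- co$phenotypes[match(r$id, co$phenotypes$id), ]
  expect_lt(abs(cor(r$residual, ph$age)), 1e-10)
  expect_lt(abs(cor(r$residual, ph$sex)), 1e-10)
  # a trait equal to its covariate prediction leaves zero residuals
  ph0 <- co$phenotypes
  ph0$FLAT <- 1 + 0.1 * ph0$age + 0.5 * ph0$sex
  r0 <- residualize(ph0, "FLAT", transformation = "none")
  expect_lt(max(abs(r0$residual)), 1e-8)
})

test_that("glycemic traits exclude T2D cases and log guards fire", {
  co <- tiny_cohort()
  r <- residualize(co$phenotypes, "FG")
  cases <- co$phenotypes$id[co$phenotypes$case_status == 1]
  expect_length(intersect(r$id, cases), 0)
  excl <- attr(r, "excluded")
  expect_true(all(cases %in% excl$id))
  ph <- co$phenotypes
  ph$TG[3] <- -1
  expect_error(residualize(ph, "TG"), "non-positive")
})

test_that("covariate coefficients are recovered from the generating model", {
  cfg <- tiny_config(n = 2000, seed = 61)
  co <- simulate_cohort(cfg)
  ph <- co$phenotypes
  fit <- lm(LDLC ~ age + I(age^2) + sex + oc_use + pregnant +
              I(cohort == "B"), data = ph)
  tp <- cfg$trait_params
  truth <- tp[tp$trait == "LDLC", ]
  ci <- confint(fit)
  expect_true(truth$b_sex >= ci["sex", 1] && truth$b_sex <= ci["sex", 2])
  expect_true(truth$b_age >= ci["age", 1] && truth$b_age <= ci["age", 2])
})

test_that("inverse-normal residuals are standard normal", {
  cfg <- tiny_config(n = 5000, seed = 71)
  co <- simulate_cohort(cfg)
  r <- residualize(co$phenotypes, "TG", transformation = "inverse_normal")
  ks <- suppressWarnings(stats::ks.test(r$residual, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("LD pruning removes duplicates and PCA finds planted structure", {
  withr::with_seed(9, {
    g1 <- dosage_at(500, 0.3)
    G <- dosage_matrix(a = g1, b = g1, c = dosage_at(500, 0.3))
  })
  expect_identical(ld_prune(G), c("a", "c"))

  cfg <- tiny_config(n = 400, seed = 31, substructure_fst = 0.01)
  G2 <- simulate_genotypes(runif(300, 0.1, 0.5), cfg)
  pcs <- genotype_pca(G2, K = 2)
  subpop <- attr(G2, "subpop")
  expect_gt(abs(cor(pcs$scores[, 1], subpop)), 0.5)
  expect_error(genotype_pca(G2[1:4, 1:3], K = 5), "rank")
})

test_that("single-variant test is calibrated under the null and recovers effects", {
  withr::with_seed(17, {
    rejections <- replicate(1000, {
      g <- dosage_at(300, 0.2)
      y <- rnorm(300)
      r <- residuals_of(y)
      G <- dosage_matrix(v = g)
      res <- single_variant_test(r, G)
      !is.na(res$p) && res$p < 0.05
    })
  })
  mc_se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(mean(rejections) - 0.05), 3 * mc_se)

  withr::with_seed(18, {
    betas <- replicate(200, {
      g <- dosage_at(6000, 0.05)
      y <- 0.3 * g + rnorm(6000)
      res <- single_variant_test(residuals_of(y), dosage_matrix(v = g))
      res$beta
    })
  })
  expect_lt(abs(mean(betas) - 0.3), 0.05 * 0.3)
})

test_that("model codings behave as specified at the boundaries", {
  withr::with_seed(19, {
    g <- dosage_at(800, 0.3)
    y_dom <- 0.5 * (g >= 1) + rnorm(800)
    r <- residuals_of(y_dom)
    G <- dosage_matrix(v = g)
    p_dom <- single_variant_test(r, G, model = "dominant")$p
    p_rec <- single_variant_test(r, G, model = "recessive")$p
  })
  # misspecified recessive coding loses power on a dominant effect
  expect_lt(p_dom, p_rec)
  # variants at or below the MAF floor are not tested
  rare <- dosage_matrix(v = c(1L, rep(0L, 999)))
  res <- single_variant_test(residuals_of(rnorm(1000),
                                          ids = rownames(rare)), rare)
  expect_true(is.na(res$p))
  expect_match(res$note, "MAF floor")
})

test_that("array-SNP selection is an argmin with deterministic tie-breaking", {
  res <- tibble::tibble(variant_id = c("a", "b", "c", "d"),
                        p = c(0.2, 1e-6, 0.5, NA))
  expect_equal(select_array_snp(res, c("a", "b", "c", "d")), "b")
  expect_equal(select_array_snp(res, c("a", "c")), "a")
  ties <- tibble::tibble(variant_id = c("x", "y"), p = c(1e-3, 1e-3))
  expect_equal(select_array_snp(ties, c("x", "y"),
                                positions = c(x = 200, y = 100)), "y")
  expect_error(select_array_snp(res, "d"), "no array")
  # brute-force argmin agreement on a random p vector
  withr::with_seed(5, {
    pv <- tibble::tibble(variant_id = paste0("v", 1:50), p = runif(50))
  })
  expect_equal(select_array_snp(pv, pv$variant_id),
               pv$variant_id[which.min(pv$p)])
})

test_that("conditioning on an irrelevant covariate changes nothing; perfect LD flags", {
  withr::with_seed(23, {
    g <- dosage_at(500, 0.2)
    y <- 0.3 * g + rnorm(500)
    G <- dosage_matrix(v = g, z = rep(0L, 500), w = g)
  })
  r <- residuals_of(y)
  plain <- single_variant_test(r, G, variants = "v")
  cond0 <- single_variant_test(r, G, condition_on = "z", variants = "v")
  expect_equal(cond0$beta, plain$beta, tolerance = 1e-12)
  expect_equal(cond0$p, plain$p, tolerance = 1e-12)
  dup <- conditional_test(r, G, array_variant = "w", variants = "v")
  expect_match(dup$note[dup$variant_id == "v"], "collinear")
})

test_that("conditional analysis separates independent signals and absorbs LD-mediated ones", {
  # correlated haplotype pair with target r2 = 0.8
  ld_pair <- function(n, q0 = 0.0457, q1 = 0.9397, p = 0.3) {
    draw <- function() {
      a <- rbinom(n, 1, p)
      b <- rbinom(n, 1, ifelse(a == 1, q1, q0))
      cbind(a, b)
    }
    h1 <- draw(); h2 <- draw()
    cbind(array = h1[, 1] + h2[, 1], test = h1[, 2] + h2[, 2])
  }
  withr::with_seed(29, {
    indep <- replicate(30, {
      ga <- dosage_at(2000, 0.3)
      gb <- dosage_at(2000, 0.05)
      y <- 0.15 * ga + 0.25 * gb + rnorm(2000)
      G <- dosage_matrix(arr = ga, v = gb)
      r <- residuals_of(y)
      pm <- single_variant_test(r, G, variants = "v")$p
      pc <- conditional_test(r, G, "arr", variants = "v")$p
      abs(log10(pc) - log10(pm))
    })
    mediated <- replicate(30, {
      d <- ld_pair(2000)
      y <- 0.25 * d[, "array"] + rnorm(2000)
      G <- dosage_matrix(arr = d[, "array"], v = d[, "test"])
      r <- residuals_of(y)
      c(marg = single_variant_test(r, G, variants = "v")$p,
        cond = conditional_test(r, G, "arr", variants = "v")$p)
    })
  })
  expect_lt(median(indep), 0.5)
  # the mediated marginal signal is strong but vanishes after conditioning
  expect_lt(median(mediated["marg", ]), 1e-4)
  expect_gt(median(mediated["cond", ]), 0.05)
})

test_that("LD r-squared and the independence rule follow their contracts", {
  withr::with_seed(41, {
    g <- dosage_at(100, 0.3)
  })
  expect_equal(ld_r2(g, g), 1)
  expect_true(is.na(ld_r2(g, rep(0L, 100))))
  expect_error(ld_r2(g[1:10], g[1:10]), "min_n")
  expect_true(is_independent(0.19))
  expect_false(is_independent(0.20))
  withr::with_seed(43, {
    r2s <- replicate(100, ld_r2(dosage_at(6000, 0.2), dosage_at(6000, 0.2)))
  })
  expect_lt(mean(r2s), 0.01)
})

test_that("case-control logistic test recovers a planted log-odds ratio", {
  withr::with_seed(47, {
    g <- dosage_at(4000, 0.2)
    eta <- -1 + 0.3 * g
    cc <- rbinom(4000, 1, plogis(eta))
    names(cc) <- sprintf("I%04d", 1:4000)
    G <- matrix(g, ncol = 1, dimnames = list(names(cc), "v"))
    res <- case_control_test(cc, G)
  })
  expect_lt(abs(res$beta - 0.3), 3 * res$se)
  expect_lt(res$p, 0.05)
  mono <- matrix(0L, 4000, 1, dimnames = list(names(cc), "m"))
  expect_match(case_control_test(cc, mono)$note, "monomorphic")
})

test_that("residualize-then-regress matches the joint fit for the genotype beta", {
  withr::with_seed(53, {
    n <- 800
    age <- runif(n, 31, 62)
    sex <- rbinom(n, 1, 0.5)
    g <- dosage_at(n, 0.2)
    y <- 2 + 0.02 * age + 0.3 * sex + 0.25 * g + rnorm(n)
    ph <- tibble::tibble(id = sprintf("I%03d", 1:n), cohort = "A",
                         case_status = 0L, age = age, sex = sex,
                         oc_use = 0L, pregnant = 0L, Y = y)
  })
  r <- residualize(ph, "Y", transformation = "none")
  G <- matrix(g, ncol = 1, dimnames = list(ph$id, "v"))
  two_stage <- single_variant_test(r, G)$beta
  joint <- coef(lm(y ~ g + age + I(age^2) + sex))[["g"]]
  # genotype is independent of the covariates, so the two routes agree
  expect_equal(two_stage, joint, tolerance = 0.02)
})
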