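test_that("GRM matches the hand-computed formula and clone structure", {
  # 2 individuals, 1 SNP, dosages 0 and 2: p = 0.5, A = [[2,-2],[-2,2]]
  g <- tiny_genotypes(matrix(c(0, 2), 2, 1))
  A <- compute_grm(g, maf_min = 0)$A
  expect_equal(unname(A), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  # identical genotype rows: off-diagonal equals diagonal for the pair
  set.seed(1)
  dos <- matrix(rbinom(5 * 50, 2, 0.4), 5, 50)
  dos[2, ] <- dos[1, ]
  A2 <- suppressWarnings(compute_grm(tiny_genotypes(dos),
                                     maf_min = 0.01))$A
  expect_equal(A2[1, 2], A2[1, 1], tolerance = 1e-12)
  expect_equal(A2, t(A2))   # symmetry
  # monomorphic SNPs are skipped with a warning
  dos3 <- cbind(matrix(rbinom(40, 2, 0.5), 4, 10), rep(2, 4))
  expect_warning(compute_grm(tiny_genotypes(dos3), maf_min = 0),
                 "monomorphic")
  # all SNPs failing QC errors
  expect_error(suppressWarnings(
    compute_grm(tiny_genotypes(matrix(2, 4, 3)))), "empty partition")
})

test_that("GRM diagonal is near 1 on a large random panel", {
  cfg <- fast_config(n_individuals = 500, n_snps = 2000, seed = 33)
  g <- gen_genotypes(cfg)
  grm <- compute_grm(g)
  expect_lt(abs(mean(diag(grm$A)) - 1), 0.05)
})

test_that("GRM QC removes high-missingness samples and mean-imputes", {
  set.seed(2)
  dos <- matrix(rbinom(20 * 100, 2, 0.3), 20, 100)
  dos[1, 1:50] <- NA          # 50% missing -> sample dropped
  dos[5, 1] <- NA             # light missingness -> imputed
  g <- tiny_genotypes(dos)
  grm <- compute_grm(g, maf_min = 0.01)
  expect_equal(nrow(grm$A), 19)
  expect_equal(unname(grm$n_removed["samples"]), 1)
  expect_true(all(is.finite(grm$A)))
})

test_that("AI-REML matches a restricted-likelihood grid search", {
  # independent oracle: profile the REML log-likelihood over h2 on a grid
  cfg <- fast_config(n_individuals = 400, n_snps = 500, n_parcels = 2,
                     h2_profile = matrix(0.4, 2, 1), seed = 35)
  g <- gen_genotypes(cfg)
  part <- snp_partition("all", g$snps$snp_id)
  ph <- gen_phenotypes(g, list(part), cfg)
  grm <- compute_grm(g, part)
  y <- ph$phenotypes$amplitude[, 1]
  X <- cbind(1, as.matrix(ph$phenotypes$covariates))
  n <- length(y); p <- ncol(X)
  vp <- var(y)
  grid <- seq(0.01, 0.99, by = 0.01)
  ll <- vapply(grid, function(h2) {
    V <- h2 * vp * grm$A + (1 - h2) * vp * diag(n)
    R <- chol(V)
    Vi <- chol2inv(R)
    XtViX <- crossprod(X, Vi %*% X)
    P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
    # profile the overall scale analytically
    s2 <- sum(y * (P %*% y)) / (n - p)
    -0.5 * (2 * sum(log(diag(R))) + determinant(XtViX)$modulus +
              (n - p) * log(s2))
  }, 0)
  h2_grid <- grid[which.max(ll)]
  fit <- reml_fit(y, grm, as.matrix(ph$phenotypes$covariates))
  expect_true(fit$converged)
  expect_lt(abs(fit$h2_total - h2_grid), 0.011)
})

test_that("REML recovers a null and flags non-identifiable models", {
  # pure-noise phenotype: average estimate near zero over 20 seeds
  # (boundary truncation leaves E[h2_hat] ~ SE/sqrt(2*pi), so n is sized
  # to keep the sampling SE of h2 small)
  cfg <- fast_config(n_individuals = 600, n_snps = 250, seed = 36)
  g <- gen_genotypes(cfg)
  grm <- compute_grm(g)
  h2s <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    suppressWarnings(reml_fit(rnorm(600), grm))$h2_total
  }, 0)
  expect_lte(mean(h2s), 0.03)
  # identity GRM is called out as non-identifiable
  gI <- structure(list(A = diag(100), m = 1L, ids = as.character(1:100),
                       partition = "ident"), class = "grm")
  expect_warning(reml_fit(rnorm(100), gI), "identifiab")
})

test_that("variance components conserve the residualized variance", {
  cfg <- fast_config(n_individuals = 400, n_snps = 600, n_parcels = 2,
                     h2_profile = matrix(c(0.2, 0.2, 0.2, 0.2), 2, 2),
                     seed = 37)
  g <- gen_genotypes(cfg)
  half <- ncol(g$dosage) %/% 2
  parts <- list(snp_partition("p1", g$snps$snp_id[1:half]),
                snp_partition("p2", g$snps$snp_id[(half + 1):(2 * half)]))
  ph <- gen_phenotypes(g, parts, cfg)
  y <- ph$phenotypes$amplitude[, 1]
  X <- as.matrix(ph$phenotypes$covariates)
  grms <- lapply(parts, function(p) compute_grm(g, p))
  fit <- reml_fit(y, grms, X)
  expect_true(fit$converged)
  resid_var <- var(residuals(lm(y ~ X)))
  expect_lt(abs(sum(fit$sigma2) - resid_var) / resid_var, 0.02)
  # h2 invariants
  expect_true(all(fit$h2_part >= 0))
  expect_lte(max(fit$h2_part), fit$h2_total + 1e-6)
  expect_lte(fit$h2_total, 1 + 1e-6)
  # warm start reproduces the cold-start optimum
  fit_w <- reml_fit(y, grms, X, init = fit$sigma2)
  expect_equal(fit_w$h2_part, fit$h2_part, tolerance = 1e-4)
})

test_that("mixture Wald test has the stated form", {
  expect_equal(wald_mixture_p(0, 1), 0.5)
  # W = 2.706 is the chi-square(1) 0.10 upper quantile: halved p ~ 0.050
  expect_equal(wald_mixture_p(sqrt(2.706), 1), 0.05, tolerance = 1e-3)
  expect_error(wald_mixture_p(1, 0), "positive")
  expect_error(wald_mixture_p(1, -1), "positive")
})

test_that("enrichment statistic reproduces the ratio formula exactly", {
  # printed worked example from the prefrontal cluster
  e <- enrichment_from_components(0.022, 0.33, 9571, 337501,
                                  se_h2_part = 0.0091)
  expect_equal(e$enrich, (0.022 / 0.33) / (9571 / 337501))
  expect_equal(round(e$enrich, 2), 2.35)
  expect_equal(round(e$se_scaled, 2), 0.32)
  # identity: full-genome partition has enrichment 1
  expect_equal(enrichment_from_components(0.3, 0.3, 100, 100)$enrich, 1)
  expect_error(enrichment_from_components(0.1, 0, 10, 100), "undefined")
  # machine-precision exactness on a fitted decomposition
  cfg <- fast_config(n_individuals = 200, n_snps = 300, n_parcels = 2,
                     h2_profile = matrix(c(0.2, 0.2, 0.1, 0.1), 2, 2),
                     seed = 38)
  g <- gen_genotypes(cfg)
  parts <- list(snp_partition("p1", g$snps$snp_id[1:100]),
                snp_partition("p2", g$snps$snp_id[101:300]))
  ph <- gen_phenotypes(g, parts, cfg)
  grms <- lapply(parts, function(p) compute_grm(g, p))
  fit <- suppressWarnings(reml_fit(ph$phenotypes$amplitude[, 1], grms))
  es <- enrichment_statistic(fit, "p1")
  expect_identical(es$enrich,
                   (fit$h2_part[["p1"]] / fit$h2_total) /
                     (fit$g_part[["p1"]] / fit$g_total))
})

test_that("equal per-SNP effect variance gives enrichment near 1", {
  # both partitions share the per-SNP variance: enrich should hover at 1
  enr <- vapply(1:20, function(s) {
    cfg <- fast_config(n_individuals = 350, n_snps = 600, n_parcels = 1,
                       h2_profile = matrix(c(0.2, 0.2), 1, 2), seed = s)
    g <- gen_genotypes(cfg)
    parts <- list(snp_partition("p1", g$snps$snp_id[1:300]),
                  snp_partition("p2", g$snps$snp_id[301:600]))
    ph <- gen_phenotypes(g, parts, cfg)
    grms <- lapply(parts, function(p) compute_grm(g, p))
    fit <- suppressWarnings(reml_fit(ph$phenotypes$amplitude[, 1], grms,
                                     as.matrix(ph$phenotypes$covariates)))
    enrichment_statistic(fit, "p1")$enrich
  }, 0)
  expect_gt(mean(enr), 0.8)
  expect_lt(mean(enr), 1.2)
})

test_that("parcel sweep masks failures and matches independent fits", {
  cfg <- fast_config(n_individuals = 250, n_snps = 400, n_parcels = 6,
                     h2_profile = matrix(0.3, 6, 1), seed = 39)
  g <- gen_genotypes(cfg)
  part <- snp_partition("p1", g$snps$snp_id)
  ph <- gen_phenotypes(g, list(part), cfg)
  grm <- compute_grm(g, part)
  sw <- parcelwise_partitioned_h2(ph$phenotypes, list(grm))
  expect_true(all(sw$h2_total_map$mask))
  # warm-started sweep results equal independent cold fits
  for (i in c(1, 4)) {
    solo <- reml_fit(ph$phenotypes$amplitude[, i], grm,
                     as.matrix(ph$phenotypes$covariates))
    expect_equal(sw$h2_maps$p1$values[i], unname(solo$h2_part), tolerance = 1e-4)
  }
  # a constant phenotype column cannot be fit and must be masked
  ph2 <- ph$phenotypes
  ph2$amplitude[, 2] <- 1
  sw2 <- parcelwise_partitioned_h2(ph2, list(grm))
  expect_false(sw2$h2_total_map$mask[2])
  expect_true(sw2$h2_total_map$mask[1])
})
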