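test_that("expression generator honours the gradient contract", {
  # noiseless, full-strength opposite loadings -> exact anti-correlation
  cfg <- fast_config(gradient_strength = 1, noise_sd = 0, seed = 5)
  sim <- gen_expression_atlas(cfg)
  r <- cor(sim$atlas$values[, "MKA"], sim$atlas$values[, "MKB"])
  expect_equal(r, -1)
  # marker A loads +g, marker B -g on the true gradient
  expect_equal(unname(sim$truth$loadings["MKA"]), 1)
  expect_equal(unname(sim$truth$loadings["MKB"]), -1)
  # degenerate geometry refused
  expect_error(gen_expression_atlas(
    sim_config(n_parcels = 3, seed = 1)), NA)
  expect_error(sim_config(n_parcels = 2) |> gen_expression_atlas(),
               "3 parcels")
})

test_that("zero gradient strength decouples the markers (Monte Carlo)", {
  rs <- vapply(1:50, function(s) {
    sim <- gen_expression_atlas(fast_config(gradient_strength = 0, seed = s))
    cor(sim$atlas$values[, "MKA"], sim$atlas$values[, "MKB"])
  }, 0)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("generators are bitwise deterministic in the seed", {
  cfg <- fast_config(seed = 11)
  expect_identical(serialize(gen_expression_atlas(cfg), NULL),
                   serialize(gen_expression_atlas(cfg), NULL))
  expect_identical(serialize(gen_genotypes(cfg), NULL),
                   serialize(gen_genotypes(cfg), NULL))
  expect_identical(serialize(gen_single_cell_profiles(cfg), NULL),
                   serialize(gen_single_cell_profiles(cfg), NULL))
  part <- snp_partition("p1", gen_genotypes(cfg)$snps$snp_id[1:100])
  cfg2 <- fast_config(seed = 11,
                      h2_profile = matrix(0.3, 12, 1))
  g <- gen_genotypes(cfg2)
  expect_identical(
    serialize(gen_phenotypes(g, list(part), cfg2), NULL),
    serialize(gen_phenotypes(g, list(part), cfg2), NULL))
  expect_identical(
    serialize(gen_summary_stats(g, part$snp_ids, cfg2), NULL),
    serialize(gen_summary_stats(g, part$snp_ids, cfg2), NULL))
  # different seeds give different draws
  expect_false(identical(gen_genotypes(fast_config(seed = 1))$dosage,
                         gen_genotypes(fast_config(seed = 2))$dosage))
})

test_that("single-cell profiles have exclusive elevated markers", {
  cfg <- fast_config(seed = 3)
  sc <- gen_single_cell_profiles(cfg)
  mk <- sc$truth$markers
  # disjoint marker sets, >= 5 per type
  expect_true(all(lengths(mk) >= 5))
  expect_equal(anyDuplicated(unlist(mk)), 0L)
  # configured fold change separates type means on its own markers
  types <- unique(sc$profiles$cell_type)
  for (ty in types) {
    own <- colMeans(sc$profiles$values[sc$profiles$cell_type == ty,
                                       mk[[ty]], drop = FALSE])
    other <- colMeans(sc$profiles$values[sc$profiles$cell_type != ty,
                                         mk[[ty]], drop = FALSE])
    expect_gt(min(own / other), cfg$marker_fold / 2)
  }
  # too many types for the gene budget is refused
  expect_error(gen_single_cell_profiles(
    fast_config(n_genes = 20, n_cell_types = 5)), "insufficient genes")
})

test_that("pure-type profiles round-trip through the deconvolution stack", {
  cfg <- fast_config(seed = 9)
  sc <- gen_single_cell_profiles(cfg)
  sig <- build_signature(sc$profiles, top_m_markers = 10)
  # bulk samples that ARE the signature columns: recovered fraction = 1
  bulk <- t(sig$signature)
  rownames(bulk) <- paste0("pure_", colnames(sig$signature))
  fr <- estimate_fractions(bulk, sig)
  for (k in seq_len(ncol(fr$fractions)))
    expect_equal(unname(fr$fractions[k, k]), 1, tolerance = 1e-8)
})

test_that("genotype generator matches its binomial model", {
  cfg <- fast_config(n_individuals = 400, n_snps = 200,
                     maf_range = c(0.5, 0.5), seed = 21)
  g <- gen_genotypes(cfg)
  expect_true(all(g$dosage %in% 0:2))
  # p = 0.5 exactly: sample frequency within 3 binomial SEs per SNP
  # (99.7% of SNPs expected inside the band; allow the multiplicity)
  se <- sqrt(0.5 * 0.5 / (2 * 400))
  freq <- colMeans(g$dosage) / 2
  expect_gte(mean(abs(freq - 0.5) <= 3 * se + 1e-12), 0.98)
  expect_lt(abs(mean(freq) - 0.5), 3 * se / sqrt(200))
  expect_error(sim_config(n_snps = 0), "n_snps")
})

test_that("generated genotypes are in Hardy-Weinberg equilibrium", {
  cfg <- fast_config(n_individuals = 500, n_snps = 2000, seed = 13)
  g <- gen_genotypes(cfg)
  n <- nrow(g$dosage)
  p <- colMeans(g$dosage) / 2
  counts <- sapply(0:2, function(k) colSums(g$dosage == k))
  expected <- cbind((1 - p)^2, 2 * p * (1 - p), p^2) * n
  chi2 <- rowSums((counts - expected)^2 / expected)
  rej <- mean(chi2 > qchisq(0.95, df = 1))
  # ~alpha of SNPs reject at alpha = 0.05
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("block-LD option induces within-block dosage correlation", {
  g <- gen_genotypes(fast_config(n_individuals = 500, n_snps = 40,
                                 ld_rho = 0.9, ld_block_size = 20,
                                 seed = 2))
  # thresholding the latent field attenuates the correlation, so the
  # dosage-scale r is well below the latent 0.9 but clearly nonzero
  within <- cor(g$dosage[, 1], g$dosage[, 2])
  across <- cor(g$dosage[, 20], g$dosage[, 21])  # block boundary
  expect_gt(within, 0.3)
  expect_lt(abs(across), 0.2)
})

test_that("phenotype generator realizes the requested architecture", {
  # null architecture: REML finds (almost) nothing
  cfg <- fast_config(n_individuals = 300, n_snps = 400, n_parcels = 3,
                     h2_profile = matrix(0, 3, 1), seed = 31)
  g <- gen_genotypes(cfg)
  part <- snp_partition("all", g$snps$snp_id)
  ph <- gen_phenotypes(g, list(part), cfg)
  grm <- compute_grm(g, part)
  h2_null <- vapply(1:3, function(i)
    suppressWarnings(reml_fit(ph$phenotypes$amplitude[, i],
                              grm))$h2_total, 0)
  expect_lt(mean(h2_null), 0.1)
  # invalid architecture refused
  expect_error(sim_config(h2_profile = matrix(c(0.6, 0.6), 1, 2)),
               "sum to <= 1")
  # realized Var(Zu)/Var(y) tracks the request at n = 2000 (10 seeds)
  reals <- vapply(1:10, function(s) {
    cfg2 <- sim_config(n_individuals = 2000, n_snps = 300, n_parcels = 2,
                       h2_profile = matrix(0.3, 2, 1), seed = s)
    g2 <- gen_genotypes(cfg2)
    p2 <- snp_partition("all", g2$snps$snp_id)
    gen_phenotypes(g2, list(p2), cfg2)$truth$realized_h2[1, 1]
  }, 0)
  expect_lt(abs(mean(reals) - 0.3), 0.05)
})

test_that("summary-statistic generator is calibrated under the global null", {
  cfg <- fast_config(n_individuals = 200, n_snps = 500, gwas_h2 = 0,
                     n_gwas = 300, seed = 17)
  g <- gen_genotypes(cfg)
  ss <- gen_summary_stats(g, character(0), cfg)$sumstats
  expect_true(all(ss$p > 0 & ss$p <= 1))
  expect_lt(abs(median(ss$p) - 0.5), 0.07)
  # empty causal set with enrichment != 1 warns, does not error
  cfgw <- fast_config(geneset_enrichment_factor = 5, seed = 17,
                      n_gwas = 50)
  expect_warning(gen_summary_stats(g, character(0), cfgw),
                 "empty causal set")
})

test_that("enrichment factor 1 leaves set and non-set chi-squares alike", {
  diffs <- ses <- numeric(20)
  for (s in 1:20) {
    cfg <- fast_config(n_individuals = 150, n_snps = 400, n_gwas = 300,
                       gwas_h2 = 0.4, geneset_enrichment_factor = 1,
                       seed = 100 + s)
    g <- gen_genotypes(cfg)
    set <- g$snps$snp_id[1:80]
    ss <- gen_summary_stats(g, set, cfg)$sumstats
    chi2 <- (ss$beta / ss$se)^2
    inset <- ss$snp_id %in% set
    diffs[s] <- mean(chi2[inset]) - mean(chi2[!inset])
    ses[s] <- sqrt(var(chi2[inset]) / sum(inset) +
                     var(chi2[!inset]) / sum(!inset))
  }
  # mean difference across reps within 2 SE of zero
  expect_lt(abs(mean(diffs)), 2 * mean(ses) / sqrt(20))
})
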