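test_that("probe filtering and collapse follow the stated rules", {
  # 10 cortical samples; probe detection fractions straddle the threshold
  set.seed(1)
  vals <- matrix(rnorm(10 * 6), 10, 6,
                 dimnames = list(NULL, paste0("probe", 1:6)))
  vals[, 3] <- vals[, 3] + 5        # probe3 has the higher mean for geneB
  gm <- data.frame(gene_id = c("geneA", "geneB", "geneB", "geneC",
                               "geneD", "geneE"),
                   probe_id = paste0("probe", 1:6),
                   entrez = c(1, 2, 2, 3, NA, 5))
  atl <- tiny_atlas(vals, gene_meta = gm)
  det <- matrix(TRUE, 10, 6)
  det[1:9, 6] <- FALSE              # probe6 detected in 10% < 20% -> removed
  det[1:8, 4] <- FALSE              # probe4 detected in exactly 20% -> kept
  out <- filter_and_collapse_probes(atl, det)
  # probe6 (under threshold) and probe5 (no entrez) gone; geneB collapsed
  expect_setequal(colnames(out$values), c("geneA", "geneB", "geneC"))
  expect_equal(out$values[, "geneB"], unname(vals[, 3]),
               ignore_attr = TRUE)

  # brute-force oracle on the same fixture: enumerate the rules directly
  keep <- colMeans(det) >= 0.2 & !is.na(gm$entrez)
  surv <- vapply(unique(gm$gene_id[keep]), function(g) {
    cand <- which(keep & gm$gene_id == g)
    cand[which.max(colMeans(vals)[cand])]
  }, 0L)
  expect_setequal(colnames(out$values), gm$gene_id[surv])
  for (g in gm$gene_id[surv])
    expect_equal(out$values[, g], unname(vals[, surv[[g]]]),
                 ignore_attr = TRUE)
  # filtering everything errors
  expect_error(filter_and_collapse_probes(atl, matrix(FALSE, 10, 6)),
               "empty atlas")
})

test_that("within-region normalization is exact, guarded, and idempotent", {
  atl <- tiny_atlas(cbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5)))
  expect_warning(norm <- normalize_within_region(atl), "zero variance")
  expect_equal(unname(norm$values[, "g1"]), c(-1, 0, 1))  # sample SD = 1
  expect_equal(unname(norm$values[, "g2"]), c(0, 0, 0))
  expect_true(norm$normalized)

  # two regions normalized independently despite different raw means
  vals <- cbind(g1 = c(1, 2, 3, 101, 102, 103))
  atl2 <- tiny_atlas(vals, region = rep(c("cortex", "striatum"), each = 3))
  n2 <- normalize_within_region(atl2)
  expect_equal(mean(n2$values[1:3, 1]), 0)
  expect_equal(mean(n2$values[4:6, 1]), 0)
  expect_equal(sd(n2$values[4:6, 1]), 1)

  # idempotence
  sim <- gen_expression_atlas(fast_config(seed = 4))
  n1 <- normalize_within_region(sim$atlas)
  nn <- normalize_within_region(n1)
  expect_lt(max(abs(nn$values - n1$values)), 1e-12)
})

test_that("marker difference is the z-difference and is anti-symmetric", {
  atl <- tiny_atlas_norm(cbind(a = c(1, 2, 3), b = c(3, 2, 1)))
  expect_equal(unname(marker_difference(atl, "a", "b")), c(-2, 0, 2))
  expect_equal(marker_difference(atl, "a", "a"), rep(0, 3),
               ignore_attr = TRUE)
  expect_equal(marker_difference(atl, "a", "b"),
               -marker_difference(atl, "b", "a"))
  expect_error(marker_difference(atl, "a", "zz"), "not found")
  # permutation equivariance
  sim <- gen_expression_atlas(fast_config(seed = 8))
  atl2 <- normalize_within_region(sim$atlas)
  d <- marker_difference(atl2, "MKA", "MKB")
  perm <- sample(nrow(atl2$values))
  atl_p <- expression_atlas(atl2$values[perm, ],
                            atl2$sample_meta[perm, ],
                            atl2$gene_meta, normalized = TRUE)
  expect_equal(unname(marker_difference(atl_p, "MKA", "MKB")),
               unname(d[perm]))
})

test_that("null AUC equals exhaustive enumeration on small fixtures", {
  set.seed(42)
  vals <- matrix(rnorm(20 * 10), 20, 10,
                 dimnames = list(NULL, sprintf("g%02d", 1:10)))
  atl <- tiny_atlas_norm(vals)
  res <- null_auc(atl, "g01", "g02", pair_null = TRUE)
  # gene-wise oracle: explicit loop over every other gene
  ref <- vapply(colnames(vals)[-1], function(g)
    cor(atl$values[, "g01"], atl$values[, g]), 0)
  obs <- cor(atl$values[, "g01"], atl$values[, "g02"])
  expect_equal(res$observed_r, obs)
  expect_equal(sort(res$reference_rs), sort(ref))
  expect_equal(res$auc, mean(ref <= obs))
  # pair oracle: all 45 pairs enumerated directly
  pair_r <- combn(10, 2, function(ij)
    cor(atl$values[, ij[1]], atl$values[, ij[2]]))
  expect_equal(res$n_pairs_evaluated, 45)
  expect_equal(res$pair_auc, mean(pair_r <= obs))
  # chunked streaming gives the identical answer
  res_chunk <- null_auc(atl, "g01", "g02", pair_null = TRUE,
                        chunk_size = 3L)
  expect_equal(res_chunk$pair_auc, res$pair_auc)
  # spearman route agrees with a rank-based oracle
  res_sp <- null_auc(atl, "g01", "g02", method = "spearman")
  expect_equal(res_sp$observed_r,
               cor(atl$values[, "g01"], atl$values[, "g02"],
                   method = "spearman"))
})

test_that("a duplicated column attains the AUC maximum", {
  set.seed(7)
  vals <- matrix(rnorm(15 * 6), 15, 6,
                 dimnames = list(NULL, sprintf("g%d", 1:6)))
  vals[, 2] <- vals[, 1]            # g2 duplicates g1
  atl <- tiny_atlas_norm(vals)
  res <- null_auc(atl, "g1", "g2")
  expect_equal(res$observed_r, 1)
  expect_equal(res$auc, 1)
  expect_error(null_auc(tiny_atlas_norm(matrix(rnorm(4), 2, 2,
    dimnames = list(NULL, c("a", "b")))), "a", "b"), "insufficient")
})

test_that("seeded pair subsampling is deterministic and consistent", {
  sim <- gen_expression_atlas(fast_config(seed = 2))
  atl <- normalize_within_region(sim$atlas)
  r1 <- null_auc(atl, "MKA", "MKB", pair_null = TRUE,
                 pair_subsample = 500, seed = 99)
  r2 <- null_auc(atl, "MKA", "MKB", pair_null = TRUE,
                 pair_subsample = 500, seed = 99)
  expect_identical(r1$pair_auc, r2$pair_auc)
  expect_equal(r1$n_pairs_evaluated, 500)
  full <- null_auc(atl, "MKA", "MKB", pair_null = TRUE)
  expect_lt(abs(r1$pair_auc - full$pair_auc), 0.05)
})

test_that("default synthetic atlas shows the anti-correlation signature", {
  hits <- 0L
  for (s in 1:50) {
    sim <- gen_expression_atlas(sim_config(seed = 400 + s))
    atl <- normalize_within_region(sim$atlas)
    r <- cor(atl$values[, "MKA"], atl$values[, "MKB"])
    auc <- null_auc(atl, "MKA", "MKB")$auc
    if (r < -0.3 && auc < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 48L)   # >= 95% of 50 seeds
})

test_that("spatial coupling matches the textbook formula and controls", {
  ids <- sprintf("P%d", 1:6)
  a <- parcel_map(ids, c(1, 3, 2, 5, 4, 6))
  b <- parcel_map(ids, c(2, 2, 3, 6, 4, 7))
  sc <- spatial_coupling(a, b)
  av <- a$values; bv <- b$values
  r_hand <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  expect_equal(sc$r, r_hand)
  expect_equal(spatial_coupling(a, a)$r, 1)
  # covariate exactly orthogonal to map_b: beta == simple correlation
  set.seed(3)
  bb <- zscore(rnorm(30))
  cv <- zscore(residuals(lm(rnorm(30) ~ bb)))   # orthogonal by construction
  aa <- 0.5 * bb + rnorm(30, 0, 0.3)
  ids30 <- sprintf("P%02d", 1:30)
  beta <- spatial_coupling(parcel_map(ids30, aa), parcel_map(ids30, bb),
                           covariate = parcel_map(ids30, cv))$beta
  expect_equal(beta, cor(aa, bb), tolerance = 1e-9)
  expect_error(spatial_coupling(parcel_map(ids[1:3], 1:3),
                                parcel_map(ids[1:3], 3:1)),
               "different parcel universes|insufficient")
})

test_that("outlier exclusion uses pre-exclusion moments and joint masks", {
  ids <- sprintf("P%d", 1:5)
  m <- parcel_map(ids, c(0, 0, 0, 0, 100))
  # mean 20, sd ~44.7: |100 - 20| = 80 < 4 sd = 178.9 -> nothing at k = 4?
  # hand computation: sd = sqrt((4*400 + 6400)/4) = sqrt(2000) = 44.72
  # 4 * 44.72 = 178.9 > 80, so k = 4 keeps it; use k = 1.5 to drop index 5
  out <- exclude_outliers(m, k_sd = 1.5)
  expect_equal(out$mask, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # all equal -> zero SD guard -> nothing masked
  eq <- exclude_outliers(parcel_map(ids, rep(2, 5)))
  expect_true(all(eq$mask))
  # infinite k is a no-op
  expect_equal(exclude_outliers(m, k_sd = Inf)$mask, m$mask)
  # joint masking across companions
  comp <- parcel_map(ids, c(0, 0, 0, 0, 0))
  both <- exclude_outliers(m, list(comp), k_sd = 1.5)
  expect_equal(both[[2]]$mask, c(TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("region medians and developmental slopes behave as constructed", {
  vals <- cbind(a = c(-1, 0, 3, 5, 6, 7), b = c(1, 1, 1, 0, 0, 0))
  atl <- tiny_atlas(vals)
  atl$normalized <- TRUE   # use raw values as-is for the median check
  grp <- rep(c("CeA", "SNr"), each = 3)
  prof <- region_median_profile(atl, c("a", "b"), grp)
  expect_equal(prof$a[prof$subregion == "CeA"], 0)     # odd-count median
  expect_equal(prof$delta[prof$subregion == "SNr"], 6) # a >> b: positive
  # noiseless construction: median differences rank like generating values
  dens <- c(5, 3, 8, 1)
  vals2 <- do.call(rbind, lapply(dens, function(d)
    matrix(rep(c(d, -d), each = 3), 3, 2)))
  colnames(vals2) <- c("a", "b")
  atl2 <- tiny_atlas(vals2)
  atl2$normalized <- TRUE
  prof2 <- region_median_profile(atl2, c("a", "b"),
                                 rep(paste0("R", 1:4), each = 3))
  expect_equal(cor(prof2$delta, 2 * dens, method = "spearman"), 1)

  # developmental regression: identity stage has slope 1
  st1 <- tiny_atlas_norm(matrix(rnorm(40), 20, 2,
                                dimnames = list(NULL, c("x", "y"))))
  st1$values[, "y"] <- st1$values[, "x"]
  dv <- suppressWarnings(   # identity regression: "perfect fit" warning
    developmental_association(list(adult = st1), "y", "x"))
  expect_equal(dv$beta, 1, tolerance = 1e-12)
  expect_false(dv$age_adjusted)
})

test_that("developmental regression recovers slopes and removes confounds", {
  # OLS sampling oracle: true slope -0.5, n = 60, noise 0.5
  set.seed(10)
  x <- rnorm(60)
  y <- -0.5 * x + rnorm(60, 0, 0.5)
  atl <- tiny_atlas(cbind(ga = y, gb = x), age = rep(c(30, 40), 30))
  atl$normalized <- TRUE
  dv <- developmental_association(list(stage = atl), "ga", "gb")
  expect_lt(abs(dv$beta - (-0.5)), 2 * dv$se)
  expect_true(dv$age_adjusted)
  # age-driven spurious slope removed by adjustment
  age <- rep(c(10, 20), each = 30)
  ga <- age / 10 + rnorm(60, 0, 0.1)    # depends only on age
  gb <- age / 10 + rnorm(60, 0, 0.1)
  atl2 <- tiny_atlas(cbind(ga, gb), age = age)
  atl2$normalized <- TRUE
  adj <- developmental_association(list(s = atl2), "ga", "gb")
  raw_slope <- coef(lm(ga ~ gb))[2]
  expect_gt(raw_slope, 0.8)             # confounded slope is large
  expect_lt(abs(adj$beta), 0.25)        # adjusted slope collapses
  # tiny stages are skipped
  expect_warning(
    developmental_association(list(tiny = tiny_atlas_norm(
      matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("ga", "gb")))),
      s = atl2), "ga", "gb"), "skipped")
})

test_that("sample-to-parcel assignment is exact nearest-neighbour", {
  cen <- rbind(P001 = c(0, 0, 0), P002 = c(10, 0, 0), P003 = c(0, 10, 0))
  # coincident sample
  a <- map_samples_to_parcels(rbind(c(0, 0, 0)), cen)
  expect_equal(unname(a[1]), "P001")
  expect_equal(attr(a, "distance")[1], 0)
  # distance 4.1 with max_dist 4 -> unassigned
  a2 <- map_samples_to_parcels(rbind(c(4.1, 0, 0), c(6, 0, 0)), cen,
                               max_dist = 4)
  expect_true(is.na(a2[1]))
  expect_equal(unname(a2[2]), "P002")
  # equidistant tie goes to the lowest parcel id
  tie <- map_samples_to_parcels(rbind(c(5, 0, 0)), cen, max_dist = 10)
  expect_equal(unname(tie[1]), "P001")
  # brute-force oracle over 20 random samples
  set.seed(5)
  pts <- matrix(rnorm(60, 0, 6), 20, 3)
  got <- map_samples_to_parcels(pts, cen, max_dist = Inf)
  want <- apply(pts, 1, function(p)
    rownames(cen)[which.min(colSums((t(cen) - p)^2))])
  expect_equal(unname(got), want, ignore_attr = TRUE)
  expect_error(map_samples_to_parcels(pts, cen[0, , drop = FALSE]),
               "empty")
})
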