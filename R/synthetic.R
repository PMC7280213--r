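#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators.  Defaults define the
#' study conditions assumed throughout the test-suite: two anti-correlated
#' marker genes riding an anterior-posterior gradient, LD-free genotypes
#' with a partitioned additive architecture, and summary statistics with
#' set-enriched effects.
#'
#' @param n_parcels number of cortical parcels (>= 3).
#' @param n_samples_per_parcel tissue samples drawn per parcel.
#' @param n_genes number of genes on the expression platform.
#' @param marker_ids character pair naming the two anti-correlated marker
#'   genes (stand-ins for SST and PVALB).
#' @param gradient_strength loading (in [0, 1]) of marker A on the spatial
#'   gradient; marker B loads with the opposite sign.
#' @param bg_loading_sd SD of the symmetric-about-zero gradient loadings of
#'   non-marker genes.
#' @param noise_sd residual expression noise SD.
#' @param n_cell_types number of single-cell types (>= 2).
#' @param n_cells_per_type cells simulated per type.
#' @param n_markers_per_type exclusive marker genes per cell type (>= 5).
#' @param marker_fold fold-change of a type's markers over other types.
#' @param n_individuals genotyped cohort size.
#' @param n_snps number of SNPs.
#' @param maf_range allele-frequency range, within (0, 0.5].
#' @param ld_rho AR(1) correlation of the latent allelic field within LD
#'   blocks; 0 (default) gives LD-free genotypes.
#' @param ld_block_size SNPs per LD block when `ld_rho > 0`.
#' @param h2_profile optional parcels x partitions matrix of per-parcel
#'   per-partition heritability fractions (row sums must be <= 1).
#' @param geneset_enrichment_factor multiplier (>= 0) of per-SNP effect
#'   variance inside the causal set when simulating summary statistics.
#' @param gwas_h2 liability heritability used by [gen_summary_stats()].
#' @param n_gwas independent GWAS-cohort size for summary statistics.
#' @param seed single global seed; each generator derives a fixed child seed
#'   from it, so adding one generator never perturbs another.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_parcels = 40L, n_samples_per_parcel = 6L,
                       n_genes = 600L,
                       marker_ids = c("MKA", "MKB"),
                       gradient_strength = 0.8,
                       bg_loading_sd = 0.3, noise_sd = 0.5,
                       n_cell_types = 4L, n_cells_per_type = 60L,
                       n_markers_per_type = 10L, marker_fold = 4,
                       n_individuals = 600L, n_snps = 2400L,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0, ld_block_size = 10L,
                       h2_profile = NULL,
                       geneset_enrichment_factor = 1,
                       gwas_h2 = 0.5, n_gwas = 1000L,
                       seed = 1L) {
  n_parcels <- check_count(n_parcels, "n_parcels")
  n_samples_per_parcel <- check_count(n_samples_per_parcel,
                                      "n_samples_per_parcel")
  n_genes <- check_count(n_genes, "n_genes", min = 2L)
  n_cell_types <- check_count(n_cell_types, "n_cell_types")
  n_individuals <- check_count(n_individuals, "n_individuals")
  n_snps <- check_count(n_snps, "n_snps")
  if (length(marker_ids) != 2L || marker_ids[1] == marker_ids[2])
    stop2("`marker_ids` must be two distinct gene ids")
  if (gradient_strength < 0 || gradient_strength > 1)
    stop2("`gradient_strength` must lie in [0, 1]")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5)
      || maf_range[1] > maf_range[2])
    stop2("`maf_range` must be within (0, 0.5] with low <= high")
  if (!is.null(h2_profile)) {
    h2_profile <- as.matrix(h2_profile)
    if (any(h2_profile < 0) || any(rowSums(h2_profile) > 1 + 1e-12))
      stop2("per-parcel partition heritabilities must be >= 0 and sum to <= 1")
  }
  if (geneset_enrichment_factor < 0)
    stop2("`geneset_enrichment_factor` must be >= 0")
  structure(list(n_parcels = n_parcels,
                 n_samples_per_parcel = n_samples_per_parcel,
                 n_genes = n_genes, marker_ids = marker_ids,
                 gradient_strength = gradient_strength,
                 bg_loading_sd = bg_loading_sd, noise_sd = noise_sd,
                 n_cell_types = n_cell_types,
                 n_cells_per_type = n_cells_per_type,
                 n_markers_per_type = n_markers_per_type,
                 marker_fold = marker_fold,
                 n_individuals = n_individuals, n_snps = n_snps,
                 maf_range = maf_range, ld_rho = ld_rho,
                 ld_block_size = as.integer(ld_block_size),
                 h2_profile = h2_profile,
                 geneset_enrichment_factor = geneset_enrichment_factor,
                 gwas_h2 = gwas_h2, n_gwas = as.integer(n_gwas),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a spatial expression atlas with anti-correlated markers
#'
#' Parcels sit along a one-dimensional anterior-posterior gradient; marker A
#' loads `+gradient_strength` on it, marker B `-gradient_strength`, and all
#' other genes receive loadings drawn symmetrically about zero, plus
#' independent Gaussian noise.  Parcel centroids are laid out in a shared
#' 3-D frame and samples scatter around their parcel's centroid.
#'
#' @param config a [sim_config()].
#' @return list with elements `atlas` (raw [expression_atlas()]),
#'   `centroids` (parcels x 3 coordinate matrix with parcel-id rownames) and
#'   `truth` (list: `true_gradient`, per-gene `loadings`).
#' @export
gen_expression_atlas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_parcels < 3L)
    stop2("degenerate geometry: need at least 3 parcels")
  P <- config$n_parcels; S <- config$n_samples_per_parcel
  G <- config$n_genes
  withr::with_seed(child_seed(config$seed, "atlas"), {
    gradient <- seq(-1.5, 1.5, length.out = P)
    gene_ids <- sprintf("G%04d", seq_len(G))
    mk <- config$marker_ids
    gene_ids[1:2] <- mk
    loadings <- stats::rnorm(G, 0, config$bg_loading_sd)
    loadings[1] <- config$gradient_strength
    loadings[2] <- -config$gradient_strength
    names(loadings) <- gene_ids

    centroids <- cbind(x = gradient * 20,
                       y = stats::rnorm(P, 0, 2),
                       z = stats::rnorm(P, 0, 2))
    rownames(centroids) <- sprintf("P%03d", seq_len(P))

    parcel_of <- rep(seq_len(P), each = S)
    n <- P * S
    coords <- centroids[parcel_of, ] +
      matrix(stats::rnorm(n * 3, 0, 0.5), n, 3)
    values <- outer(gradient[parcel_of], loadings) +
      matrix(stats::rnorm(n * G, 0, config$noise_sd), n, G)
    colnames(values) <- gene_ids
    sample_meta <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      donor = sprintf("D%d", 1L + (seq_len(n) - 1L) %% 2L),
      region = "cortex",
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      parcel = rownames(centroids)[parcel_of],
      stringsAsFactors = FALSE)
    atlas <- expression_atlas(values, sample_meta)
  })
  list(atlas = atlas, centroids = centroids,
       truth = list(true_gradient = stats::setNames(gradient,
                                                    rownames(centroids)),
                    loadings = loadings))
}

#' Generate labeled single-cell expression profiles
#'
#' Each cell type gets `n_markers_per_type` exclusive marker genes with a
#' `marker_fold` elevated mean; within-type noise is log-normal.  The first
#' two cell types are the marker-linked types: the atlas markers
#' (`marker_ids`) are among their exclusive markers.
#'
#' @param config a [sim_config()].
#' @return list with `profiles` ([cell_profiles()]) and `truth`
#'   (list: `markers` per type).
#' @export
gen_single_cell_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$n_cell_types
  if (K < 2L) stop2("need at least 2 cell types")
  m <- config$n_markers_per_type
  if (m < 5L) stop2("need at least 5 exclusive markers per type")
  if (K > config$n_genes / m)
    stop2("insufficient genes: n_cell_types > n_genes / n_markers_per_type")
  G <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(G))
  gene_ids[1:2] <- config$marker_ids
  types <- sprintf("type%02d", seq_len(K))
  withr::with_seed(child_seed(config$seed, "cells"), {
    base_mean <- stats::rlnorm(G, meanlog = 1, sdlog = 0.6)
    marker_sets <- split(gene_ids[seq_len(K * m)],
                         rep(seq_len(K), each = m))
    names(marker_sets) <- types
    n_cells <- K * config$n_cells_per_type
    cell_type <- rep(types, each = config$n_cells_per_type)
    mu <- matrix(rep(base_mean, each = n_cells), n_cells, G)
    for (k in seq_len(K)) {
      idx <- match(marker_sets[[k]], gene_ids)
      mu[cell_type == types[k], idx] <-
        mu[cell_type == types[k], idx] * config$marker_fold
    }
    values <- mu * matrix(stats::rlnorm(n_cells * G, 0, 0.3), n_cells, G)
    colnames(values) <- gene_ids
    rownames(values) <- sprintf("C%05d", seq_len(n_cells))
  })
  list(profiles = cell_profiles(values, cell_type),
       truth = list(markers = marker_sets))
}

#' Generate a genotype dosage panel
#'
#' Dosages in {0, 1, 2} drawn binomial(2, p_j) with p_j ~ U(maf_range);
#' LD-free by default, with an optional AR(1) block-LD latent field.  The
#' SNP table places SNPs on a single synthetic chromosome at 1 kb spacing
#' so gene windows of [gen_gene_annotation()] tile them.
#'
#' @param config a [sim_config()].
#' @return a [genotype_set()].
#' @export
gen_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals; m <- config$n_snps
  withr::with_seed(child_seed(config$seed, "geno"), {
    p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    if (config$ld_rho > 0) {
      dos <- matrix(0L, n, m)
      thr <- stats::qnorm(p)
      block <- rep(seq_len(ceiling(m / config$ld_block_size)),
                   each = config$ld_block_size)[seq_len(m)]
      for (hap in 1:2) {
        z <- matrix(stats::rnorm(n * m), n, m)
        for (j in 2:m) {
          if (block[j] == block[j - 1L])
            z[, j] <- config$ld_rho * z[, j - 1L] +
              sqrt(1 - config$ld_rho^2) * z[, j]
        }
        dos <- dos + (sweep(z, 2, thr, "<") * 1L)
      }
    } else {
      dos <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
    }
    alleles <- cbind(a1 = rep(c("A", "G", "A", "C"), length.out = m),
                     a2 = rep(c("G", "A", "C", "T"), length.out = m))
    snps <- data.frame(snp_id = sprintf("rs%05d", seq_len(m)),
                       chrom = "1",
                       pos = seq_len(m) * 1000L,
                       a1 = alleles[, "a1"], a2 = alleles[, "a2"],
                       stringsAsFactors = FALSE)
    rownames(dos) <- sprintf("ind%04d", seq_len(n))
  })
  genotype_set(dos, snps)
}

#' Synthetic gene annotation tiling the genotype panel
#'
#' Genes of fixed span laid down along the synthetic chromosome so each gene
#' body (plus a +/-5 kb window) covers a handful of consecutive SNPs.
#'
#' @param config a [sim_config()].
#' @param gene_span gene body length in bp.
#' @param snps_per_gene SNP spacing is 1 kb; genes start every
#'   `snps_per_gene` kb.
#' @return a [gene_annotation()] with one row per atlas gene.
#' @export
gen_gene_annotation <- function(config, gene_span = 2000L,
                                snps_per_gene = 4L) {
  G <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(G))
  gene_ids[1:2] <- config$marker_ids
  start <- (seq_len(G) - 1L) * snps_per_gene * 1000L + 500L
  gene_annotation(data.frame(
    gene_id = gene_ids, chrom = "1",
    start = start, stop = start + gene_span,
    strand = "+", stringsAsFactors = FALSE))
}

#' Generate heritable parcel phenotypes from a partitioned architecture
#'
#' Per-parcel phenotype `y_p = sum_k Z_k u_kp + X c + s * w_p * g_scz + e`
#' with standardized dosages Z, per-SNP effects
#' `u_kp ~ N(0, h2_kp / g_k)`, a small covariate effect, and (optionally)
#' a parcel-weighted polygenic liability term shared with
#' [gen_summary_stats()] ground-truth effects, used to emulate a
#' spatially-varying PRS association.
#'
#' @param genotypes a [genotype_set()].
#' @param partitions list of [snp_partition()]s (disjoint subsets of the
#'   genotyped SNPs).
#' @param config a [sim_config()]; `config$h2_profile` (parcels x
#'   partitions) sets the architecture, defaulting to a flat 0.2 per
#'   partition when NULL.
#' @param scz_effects optional per-SNP liability effect vector (named by
#'   SNP id) from [gen_summary_stats()] ground truth.
#' @param scz_weight optional per-parcel weight `w_p` of the liability
#'   term (e.g. proportional to a marker's expression map).
#' @param scz_scale scale `s` of the liability term.
#' @return list with `phenotypes` (a [phenotype_table()]) and `truth`
#'   (realized per-parcel per-partition genetic variance fractions).
#' @export
gen_phenotypes <- function(genotypes, partitions, config,
                           scz_effects = NULL, scz_weight = NULL,
                           scz_scale = 0.3) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(genotypes$dosage)
  K <- length(partitions)
  all_ids <- colnames(genotypes$dosage)
  for (p in partitions)
    if (!all(p$snp_ids %in% all_ids))
      stop2("partition '", p$name, "' contains SNPs absent from genotypes")
  if (anyDuplicated(unlist(lapply(partitions, `[[`, "snp_ids"))))
    stop2("partitions must be disjoint")
  P <- config$n_parcels
  h2 <- config$h2_profile
  if (is.null(h2)) h2 <- matrix(0.2, P, K)
  if (nrow(h2) != P || ncol(h2) != K)
    stop2("`h2_profile` must be n_parcels x n_partitions")
  if (any(rowSums(h2) > 1 + 1e-12))
    stop2("invalid architecture: per-parcel partition heritabilities sum > 1")

  Z <- scale_dosages(genotypes$dosage)
  withr::with_seed(child_seed(config$seed, "pheno"), {
    X <- cbind(age = scale(stats::rnorm(n, 60, 7)),
               sex = stats::rbinom(n, 1L, 0.5))
    cvec <- c(0.1, 0.1)
    fixed <- drop(X %*% cvec)
    gen_liab <- 0
    if (!is.null(scz_effects)) {
      idx <- match(names(scz_effects), all_ids)
      if (any(is.na(idx))) stop2("scz_effects names must be genotyped SNPs")
      gen_liab <- zscore(drop(Z[, idx, drop = FALSE] %*% scz_effects))
      if (is.null(scz_weight)) scz_weight <- rep(1, P)
    }
    amp <- matrix(0, n, P)
    realized <- matrix(0, P, K,
                       dimnames = list(NULL, vapply(partitions, `[[`, "",
                                                    "name")))
    for (pp in seq_len(P)) {
      g_sum <- 0
      for (k in seq_len(K)) {
        ids <- partitions[[k]]$snp_ids
        gk <- length(ids)
        u <- stats::rnorm(gk, 0, sqrt(h2[pp, k] / max(gk, 1L)))
        gval <- drop(Z[, ids, drop = FALSE] %*% u)
        realized[pp, k] <- stats::var(gval)
        g_sum <- g_sum + gval
      }
      e <- stats::rnorm(n, 0, sqrt(max(1 - sum(h2[pp, ]), 1e-8)))
      y <- g_sum + fixed + e
      if (!is.null(scz_effects)) y <- y - scz_scale * scz_weight[pp] * gen_liab
      amp[, pp] <- y
    }
    colnames(amp) <- sprintf("P%03d", seq_len(P))
    rownames(amp) <- rownames(genotypes$dosage)
    covariates <- data.frame(age = drop(X[, 1]), sex = X[, 2],
                             row.names = rownames(genotypes$dosage))
  })
  list(phenotypes = phenotype_table(amp, covariates, raw_amplitude = amp),
       truth = list(requested_h2 = h2, realized_var = realized,
                    realized_h2 = realized / matrix(apply(amp, 2, stats::var),
                                                    P, K)))
}

#' Generate GWAS summary statistics with set-enriched effects
#'
#' Simulates a continuous liability trait in an independent cohort drawn
#' from the same SNP frequency spectrum, with per-SNP effect variance
#' multiplied by `geneset_enrichment_factor` inside `causal_set`, then
#' regresses the liability on each SNP dosage to obtain beta, SE and p.
#'
#' @param genotypes a [genotype_set()] supplying the SNP table and allele
#'   frequencies.
#' @param causal_set character vector of SNP ids forming the enriched set.
#' @param config a [sim_config()] (`gwas_h2`, `n_gwas`,
#'   `geneset_enrichment_factor`).
#' @return list with `sumstats` (a [summary_stats()]) and `truth`
#'   (list: per-SNP liability `effects` named by SNP id).
#' @export
gen_summary_stats <- function(genotypes, causal_set, config) {
  stopifnot(inherits(config, "sim_config"))
  snps <- genotypes$snps
  m <- nrow(snps)
  if (!all(causal_set %in% snps$snp_id))
    stop2("causal_set must be a subset of genotyped SNPs")
  if (length(causal_set) == 0L && config$geneset_enrichment_factor != 1)
    warning("empty causal set: enrichment factor has no effect")
  n <- config$n_gwas
  withr::with_seed(child_seed(config$seed, "sumstats"), {
    p_hat <- pmax(pmin(colMeans(genotypes$dosage, na.rm = TRUE) / 2,
                       0.99), 0.01)
    dos <- matrix(stats::rbinom(n * m, 2L, rep(p_hat, each = n)), n, m)
    Z <- scale_dosages(dos)
    in_set <- snps$snp_id %in% causal_set
    w <- ifelse(in_set, config$geneset_enrichment_factor, 1)
    h2 <- config$gwas_h2
    if (h2 > 0 && sum(w) > 0) {
      u <- stats::rnorm(m, 0, sqrt(h2 * w / sum(w)))
      g <- drop(Z %*% u)
    } else {
      u <- rep(0, m); g <- rep(0, n)
    }
    y <- g + stats::rnorm(n, 0, sqrt(max(1 - stats::var(g), 0.05)))
    fit <- fast_univariate_gwas(dos, y)
  })
  ss <- summary_stats(data.frame(
    snp_id = snps$snp_id, chrom = snps$chrom, pos = snps$pos,
    a1 = snps$a1, a2 = snps$a2,
    beta = fit$beta, se = fit$se, p = fit$p,
    stringsAsFactors = FALSE))
  list(sumstats = ss,
       truth = list(effects = stats::setNames(u, snps$snp_id)))
}

# per-SNP simple linear regression of y on dosage, vectorized
fast_univariate_gwas <- function(dos, y) {
  n <- length(y)
  xm <- colMeans(dos)
  xc <- sweep(dos, 2, xm)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxx[sxx == 0] <- NA_real_
  beta <- drop(crossprod(xc, yc)) / sxx
  sse <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(pmax(sse, 0) / (n - 2) / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  p[!is.finite(p)] <- 1
  p <- pmax(pmin(p, 1), .Machine$double.xmin)
  beta[!is.finite(beta)] <- 0
  se[!is.finite(se)] <- Inf
  list(beta = beta, se = se, p = p)
}

# column-standardize dosages by sample allele frequency, mean-imputing NA
scale_dosages <- function(dos) {
  p <- colMeans(dos, na.rm = TRUE) / 2
  if (anyNA(dos)) {
    for (j in which(colSums(is.na(dos)) > 0))
      dos[is.na(dos[, j]), j] <- 2 * p[j]
  }
  denom <- sqrt(2 * p * (1 - p))
  denom[denom == 0] <- Inf   # monomorphic -> zero column
  sweep(sweep(dos, 2, 2 * p), 2, denom, "/")
}
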