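#' Filter probes by detection and collapse duplicates per gene
#'
#' Applies the microarray preprocessing rules: probes expressed in fewer
#' than `min_cortical_fraction` of cortical samples are removed, probes
#' without a numeric (Entrez-style) gene id are removed, and when several
#' probes map to one gene the probe with the highest mean expression is
#' retained.
#'
#' @param raw an [expression_atlas()] whose columns are probes; `gene_meta`
#'   must carry `gene_id` (the target gene symbol) and `entrez`.
#' @param detection logical samples x probes matrix aligned to `raw`
#'   (TRUE = probe detected above background in that sample).
#' @param min_cortical_fraction detection threshold, default 0.20; a probe
#'   is kept when its detection fraction across cortical samples is at
#'   least this value.
#' @return a collapsed [expression_atlas()], one column per gene.
#' @export
filter_and_collapse_probes <- function(raw, detection,
                                       min_cortical_fraction = 0.20) {
  stopifnot(inherits(raw, "expression_atlas"))
  detection <- as.matrix(detection)
  if (!all(dim(detection) == dim(raw$values)))
    stop2("`detection` must be aligned to the atlas values")
  cortical <- raw$sample_meta$region == "cortex"
  if (!any(cortical)) stop2("no cortical samples to compute detection over")
  frac <- colMeans(detection[cortical, , drop = FALSE])
  keep <- frac >= min_cortical_fraction
  gm <- raw$gene_meta
  if ("entrez" %in% names(gm)) keep <- keep & !is.na(gm$entrez)
  if (!any(keep)) stop2("all probes removed by filtering: empty atlas")
  vals <- raw$values[, keep, drop = FALSE]
  gm <- gm[keep, , drop = FALSE]
  # collapse duplicate probes per gene: max mean expression wins
  means <- colMeans(vals)
  ord <- order(gm$gene_id, -means)
  first <- !duplicated(gm$gene_id[ord])
  sel <- ord[first]
  sel <- sel[order(sel)]
  vals <- vals[, sel, drop = FALSE]
  gm <- gm[sel, , drop = FALSE]
  colnames(vals) <- gm$gene_id
  expression_atlas(vals, raw$sample_meta, gm, normalized = FALSE)
}

#' Mean- and variance-normalize expression within each region group
#'
#' Per gene and per region group, subtracts the mean and divides by the
#' sample SD (denominator n - 1), so microarray intensities become
#' comparable across samples within each anatomical territory.  Genes with
#' zero variance within a region are set to 0 there, with a warning.
#'
#' @param atlas an [expression_atlas()].
#' @param center_donors if TRUE, sample values are first mean-centered per
#'   donor (within region) as a light-weight batch adjustment.
#' @return the atlas with `normalized = TRUE`.
#' @export
normalize_within_region <- function(atlas, center_donors = FALSE) {
  stopifnot(inherits(atlas, "expression_atlas"))
  vals <- atlas$values
  regions <- atlas$sample_meta$region
  n_const <- 0L
  for (r in unique(regions)) {
    i <- which(regions == r)
    if (length(i) < 2L)
      stop2("region '", r, "' has fewer than 2 samples")
    block <- vals[i, , drop = FALSE]
    if (center_donors) {
      for (d in unique(atlas$sample_meta$donor[i])) {
        di <- atlas$sample_meta$donor[i] == d
        block[di, ] <- sweep(block[di, , drop = FALSE], 2,
                             colMeans(block[di, , drop = FALSE]))
      }
    }
    sds <- apply(block, 2, stats::sd)
    const <- !is.finite(sds) | sds == 0
    n_const <- n_const + sum(const)
    block <- sweep(block, 2, colMeans(block))
    block[, !const] <- sweep(block[, !const, drop = FALSE], 2,
                             sds[!const], "/")
    block[, const] <- 0
    vals[i, ] <- block
  }
  if (n_const > 0L)
    warning(sprintf("%d gene/region blocks had zero variance; set to 0",
                    n_const))
  expression_atlas(vals, atlas$sample_meta, atlas$gene_meta,
                   normalized = TRUE)
}

#' Marker-difference map
#'
#' Per-sample difference of two normalized marker genes,
#' `z(gene_a) - z(gene_b)` (e.g. SST - PVALB), optionally aggregated to a
#' [parcel_map()] by the mean over samples assigned to each parcel.
#'
#' @param atlas a normalized [expression_atlas()].
#' @param gene_a,gene_b gene identifiers present in the atlas.
#' @param assignment optional parcel assignment from
#'   [map_samples_to_parcels()] (character per sample, NA = unassigned).
#' @return numeric per-sample difference; when `assignment` is supplied,
#'   a list with `per_sample` and `map` (a [parcel_map()]).
#' @export
marker_difference <- function(atlas, gene_a, gene_b, assignment = NULL) {
  stopifnot(inherits(atlas, "expression_atlas"))
  if (!atlas$normalized) stop2("atlas must be normalized first")
  d <- atlas$values[, gene_index(atlas, gene_a)] -
       atlas$values[, gene_index(atlas, gene_b)]
  if (is.null(assignment)) return(d)
  list(per_sample = d, map = aggregate_to_parcels(d, assignment))
}

#' Aggregate a per-sample statistic to a parcel map
#'
#' @param x numeric per-sample values.
#' @param assignment per-sample parcel id (NA = unassigned); the parcel
#'   universe is `levels(assignment)` when it is a factor, otherwise the
#'   sorted unique ids.
#' @param parcel_ids optional explicit parcel universe.
#' @return a [parcel_map()]; parcels with no samples are masked.
#' @export
aggregate_to_parcels <- function(x, assignment, parcel_ids = NULL) {
  if (is.null(parcel_ids))
    parcel_ids <- if (is.factor(assignment)) levels(assignment)
                  else sort(unique(assignment[!is.na(assignment)]))
  assignment <- as.character(assignment)
  means <- vapply(parcel_ids, function(p) {
    i <- which(assignment == p)
    if (length(i) == 0L) NA_real_ else mean(x[i])
  }, 0)
  parcel_map(parcel_ids, ifelse(is.na(means), 0, means), !is.na(means))
}

#' Benchmark a two-gene correlation against gene-wise and pair nulls
#'
#' The observed correlation of `gene_a` with `gene_b` is ranked within the
#' reference distribution of correlations of every other gene with
#' `gene_a` (excluding the anchor's self-correlation, including the
#' partner), and optionally within the null of all G*(G-1)/2 two-gene
#' pairings.  The AUC is the exact fraction of reference correlations less
#' than or equal to the observed one (correlations within 1e-12 of the
#' observed value count as ties and are included, so the result does not
#' depend on the arithmetic route), and small values flag an unusually
#' negative pair.
#'
#' @param atlas a normalized [expression_atlas()], typically restricted to
#'   one region class.
#' @param gene_a anchor gene; @param gene_b partner gene.
#' @param region region label to restrict samples to (NULL = all samples).
#' @param method "pearson" or "spearman".
#' @param pair_null also compute the all-pairs null.
#' @param pair_subsample number of random pairs to evaluate instead of all
#'   (seeded), or `Inf` for exhaustive enumeration (streamed in chunks).
#' @param chunk_size genes per block in the streamed pair enumeration.
#' @param seed seed for pair subsampling.
#' @return list of class `null_auc_result`: `observed_r`, `reference_rs`,
#'   `auc`, and when requested `pair_auc`, `n_pairs_evaluated`.
#' @export
null_auc <- function(atlas, gene_a, gene_b, region = "cortex",
                     method = c("pearson", "spearman"),
                     pair_null = FALSE, pair_subsample = Inf,
                     chunk_size = 500L, seed = 1L) {
  stopifnot(inherits(atlas, "expression_atlas"))
  if (!atlas$normalized) stop2("atlas must be normalized first")
  method <- match.arg(method)
  vals <- atlas$values
  if (!is.null(region)) {
    i <- atlas$sample_meta$region == region
    vals <- vals[i, , drop = FALSE]
  }
  if (nrow(vals) < 3L) stop2("insufficient data: fewer than 3 samples")
  ja <- gene_index(atlas, gene_a); jb <- gene_index(atlas, gene_b)
  if (method == "spearman") vals <- apply(vals, 2, rank)
  a <- vals[, ja]
  observed <- stats::cor(a, vals[, jb])
  cut <- observed + 1e-12   # count numerical ties as included
  ref <- drop(stats::cor(a, vals[, -ja, drop = FALSE]))
  names(ref) <- colnames(vals)[-ja]
  auc <- mean(ref <= cut)
  out <- list(observed_r = observed, reference_rs = ref, auc = auc,
              method = method)
  if (pair_null) {
    G <- ncol(vals)
    n_all <- G * (G - 1) / 2
    if (is.finite(pair_subsample) && pair_subsample < n_all) {
      withr::with_seed(seed, {
        i1 <- sample.int(G, pair_subsample, replace = TRUE)
        i2 <- sample.int(G - 1L, pair_subsample, replace = TRUE)
        i2 <- ifelse(i2 >= i1, i2 + 1L, i2)
      })
      le <- 0L
      for (s in seq(1L, pair_subsample, by = 10000L)) {
        e <- min(s + 9999L, pair_subsample)
        rs <- colSums(scale(vals[, i1[s:e], drop = FALSE]) *
                        scale(vals[, i2[s:e], drop = FALSE])) /
          (nrow(vals) - 1)
        le <- le + sum(rs <= cut)
      }
      out$pair_auc <- le / pair_subsample
      out$n_pairs_evaluated <- as.numeric(pair_subsample)
    } else {
      zs <- scale(vals) / sqrt(nrow(vals) - 1)
      le <- 0L
      for (s in seq(1L, G, by = chunk_size)) {
        e <- min(s + chunk_size - 1L, G)
        block <- crossprod(zs[, s:e, drop = FALSE], zs)
        for (r in seq_len(nrow(block))) {
          j <- s + r - 1L
          if (j < G)
            le <- le + sum(block[r, (j + 1L):G] <= cut)
        }
      }
      out$pair_auc <- le / n_all
      out$n_pairs_evaluated <- n_all
    }
  }
  class(out) <- "null_auc_result"
  out
}

#' @export
print.null_auc_result <- function(x, ...) {
  cat(sprintf("<null_auc_result> observed r = %.3f, AUC = %.4f",
              x$observed_r, x$auc))
  if (!is.null(x$pair_auc))
    cat(sprintf(", pair AUC = %.4f (%g pairs)", x$pair_auc,
                x$n_pairs_evaluated))
  cat("\n")
  invisible(x)
}

#' Spatial coupling between two parcel maps
#'
#' Correlation across jointly valid parcels, or — when a covariate map is
#' supplied — the standardized coefficient of `map_b` from regressing
#' standardized `map_a` on standardized `map_b` and the covariate (the
#' covariate-controlled coupling used for heritability and PRS-effect
#' maps).
#'
#' @param map_a,map_b [parcel_map()]s on the same parcel universe.
#' @param covariate optional [parcel_map()] (e.g. total SNP heritability).
#' @param method "pearson" or "spearman" (spearman rank-transforms all maps
#'   before regression).
#' @return list: `r` (or `beta`), `stat`, `p`, `n`.
#' @export
spatial_coupling <- function(map_a, map_b, covariate = NULL,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(map_a, "parcel_map"), inherits(map_b, "parcel_map"))
  if (!identical(map_a$parcel_ids, map_b$parcel_ids))
    stop2("parcel maps are on different parcel universes")
  ok <- map_a$mask & map_b$mask
  if (!is.null(covariate)) ok <- ok & covariate$mask
  if (sum(ok) < 4L) stop2("insufficient data: fewer than 4 joint parcels")
  a <- map_a$values[ok]; b <- map_b$values[ok]
  if (is.null(covariate)) {
    ct <- stats::cor.test(a, b, method = method, exact = FALSE)
    return(list(r = unname(ct$estimate), stat = unname(ct$statistic),
                p = ct$p.value, n = sum(ok)))
  }
  cv <- covariate$values[ok]
  if (method == "spearman") {
    a <- rank(a); b <- rank(b); cv <- rank(cv)
  }
  fit <- stats::lm(zscore(a) ~ zscore(b) + zscore(cv))
  sm <- summary(fit)$coefficients
  list(beta = sm[2, 1], stat = sm[2, 3], p = sm[2, 4], n = sum(ok))
}

#' Jointly mask outlier parcels across a family of maps
#'
#' A parcel is masked in every map when its value in any of the listed maps
#' lies more than `k_sd` standard deviations from that map's mean; means
#' and SDs are computed once on the pre-exclusion (currently valid) values.
#' Zero-SD maps exclude nothing.
#'
#' @param map a [parcel_map()].
#' @param companion_maps list of further [parcel_map()]s masked jointly.
#' @param k_sd exclusion threshold in SD units (default 4).
#' @return the updated map, or a list of updated maps when companions were
#'   supplied (first element corresponds to `map`).
#' @export
exclude_outliers <- function(map, companion_maps = list(), k_sd = 4) {
  maps <- c(list(map), companion_maps)
  drop_flag <- rep(FALSE, length(map$parcel_ids))
  for (m in maps) {
    v <- m$values[m$mask]
    mu <- mean(v); s <- stats::sd(v)
    if (!is.finite(s) || s == 0) next
    out <- m$mask & abs(m$values - mu) > k_sd * s
    drop_flag <- drop_flag | out
  }
  maps <- lapply(maps, function(m)
    parcel_map(m$parcel_ids, m$values, m$mask & !drop_flag))
  if (length(companion_maps) == 0L) maps[[1]] else maps
}

#' Per-subregion median expression profile
#'
#' Median normalized expression per subregion for the requested genes, plus
#' the difference (or log-ratio) of the first two genes' medians, for rank
#' comparison against external cell-density tables.
#'
#' @param atlas a normalized [expression_atlas()].
#' @param genes gene ids (first two define the difference).
#' @param grouping per-sample subregion labels (NA = ungrouped, dropped).
#' @param mode "difference" or "ratio" for the two-gene summary.
#' @return data.frame: subregion, n, one median column per gene, and
#'   `delta` (gene1 - gene2 median difference, or ratio).
#' @export
region_median_profile <- function(atlas, genes, grouping,
                                  mode = c("difference", "ratio")) {
  stopifnot(inherits(atlas, "expression_atlas"))
  if (!atlas$normalized) stop2("atlas must be normalized first")
  mode <- match.arg(mode)
  subs <- if (is.factor(grouping)) levels(grouping)
          else unique(grouping[!is.na(grouping)])
  grouping <- as.character(grouping)
  idx <- vapply(genes, function(g) gene_index(atlas, g), 0L)
  rows <- lapply(subs, function(s) {
    i <- which(grouping == s)
    med <- apply(atlas$values[i, idx, drop = FALSE], 2, stats::median)
    c(n = length(i), med)
  })
  empty <- vapply(rows, function(r) r["n"] == 0, TRUE)
  if (any(empty)) warning("dropped subregions with no samples")
  out <- as.data.frame(do.call(rbind, rows[!empty]))
  names(out) <- c("n", genes)
  out <- cbind(subregion = subs[!empty], out)
  out$delta <- if (mode == "difference") out[[genes[1]]] - out[[genes[2]]]
               else out[[genes[1]]] / out[[genes[2]]]
  rownames(out) <- NULL
  out
}

#' Per-stage association between two genes across development
#'
#' Within each developmental stage (each its own normalized atlas), fits a
#' linear regression of normalized `gene_a` on normalized `gene_b`,
#' including donor age as a covariate whenever the stage spans multiple
#' ages.  Stages with fewer than 4 samples are skipped with a warning.
#'
#' @param stage_atlases named list of normalized [expression_atlas()]s with
#'   an `age` column in `sample_meta`.
#' @param gene_a,gene_b gene identifiers.
#' @return data.frame: stage, beta (slope of gene_a on gene_b), se, p, n,
#'   age_adjusted.
#' @export
developmental_association <- function(stage_atlases, gene_a, gene_b) {
  rows <- list()
  for (nm in names(stage_atlases)) {
    atl <- stage_atlases[[nm]]
    if (nrow(atl$values) < 4L) {
      warning("stage '", nm, "' skipped: fewer than 4 samples")
      next
    }
    a <- atl$values[, gene_index(atl, gene_a)]
    b <- atl$values[, gene_index(atl, gene_b)]
    age <- atl$sample_meta$age
    multi_age <- !is.null(age) && length(unique(age)) > 1L
    fit <- if (multi_age) stats::lm(a ~ b + age) else stats::lm(a ~ b)
    sm <- summary(fit)$coefficients
    rows[[nm]] <- data.frame(stage = nm, beta = sm["b", 1],
                             se = sm["b", 2], p = sm["b", 4],
                             n = length(a), age_adjusted = multi_age)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign tissue samples to the nearest parcel centroid
#'
#' Euclidean nearest-neighbour assignment in a shared coordinate frame;
#' samples farther than `max_dist` from every centroid are left
#' unassigned (NA), mirroring the distance-based sample exclusion rule.
#' Ties go to the lowest parcel id.
#'
#' @param sample_coords samples x 3 coordinate matrix (mm).
#' @param parcel_centroids parcels x 3 coordinate matrix with parcel-id
#'   rownames.
#' @param max_dist exclusion radius, default 4 (same length units).
#' @return character vector of parcel ids (NA = unassigned), with the
#'   distances as attribute `"distance"`.
#' @export
map_samples_to_parcels <- function(sample_coords, parcel_centroids,
                                   max_dist = 4) {
  sample_coords <- as.matrix(sample_coords)
  parcel_centroids <- as.matrix(parcel_centroids)
  if (nrow(parcel_centroids) == 0L) stop2("empty parcel centroid set")
  ids <- rownames(parcel_centroids)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(nrow(parcel_centroids)))
  ord <- order(ids)   # lowest parcel id wins ties (which.min takes first)
  cen <- parcel_centroids[ord, , drop = FALSE]
  ids_ord <- ids[ord]
  d2 <- outer(rowSums(sample_coords^2), rep(1, nrow(cen))) +
    outer(rep(1, nrow(sample_coords)), rowSums(cen^2)) -
    2 * tcrossprod(sample_coords, cen)
  d2[d2 < 0] <- 0
  best <- apply(d2, 1, which.min)
  dist <- sqrt(d2[cbind(seq_len(nrow(d2)), best)])
  assign <- ids_ord[best]
  assign[dist > max_dist] <- NA_character_
  attr(assign, "distance") <- dist
  assign
}
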