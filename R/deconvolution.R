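#' Build a cell-type signature matrix from labeled profiles
#'
#' Mean expression profile per cell type, restricted to the union of the
#' top `top_m_markers` marker genes per type.  The marker score of a gene
#' for a type is log2 fold-change (type mean vs rest mean, with a
#' pseudocount) times -log10 of a Wilcoxon rank-sum p-value; ties are
#' broken deterministically by gene id.  Types with fewer than 10 cells
#' are dropped with a warning.
#'
#' @param profiles a [cell_profiles()] object.
#' @param top_m_markers markers retained per type (default 50); clamped to
#'   the gene count with a warning when larger.
#' @param pseudocount added to means before the log fold-change.
#' @return list of class `cell_signature`: `signature` (genes x types mean
#'   matrix), `markers` (per-type character list), `source`, `kappa`
#'   (condition number of the signature).
#' @export
build_signature <- function(profiles, top_m_markers = 50L,
                            pseudocount = 0.5) {
  stopifnot(inherits(profiles, "cell_profiles"))
  tab <- table(profiles$cell_type)
  small <- names(tab)[tab < 10L]
  if (length(small) > 0L)
    warning("dropping cell types with < 10 cells: ",
            paste(small, collapse = ", "))
  types <- setdiff(names(tab), small)
  if (length(types) < 2L) stop2("need at least 2 cell types with >= 10 cells")
  G <- ncol(profiles$values)
  gene_ids <- colnames(profiles$values)
  if (top_m_markers > G) {
    warning("top_m_markers exceeds gene count; using all genes")
    top_m_markers <- G
  }
  sig <- sapply(types, function(ty)
    colMeans(profiles$values[profiles$cell_type == ty, , drop = FALSE]))
  markers <- list()
  for (ty in types) {
    in_ty <- profiles$cell_type == ty
    rest_mean <- colMeans(profiles$values[profiles$cell_type %in%
                                            setdiff(types, ty), ,
                                          drop = FALSE])
    lfc <- log2((sig[, ty] + pseudocount) / (rest_mean + pseudocount))
    pv <- vapply(seq_len(G), function(j)
      stats::wilcox.test(profiles$values[in_ty, j],
                         profiles$values[!in_ty & profiles$cell_type %in%
                                           types, j],
                         exact = FALSE)$p.value, 0)
    score <- lfc * -log10(pmax(pv, .Machine$double.xmin))
    ord <- order(-score, gene_ids)
    markers[[ty]] <- gene_ids[ord[seq_len(top_m_markers)]]
  }
  union_genes <- sort(unique(unlist(markers)))
  sig <- sig[union_genes, , drop = FALSE]
  kap <- kappa(sig, exact = TRUE)
  structure(list(signature = sig, markers = markers,
                 source = profiles$source, kappa = kap),
            class = "cell_signature")
}

#' @export
print.cell_signature <- function(x, ...) {
  cat(sprintf("<cell_signature> %d genes x %d types (kappa = %.1f)\n",
              nrow(x$signature), ncol(x$signature), x$kappa))
  invisible(x)
}

#' @importFrom stats wilcox.test
NULL

#' Estimate cell-type fractions in bulk samples
#'
#' Non-negative least-squares fit of each bulk expression vector on the
#' signature columns over the shared genes, renormalized to the unit
#' simplex.  Bulk samples and signature columns are first scaled to a
#' common total so platform scale differences cancel.  Gene identifiers
#' are matched exactly; ambiguous (duplicated) ids are dropped.
#'
#' @param bulk an [expression_atlas()] on a linear (non-log) scale, or a
#'   samples x genes matrix with gene column names.
#' @param signature a `cell_signature` from [build_signature()].
#' @param min_overlap minimum shared gene count (default 20).
#' @return list of class `fraction_estimate`: `fractions` (samples x
#'   types, rows on the simplex), `residual` (per-sample residual norm).
#' @export
estimate_fractions <- function(bulk, signature, min_overlap = 20L) {
  stopifnot(inherits(signature, "cell_signature"))
  vals <- if (inherits(bulk, "expression_atlas")) bulk$values
          else as.matrix(bulk)
  bulk_genes <- colnames(vals)
  bulk_genes <- bulk_genes[!duplicated(bulk_genes)]
  sig_genes <- rownames(signature$signature)
  shared <- intersect(bulk_genes, sig_genes[!duplicated(sig_genes)])
  if (length(shared) < min_overlap)
    stop2(sprintf("insufficient overlap: %d shared genes < %d",
                  length(shared), min_overlap))
  S <- signature$signature[shared, , drop = FALSE]
  B <- vals[, shared, drop = FALSE]
  # library-size scaling: each bulk sample to a fixed total, the signature
  # by one global factor (a per-column factor would distort the mixture
  # weights and break exact recovery on noiseless mixtures)
  tot <- 1e4
  S <- S * (tot * ncol(S) / max(sum(S), .Machine$double.eps))
  rsum <- rowSums(B); rsum[rsum == 0] <- 1
  B <- sweep(B, 1, rsum / tot, "/")
  K <- ncol(S)
  frac <- matrix(0, nrow(B), K, dimnames = list(rownames(B), colnames(S)))
  resid <- numeric(nrow(B))
  for (i in seq_len(nrow(B))) {
    fit <- pracma::lsqnonneg(S, B[i, ])
    w <- fit$x
    resid[i] <- sqrt(max(fit$resnorm, 0))
    frac[i, ] <- if (sum(w) > 0) w / sum(w) else rep(1 / K, K)
  }
  structure(list(fractions = frac, residual = resid),
            class = "fraction_estimate")
}

#' Parcel maps of cell fractions, with pair ranking against a target map
#'
#' Averages estimated fractions within parcels to one [parcel_map()] per
#' cell type.  When a target map is supplied (e.g. an amplitude map), every
#' ordered pair of cell types is summarized as the z-difference of their
#' fraction maps and ranked by absolute spatial coupling to the target;
#' the top pair is reported.
#'
#' @param fractions a `fraction_estimate`.
#' @param assignment per-sample parcel ids from [map_samples_to_parcels()].
#' @param target_map optional [parcel_map()] to rank cell-type pairs
#'   against.
#' @param parcel_ids optional explicit parcel universe.
#' @return list: `maps` (named list of [parcel_map()]s), and when a target
#'   was given `pair_ranking` (data.frame ordered by |r|) and `top_pair`.
#' @export
fraction_parcel_maps <- function(fractions, assignment, target_map = NULL,
                                 parcel_ids = NULL) {
  stopifnot(inherits(fractions, "fraction_estimate"))
  types <- colnames(fractions$fractions)
  if (is.null(parcel_ids) && !is.null(target_map))
    parcel_ids <- target_map$parcel_ids
  maps <- lapply(types, function(ty)
    aggregate_to_parcels(fractions$fractions[, ty], assignment, parcel_ids))
  names(maps) <- types
  out <- list(maps = maps)
  if (!is.null(target_map)) {
    pairs <- t(utils::combn(types, 2))
    rows <- apply(pairs, 1, function(pr) {
      m1 <- maps[[pr[1]]]; m2 <- maps[[pr[2]]]
      ok <- m1$mask & m2$mask
      dmap <- parcel_map(m1$parcel_ids,
                         ifelse(ok, zs_masked(m1) - zs_masked(m2), 0), ok)
      sc <- spatial_coupling(dmap, target_map)
      data.frame(type_a = pr[1], type_b = pr[2], r = sc$r, p = sc$p,
                 n = sc$n)
    })
    ranking <- do.call(rbind, rows)
    ranking <- ranking[order(-abs(ranking$r)), ]
    rownames(ranking) <- NULL
    out$pair_ranking <- ranking
    out$top_pair <- c(ranking$type_a[1], ranking$type_b[1])
  }
  out
}

# z-score the valid entries of a parcel map, zeros elsewhere
zs_masked <- function(m) {
  v <- rep(0, length(m$values))
  v[m$mask] <- zscore(m$values[m$mask])
  v
}
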