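#' Nominate marker-correlated gene sets by spatial correlation
#'
#' Guilt-by-association: every gene is correlated with the marker across
#' (normalized, cortical) samples, genes are sorted by descending
#' correlation (the marker itself ranks first with correlation 1, ties
#' broken by gene id) and divided into consecutive bins of `top_k` genes.
#'
#' @param atlas a normalized [expression_atlas()].
#' @param marker marker gene id (e.g. the PVALB stand-in).
#' @param top_k bin size (default 500); bin 1 is "the top `top_k`
#'   most-correlated genes".
#' @param n_bins number of bins to label (default 20); genes beyond
#'   `n_bins * top_k` get bin NA.
#' @param method "pearson" or "spearman".
#' @param region region label to restrict samples to (NULL = all).
#' @return data.frame of class `gene_ranking`: gene_id, r, rank, bin.
#' @export
nominate_genesets <- function(atlas, marker, top_k = 500L, n_bins = 20L,
                              method = c("pearson", "spearman"),
                              region = "cortex") {
  stopifnot(inherits(atlas, "expression_atlas"))
  if (!atlas$normalized) stop2("atlas must be normalized first")
  method <- match.arg(method)
  vals <- atlas$values
  if (!is.null(region))
    vals <- vals[atlas$sample_meta$region == region, , drop = FALSE]
  jm <- gene_index(atlas, marker)
  rs <- drop(stats::cor(vals[, jm], vals, method = method))
  rs[jm] <- 1   # self-correlation ranks first even if the marker is constant
  ord <- order(-rs, colnames(vals))
  out <- data.frame(gene_id = colnames(vals)[ord], r = rs[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  out$bin <- ceiling(out$rank / top_k)
  out$bin[out$bin > n_bins] <- NA_integer_
  attr(out, "marker") <- marker
  attr(out, "top_k") <- as.integer(top_k)
  class(out) <- c("gene_ranking", class(out))
  out
}

ranking_genes <- function(ranking, bin = 1L) {
  stopifnot(inherits(ranking, "gene_ranking"))
  ranking$gene_id[!is.na(ranking$bin) & ranking$bin == bin]
}

#' Map a gene set to its SNP partition
#'
#' A SNP belongs to the partition when its position falls inside
#' `[start - window, stop + window]` (1-based inclusive) of any gene in the
#' set, or when it is listed as an eQTL of a set gene.  Genes missing from
#' the annotation are skipped with a warning; genes contributing zero SNPs
#' are counted in a message.
#'
#' @param genes character vector of gene ids, or a `gene_ranking` (its
#'   bin-1 genes are used).
#' @param annotation a [gene_annotation()].
#' @param snps SNP table (`snp_id`, `chrom`, `pos`) or [genotype_set()].
#' @param window flanking window in bp (default 5000).
#' @param eqtl_links optional data.frame `gene_id`, `snp_id` of eQTL links.
#' @param name partition name.
#' @return a [snp_partition()].
#' @export
map_snps_to_partition <- function(genes, annotation, snps, window = 5000L,
                                  eqtl_links = NULL, name = "partition") {
  if (inherits(genes, "gene_ranking")) genes <- ranking_genes(genes, 1L)
  if (inherits(snps, "genotype_set")) snps <- snps$snps
  stopifnot(inherits(annotation, "gene_annotation"))
  missing_ann <- setdiff(genes, annotation$gene_id)
  if (length(missing_ann) > 0L)
    warning(length(missing_ann), " gene(s) missing from annotation, skipped")
  ann <- annotation[annotation$gene_id %in% genes, , drop = FALSE]
  hit_ids <- character(0)
  genes_with_snps <- character(0)
  for (ch in unique(ann$chrom)) {
    a <- ann[ann$chrom == ch, , drop = FALSE]
    s <- snps[snps$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0L) next
    gene_rng <- IRanges::IRanges(start = pmax(a$start - window, 1L),
                                 end = a$stop + window)
    snp_rng <- IRanges::IRanges(start = s$pos, width = 1L)
    ov <- IRanges::findOverlaps(snp_rng, gene_rng)
    hit_ids <- c(hit_ids, s$snp_id[unique(S4Vectors::queryHits(ov))])
    genes_with_snps <- c(genes_with_snps,
                         a$gene_id[unique(S4Vectors::subjectHits(ov))])
  }
  if (!is.null(eqtl_links)) {
    eq <- eqtl_links[eqtl_links$gene_id %in% genes, , drop = FALSE]
    eq <- eq[eq$snp_id %in% snps$snp_id, , drop = FALSE]
    hit_ids <- c(hit_ids, eq$snp_id)
    genes_with_snps <- c(genes_with_snps, eq$gene_id)
  }
  zero <- setdiff(intersect(genes, annotation$gene_id),
                  unique(genes_with_snps))
  if (length(zero) > 0L)
    message(length(zero), " gene(s) contributed no analyzable SNPs")
  snp_partition(name, hit_ids,
                provenance = sprintf("%d genes, +/-%d bp window%s",
                                     length(genes), window,
                                     if (is.null(eqtl_links)) ""
                                     else " + eQTL links"))
}

#' Make named SNP partitions disjoint and add the remainder
#'
#' SNPs appearing in two or more named partitions are removed from all of
#' them (the most conservative reading of non-overlapping sets); the
#' remainder partition collects every genotyped SNP not in any named
#' partition, so the outputs tile the genotyped SNP set exactly.
#'
#' @param partitions list of [snp_partition()]s.
#' @param remainder_source SNP table (`snp_id`) or [genotype_set()]
#'   defining the genotyped universe.
#' @return named list of [snp_partition()]s, the last one `"remainder"`.
#' @export
disjointify <- function(partitions, remainder_source) {
  if (length(partitions) < 1L) stop2("need at least one partition")
  if (inherits(remainder_source, "genotype_set"))
    remainder_source <- remainder_source$snps
  universe <- unique(as.character(remainder_source$snp_id))
  ids <- lapply(partitions, function(p) intersect(p$snp_ids, universe))
  all_ids <- unlist(ids)
  shared <- unique(all_ids[duplicated(all_ids)])
  if (length(shared) > 0L)
    message(length(shared), " SNP(s) shared between named partitions ",
            "removed from all of them")
  out <- lapply(seq_along(partitions), function(k)
    snp_partition(partitions[[k]]$name, setdiff(ids[[k]], shared),
                  provenance = partitions[[k]]$provenance))
  names(out) <- vapply(partitions, `[[`, "", "name")
  # shared SNPs removed from named sets fall back into the remainder
  out$remainder <- snp_partition("remainder",
                                 c(setdiff(universe, unique(all_ids)),
                                   shared))
  out
}

#' Fraction of the genotyped SNPs in a partition
#' @param g_part partition SNP count; @param g_total genotyped SNP count.
#' @return `g_part / g_total`.
#' @export
partition_fraction <- function(g_part, g_total) g_part / g_total

#' Rank expressed as a percentile of a gene universe
#' @param rank 1-based rank; @param n_total universe size.
#' @return `100 * rank / n_total` (percent).
#' @export
rank_percentile <- function(rank, n_total) 100 * rank / n_total

#' Competitive gene-set enrichment across ordered bins
#'
#' Gene statistic: mean chi-square (squared per-SNP z = beta/se) over the
#' SNPs in the gene's window.  Per-bin competitive test: linear regression
#' of gene statistics on the bin-membership indicator with covariates
#' log(SNP count) and gene length, one-sided p for a positive coefficient.
#' Trend: Spearman rank correlation between bin index and bin coefficient
#' (negative when enrichment decays down the ranking).
#'
#' @param sumstats a [summary_stats()] table.
#' @param ranking a `gene_ranking` from [nominate_genesets()].
#' @param annotation a [gene_annotation()].
#' @param window flanking window in bp (default 5000).
#' @return list of class `competitive_enrichment`: `gene_stats`
#'   (data.frame gene_id, bin, stat, n_snps, length), `bins` (data.frame
#'   bin, beta, se, p, n_genes), `trend` (list rho, p).
#' @export
competitive_enrichment <- function(sumstats, ranking, annotation,
                                   window = 5000L) {
  stopifnot(inherits(ranking, "gene_ranking"),
            inherits(annotation, "gene_annotation"))
  binned <- ranking[!is.na(ranking$bin), , drop = FALSE]
  ann <- annotation[match(binned$gene_id, annotation$gene_id), ,
                    drop = FALSE]
  keep <- !is.na(ann$gene_id)
  binned <- binned[keep, , drop = FALSE]
  ann <- ann[keep, , drop = FALSE]
  z2 <- (sumstats$beta / sumstats$se)^2
  stat <- numeric(nrow(binned)); nsnp <- integer(nrow(binned))
  for (ch in unique(ann$chrom)) {
    gi <- which(ann$chrom == ch)
    si <- which(sumstats$chrom == ch)
    if (length(si) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = sumstats$pos[si], width = 1L),
      IRanges::IRanges(start = pmax(ann$start[gi] - window, 1L),
                       end = ann$stop[gi] + window))
    hits <- split(si[S4Vectors::queryHits(ov)],
                  factor(S4Vectors::subjectHits(ov),
                         levels = seq_along(gi)))
    stat[gi] <- vapply(hits, function(ix)
      if (length(ix)) mean(z2[ix]) else NA_real_, 0)
    nsnp[gi] <- vapply(hits, length, 0L)
  }
  gs <- data.frame(gene_id = binned$gene_id, bin = binned$bin,
                   stat = stat, n_snps = nsnp,
                   length = ann$stop - ann$start + 1L)
  gs <- gs[gs$n_snps > 0L & is.finite(gs$stat), , drop = FALSE]
  bins_present <- sort(unique(gs$bin))
  dropped <- setdiff(sort(unique(binned$bin)), bins_present)
  if (length(dropped) > 0L)
    warning("bin(s) without analyzable genes dropped: ",
            paste(dropped, collapse = ", "))
  if (length(bins_present) < 2L)
    stop2("need at least 2 bins with mapped SNPs")
  covlen <- zscore(gs$length)
  covsnp <- zscore(log(gs$n_snps))
  rows <- lapply(bins_present, function(b) {
    memb <- as.numeric(gs$bin == b)
    if (stats::sd(gs$stat) == 0)
      return(data.frame(bin = b, beta = 0, se = NA_real_, p = 1,
                        n_genes = sum(memb)))
    fit <- stats::lm(gs$stat ~ memb + covsnp + covlen)
    sm <- summary(fit)$coefficients
    data.frame(bin = b, beta = sm["memb", 1], se = sm["memb", 2],
               p = stats::pt(sm["memb", 3], df = fit$df.residual,
                             lower.tail = FALSE),
               n_genes = sum(memb))
  })
  bins <- do.call(rbind, rows)
  trend <- if (nrow(bins) >= 3L && stats::sd(bins$beta) > 0) {
    ct <- stats::cor.test(bins$bin, bins$beta, method = "spearman",
                          exact = FALSE)
    list(rho = unname(ct$estimate), p = ct$p.value)
  } else list(rho = NA_real_, p = NA_real_)
  structure(list(gene_stats = gs, bins = bins, trend = trend),
            class = "competitive_enrichment")
}

#' @export
print.competitive_enrichment <- function(x, ...) {
  cat(sprintf("<competitive_enrichment> %d bins, %d genes; trend rho = %.3f (p = %.3g)\n",
              nrow(x$bins), nrow(x$gene_stats), x$trend$rho, x$trend$p))
  invisible(x)
}
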