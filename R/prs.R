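#' Clump-and-threshold polygenic risk scores with an MHC top-SNP rule
#'
#' Matches genotyped SNPs to summary statistics by id and alleles
#' (dosages are flipped when effect/other alleles are swapped;
#' strand-ambiguous A/T and C/G SNPs are dropped), keeps only the single
#' most significant SNP inside the MHC region, optionally performs greedy
#' p-ordered LD clumping, and accumulates
#' `score_i = sum_j beta_j * dosage_ij` over SNPs passing each p-value
#' threshold.
#'
#' @param genotypes a [genotype_set()].
#' @param sumstats a [summary_stats()] table.
#' @param thresholds GWAS p-value thresholds (include 1.0 to use every
#'   post-clump SNP).
#' @param mhc_region optional list `(chrom, start, stop)` of the MHC.
#' @param ld optional SNP x SNP squared-correlation matrix (dimnames are
#'   SNP ids); clumping is a no-op when absent (the LD-free default).
#' @param clump_r2 r-squared exclusion threshold for clumping.
#' @return list of class `prs_result`: `scores` (individuals x
#'   thresholds), `n_snps` (per threshold), `mhc_snp` (retained id or NA),
#'   `n_dropped` (allele-mismatch/ambiguous counts), `snp_ids` (post-clump
#'   SNPs per threshold).
#' @export
compute_prs <- function(genotypes, sumstats, thresholds = c(0.01, 0.05, 1.0),
                        mhc_region = NULL, ld = NULL, clump_r2 = 0.1) {
  stopifnot(inherits(genotypes, "genotype_set"))
  thresholds <- sort(unique(thresholds))
  ss <- as.data.frame(sumstats)
  gt <- genotypes$snps
  m <- match(ss$snp_id, gt$snp_id)
  keep <- !is.na(m)
  ss <- ss[keep, , drop = FALSE]; m <- m[keep]
  if (nrow(ss) == 0L) stop2("zero overlapping SNPs")
  ambig <- function(a, b) (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  is_ambig <- ambig(ss$a1, ss$a2)
  same <- ss$a1 == gt$a1[m] & ss$a2 == gt$a2[m]
  swapped <- ss$a1 == gt$a2[m] & ss$a2 == gt$a1[m]
  usable <- !is_ambig & (same | swapped)
  n_dropped <- c(ambiguous = sum(is_ambig),
                 mismatch = sum(!is_ambig & !same & !swapped))
  ss <- ss[usable, , drop = FALSE]
  m <- m[usable]; swapped <- swapped[usable]
  if (nrow(ss) == 0L) stop2("zero allele-matched SNPs")
  dos <- genotypes$dosage[, m, drop = FALSE]
  if (any(swapped)) dos[, swapped] <- 2 - dos[, swapped, drop = FALSE]
  if (anyNA(dos)) {
    cm <- colMeans(dos, na.rm = TRUE)
    for (j in which(colSums(is.na(dos)) > 0)) dos[is.na(dos[, j]), j] <- cm[j]
  }
  mhc_snp <- NA_character_
  if (!is.null(mhc_region)) {
    in_mhc <- ss$chrom == mhc_region$chrom & ss$pos >= mhc_region$start &
      ss$pos <= mhc_region$stop
    if (any(in_mhc)) {
      top <- which(in_mhc)[which.min(ss$p[in_mhc])]
      mhc_snp <- ss$snp_id[top]
      keep <- !in_mhc; keep[top] <- TRUE
      ss <- ss[keep, , drop = FALSE]; dos <- dos[, keep, drop = FALSE]
    }
  }
  if (!is.null(ld)) {
    ord <- order(ss$p)
    kept <- logical(nrow(ss))
    excluded <- logical(nrow(ss))
    for (i in ord) {
      if (excluded[i]) next
      kept[i] <- TRUE
      r2 <- ld[ss$snp_id[i], ss$snp_id]
      excluded <- excluded | (!kept & r2 >= clump_r2)
    }
    ss <- ss[kept, , drop = FALSE]; dos <- dos[, kept, drop = FALSE]
  }
  scores <- sapply(thresholds, function(th) {
    j <- ss$p <= th
    if (!any(j)) return(rep(0, nrow(dos)))
    drop(dos[, j, drop = FALSE] %*% ss$beta[j])
  })
  colnames(scores) <- sprintf("p%g", thresholds)
  rownames(scores) <- rownames(genotypes$dosage)
  structure(list(scores = scores,
                 n_snps = stats::setNames(vapply(thresholds, function(th)
                   sum(ss$p <= th), 0L), colnames(scores)),
                 mhc_snp = mhc_snp, n_dropped = n_dropped,
                 snp_ids = lapply(stats::setNames(thresholds,
                                                  colnames(scores)),
                                  function(th) ss$snp_id[ss$p <= th])),
            class = "prs_result")
}

#' @export
print.prs_result <- function(x, ...) {
  cat("<prs_result> thresholds:",
      paste(sprintf("%s (%d SNPs)", names(x$n_snps), x$n_snps),
            collapse = ", "), "\n")
  invisible(x)
}

#' Regress phenotypes on polygenic scores with per-threshold FDR
#'
#' For each threshold and each phenotype column, fits an OLS of the
#' phenotype on the standardized score plus covariates and reports the
#' standardized effect.  Benjamini-Hochberg q-values are computed
#' separately within each threshold across the phenotypes tested.
#'
#' @param prs a `prs_result` from [compute_prs()].
#' @param phenotypes a [phenotype_table()] or individuals x phenotypes
#'   matrix (cluster phenotypes or parcel phenotypes), rows aligned to the
#'   scored individuals.
#' @param covariates optional per-individual covariate matrix (e.g. age,
#'   sex, genetic principal components); must be full rank.
#' @return data.frame of class `prs_association`: threshold, phenotype,
#'   beta (per-SD effect), se, p, q.
#' @export
prs_phenotype_association <- function(prs, phenotypes, covariates = NULL) {
  stopifnot(inherits(prs, "prs_result"))
  amp <- if (inherits(phenotypes, "phenotype_table")) phenotypes$amplitude
         else as.matrix(phenotypes)
  if (nrow(amp) != nrow(prs$scores))
    stop2("phenotype rows must align with scored individuals")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    q0 <- qr(cbind(1, covariates))
    if (q0$rank < ncol(covariates) + 1L)
      stop2("covariates are rank deficient; collinear columns: ",
            paste(colnames(covariates)[q0$pivot[q0$rank:ncol(covariates)]],
                  collapse = ", "))
  }
  rows <- list()
  for (th in colnames(prs$scores)) {
    s <- zscore(prs$scores[, th])
    res <- lapply(colnames(amp), function(ph) {
      yy <- zscore(amp[, ph])
      fit <- if (is.null(covariates)) stats::lm(yy ~ s)
             else stats::lm(yy ~ s + covariates)
      sm <- summary(fit)$coefficients
      data.frame(threshold = th, phenotype = ph, beta = sm["s", 1],
                 se = sm["s", 2], p = sm["s", 4])
    })
    block <- do.call(rbind, res)
    block$q <- stats::p.adjust(block$p, method = "BH")
    rows[[th]] <- block
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("prs_association", class(out))
  out
}

#' Assemble per-parcel PRS effects into a parcel map
#'
#' @param assoc a `prs_association` whose phenotypes are parcel ids.
#' @param threshold which threshold column to map (default the loosest).
#' @param parcel_ids optional explicit parcel universe.
#' @return a [parcel_map()] of standardized PRS effects.
#' @export
prs_effect_map <- function(assoc, threshold = NULL, parcel_ids = NULL) {
  stopifnot(inherits(assoc, "prs_association"))
  if (is.null(threshold)) threshold <- utils::tail(unique(assoc$threshold), 1)
  a <- assoc[assoc$threshold == threshold, , drop = FALSE]
  if (is.null(parcel_ids)) parcel_ids <- a$phenotype
  v <- a$beta[match(parcel_ids, a$phenotype)]
  parcel_map(parcel_ids, ifelse(is.na(v), 0, v), !is.na(v))
}
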