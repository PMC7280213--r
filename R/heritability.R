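#' Genetic relatedness matrix from standardized dosages
#'
#' `A_jk = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' with `p_i` the sample allele frequency.  Missing dosages are
#' mean-imputed per SNP.  QC: samples with missingness above `missing_max`
#' and SNPs with minor-allele frequency below `maf_min` are removed;
#' monomorphic SNPs are skipped with a warning.
#'
#' @param genotypes a [genotype_set()].
#' @param snp_subset optional [snp_partition()] (or character vector of
#'   SNP ids) restricting the SNPs used.
#' @param maf_min minor-allele-frequency filter (default 0.05).
#' @param missing_max per-sample missingness filter (default 0.10).
#' @return list of class `grm`: `A` (n x n symmetric), `m` (SNPs used),
#'   `ids` (individual ids), `partition` (name), `n_removed`
#'   (QC counts).
#' @export
compute_grm <- function(genotypes, snp_subset = NULL, maf_min = 0.05,
                        missing_max = 0.10) {
  stopifnot(inherits(genotypes, "genotype_set"))
  dos <- genotypes$dosage
  part_name <- "all"
  if (!is.null(snp_subset)) {
    ids <- if (inherits(snp_subset, "snp_partition")) snp_subset$snp_ids
           else as.character(snp_subset)
    if (inherits(snp_subset, "snp_partition")) part_name <- snp_subset$name
    miss <- setdiff(ids, colnames(dos))
    if (length(miss) > 0L)
      stop2(length(miss), " subset SNPs absent from genotypes")
    dos <- dos[, ids, drop = FALSE]
  }
  sample_miss <- rowMeans(is.na(dos))
  drop_samples <- sample_miss > missing_max
  if (any(drop_samples)) dos <- dos[!drop_samples, , drop = FALSE]
  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  mono <- maf == 0
  if (any(mono)) warning(sum(mono), " monomorphic SNP(s) skipped")
  keep <- !mono & maf >= maf_min
  if (!any(keep)) stop2("empty partition: all SNPs removed by QC")
  dos <- dos[, keep, drop = FALSE]
  Z <- scale_dosages(dos)
  m <- ncol(Z)
  A <- tcrossprod(Z) / m
  structure(list(A = A, m = m, ids = rownames(dos),
                 partition = part_name,
                 n_removed = c(samples = sum(drop_samples),
                               snps = sum(!keep))),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> '%s': %d individuals, %d SNPs (mean diag %.3f)\n",
              x$partition, nrow(x$A), x$m, mean(diag(x$A))))
  invisible(x)
}

#' Multi-partition variance-component estimation by AI-REML
#'
#' Fits `y = X b + sum_k g_k + e`, `g_k ~ N(0, A_k sigma2_k)`,
#' `e ~ N(0, I sigma2_e)` by restricted maximum likelihood using
#' average-information updates with an EM fallback whenever an AI step
#' would leave the feasible region; variance components hitting the
#' boundary are clamped at `1e-6 * Vp`.  Standard errors come from the
#' inverse average-information matrix at convergence.  Each partition is
#' tested against `sigma2_k = 0` with the half-half chi-square mixture
#' Wald test ([wald_mixture_p()]).
#'
#' @param phenotype numeric vector (one value per individual).
#' @param grms a `grm` or list of `grm`s (same individuals, same order).
#' @param covariates optional numeric matrix of covariates (an intercept
#'   is always added); must be full rank.
#' @param tol convergence tolerance on the restricted log-likelihood
#'   change (default 1e-6).
#' @param max_iter maximum iterations (default 100).
#' @param init optional starting values for the K + 1 variance components
#'   (genetic components then residual); defaults to an equal split of the
#'   phenotypic variance.
#' @return list of class `variance_decomposition` with elements `sigma2`
#'   (named, incl. `residual`), `se_sigma2`, `vp`, `h2_part`, `se_h2`,
#'   `h2_total`, `se_h2_total`, `wald_p`, `g_part`, `g_total`, `loglik`,
#'   `converged`, `n_iter`, `boundary`.
#' @export
reml_fit <- function(phenotype, grms, covariates = NULL, tol = 1e-6,
                     max_iter = 100L, init = NULL) {
  if (inherits(grms, "grm")) grms <- list(grms)
  K <- length(grms)
  y <- as.numeric(phenotype)
  n <- length(y)
  for (g in grms)
    if (nrow(g$A) != n) stop2("GRM dimension does not match phenotype")
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop2("covariates are rank deficient; drop collinear columns: ",
          paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
                collapse = ", "))
  p <- ncol(X)
  A <- lapply(grms, `[[`, "A")
  for (g in grms)
    if (mean(abs(g$A - diag(n))) < 1e-12)
      warning("GRM '", g$partition,
              "' is numerically an identity matrix; genetic and residual ",
              "variance are not identifiable")
  vp <- stats::var(y)
  floor_v <- 1e-6 * vp
  theta <- rep(vp / (K + 1), K + 1)   # K genetic components + residual
  if (!is.null(init)) {
    if (length(init) != K + 1 || any(!is.finite(init)))
      stop2("`init` must supply K + 1 finite variance components")
    theta <- pmax(init, floor_v)
  }
  ll_old <- -Inf
  converged <- FALSE
  boundary <- rep(FALSE, K + 1)
  for (iter in seq_len(max_iter)) {
    V <- diag(theta[K + 1], n)
    for (k in seq_len(K)) V <- V + theta[k] * A[[k]]
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) {   # numerical rescue: lift the ridge
      theta[K + 1] <- theta[K + 1] + 1e-4 * vp
      next
    }
    Vi <- chol2inv(R)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    RX <- chol(XtViX)
    P <- Vi - ViX %*% chol2inv(RX) %*% t(ViX)
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(R))) + 2 * sum(log(diag(RX))) +
                    sum(y * Py))
    # score and average information
    q <- vector("list", K + 1)
    trPA <- numeric(K + 1)
    for (k in seq_len(K)) {
      q[[k]] <- A[[k]] %*% Py
      trPA[k] <- sum(P * A[[k]])
    }
    q[[K + 1]] <- Py
    trPA[K + 1] <- sum(diag(P))
    score <- vapply(seq_len(K + 1), function(k)
      -0.5 * (trPA[k] - sum(q[[k]] * Py)), 0)
    Pq <- lapply(q, function(v) P %*% v)
    AI <- matrix(0, K + 1, K + 1)
    for (i in seq_len(K + 1))
      for (j in i:(K + 1))
        AI[i, j] <- AI[j, i] <- 0.5 * sum(q[[i]] * Pq[[j]])
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    proposal <- if (is.null(step) || iter == 1L) NULL else theta + step
    if (is.null(proposal) || any(!is.finite(proposal))) {
      # EM fallback when the AI system is unusable (or as the first,
      # always-feasible step)
      proposal <- vapply(seq_len(K + 1), function(k)
        theta[k] + theta[k]^2 * (sum(q[[k]] * Py) - trPA[k]) / n, 0)
    }
    # components pushed out of the feasible region are boundary hits:
    # clamp them at the floor (an EM fallback would creep toward the
    # boundary so slowly that the likelihood criterion fires early)
    hit <- proposal < floor_v
    proposal[hit] <- floor_v
    boundary <- boundary | hit
    theta <- proposal
  }
  se <- tryCatch(sqrt(pmax(diag(solve(AI)), 0)),
                 error = function(e) rep(NA_real_, K + 1))
  if (!converged)
    warning("REML did not converge in ", max_iter,
            " iterations; returning last iterate")
  vp_hat <- sum(theta)
  part_names <- vapply(grms, `[[`, "", "partition")
  g_part <- vapply(grms, `[[`, 0L, "m")
  names(theta) <- names(se) <- c(part_names, "residual")
  h2_part <- theta[seq_len(K)] / vp_hat
  se_h2 <- se[seq_len(K)] / vp_hat
  wald_p <- vapply(seq_len(K), function(k)
    if (is.na(se[k]) || se[k] <= 0) NA_real_
    else wald_mixture_p(theta[k], se[k]), 0)
  names(wald_p) <- part_names
  # SE of h2_total from the summed AI covariance of the genetic components
  se_h2_total <- tryCatch({
    Cv <- solve(AI)
    sqrt(max(sum(Cv[seq_len(K), seq_len(K)]), 0)) / vp_hat
  }, error = function(e) NA_real_)
  structure(list(sigma2 = theta, se_sigma2 = se, vp = vp_hat,
                 h2_part = h2_part, se_h2 = se_h2,
                 h2_total = sum(h2_part), se_h2_total = se_h2_total,
                 wald_p = wald_p,
                 g_part = stats::setNames(g_part, part_names),
                 g_total = sum(g_part),
                 loglik = ll, converged = converged, n_iter = iter,
                 boundary = stats::setNames(boundary,
                                            c(part_names, "residual"))),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("<variance_decomposition> h2_total = %.3f (%s, %d iter)\n",
              x$h2_total, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  df <- data.frame(sigma2 = x$sigma2,
                   se = x$se_sigma2,
                   h2 = c(x$h2_part, NA),
                   wald_p = c(x$wald_p, NA))
  print(round(df, 4))
  invisible(x)
}

#' Half-half chi-square mixture p-value for a variance component
#'
#' Under the null a variance component sits on the boundary of its
#' parameter space, so the Wald statistic `W = (sigma2 / se)^2` follows a
#' 50:50 mixture of a point mass at zero and a 1-df chi-square:
#' `p = 0.5 * Pr(chisq_1 > W)`, giving `p = 0.5` at `W = 0`.
#'
#' @param sigma2 estimated variance component (>= 0).
#' @param se its standard error (> 0).
#' @return the mixture p-value.
#' @export
wald_mixture_p <- function(sigma2, se) {
  if (!is.finite(se) || se <= 0) stop2("`se` must be a positive number")
  W <- (sigma2 / se)^2
  0.5 * stats::pchisq(W, df = 1, lower.tail = FALSE)
}

#' Partition enrichment statistic
#'
#' `enrich = (h2_part / h2_total) / (g_part / g_total)`: the partition's
#' share of heritable variance divided by its share of SNPs; values above
#' 1 flag enrichment.  The partition's standard error is scaled by the
#' same genome-fraction denominator.
#'
#' @param vd a `variance_decomposition` from [reml_fit()].
#' @param partition partition name.
#' @return list: `enrich`, `se_scaled`.
#' @export
enrichment_statistic <- function(vd, partition) {
  stopifnot(inherits(vd, "variance_decomposition"))
  if (!partition %in% names(vd$h2_part))
    stop2("unknown partition: ", partition)
  res <- enrichment_from_components(vd$h2_part[[partition]], vd$h2_total,
                                    vd$g_part[[partition]], vd$g_total)
  res$se_scaled <- vd$se_h2[[partition]] /
    (vd$g_part[[partition]] / vd$g_total)
  res
}

#' Enrichment from printed variance and SNP-count components
#'
#' @param h2_part partition heritability.
#' @param h2_total total heritability across all partitions (> 0).
#' @param g_part partition SNP count (> 0).
#' @param g_total total genotyped SNP count.
#' @param se_h2_part optional SE of `h2_part`, scaled by the genome
#'   fraction when given.
#' @return list: `enrich` and, when an SE was supplied, `se_scaled`.
#' @export
enrichment_from_components <- function(h2_part, h2_total, g_part, g_total,
                                       se_h2_part = NULL) {
  if (h2_total <= 0) stop2("enrichment undefined: h2_total must be > 0")
  if (g_part <= 0) stop2("g_part must be > 0")
  out <- list(enrich = (h2_part / h2_total) / (g_part / g_total))
  if (!is.null(se_h2_part))
    out$se_scaled <- se_h2_part / (g_part / g_total)
  out
}

#' Parcel-wise partitioned heritability sweep
#'
#' Runs [reml_fit()] for every parcel phenotype against a shared set of
#' partition GRMs, and assembles [parcel_map()]s of per-partition
#' heritability, total heritability and enrichment.  Parcels whose fit
#' fails or does not converge are masked, never aborting the sweep.
#'
#' @param phenotypes a [phenotype_table()] (residualized or raw; the
#'   covariates stored in the table are passed to each fit unless
#'   `covariates` overrides them).
#' @param grms list of `grm`s.
#' @param covariates optional covariate matrix overriding the table's.
#' @param verbose log progress every 10 parcels.
#' @return list: `h2_maps` (named per partition), `h2_total_map`,
#'   `enrich_maps` (named per partition), `table` (per-parcel results),
#'   `fits` (list of `variance_decomposition`s or NULL).
#' @export
parcelwise_partitioned_h2 <- function(phenotypes, grms, covariates = NULL,
                                      verbose = FALSE) {
  stopifnot(inherits(phenotypes, "phenotype_table"))
  if (inherits(grms, "grm")) grms <- list(grms)
  amp <- phenotypes$amplitude
  if (is.null(covariates) && !is.null(phenotypes$covariates))
    covariates <- as.matrix(phenotypes$covariates)
  parcels <- colnames(amp)
  part_names <- vapply(grms, `[[`, "", "partition")
  K <- length(grms)
  h2 <- matrix(NA_real_, length(parcels), K,
               dimnames = list(parcels, part_names))
  h2_tot <- rep(NA_real_, length(parcels))
  enr <- h2
  fits <- vector("list", length(parcels))
  rows <- vector("list", length(parcels))
  warm <- NULL   # GRMs are shared across parcels: warm-start each fit
  for (i in seq_along(parcels)) {
    fit <- tryCatch(
      suppressWarnings(reml_fit(amp[, i], grms, covariates, init = warm)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$converged)
      warm <- fit$sigma2 * stats::var(amp[, min(i + 1L, length(parcels))]) /
        fit$vp
    if (!is.null(fit) && fit$converged) {
      h2[i, ] <- fit$h2_part
      h2_tot[i] <- fit$h2_total
      enr[i, ] <- vapply(part_names, function(pn)
        if (fit$h2_total > 0)
          enrichment_statistic(fit, pn)$enrich else NA_real_, 0)
      rows[[i]] <- data.frame(parcel = parcels[i], partition = part_names,
                              sigma2 = fit$sigma2[seq_len(K)],
                              se = fit$se_sigma2[seq_len(K)],
                              h2_part = fit$h2_part,
                              wald_p = fit$wald_p,
                              h2_total = fit$h2_total,
                              enrich = enr[i, ])
    }
    fits[[i]] <- fit
    if (verbose && i %% 10L == 0L)
      message("parcel sweep: ", i, "/", length(parcels))
  }
  mk_map <- function(v) parcel_map(parcels, ifelse(is.na(v), 0, v), !is.na(v))
  list(h2_maps = stats::setNames(lapply(seq_len(K),
                                        function(k) mk_map(h2[, k])),
                                 part_names),
       h2_total_map = mk_map(h2_tot),
       enrich_maps = stats::setNames(lapply(seq_len(K),
                                            function(k) mk_map(enr[, k])),
                                     part_names),
       table = do.call(rbind, rows),
       fits = fits)
}
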