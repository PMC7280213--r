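#' Resting-state amplitude from parcel time series
#'
#' Amplitude of a parcel's signal is the sample standard deviation
#' (denominator n - 1) of its linearly detrended time series — the
#' desk-scale core of resting-state fluctuation amplitude (RSFA).
#' Constant series get amplitude 0.
#'
#' @param timeseries a parcels x time matrix for one individual, or a list
#'   of such matrices (one per individual).
#' @param detrend remove a per-parcel linear trend first (default TRUE).
#' @return per-parcel amplitude vector, or an individuals x parcels matrix
#'   when a list was given.
#' @export
compute_amplitude <- function(timeseries, detrend = TRUE) {
  one <- function(ts) {
    ts <- as.matrix(ts)
    if (ncol(ts) < 10L) stop2("need at least 10 time points")
    if (detrend) {
      tc <- seq_len(ncol(ts)) - (ncol(ts) + 1) / 2
      ts <- sweep(ts, 1, rowMeans(ts))
      beta <- drop(ts %*% tc) / sum(tc^2)
      ts <- ts - tcrossprod(beta, tc)
    }
    apply(ts, 1, stats::sd)
  }
  if (is.list(timeseries)) {
    out <- t(vapply(timeseries, one, numeric(nrow(as.matrix(
      timeseries[[1]])))))
    rownames(out) <- names(timeseries)
    out
  } else one(timeseries)
}

#' Residualize parcel phenotypes for covariates
#'
#' Per parcel, replaces the amplitude by the OLS residual of amplitude on
#' the covariate design built from `formula_terms` (each term is an R
#' expression over covariate columns, so interactions and polynomial terms
#' like `"I(age^2)"` or `"age:sex"` are available).  Individuals with any
#' missing value in the design are removed first (row-wise deletion) with
#' a message.
#'
#' @param pheno a [phenotype_table()].
#' @param formula_terms character vector of design terms referencing
#'   covariate columns (default: all covariate columns).
#' @return a [phenotype_table()] of residuals; the raw amplitudes are kept
#'   in `raw_amplitude` for cluster-mean phenotypes.
#' @export
residualize <- function(pheno, formula_terms = NULL) {
  stopifnot(inherits(pheno, "phenotype_table"))
  if (is.null(pheno$covariates)) stop2("phenotype table has no covariates")
  if (is.null(formula_terms)) formula_terms <- names(pheno$covariates)
  f <- stats::as.formula(paste("~", paste(formula_terms, collapse = " + ")))
  design <- stats::model.matrix(f, stats::model.frame(
    f, pheno$covariates, na.action = stats::na.pass))
  ok <- stats::complete.cases(design) &
    stats::complete.cases(pheno$amplitude)
  if (!all(ok))
    message(sum(!ok), " individual(s) removed by row-wise deletion")
  design <- design[ok, , drop = FALSE]
  q0 <- qr(design)
  if (q0$rank < ncol(design))
    stop2("collinear covariate design; drop columns: ",
          paste(colnames(design)[q0$pivot[(q0$rank + 1):ncol(design)]],
                collapse = ", "))
  amp <- pheno$amplitude[ok, , drop = FALSE]
  res <- as.matrix(stats::lm.fit(design, amp)$residuals)
  dimnames(res) <- dimnames(amp)
  phenotype_table(res, pheno$covariates[ok, , drop = FALSE],
                  raw_amplitude = (pheno$raw_amplitude %||%
                                     pheno$amplitude)[ok, , drop = FALSE],
                  clusters = pheno$clusters)
}

#' Cluster parcels by between-subject covariation
#'
#' Agglomerative (Ward linkage, Euclidean distance) clustering of parcels
#' using each parcel's across-individual residualized profile, cut at `k`
#' clusters.  The cluster phenotype returned to heritability analyses is
#' the mean of the *raw* (non-residualized) amplitudes over member
#' parcels.
#'
#' @param residualized a residualized [phenotype_table()].
#' @param k number of clusters (default 7).
#' @return list: `labels` (named integer per parcel), `cluster_phenotypes`
#'   (individuals x k matrix of raw-amplitude means), `hclust` (the tree).
#' @export
cluster_parcels <- function(residualized, k = 7L) {
  stopifnot(inherits(residualized, "phenotype_table"))
  amp <- residualized$amplitude
  if (k > ncol(amp)) stop2("k exceeds the number of parcels")
  d <- stats::dist(t(amp))
  hc <- stats::hclust(d, method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  raw <- residualized$raw_amplitude %||% amp
  cl_pheno <- sapply(sort(unique(labels)), function(cl)
    rowMeans(raw[, labels == cl, drop = FALSE]))
  colnames(cl_pheno) <- sprintf("cluster%d", sort(unique(labels)))
  list(labels = labels, cluster_phenotypes = cl_pheno, hclust = hc)
}
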