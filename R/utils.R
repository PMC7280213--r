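#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test lm pchisq pt pnorm qnorm rnorm rbinom runif
#'   sd var median coef residuals quantile p.adjust hclust cutree dist
#'   complete.cases setNames rlnorm
#' @importFrom utils read.delim write.table head tail combn
NULL

# z-score a vector with sample SD (denominator n - 1); constant input -> zeros
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop2(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

# deterministic child seed for a named generator component, so that adding a
# generator never perturbs the draws of another
child_seed <- function(seed, component) {
  offsets <- c(atlas = 11L, cells = 29L, geno = 47L, pheno = 83L,
               sumstats = 131L, covar = 173L, timeseries = 199L)
  off <- offsets[[component]]
  (as.integer(seed) * 2L + off) %% .Machine$integer.max
}
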