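# Small fixture builders shared across test files.

# a tiny raw atlas from an explicit matrix (one region unless given)
tiny_atlas <- function(values, region = "cortex", donor = "D1",
                       gene_meta = NULL, age = NULL) {
  values <- as.matrix(values)
  meta <- data.frame(sample_id = sprintf("S%02d", seq_len(nrow(values))),
                     donor = donor, region = region,
                     stringsAsFactors = FALSE)
  if (!is.null(age)) meta$age <- age
  expression_atlas(values, meta, gene_meta = gene_meta)
}

# normalized atlas wrapper
tiny_atlas_norm <- function(values, ...) {
  suppressWarnings(normalize_within_region(tiny_atlas(values, ...)))
}

# small fast sim config for unit tests; overrides replace the fast defaults
fast_config <- function(...) {
  args <- utils::modifyList(
    list(n_parcels = 12L, n_samples_per_parcel = 4L, n_genes = 80L,
         n_cell_types = 3L, n_cells_per_type = 20L,
         n_markers_per_type = 5L,
         n_individuals = 150L, n_snps = 300L),
    list(...))
  do.call(sim_config, args)
}

# genotype set from an explicit dosage matrix
tiny_genotypes <- function(dosage, pos = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  genotype_set(dosage,
               data.frame(snp_id = sprintf("rs%03d", seq_len(m)),
                          chrom = "1",
                          pos = pos %||% (seq_len(m) * 1000L),
                          a1 = "A", a2 = "G", stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force BH step-up used as the independent multiple-testing oracle
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}
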