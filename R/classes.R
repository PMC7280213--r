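#' Spatial expression atlas
#'
#' Container for a samples-by-genes expression matrix with per-sample
#' annotations (donor, region, 3-D coordinates in mm, optional age) and
#' optional per-gene metadata (e.g. an Entrez-style numeric identifier used
#' by probe filtering).
#'
#' @param values numeric matrix, samples in rows, genes in columns; column
#'   names are the gene (or probe) identifiers.
#' @param sample_meta data.frame with one row per sample; must contain
#'   `sample_id`, `donor` and `region`; coordinate columns `x`, `y`, `z`
#'   and `age` are optional.
#' @param gene_meta optional data.frame with one row per column of `values`;
#'   must contain `gene_id`, may carry `entrez` and `probe_id`.
#' @param normalized logical; TRUE once [normalize_within_region()] has run.
#' @return an object of class `expression_atlas`.
#' @export
expression_atlas <- function(values, sample_meta, gene_meta = NULL,
                             normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop2("`values` must have gene column names")
  if (nrow(values) != nrow(sample_meta))
    stop2("`sample_meta` must have one row per sample")
  need <- c("sample_id", "donor", "region")
  if (!all(need %in% names(sample_meta)))
    stop2("`sample_meta` needs columns: ", paste(need, collapse = ", "))
  if (is.null(gene_meta)) {
    gene_meta <- data.frame(gene_id = colnames(values),
                            stringsAsFactors = FALSE)
  }
  if (nrow(gene_meta) != ncol(values))
    stop2("`gene_meta` must have one row per gene column")
  rownames(values) <- sample_meta$sample_id
  structure(list(values = values,
                 sample_meta = as.data.frame(sample_meta),
                 gene_meta = as.data.frame(gene_meta),
                 normalized = isTRUE(normalized)),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat(sprintf("<expression_atlas> %d samples x %d genes (%s), regions: %s\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw",
              paste(unique(x$sample_meta$region), collapse = ", ")))
  invisible(x)
}

gene_index <- function(atlas, gene) {
  j <- match(gene, colnames(atlas$values))
  if (is.na(j)) stop2("gene not found in atlas: ", gene)
  j
}

#' Per-parcel scalar map
#'
#' One scalar per parcel of a fixed parcellation, with a validity mask.
#' The common currency for spatial coupling between expression, cell
#' fraction, heritability and PRS-effect maps.
#'
#' @param parcel_ids ordered parcel identifiers.
#' @param values numeric, one value per parcel.
#' @param mask logical validity flags; masked parcels are ignored by all
#'   downstream spatial statistics.
#' @return object of class `parcel_map`.
#' @export
parcel_map <- function(parcel_ids, values, mask = NULL) {
  if (length(values) != length(parcel_ids))
    stop2("`values` and `parcel_ids` lengths differ")
  if (is.null(mask)) mask <- is.finite(values)
  if (length(mask) != length(parcel_ids)) stop2("`mask` length mismatch")
  if (any(!is.finite(values[mask])))
    stop2("parcel_map values must be finite wherever mask is TRUE")
  structure(list(parcel_ids = parcel_ids,
                 values = as.numeric(values),
                 mask = as.logical(mask)),
            class = "parcel_map")
}

#' @export
print.parcel_map <- function(x, ...) {
  cat(sprintf("<parcel_map> %d parcels (%d valid)\n",
              length(x$parcel_ids), sum(x$mask)))
  invisible(x)
}

#' Genotype dosage set
#'
#' Individuals-by-SNPs additive dosage matrix (0/1/2 copies of the A1
#' allele, NA for missing) together with the SNP position/allele table.
#'
#' @param dosage numeric matrix, individuals in rows (rownames are
#'   individual ids), SNPs in columns (colnames are SNP ids).
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`, `a1`, `a2`.
#' @return object of class `genotype_set`.
#' @export
genotype_set <- function(dosage, snps) {
  dosage <- as.matrix(dosage)
  need <- c("snp_id", "chrom", "pos", "a1", "a2")
  if (!all(need %in% names(snps)))
    stop2("`snps` needs columns: ", paste(need, collapse = ", "))
  if (nrow(snps) != ncol(dosage))
    stop2("`snps` must have one row per dosage column")
  if (any(snps$a1 == snps$a2)) stop2("alleles a1 and a2 must differ")
  colnames(dosage) <- snps$snp_id
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("ind%04d", seq_len(nrow(dosage)))
  structure(list(dosage = dosage, snps = as.data.frame(snps)),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("<genotype_set> %d individuals x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Named SNP partition
#'
#' A named set of SNP identifiers (e.g. the SNPs mapped to a
#' marker-correlated gene set), used to build partition-specific GRMs.
#'
#' @param name partition label.
#' @param snp_ids character vector of SNP ids (deduplicated).
#' @param provenance free-text note on how the set was derived.
#' @return object of class `snp_partition` with `g_part = length(snp_ids)`.
#' @export
snp_partition <- function(name, snp_ids, provenance = "") {
  snp_ids <- unique(as.character(snp_ids))
  structure(list(name = name, snp_ids = snp_ids,
                 provenance = provenance, g_part = length(snp_ids)),
            class = "snp_partition")
}

#' @export
print.snp_partition <- function(x, ...) {
  cat(sprintf("<snp_partition> '%s': %d SNPs\n", x$name, x$g_part))
  invisible(x)
}

#' Labeled single-cell expression profiles
#'
#' @param values cells-by-genes expression matrix (linear scale).
#' @param cell_type character/factor of type labels, one per cell.
#' @param source free-text provenance label (e.g. "frontal", "visual").
#' @return object of class `cell_profiles`.
#' @export
cell_profiles <- function(values, cell_type, source = "synthetic") {
  values <- as.matrix(values)
  if (nrow(values) != length(cell_type))
    stop2("`cell_type` must have one label per cell row")
  structure(list(values = values, cell_type = as.character(cell_type),
                 source = source),
            class = "cell_profiles")
}

#' Per-individual parcel phenotype table
#'
#' Individuals-by-parcels amplitude phenotypes plus a covariate matrix and
#' optional parcel cluster labels.
#'
#' @param amplitude numeric matrix individuals x parcels (rownames are
#'   individual ids, colnames parcel ids).
#' @param covariates data.frame of per-individual covariates, aligned rows.
#' @param raw_amplitude optional un-residualized copy kept for cluster-mean
#'   phenotypes.
#' @param clusters optional integer parcel-cluster labels (one per parcel).
#' @return object of class `phenotype_table`.
#' @export
phenotype_table <- function(amplitude, covariates = NULL,
                            raw_amplitude = NULL, clusters = NULL) {
  amplitude <- as.matrix(amplitude)
  if (is.null(colnames(amplitude)))
    colnames(amplitude) <- sprintf("parcel%03d", seq_len(ncol(amplitude)))
  if (is.null(rownames(amplitude)))
    rownames(amplitude) <- sprintf("ind%04d", seq_len(nrow(amplitude)))
  if (!is.null(covariates) && nrow(covariates) != nrow(amplitude))
    stop2("`covariates` rows must match individuals")
  structure(list(amplitude = amplitude,
                 covariates = if (is.null(covariates)) NULL
                              else as.data.frame(covariates),
                 raw_amplitude = raw_amplitude,
                 clusters = clusters),
            class = "phenotype_table")
}

#' GWAS summary statistics table
#'
#' Validates and classes a per-SNP association table with columns
#' `snp_id`, `chrom`, `pos`, `a1` (effect allele), `a2`, `beta`, `se`, `p`.
#'
#' @param df data.frame with the columns above.
#' @return the data.frame with class `summary_stats` prepended.
#' @export
summary_stats <- function(df) {
  need <- c("snp_id", "chrom", "pos", "a1", "a2", "beta", "se", "p")
  if (!all(need %in% names(df)))
    stop2("summary stats need columns: ", paste(need, collapse = ", "))
  if (any(df$p <= 0 | df$p > 1)) stop2("p-values must lie in (0, 1]")
  if (any(df$a1 == df$a2)) stop2("effect and other allele must differ")
  class(df) <- c("summary_stats", class(df))
  df
}

#' Gene annotation table (1-based inclusive coordinates)
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `start`, `stop`
#'   (1-based inclusive) and optionally `strand` (unused).
#' @return validated data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "chrom", "start", "stop")
  if (!all(need %in% names(df)))
    stop2("annotation needs columns: ", paste(need, collapse = ", "))
  if (any(df$start > df$stop)) stop2("annotation start must be <= stop")
  if (any(df$start < 1)) stop2("coordinates are 1-based; start must be >= 1")
  class(df) <- c("gene_annotation", class(df))
  df
}
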