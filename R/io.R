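# Plain-text TSV is the interchange dialect throughout: tab-delimited,
# UTF-8, '#'-prefixed comment lines allowed before the header.

read_tsv0 <- function(path, ...) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv0 <- function(df, path, row.names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row.names, col.names = TRUE)
  invisible(path)
}

#' Write / read an expression atlas as TSV
#'
#' The expression matrix is written genes x samples with a header row of
#' sample ids; sample metadata (donor, region, coordinates) goes to a
#' side file `<path>.samples.tsv`, gene metadata (when present) to
#' `<path>.genes.tsv`.
#'
#' @param atlas an [expression_atlas()].
#' @param path expression TSV path.
#' @return `path`, invisibly (writer); an [expression_atlas()] (reader).
#' @export
write_expression_tsv <- function(atlas, path) {
  stopifnot(inherits(atlas, "expression_atlas"))
  m <- t(atlas$values)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write_tsv0(df, path)
  write_tsv0(atlas$sample_meta, paste0(path, ".samples.tsv"))
  write_tsv0(atlas$gene_meta, paste0(path, ".genes.tsv"))
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv0(path)
  vals <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(vals) <- df$gene_id
  meta <- read_tsv0(paste0(path, ".samples.tsv"))
  gm_path <- paste0(path, ".genes.tsv")
  gm <- if (file.exists(gm_path)) read_tsv0(gm_path) else NULL
  expression_atlas(vals, meta, gm)
}

#' Write / read a genotype set as dosage TSV
#'
#' Dosages are written individuals-in-columns with SNP annotation columns
#' first (`snp_id chrom pos a1 a2`), so the file round-trips the full
#' [genotype_set()].
#'
#' @param genotypes a [genotype_set()]; @param path output path.
#' @return `path` invisibly (writer); a [genotype_set()] (reader).
#' @export
write_dosage_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_set"))
  df <- cbind(genotypes$snps, as.data.frame(t(genotypes$dosage)))
  write_tsv0(df, path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read_tsv0(path)
  ann <- df[, c("snp_id", "chrom", "pos", "a1", "a2")]
  dos <- t(as.matrix(df[, setdiff(names(df), names(ann)), drop = FALSE]))
  colnames(dos) <- ann$snp_id
  ann$chrom <- as.character(ann$chrom)
  genotype_set(dos, ann)
}

#' Write a genotype set as a minimal VCF (GT fields)
#'
#' Dosage 0/1/2 of the a1 allele maps to GT `0/0`, `0/1`, `1/1` with a1 as
#' ALT; missing dosages become `./.`.
#'
#' @param genotypes a [genotype_set()]; @param path output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_set"))
  s <- genotypes$snps
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  dos <- t(genotypes$dosage)
  gt <- matrix(gt_code[as.character(dos)], nrow(dos), ncol(dos))
  gt[is.na(gt)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##source=gradh2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(genotypes$dosage)),
                    collapse = "\t"))
  body <- paste(s$chrom, s$pos, s$snp_id, s$a2, s$a1, ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF with GT genotypes into a genotype set
#'
#' Counts ALT-allele copies per genotype; requires the `vcfR` package.
#'
#' @param path a `.vcf` file.
#' @return a [genotype_set()] (a1 = ALT allele).
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop2("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    out <- rep(NA_integer_, length(g))
    ok <- !is.na(g) & g != "./." & g != ".|."
    out[ok] <- vapply(strsplit(g[ok], "[/|]"),
                      function(a) sum(a == "1"), 0L)
    out
  }
  dos <- t(matrix(count_alt(as.vector(gt)), nrow(gt), ncol(gt)))
  colnames(dos) <- rownames(gt)   # SNP ids
  rownames(dos) <- colnames(gt)   # individual ids
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  genotype_set(dos, data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                               pos = as.integer(fix$POS),
                               a1 = fix$ALT, a2 = fix$REF,
                               stringsAsFactors = FALSE))
}

#' Write / read GWAS summary statistics TSV
#'
#' Columns `SNP CHR BP A1 A2 BETA SE P` (A1 = effect allele).
#'
#' @param sumstats a [summary_stats()] table; @param path output path.
#' @return `path` invisibly (writer); a [summary_stats()] (reader).
#' @export
write_sumstats_tsv <- function(sumstats, path) {
  df <- data.frame(SNP = sumstats$snp_id, CHR = sumstats$chrom,
                   BP = sumstats$pos, A1 = sumstats$a1, A2 = sumstats$a2,
                   BETA = sumstats$beta, SE = sumstats$se, P = sumstats$p)
  write_tsv0(df, path)
}

#' @rdname write_sumstats_tsv
#' @export
read_sumstats_tsv <- function(path) {
  df <- read_tsv0(path)
  summary_stats(data.frame(snp_id = df$SNP, chrom = as.character(df$CHR),
                           pos = df$BP, a1 = df$A1, a2 = df$A2,
                           beta = df$BETA, se = df$SE, p = df$P,
                           stringsAsFactors = FALSE))
}

#' Write / read gene annotation as BED
#'
#' Internal coordinates are 1-based inclusive; the BED writer converts to
#' 0-based half-open at the file boundary and the reader converts back.
#'
#' @param annotation a [gene_annotation()]; @param path output `.bed` path.
#' @return `path` invisibly (writer); a [gene_annotation()] (reader).
#' @export
write_annotation_bed <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  df <- data.frame(chrom = annotation$chrom,
                   start = annotation$start - 1L,   # 0-based half-open
                   stop = annotation$stop,
                   gene_id = annotation$gene_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("chrom", "start", "stop", "gene_id"),
                          stringsAsFactors = FALSE)
  gene_annotation(data.frame(gene_id = df$gene_id,
                             chrom = as.character(df$chrom),
                             start = df$start + 1L, stop = df$stop,
                             stringsAsFactors = FALSE))
}

#' Write / read a parcel map TSV (`parcel_id value mask`)
#'
#' @param map a [parcel_map()]; @param path output path.
#' @return `path` invisibly (writer); a [parcel_map()] (reader).
#' @export
write_parcel_map_tsv <- function(map, path) {
  stopifnot(inherits(map, "parcel_map"))
  write_tsv0(data.frame(parcel_id = map$parcel_ids, value = map$values,
                        mask = as.integer(map$mask)), path)
}

#' @rdname write_parcel_map_tsv
#' @export
read_parcel_map_tsv <- function(path) {
  df <- read_tsv0(path)
  parcel_map(as.character(df$parcel_id), df$value, df$mask == 1L)
}

#' Write / read a phenotype/covariate table TSV
#'
#' Phenotypes and covariates share one wide table keyed by
#' `individual_id`; covariate columns are prefixed `cov_`.
#'
#' @param pheno a [phenotype_table()]; @param path output path.
#' @return `path` invisibly (writer); a [phenotype_table()] (reader).
#' @export
write_phenotype_tsv <- function(pheno, path) {
  stopifnot(inherits(pheno, "phenotype_table"))
  df <- data.frame(individual_id = rownames(pheno$amplitude),
                   pheno$amplitude, check.names = FALSE)
  if (!is.null(pheno$covariates)) {
    cv <- pheno$covariates
    names(cv) <- paste0("cov_", names(cv))
    df <- cbind(df, cv)
  }
  write_tsv0(df, path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  df <- read_tsv0(path)
  cov_cols <- grep("^cov_", names(df), value = TRUE)
  amp <- as.matrix(df[, setdiff(names(df), c("individual_id", cov_cols)),
                      drop = FALSE])
  rownames(amp) <- df$individual_id
  cov <- if (length(cov_cols) > 0) {
    cv <- df[, cov_cols, drop = FALSE]
    names(cv) <- sub("^cov_", "", names(cv))
    rownames(cv) <- df$individual_id
    cv
  } else NULL
  phenotype_table(amp, cov)
}
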