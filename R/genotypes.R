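#' Genotype matrices
#'
#' A `GenotypeMatrix` stores complete biallelic SNP calls coded 0/1/2 as
#' counts of the ALTERNATIVE allele, together with per-locus alternative
#' allele frequencies estimated in-sample, `p_i = colSums(calls) / (2n)`.
#' Missing calls are an error at construction: imputation is assumed to have
#' happened upstream and is out of scope here.
#'
#' @param calls integer matrix, individuals in rows, loci in columns, values
#'   in \{0, 1, 2\}; `dimnames` supply individual and locus ids (generated
#'   when absent).
#' @param maf_threshold minor allele frequency threshold; loci with
#'   `min(p, 1 - p) < maf_threshold` are dropped. Default 0 (keep all).
#' @return An object of class `GenotypeMatrix`: a list with elements
#'   `calls` (integer matrix), `ids`, `loci`, `p` (alternative allele
#'   frequencies), `maf_threshold`, `n_dropped`.
#' @examples
#' g <- genotype_matrix(rbind(a = c(0L, 1L), b = c(2L, 1L)))
#' g$p
#' @export
genotype_matrix <- function(calls, maf_threshold = 0) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("locus", seq_len(ncol(calls)))
  if (anyNA(calls)) {
    w <- which(is.na(calls), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing genotype call for individual '%s' at locus '%s'",
                 rownames(calls)[w[1L]], colnames(calls)[w[2L]]))
  }
  if (!all(calls %in% c(0, 1, 2)))
    stop("genotype calls must be 0, 1 or 2 (alternative-allele counts)")
  storage.mode(calls) <- "integer"
  p <- colSums(calls) / (2 * nrow(calls))
  keep <- pmin(p, 1 - p) >= maf_threshold
  out <- list(calls = calls[, keep, drop = FALSE],
              ids = rownames(calls),
              loci = colnames(calls)[keep],
              p = p[keep],
              maf_threshold = maf_threshold,
              n_dropped = sum(!keep))
  class(out) <- "GenotypeMatrix"
  out
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf(
    "GenotypeMatrix: %d individuals x %d loci (MAF >= %g; %d loci dropped)\n",
    length(x$ids), length(x$loci), x$maf_threshold, x$n_dropped))
  invisible(x)
}

#' Read a genotype matrix from CSV, PLINK-RAW or VCF
#'
#' CSV: individuals in rows (first column = id), loci in columns, complete
#' 0/1/2 alternative-allele counts. PLINK-RAW (`--recode A`): the six
#' leading columns `FID IID PAT MAT SEX PHENOTYPE` are dropped and the SNP
#' dosages kept. VCF: the GT field of biallelic records is converted to
#' alternative-allele counts; non-biallelic records are skipped with a
#' warning (requires the `vcfR` package).
#'
#' @param path input file path.
#' @param format one of `"csv"`, `"plink_raw"`, `"vcf"`.
#' @param maf_threshold minor allele frequency filter, applied after
#'   loading (default 0.01, the conventional post-imputation cutoff).
#' @return A [genotype_matrix()] object. The number of retained loci is
#'   reported with a message.
#' @export
read_genotypes <- function(path, format = c("csv", "plink_raw", "vcf"),
                           maf_threshold = 0.01) {
  format <- match.arg(format)
  calls <- switch(format,
    csv = {
      dt <- data.table::fread(path, header = TRUE)
      m <- as.matrix(dt[, -1L, drop = FALSE])
      rownames(m) <- as.character(dt[[1L]])
      m
    },
    plink_raw = {
      dt <- data.table::fread(path, header = TRUE)
      lead <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                        names(dt))
      m <- as.matrix(dt[, setdiff(names(dt), lead), with = FALSE])
      rownames(m) <- as.character(dt[["IID"]])
      m
    },
    vcf = .read_vcf_calls(path)
  )
  g <- genotype_matrix(calls, maf_threshold = maf_threshold)
  message(sprintf("read_genotypes: retained %d of %d loci (MAF >= %g)",
                  length(g$loci), length(g$loci) + g$n_dropped,
                  maf_threshold))
  g
}

.read_vcf_calls <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- vcfR::is.biallelic(v)
  if (any(!biallelic)) {
    warning(sprintf("skipped %d non-biallelic VCF record(s)", sum(!biallelic)))
    v <- v[biallelic, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # rows = loci, cols = individuals; count ALT alleles in e.g. "0/1", "1|1"
  counts <- apply(gt, c(1, 2), function(s) {
    if (is.na(s)) return(NA_integer_)
    sum(as.integer(strsplit(s, "[/|]")[[1L]]) > 0L)
  })
  t(counts)
}

#' Read an adjusted-phenotype table
#'
#' One row per individual; first column is the individual id, remaining
#' numeric columns are environmentally adjusted trait values (missing
#' allowed per trait).
#'
#' @param path CSV file path.
#' @return A `data.frame` with character `id` first column and one numeric
#'   column per trait.
#' @export
read_phenotypes <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  out <- as.data.frame(dt)
  names(out)[1L] <- "id"
  out$id <- as.character(out$id)
  if (anyDuplicated(out$id))
    stop("duplicate individual id(s) in phenotype table")
  out
}
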