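#' Canonical mutation identity key
#'
#' Mutation identity throughout the package is the exact
#' chromosome/position/ref/alt tuple; gene annotation is deliberately
#' ignored so that identity is robust to annotation version drift.
#'
#' @param x a variant `data.frame` with columns `chrom, pos, ref, alt`, or
#'   `NULL` when the four vectors are given directly.
#' @param chrom,pos,ref,alt vectors used when `x` is `NULL`.
#' @return character vector of keys, `"chrom:pos:ref>alt"`.
#' @examples
#' mutationKey(chrom = "7", pos = 140453136, ref = "A", alt = "T")
#' @export
mutationKey <- function(x = NULL, chrom = NULL, pos = NULL, ref = NULL,
                        alt = NULL) {
  if (!is.null(x)) {
    stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(x)))
    chrom <- x$chrom; pos <- x$pos; ref <- x$ref; alt <- x$alt
  }
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

#' Expected variant allele frequency under the CCF model
#'
#' For a mutation present at cancer cell fraction `ccf` with multiplicity
#' `m` on a segment of tumour total copy number `cnt` in a sample of the
#' given purity, the expected fraction of mutant reads is
#' `ccf * purity * m / (purity * cnt + (1 - purity) * cnn)`.
#'
#' @param ccf cancer cell fraction in `[0, 1]`.
#' @param purity tumour purity in (0, 1].
#' @param m mutation multiplicity (mutant copies per carrying cell).
#' @param cnt tumour total copy number at the locus.
#' @param cnn normal copy number at the locus (2, or 1 on male sex
#'   chromosomes).
#' @return expected VAF (vectorised).
#' @examples
#' expectedVaf(1, 0.5, 1, 2, 2)  # 0.25
#' @export
expectedVaf <- function(ccf, purity, m = 1, cnt = 2, cnn = 2) {
  ccf * purity * m / (purity * cnt + (1 - purity) * cnn)
}

## substitution class helper: TRUE for C>T or G>A single-base changes
.isCtGa <- function(ref, alt) {
  (ref == "C" & alt == "T") | (ref == "G" & alt == "A")
}

## empty variant table with the canonical column set
.emptyVariantTable <- function() {
  data.frame(
    patient = character(), sample = character(), timepoint = character(),
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), t_ref_count = integer(), t_alt_count = integer(),
    vaf = numeric(), variant_classification = character(),
    gene_symbol = character(), filter_flags = character(),
    stringsAsFactors = FALSE
  )
}

## write a TSV the way every exporter in the package does
.writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
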