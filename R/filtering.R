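#' Read a somatic variant table (MAF-style TSV or VCF)
#'
#' MAF-style input is a tab-separated table with one row per called
#' variant and at least the columns `patient, sample, timepoint, chrom,
#' pos, ref, alt, t_ref_count, t_alt_count`; `vaf` is recomputed from the
#' read counts whenever both are present. VCF 4.x input is parsed with
#' VariantAnnotation; multi-allelic records are split into per-allele
#' calls and the VAF is derived from the `AD` genotype field. Coordinates
#' are 1-based inclusive throughout.
#'
#' @param path file path.
#' @param format `"maf_tsv"` or `"vcf"`.
#' @param patient,sample,timepoint metadata attached to VCF calls (VCFs do
#'   not carry the cohort bookkeeping a MAF does). Ignored for MAF input.
#' @return a variant `data.frame` in the canonical long format (see
#'   [variantCalls()]); zero rows (with a warning) for an empty file.
#' @export
readVariantTable <- function(path, format = c("maf_tsv", "vcf"),
                             patient = NA_character_,
                             sample = NA_character_,
                             timepoint = "baseline") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "maf_tsv") .readMafTsv(path) else
    .readVcfCalls(path, patient, sample, timepoint)
}

.readMafTsv <- function(path) {
  tab <- tryCatch(
    read.delim(path, stringsAsFactors = FALSE, colClasses = NA),
    error = function(e) NULL
  )
  if (is.null(tab) || nrow(tab) == 0L) {
    warning("empty variant table: ", path)
    return(.emptyVariantTable())
  }
  required <- c("patient", "sample", "timepoint", "chrom", "pos", "ref",
                "alt", "t_ref_count", "t_alt_count")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("required column(s) missing from ", path, ": ",
         paste(miss, collapse = ", "))
  if (!"variant_classification" %in% names(tab))
    tab$variant_classification <- "other"
  if (!"gene_symbol" %in% names(tab)) tab$gene_symbol <- NA_character_
  if (!"filter_flags" %in% names(tab)) tab$filter_flags <- ""
  tab$filter_flags[is.na(tab$filter_flags)] <- ""

  tab$pos <- suppressWarnings(as.integer(tab$pos))
  tab$t_ref_count <- suppressWarnings(as.integer(tab$t_ref_count))
  tab$t_alt_count <- suppressWarnings(as.integer(tab$t_alt_count))
  bad <- is.na(tab$pos) | tab$pos < 1L |
    is.na(tab$t_ref_count) | tab$t_ref_count < 0L |
    is.na(tab$t_alt_count) | tab$t_alt_count < 0L |
    (tab$t_ref_count + tab$t_alt_count) == 0L
  if (any(bad)) {
    ## +1 for the header line so numbers refer to the file as seen on disk
    warning("dropping ", sum(bad), " malformed row(s) in ", path,
            " (file line ", paste(which(bad) + 1L, collapse = ", "), ")")
    tab <- tab[!bad, , drop = FALSE]
  }
  tab$vaf <- tab$t_alt_count / (tab$t_ref_count + tab$t_alt_count)
  tab$chrom <- as.character(tab$chrom)
  rownames(tab) <- NULL
  tab[, .VARIANT_COLUMNS]
}

.readVcfCalls <- function(path, patient, sample, timepoint) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (nrow(vcf) == 0L) {
    warning("empty VCF: ", path)
    return(.emptyVariantTable())
  }
  vcf <- VariantAnnotation::expand(vcf)   # split multi-allelic records
  rr <- SummarizedExperiment::rowRanges(vcf)
  geno <- VariantAnnotation::geno(vcf)
  if (!"AD" %in% names(geno))
    stop("required genotype field missing from ", path, ": AD")
  ad <- geno$AD
  ## after expand(), AD (Number=R) is an n x samples x 2 array or a matrix
  ## of 2-vectors; normalise to ref/alt count vectors for the first sample
  if (is.array(ad) && length(dim(ad)) == 3L) {
    refC <- ad[, 1L, 1L]
    altC <- ad[, 1L, 2L]
  } else {
    refC <- vapply(ad[, 1L], function(v) as.integer(v[1L]), integer(1))
    altC <- vapply(ad[, 1L], function(v) as.integer(v[2L]), integer(1))
  }
  sampleId <- if (!is.na(sample)) sample else
    colnames(vcf)[1] %||% NA_character_
  flt <- as.character(rr$FILTER)
  flt[is.na(flt) | flt %in% c("PASS", ".")] <- ""
  out <- data.frame(
    patient = patient, sample = sampleId, timepoint = timepoint,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    t_ref_count = as.integer(refC), t_alt_count = as.integer(altC),
    vaf = as.integer(altC) / (as.integer(refC) + as.integer(altC)),
    variant_classification = "other", gene_symbol = NA_character_,
    filter_flags = flt, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a

#' Dual FFPE artefact filtering (signature stage, then VAF stage)
#'
#' Applies the two-stage filter used to clean FFPE-derived somatic calls.
#' Stage 1 (signature filter) removes C>T/G>A substitutions that look like
#' formalin deamination artefacts: calls carrying an artefact filter flag
#' when the input has caller flags, or — for flag-less inputs — calls with
#' VAF below `signatureSubThreshold`. Stage 2 removes every variant with
#' VAF strictly below `vafThreshold` (default 10%; a VAF exactly at the
#' threshold is retained). The stage order is fixed so the report
#' attributes each removal unambiguously.
#'
#' @param variants a variant `data.frame` (canonical columns).
#' @param vafThreshold VAF below which variants are removed (strict `<`).
#' @param signatureFilter logical; apply the signature stage.
#' @param signatureSubThreshold VAF used by the signature stage when the
#'   input carries no caller filter flags.
#' @param artifactFlag regular expression matched against `filter_flags`
#'   to identify caller-flagged artefacts.
#' @return list with `variants` (retained rows) and `report`
#'   (a [FilterReport-class]).
#' @examples
#' cohort <- simulateCohort(simulationConfig(n_patients = 2, seed = 5))
#' out <- applyArtifactFilters(variantCalls(cohort))
#' out$report
#' @export
applyArtifactFilters <- function(variants, vafThreshold = 0.10,
                                 signatureFilter = TRUE,
                                 signatureSubThreshold = 0.05,
                                 artifactFlag = "artifact|ffpe|orientation") {
  if (!is.finite(vafThreshold) || vafThreshold < 0 || vafThreshold > 1)
    stop("vafThreshold must lie in [0, 1]")
  stopifnot(all(c("ref", "alt", "vaf", "filter_flags") %in% names(variants)))
  nInput <- nrow(variants)

  removeSig <- rep(FALSE, nInput)
  if (signatureFilter && nInput) {
    sigClass <- .isCtGa(variants$ref, variants$alt)
    hasFlags <- any(nzchar(variants$filter_flags), na.rm = TRUE)
    removeSig <- if (hasFlags) {
      sigClass & grepl(artifactFlag, variants$filter_flags,
                       ignore.case = TRUE)
    } else {
      sigClass & variants$vaf < signatureSubThreshold
    }
  }
  afterSig <- variants[!removeSig, , drop = FALSE]
  removeVaf <- afterSig$vaf < vafThreshold
  retained <- afterSig[!removeVaf, , drop = FALSE]
  rownames(retained) <- NULL
  report <- new("FilterReport",
    n_input = as.integer(nInput),
    n_removed_signature = as.integer(sum(removeSig)),
    n_removed_vaf = as.integer(sum(removeVaf)),
    n_retained = as.integer(nrow(retained))
  )
  list(variants = retained, report = report)
}
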