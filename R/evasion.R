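#' Read an immune-evasion gene catalogue
#'
#' Parses the one-gene-per-line TSV catalogue (columns `gene_symbol`,
#' `provenance`). The packaged default seeds the antigen presentation
#' machinery and CRISPR-screen CD8-killing-resistance hits recurrently
#' altered in immunosuppressed recurrent tumours (HLA class II genes,
#' CIITA, B2M, TAP1, IRF2/IRF8, JAK2, PRKCD, among others); it is an
#' editable starting point, not a frozen re-derivation of the
#' version-dependent KEGG and screen gene lists.
#'
#' @param path TSV path; defaults to the packaged catalogue.
#' @return an [EvasionCatalog-class].
#' @examples
#' readEvasionCatalog()
#' @export
readEvasionCatalog <- function(path = system.file("extdata",
                                                  "evasion_catalog.tsv",
                                                  package = "ClonalDivergence")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_symbol", "provenance") %in% names(tab)))
    stop("catalogue must have columns gene_symbol and provenance")
  genes <- toupper(trimws(tab$gene_symbol))
  keep <- !duplicated(genes)
  new("EvasionCatalog", genes = genes[keep],
      provenance = tab$provenance[keep])
}

#' Is a variant classification loss-of-function?
#'
#' Missense calls are excluded because their functional impact is hard to
#' interpret; the loss-of-function set is nonsense, frameshift insertions
#' and deletions, other (in-frame) indels, and nonstop mutations.
#' Classifications outside the known vocabulary return `FALSE` with a
#' warning.
#'
#' @param classification character vector of variant classifications.
#' @return logical vector.
#' @examples
#' isLof(c("nonsense", "missense", "silent", "frameshift_del"))
#' @export
isLof <- function(classification) {
  unknown <- !classification %in% .VARIANT_CLASSES
  if (any(unknown))
    warning("unknown variant classification(s) treated as non-LoF: ",
            paste(unique(classification[unknown]), collapse = ", "))
  classification %in% .LOF_CLASSES
}

#' Flag samples carrying an immune-evasion LoF mutation
#'
#' A sample (or patient, when `by = "patient"` aggregates baseline and
#' recurrence) is flagged when it carries at least one loss-of-function
#' mutation in a catalogue gene.
#'
#' @param variants variant `data.frame` or [ClonalCohort-class].
#' @param catalog an [EvasionCatalog-class] (defaults to the packaged
#'   catalogue).
#' @param by `"sample"` (default) or `"patient"`.
#' @return `data.frame` with the unit id, `has_evasion_lof`, `n_support`,
#'   and `supporting` (comma-separated `gene:mutation` entries; empty when
#'   unflagged).
#' @export
flagSamples <- function(variants, catalog = readEvasionCatalog(),
                        by = c("sample", "patient")) {
  by <- match.arg(by)
  if (is(variants, "ClonalCohort")) variants <- variantCalls(variants)
  stopifnot(is(catalog, "EvasionCatalog"))
  unit <- variants[[by]]
  support <- isLof(variants$variant_classification) &
    toupper(variants$gene_symbol) %in% catalogGenes(catalog)
  keys <- paste0(variants$gene_symbol, ":", mutationKey(variants))
  out <- lapply(split(seq_along(unit), unit), function(idx) {
    hit <- idx[support[idx]]
    data.frame(
      id = unit[idx[1]],
      has_evasion_lof = length(hit) > 0L,
      n_support = length(unique(keys[hit])),
      supporting = paste(unique(keys[hit]), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  names(out)[1] <- by
  rownames(out) <- NULL
  out
}
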