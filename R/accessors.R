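#' @describeIn ClonalCohort-class per-sample variant table.
#' @export
setMethod("variantCalls", "ClonalCohort", function(x) x@variants)

#' @describeIn ClonalCohort-class copy-number segment table.
#' @export
setMethod("segmentTable", "ClonalCohort", function(x) x@segments)

#' @describeIn ClonalCohort-class sample metadata (purity, timepoint, group).
#' @export
setMethod("sampleMeta", "ClonalCohort", function(x) x@samples)

#' @describeIn ClonalCohort-class simulation truth labels (empty for real data).
#' @export
setMethod("truthLabels", "ClonalCohort", function(x) x@truth)

setMethod("show", "ClonalCohort", function(object) {
  s <- object@samples
  cat("ClonalCohort:", length(unique(s$patient)), "patients,",
      nrow(s), "samples,", nrow(object@variants), "variant calls\n")
  if (nrow(s)) {
    tp <- table(s$timepoint)
    cat("  timepoints:", paste(sprintf("%s (%d)", names(tp), tp),
                               collapse = ", "), "\n")
  }
  cat("  truth labels:", if (nrow(object@truth)) "present" else "absent", "\n")
  invisible(NULL)
})

#' @describeIn FilterReport-class retained / input (errors when no input).
#' @export
setMethod("retentionRate", "FilterReport", function(report) {
  if (report@n_input == 0L)
    stop("retention rate undefined: report has zero input variants")
  report@n_retained / report@n_input
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:", object@n_input, "in;",
      object@n_removed_signature, "removed (artefact signature);",
      object@n_removed_vaf, "removed (VAF);",
      object@n_retained, "retained")
  if (object@n_input > 0L)
    cat(sprintf(" (%.1f%%)", 100 * retentionRate(object)))
  cat("\n")
  invisible(NULL)
})

#' Coerce a FilterReport to a one-row data.frame
#'
#' @param report a [FilterReport-class].
#' @return data.frame with the four counts and the retention rate.
#' @export
filterReportTable <- function(report) {
  stopifnot(is(report, "FilterReport"))
  data.frame(
    n_input = report@n_input,
    n_removed_signature = report@n_removed_signature,
    n_removed_vaf = report@n_removed_vaf,
    n_retained = report@n_retained,
    retention_rate = if (report@n_input > 0L) retentionRate(report) else NA_real_
  )
}

#' @describeIn CloneSet-class number of clusters in the selected model.
#' @export
setMethod("nClusters", "CloneSet", function(x) nrow(x@clusters))

#' @describeIn CloneSet-class cluster table (id, CCF centre, mutation fraction).
#' @export
setMethod("cloneClusters", "CloneSet", function(x) x@clusters)

#' @describeIn CloneSet-class per-mutation cluster index.
#' @export
setMethod("cloneAssignments", "CloneSet", function(x) x@assignments)

setMethod("show", "CloneSet", function(object) {
  cat("CloneSet:", nrow(object@clusters), "clones,",
      length(object@assignments), "mutations (BIC",
      format(object@bic, digits = 6), ")\n")
  print(object@clusters, row.names = FALSE)
  invisible(NULL)
})

#' @describeIn CloneSet-class clonality score from clone centres weighted by
#'   mutation fractions.
#' @param x a `CloneSet`.
#' @export
setMethod("clonalityScore", "CloneSet", function(x, ...) {
  cl <- x@clusters
  if (!nrow(cl)) stop("clonality score undefined for an empty CloneSet")
  sum(cl$mutation_fraction * cl$ccf_centre)
})

#' @describeIn OverlapNull-class the overlap percentages.
#' @export
setMethod("nullValues", "OverlapNull", function(x) x@values)

setMethod("show", "OverlapNull", function(object) {
  cat("OverlapNull:", object@n_pairs, "ordered pairs",
      if (object@includes_self_pairs) "(self-pairs included)" else
        "(self-pairs excluded)", "\n")
  if (length(object@values))
    cat(sprintf("  overlap %%: median %.2f, mean %.2f, max %.2f\n",
                median(object@values), mean(object@values),
                max(object@values)))
  invisible(NULL)
})

#' @describeIn EvasionCatalog-class the gene symbols.
#' @export
setMethod("catalogGenes", "EvasionCatalog", function(x) x@genes)

setMethod("show", "EvasionCatalog", function(object) {
  cat("EvasionCatalog:", length(object@genes), "genes (",
      sum(object@provenance != "crispr_screen_hit"), "antigen presentation,",
      sum(object@provenance != "antigen_presentation_kegg"), "screen hits )\n")
  cat(" ", paste(head(object@genes, 12), collapse = ", "),
      if (length(object@genes) > 12) "...", "\n")
  invisible(NULL)
})
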