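#' Frequency-weighted clonality score
#'
#' The clonality score of a tumour sample is the sum over clones of the
#' clone's CCF centre weighted by the fraction of mutations it contains,
#' which is algebraically the mutation-level mean CCF. It ranges from 0
#' (entirely subclonal, all CCFs near zero) to 1 (entirely clonal, all
#' mutations at CCF 1).
#'
#' @param x a numeric vector of per-mutation CCFs, or a [CloneSet-class].
#' @param ... unused.
#' @return a single number in `[0, 1]`.
#' @examples
#' clonalityScore(c(1, 1, 1))          # fully clonal -> 1
#' clonalityScore(c(0.2, 0.2, 0.8, 0.8)) # -> 0.5
#' @export
setGeneric("clonalityScore", function(x, ...) standardGeneric("clonalityScore"))

#' Retention rate of a variant filter
#'
#' @param report a [FilterReport-class].
#' @return fraction of input variants retained, in `[0, 1]`.
#' @export
setGeneric("retentionRate", function(report) standardGeneric("retentionRate"))

#' @rdname ClonalCohort-class
#' @param object,x a `ClonalCohort`.
#' @export
setGeneric("variantCalls", function(x) standardGeneric("variantCalls"))

#' @rdname ClonalCohort-class
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @rdname ClonalCohort-class
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @rdname ClonalCohort-class
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' @rdname CloneSet-class
#' @param x a `CloneSet`.
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname CloneSet-class
#' @export
setGeneric("cloneClusters", function(x) standardGeneric("cloneClusters"))

#' @rdname CloneSet-class
#' @export
setGeneric("cloneAssignments", function(x) standardGeneric("cloneAssignments"))

#' @rdname OverlapNull-class
#' @param x an `OverlapNull`.
#' @export
setGeneric("nullValues", function(x) standardGeneric("nullValues"))

#' @rdname EvasionCatalog-class
#' @param x an `EvasionCatalog`.
#' @export
setGeneric("catalogGenes", function(x) standardGeneric("catalogGenes"))
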