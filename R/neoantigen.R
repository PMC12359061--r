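#' Tier mutations by predicted MHC class I binding affinity
#'
#' Conventional affinity tiers: half-maximal inhibitory concentration
#' (IC50) of at most 100 nM marks a strong binder, at most 500 nM a weak
#' binder, anything larger a non-binder; both boundaries are inclusive and
#' configurable. Records without an affinity are tiered `unknown` (e.g.
#' samples whose HLA type could not be called). A separate externally
#' supplied stringent-consensus flag (`stringent_pass`) is carried through
#' untouched when present.
#'
#' @param annotations `data.frame` with `affinity_nm` (positive or `NA`)
#'   and optionally `stringent_pass`.
#' @param strongNm,weakNm tier boundaries in nM (inclusive).
#' @return the input with a `tier` column
#'   (`strong`/`weak`/`non_binder`/`unknown`).
#' @examples
#' classifyBinders(data.frame(affinity_nm = c(100, 500, 501, NA)))$tier
#' @export
classifyBinders <- function(annotations, strongNm = 100, weakNm = 500) {
  stopifnot("affinity_nm" %in% names(annotations))
  aff <- annotations$affinity_nm
  bad <- !is.na(aff) & aff <= 0
  if (any(bad))
    stop("non-positive binding affinity in ", sum(bad),
         " record(s); affinities are IC50 values in nM and must be > 0")
  tier <- rep("unknown", length(aff))
  tier[!is.na(aff) & aff <= strongNm] <- "strong"
  tier[!is.na(aff) & aff > strongNm & aff <= weakNm] <- "weak"
  tier[!is.na(aff) & aff > weakNm] <- "non_binder"
  annotations$tier <- tier
  annotations
}

#' Per-mutation delta-CCF between recurrence and baseline
#'
#' For each mutation in the union of the two timepoints' profiles, the
#' delta is the recurrence CCF minus the baseline CCF, with a mutation
#' absent from a timepoint contributing CCF 0 there (it is carried by no
#' tumour cell at that timepoint). An intersection mode restricted to
#' mutations observed at both timepoints is provided for sensitivity
#' analysis, since private mutations dominate these cohorts.
#'
#' @param baseline,recurrence `data.frame`s with `mutation_id` and `ccf`
#'   (e.g. slices of [ccfTable()] output).
#' @param mode `"union"` (default) or `"intersection"`.
#' @return `data.frame` with `mutation_id, ccf_baseline, ccf_recurrence,
#'   delta`.
#' @export
computeDeltaCcf <- function(baseline, recurrence,
                            mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(all(c("mutation_id", "ccf") %in% names(baseline)),
            all(c("mutation_id", "ccf") %in% names(recurrence)))
  b <- setNames(baseline$ccf, baseline$mutation_id)
  r <- setNames(recurrence$ccf, recurrence$mutation_id)
  keys <- if (mode == "union") union(names(b), names(r)) else
    intersect(names(b), names(r))
  cb <- ifelse(keys %in% names(b), b[keys], 0)
  cr <- ifelse(keys %in% names(r), r[keys], 0)
  out <- data.frame(
    mutation_id = keys,
    ccf_baseline = unname(cb),
    ccf_recurrence = unname(cr),
    delta = unname(cr - cb),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Compare delta-CCF dynamics of neoantigens against control mutations
#'
#' Tests whether candidate neoantigens show different CCF dynamics
#' between timepoints than the remaining mutations — the genomic footprint
#' immunoediting would leave. Per patient, the two groups' delta-CCF
#' distributions are compared by a tie-corrected rank-sum test; the pooled
#' analysis stratifies by patient by centring each patient's deltas on
#' their within-patient mean before pooling (configurable to Fisher's
#' combination of the per-patient p-values instead).
#'
#' @param records `data.frame` with `patient, delta, is_neoantigen`
#'   (logical).
#' @param pooled `"centred"` (default: rank-sum on patient-centred pooled
#'   deltas) or `"fisher"` (Fisher's combined probability over per-patient
#'   tests).
#' @param alternative location of the neoantigen group relative to the
#'   controls; `"less"` tests for neoantigen depletion.
#' @return list with `per_patient` (`data.frame` of per-patient p-values
#'   and median differences; patients lacking either group are skipped
#'   with a warning), `pooled_p`, `pooled_median_difference` (neoantigen
#'   minus control, pooled centred deltas), `method`, `alternative`.
#' @export
compareDynamics <- function(records, pooled = c("centred", "fisher"),
                            alternative = "two.sided") {
  pooled <- match.arg(pooled)
  stopifnot(all(c("patient", "delta", "is_neoantigen") %in% names(records)))
  records <- records[!is.na(records$delta), , drop = FALSE]
  perPatient <- lapply(split(records, records$patient), function(d) {
    a <- d$delta[d$is_neoantigen]
    b <- d$delta[!d$is_neoantigen]
    if (!length(a) || !length(b)) return(NULL)
    res <- rankSumTest(a, b, alternative = alternative)
    data.frame(
      patient = d$patient[1],
      n_neoantigen = length(a), n_control = length(b),
      median_difference = median(a) - median(b),
      p.value = res$p.value,
      stringsAsFactors = FALSE
    )
  })
  skipped <- names(perPatient)[vapply(perPatient, is.null, logical(1))]
  if (length(skipped))
    warning("patient(s) without both groups skipped: ",
            paste(skipped, collapse = ", "))
  perPatient <- do.call(rbind,
                        perPatient[!vapply(perPatient, is.null, logical(1))])
  if (is.null(perPatient) || !nrow(perPatient))
    stop("no patient has both neoantigen and control mutations")
  rownames(perPatient) <- NULL

  ## pooled, stratified by patient
  centred <- unlist(lapply(split(records$delta, records$patient),
                           function(x) x - mean(x)), use.names = FALSE)
  isNeo <- unlist(lapply(split(records$is_neoantigen, records$patient),
                         identity), use.names = FALSE)
  if (pooled == "centred") {
    a <- centred[isNeo]; b <- centred[!isNeo]
    if (!length(a) || !length(b))
      stop("pooled comparison requires both groups")
    pooledTest <- rankSumTest(a, b, alternative = alternative)
    pooledP <- pooledTest$p.value
    method <- "rank-sum on pooled within-patient-centred deltas"
  } else {
    chi <- -2 * sum(log(pmax(perPatient$p.value, 1e-300)))
    pooledP <- stats::pchisq(chi, df = 2 * nrow(perPatient),
                             lower.tail = FALSE)
    method <- "Fisher's combined probability over per-patient rank-sum tests"
  }
  list(
    per_patient = perPatient,
    pooled_p = pooledP,
    pooled_median_difference = median(centred[isNeo]) - median(centred[!isNeo]),
    method = method,
    alternative = alternative
  )
}

#' Extract neoantigen annotations from a simulated cohort's truth
#'
#' @param cohort a simulated [ClonalCohort-class].
#' @return `data.frame` with `patient, mutation_id, affinity_nm,
#'   stringent_pass` for non-artefact mutations.
#' @export
neoantigenAnnotations <- function(cohort) {
  stopifnot(is(cohort, "ClonalCohort"))
  truth <- truthLabels(cohort)
  if (!nrow(truth)) stop("cohort has no truth labels")
  truth <- truth[!truth$is_artifact, , drop = FALSE]
  out <- truth[, c("patient", "mutation_id", "affinity_nm",
                   "stringent_pass")]
  rownames(out) <- NULL
  out
}
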