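#' @import methods
#' @importFrom stats median quantile rbeta rbinom rnorm rpois runif setNames
#'   fisher.test pchisq plogis qlogis wilcox.test dbinom
#' @importFrom utils read.delim write.table packageVersion head
#' @importFrom tools md5sum
NULL

## Column contract for the long variant table used throughout the package.
.VARIANT_COLUMNS <- c(
  "patient", "sample", "timepoint", "chrom", "pos", "ref", "alt",
  "t_ref_count", "t_alt_count", "vaf", "variant_classification",
  "gene_symbol", "filter_flags"
)

.VARIANT_CLASSES <- c(
  "missense", "nonsense", "frameshift_ins", "frameshift_del",
  "in_frame_indel", "nonstop", "silent", "splice", "other"
)

.TIMEPOINTS <- c("baseline", "recurrence", "recurrence2", "recurrence3")

#' Simulation configuration for a paired baseline/recurrence tumour cohort
#'
#' Holds every tunable of the synthetic-cohort generator. Sequencing depth
#' defaults follow the study design the generator emulates: 100x mean
#' coverage for tumour samples and 50x for the matched normal. All other
#' defaults describe a cohort with marked baseline/recurrence divergence
#' (most mutations private), moderate purity, and low-VAF formalin (FFPE)
#' deamination artefacts.
#'
#' @slot n_patients number of patients, each with a baseline and a
#'   recurrence sample.
#' @slot clones_per_sample_range integer range (min, max) for the number of
#'   clones detectable in one sample, truncal clone included.
#' @slot trunk_shared_fraction fraction in `[0, 1]` of a sample's mutations
#'   shared between the two timepoints.
#' @slot shared_subclone_fraction fraction in `[0, 1]` of the shared
#'   mutations assigned to a persistent shared subclone rather than the
#'   truncal (CCF 1) clone; 0 makes every shared mutation truncal, so a
#'   `trunk_shared_fraction = 1` cohort is fully clonal.
#' @slot mutations_per_sample_range integer range for somatic mutation count
#'   per sample (before artefact injection).
#' @slot purity_range tumour purity range, fractions in (0, 1].
#' @slot tumour_depth_mean mean sequencing depth of tumour samples (reads).
#' @slot normal_depth_mean mean sequencing depth of the matched normal.
#' @slot ffpe_artifact_rate expected number of FFPE artefact calls injected
#'   per sample (Poisson rate; 0 disables injection).
#' @slot artifact_vaf_beta_params shape1/shape2 of the Beta distribution the
#'   artefact variant allele frequencies are drawn from.
#' @slot neoantigen_fraction fraction of non-silent mutations labelled as
#'   (stringent) candidate neoantigens.
#' @slot selection_coefficient_s immunoediting selection coefficient in
#'   `[0, 1]`: recurrence CCFs of neoantigen mutations are multiplied by
#'   `1 - s` before read sampling. `s = 0` is the immune-escape null.
#' @slot detection_limit VAF below which detected variants are censored from
#'   the emitted tables (0 disables censoring; private mutations are truly
#'   absent at the other timepoint regardless).
#' @slot cn_profile `"mixed"` for a realistic aneuploid genome or
#'   `"diploid"` to force CNt = 2, multiplicity 1 everywhere.
#' @slot seed integer seed; identical configurations with identical seeds
#'   produce byte-identical cohorts.
#' @seealso [simulationConfig()], [simulateCohort()]
#' @export
setClass("SimulationConfig",
  representation(
    n_patients = "integer",
    clones_per_sample_range = "integer",
    trunk_shared_fraction = "numeric",
    shared_subclone_fraction = "numeric",
    mutations_per_sample_range = "integer",
    purity_range = "numeric",
    tumour_depth_mean = "numeric",
    normal_depth_mean = "numeric",
    ffpe_artifact_rate = "numeric",
    artifact_vaf_beta_params = "numeric",
    neoantigen_fraction = "numeric",
    selection_coefficient_s = "numeric",
    detection_limit = "numeric",
    cn_profile = "character",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  chkFrac <- function(x, name) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      sprintf("%s must lie in [0, 1]", name) else character()
  }
  if (length(object@n_patients) != 1L || object@n_patients < 1L)
    msg <- c(msg, "n_patients must be a single positive integer")
  for (s in c("clones_per_sample_range", "mutations_per_sample_range")) {
    r <- slot(object, s)
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1L)
      msg <- c(msg, sprintf("%s must be a non-empty positive interval", s))
  }
  if (length(object@clones_per_sample_range) == 2L &&
      object@clones_per_sample_range[1] < 2L)
    msg <- c(msg, "clones_per_sample_range minimum is 2 (truncal + 1)")
  msg <- c(msg, chkFrac(object@trunk_shared_fraction, "trunk_shared_fraction"))
  msg <- c(msg, chkFrac(object@shared_subclone_fraction,
                        "shared_subclone_fraction"))
  msg <- c(msg, chkFrac(object@neoantigen_fraction, "neoantigen_fraction"))
  msg <- c(msg, chkFrac(object@selection_coefficient_s, "selection_coefficient_s"))
  msg <- c(msg, chkFrac(object@detection_limit, "detection_limit"))
  if (length(object@purity_range) != 2L || any(object@purity_range <= 0) ||
      any(object@purity_range > 1) ||
      object@purity_range[1] > object@purity_range[2])
    msg <- c(msg, "purity_range must be a non-empty interval within (0, 1]")
  if (object@tumour_depth_mean <= 0 || object@normal_depth_mean <= 0)
    msg <- c(msg, "depth means must be positive")
  if (object@ffpe_artifact_rate < 0)
    msg <- c(msg, "ffpe_artifact_rate must be non-negative")
  if (length(object@artifact_vaf_beta_params) != 2L ||
      any(object@artifact_vaf_beta_params <= 0))
    msg <- c(msg, "artifact_vaf_beta_params must be two positive shapes")
  if (!object@cn_profile %in% c("mixed", "diploid"))
    msg <- c(msg, "cn_profile must be 'mixed' or 'diploid'")
  if (length(msg)) msg else TRUE
})

#' Construct a [SimulationConfig-class]
#'
#' @param n_patients,clones_per_sample_range,trunk_shared_fraction,shared_subclone_fraction,mutations_per_sample_range,purity_range,tumour_depth_mean,normal_depth_mean,ffpe_artifact_rate,artifact_vaf_beta_params,neoantigen_fraction,selection_coefficient_s,detection_limit,cn_profile,seed
#'   see the slot documentation in [SimulationConfig-class].
#' @return a validated `SimulationConfig` object.
#' @examples
#' cfg <- simulationConfig(n_patients = 4, seed = 7)
#' cfg
#' @export
simulationConfig <- function(n_patients = 15L,
                             clones_per_sample_range = c(3L, 6L),
                             trunk_shared_fraction = 0.2,
                             shared_subclone_fraction = 0.3,
                             mutations_per_sample_range = c(80L, 150L),
                             purity_range = c(0.4, 0.9),
                             tumour_depth_mean = 100,
                             normal_depth_mean = 50,
                             ffpe_artifact_rate = 10,
                             artifact_vaf_beta_params = c(1.5, 30),
                             neoantigen_fraction = 0.15,
                             selection_coefficient_s = 0,
                             detection_limit = 0,
                             cn_profile = "mixed",
                             seed = 1L) {
  new("SimulationConfig",
    n_patients = as.integer(n_patients),
    clones_per_sample_range = as.integer(clones_per_sample_range),
    trunk_shared_fraction = as.numeric(trunk_shared_fraction),
    shared_subclone_fraction = as.numeric(shared_subclone_fraction),
    mutations_per_sample_range = as.integer(mutations_per_sample_range),
    purity_range = as.numeric(purity_range),
    tumour_depth_mean = as.numeric(tumour_depth_mean),
    normal_depth_mean = as.numeric(normal_depth_mean),
    ffpe_artifact_rate = as.numeric(ffpe_artifact_rate),
    artifact_vaf_beta_params = as.numeric(artifact_vaf_beta_params),
    neoantigen_fraction = as.numeric(neoantigen_fraction),
    selection_coefficient_s = as.numeric(selection_coefficient_s),
    detection_limit = as.numeric(detection_limit),
    cn_profile = as.character(cn_profile),
    seed = as.integer(seed)
  )
}

#' Paired-tumour cohort container
#'
#' Bundles the per-sample somatic variant table, allele-specific copy-number
#' segments, sample metadata (purity, ploidy, timepoint, immune group) and —
#' for simulated cohorts — per-mutation truth labels (true CCFs by
#' timepoint, clone membership, artefact / neoantigen / evasion-LoF flags).
#'
#' @slot variants `data.frame` with one row per called variant per sample
#'   (MAF-like long format; see [variantCalls()]).
#' @slot segments `data.frame` of copy-number segments with columns
#'   `sample, chrom, start, end, major_cn, minor_cn, normal_cn`.
#' @slot samples `data.frame` of sample metadata with columns
#'   `patient, sample, timepoint, purity, ploidy, immune_group`.
#' @slot truth `data.frame` of simulation truth (zero rows for real data).
#' @slot config the [SimulationConfig-class] used, or `NULL`.
#' @export
setClass("ClonalCohort",
  representation(
    variants = "data.frame",
    segments = "data.frame",
    samples = "data.frame",
    truth = "data.frame",
    config = "ANY"
  )
)

setValidity("ClonalCohort", function(object) {
  msg <- character()
  miss <- setdiff(.VARIANT_COLUMNS, names(object@variants))
  if (length(miss))
    msg <- c(msg, paste("variants table missing columns:",
                        paste(miss, collapse = ", ")))
  if (nrow(object@variants)) {
    if (any(object@variants$vaf < 0 | object@variants$vaf > 1, na.rm = TRUE))
      msg <- c(msg, "vaf outside [0, 1]")
    if (any(object@variants$pos < 1))
      msg <- c(msg, "pos must be >= 1 (1-based coordinates)")
  }
  smiss <- setdiff(c("patient", "sample", "timepoint", "purity"),
                   names(object@samples))
  if (length(smiss))
    msg <- c(msg, paste("samples table missing columns:",
                        paste(smiss, collapse = ", ")))
  if (nrow(object@samples) &&
      (any(object@samples$purity <= 0) || any(object@samples$purity > 1)))
    msg <- c(msg, "purity must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Variant filtering report
#'
#' Count reconciliation for the dual FFPE filter: input = signature-removed
#' + VAF-removed + retained.
#'
#' @slot n_input,n_removed_signature,n_removed_vaf,n_retained integer counts.
#' @seealso [applyArtifactFilters()], [retentionRate()]
#' @export
setClass("FilterReport",
  representation(
    n_input = "integer",
    n_removed_signature = "integer",
    n_removed_vaf = "integer",
    n_retained = "integer"
  )
)

setValidity("FilterReport", function(object) {
  if (object@n_input !=
      object@n_removed_signature + object@n_removed_vaf + object@n_retained)
    return("counts do not reconcile: input != signature + vaf + retained")
  if (any(c(object@n_input, object@n_removed_signature,
            object@n_removed_vaf, object@n_retained) < 0L))
    return("counts must be non-negative")
  TRUE
})

#' Clone clustering result
#'
#' Clusters of mutations sharing a cancer cell fraction, fitted by a seeded
#' EM binomial mixture with BIC model selection (see [clusterCcfs()]).
#'
#' @slot clusters `data.frame` with columns `clone_id`, `ccf_centre`,
#'   `mutation_fraction` (fractions sum to 1, centres in `[0, 1]`).
#' @slot assignments integer vector mapping each input mutation to the row
#'   of `clusters` with maximal responsibility.
#' @slot logLik,bic fit diagnostics of the selected model.
#' @export
setClass("CloneSet",
  representation(
    clusters = "data.frame",
    assignments = "integer",
    logLik = "numeric",
    bic = "numeric"
  )
)

setValidity("CloneSet", function(object) {
  msg <- character()
  cl <- object@clusters
  if (!all(c("clone_id", "ccf_centre", "mutation_fraction") %in% names(cl)))
    return("clusters must have clone_id, ccf_centre, mutation_fraction")
  if (nrow(cl) > 15L)
    msg <- c(msg, "more than 15 clusters")
  if (nrow(cl) && abs(sum(cl$mutation_fraction) - 1) > 1e-8)
    msg <- c(msg, "mutation fractions must sum to 1")
  if (nrow(cl) && any(cl$ccf_centre < 0 | cl$ccf_centre > 1))
    msg <- c(msg, "ccf centres must lie in [0, 1]")
  if (length(object@assignments) &&
      (min(object@assignments) < 1L || max(object@assignments) > nrow(cl)))
    msg <- c(msg, "assignments out of range")
  if (length(msg)) msg else TRUE
})

#' Unmatched-pair overlap null distribution
#'
#' Overlap percentages across all ordered pairs of unrelated tumour
#' profiles, used as the null against which matched baseline/recurrence
#' overlap is tested. With self-pairs included the enumeration over N
#' profiles yields N^2 values (360 profiles give 129,600).
#'
#' @slot values overlap percentages in `[0, 100]`, one per ordered pair.
#' @slot n_pairs number of pairs enumerated.
#' @slot includes_self_pairs whether (i, i) pairs were included.
#' @seealso [buildUnmatchedNull()], [compareMatchedVsNull()]
#' @export
setClass("OverlapNull",
  representation(
    values = "numeric",
    n_pairs = "integer",
    includes_self_pairs = "logical"
  )
)

setValidity("OverlapNull", function(object) {
  msg <- character()
  if (length(object@values) != object@n_pairs)
    msg <- c(msg, "n_pairs must equal length(values)")
  if (length(object@values) &&
      (min(object@values) < 0 || max(object@values) > 100))
    msg <- c(msg, "overlap values must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Immune-evasion gene catalogue
#'
#' Gene symbols whose loss of function confers resistance to CD8 T-cell
#' mediated killing: antigen presentation pathway members plus CRISPR-screen
#' resistance hits. Shipped as an editable text fixture (see
#' [readEvasionCatalog()]); it seeds the recurrently hit genes and does not
#' claim to reproduce the full, version-dependent KEGG/screen lists.
#'
#' @slot genes uppercase, deduplicated gene symbols.
#' @slot provenance per-gene tag: `antigen_presentation_kegg`,
#'   `crispr_screen_hit`, or `both`.
#' @export
setClass("EvasionCatalog",
  representation(genes = "character", provenance = "character")
)

setValidity("EvasionCatalog", function(object) {
  msg <- character()
  if (!length(object@genes)) msg <- c(msg, "catalogue must be non-empty")
  if (anyDuplicated(object@genes)) msg <- c(msg, "gene symbols must be unique")
  if (length(object@genes) && !identical(object@genes, toupper(object@genes)))
    msg <- c(msg, "gene symbols must be uppercase")
  if (length(object@provenance) != length(object@genes))
    msg <- c(msg, "provenance must be parallel to genes")
  bad <- setdiff(unique(object@provenance),
                 c("antigen_presentation_kegg", "crispr_screen_hit", "both"))
  if (length(bad))
    msg <- c(msg, paste("unknown provenance:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})
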