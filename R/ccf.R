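#' Cancer cell fraction from VAF, purity and allele-specific copy number
#'
#' For each variant the multiplicity `m` is chosen from `1..major_cn` as
#' the value whose expected clonal VAF,
#' `m * purity / (purity * CNt + (1 - purity) * CNn)`, is closest to the
#' observed VAF (ties broken towards the smaller, more conservative `m`).
#' The CCF is then
#' `vaf * (purity * CNt + (1 - purity) * CNn) / (purity * m)`, capped at 1;
#' the uncapped value is kept as a purity/copy-number consistency
#' diagnostic. Variants on homozygous deletions (`major_cn = 0`) cannot
#' carry a mutation in the tumour and are flagged inconsistent.
#'
#' @param vaf observed variant allele frequencies.
#' @param purity tumour purity (scalar or per-variant).
#' @param majorCn,minorCn allele-specific copy numbers (per-variant;
#'   `CNt = majorCn + minorCn`).
#' @param normalCn copy number in normal cells (default 2).
#' @return `data.frame` with columns `multiplicity`, `ccf`,
#'   `ccf_uncapped`, `inconsistent` (TRUE for `major_cn = 0`; such rows
#'   have `NA` estimates and must be excluded from clustering).
#' @examples
#' computeCcf(0.25, purity = 0.5, majorCn = 1, minorCn = 1)   # ccf 1
#' computeCcf(0.5,  purity = 1.0, majorCn = 1, minorCn = 1)   # ccf 1
#' @export
computeCcf <- function(vaf, purity, majorCn, minorCn, normalCn = 2) {
  n <- length(vaf)
  purity <- rep_len(purity, n)
  majorCn <- rep_len(as.integer(majorCn), n)
  minorCn <- rep_len(as.integer(minorCn), n)
  normalCn <- rep_len(as.integer(normalCn), n)
  if (any(purity <= 0)) stop("purity must be positive")
  if (any(minorCn > majorCn)) stop("major_cn must be >= minor_cn")
  cnt <- majorCn + minorCn
  denom <- purity * cnt + (1 - purity) * normalCn

  mult <- integer(n)
  inconsistent <- majorCn == 0L
  mult[inconsistent] <- NA_integer_
  maxM <- max(1L, majorCn, na.rm = TRUE)
  ## pick m in 1..major_cn minimising |expected clonal VAF - observed VAF|;
  ## evaluated columnwise over candidate m, smaller m wins ties
  dist <- matrix(Inf, n, maxM)
  for (m in seq_len(maxM)) {
    ok <- majorCn >= m
    dist[ok, m] <- abs(m * purity[ok] / denom[ok] - vaf[ok])
  }
  pick <- max.col(-dist, ties.method = "first")
  mult[!inconsistent] <- pick[!inconsistent]

  ccfRaw <- vaf * denom / (purity * mult)
  ccfRaw[inconsistent] <- NA_real_
  data.frame(
    multiplicity = mult,
    ccf = pmin(ccfRaw, 1),
    ccf_uncapped = ccfRaw,
    inconsistent = inconsistent
  )
}

#' Per-sample CCF table for a cohort
#'
#' Joins each variant to its covering copy-number segment (1-based
#' inclusive containment, via GenomicRanges) and the sample's purity, then
#' applies [computeCcf()]. Variants with no covering segment assume a
#' diploid locus (`CNt = normal_cn`, `m = 1`).
#'
#' @param variants variant `data.frame` (canonical columns), or a
#'   [ClonalCohort-class] (in which case segments/meta are taken from it).
#' @param segments segment `data.frame` with `sample, chrom, start, end,
#'   major_cn, minor_cn` (+ optional `normal_cn`).
#' @param samples sample metadata with `sample, purity`.
#' @return the variant table augmented with `purity, major_cn, minor_cn,
#'   normal_cn, multiplicity, ccf, ccf_uncapped, inconsistent,
#'   mutation_id`.
#' @export
ccfTable <- function(variants, segments = NULL, samples = NULL) {
  if (is(variants, "ClonalCohort")) {
    segments <- segmentTable(variants)
    samples <- sampleMeta(variants)
    variants <- variantCalls(variants)
  }
  stopifnot(!is.null(segments), !is.null(samples))
  if (!nrow(variants)) stop("no variants to compute CCFs for")
  if (!"normal_cn" %in% names(segments)) segments$normal_cn <- 2L

  variants$major_cn <- NA_integer_
  variants$minor_cn <- NA_integer_
  variants$normal_cn <- 2L
  ## containment join per sample so segments from other samples never match
  vGr <- GenomicRanges::GRanges(
    paste0(variants$sample, "|", variants$chrom),
    IRanges::IRanges(variants$pos, variants$pos)
  )
  sGr <- GenomicRanges::GRanges(
    paste0(segments$sample, "|", segments$chrom),
    IRanges::IRanges(segments$start, segments$end)
  )
  hit <- GenomicRanges::findOverlaps(vGr, sGr, select = "first")
  has <- !is.na(hit)
  variants$major_cn[has] <- segments$major_cn[hit[has]]
  variants$minor_cn[has] <- segments$minor_cn[hit[has]]
  variants$normal_cn[has] <- segments$normal_cn[hit[has]]
  ## no covering segment: assume a diploid locus
  variants$major_cn[!has] <- 1L
  variants$minor_cn[!has] <- 1L

  variants$purity <- samples$purity[match(variants$sample, samples$sample)]
  if (anyNA(variants$purity))
    stop("purity missing for sample(s): ",
         paste(unique(variants$sample[is.na(variants$purity)]),
               collapse = ", "))
  est <- computeCcf(variants$vaf, variants$purity, variants$major_cn,
                    variants$minor_cn, variants$normal_cn)
  variants$multiplicity <- est$multiplicity
  variants$ccf <- est$ccf
  variants$ccf_uncapped <- est$ccf_uncapped
  variants$inconsistent <- est$inconsistent
  variants$mutation_id <- mutationKey(variants)
  rownames(variants) <- NULL
  variants
}

#' @describeIn clonalityScore mutation-level mean CCF (equals the
#'   clone-frequency-weighted sum).
#' @export
setMethod("clonalityScore", "numeric", function(x, ...) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("clonality score undefined for an empty mutation set")
  if (any(x < 0 | x > 1)) stop("CCFs must lie in [0, 1]")
  mean(x)
})

#' Per-patient change in clonality score between timepoints
#'
#' Computes recurrence minus baseline clonality per patient and, when an
#' immune-group column is present, compares the deltas between groups with
#' a two-sided tie-corrected rank-sum test. Patients missing either
#' timepoint are excluded with a warning.
#'
#' @param scores `data.frame` with columns `patient, timepoint, score` and
#'   optionally `immune_group`; `timepoint` must contain `"baseline"` and
#'   `"recurrence"`.
#' @return list with `deltas` (patient, delta, and group when available)
#'   and `group_test` (a [rankSumTest()] result, or `NULL` without
#'   groups).
#' @export
deltaClonality <- function(scores) {
  stopifnot(all(c("patient", "timepoint", "score") %in% names(scores)))
  wide <- split(scores, scores$patient)
  rows <- lapply(wide, function(d) {
    b <- d$score[d$timepoint == "baseline"]
    r <- d$score[d$timepoint == "recurrence"]
    if (length(b) != 1L || length(r) != 1L) return(NULL)
    data.frame(
      patient = d$patient[1],
      delta = r - b,
      immune_group = if ("immune_group" %in% names(d))
        d$immune_group[1] else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  dropped <- names(rows)[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warning("excluding patient(s) without both timepoints: ",
            paste(dropped, collapse = ", "))
  deltas <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(deltas) || !nrow(deltas))
    stop("no patient has both timepoints scored")
  rownames(deltas) <- NULL
  groupTest <- NULL
  grp <- unique(deltas$immune_group[!is.na(deltas$immune_group)])
  if (length(grp) == 2L) {
    a <- deltas$delta[deltas$immune_group == grp[1]]
    b <- deltas$delta[deltas$immune_group == grp[2]]
    groupTest <- rankSumTest(a, b)
    groupTest$groups <- grp
  }
  list(deltas = deltas, group_test = groupTest)
}
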