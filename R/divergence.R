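#' Classify a patient's mutations as private or public across timepoints
#'
#' A mutation (identified by its exact chrom/pos/ref/alt key) is *public*
#' when found at both timepoints and *private* when found at only one.
#' The displayed percent public is union-based,
#' `100 * |A n B| / |A u B|`, and is symmetric in the two profiles.
#'
#' @param baselineKeys,recurrenceKeys character vectors of mutation keys
#'   (see [mutationKey()]) for the two timepoints.
#' @return list with `labels` (`data.frame`: mutation_id, status in
#'   private_baseline/private_recurrence/public), `percent_public`, and
#'   the three counts.
#' @examples
#' classifyPrivatePublic(c("1:10:A>T", "1:20:C>G"), c("1:10:A>T"))
#' @export
classifyPrivatePublic <- function(baselineKeys, recurrenceKeys) {
  a <- unique(as.character(baselineKeys))
  b <- unique(as.character(recurrenceKeys))
  if (!length(a) && !length(b))
    stop("percent public undefined: both profiles are empty")
  shared <- intersect(a, b)
  privA <- setdiff(a, b)
  privB <- setdiff(b, a)
  labels <- data.frame(
    mutation_id = c(shared, privA, privB),
    status = rep(c("public", "private_baseline", "private_recurrence"),
                 c(length(shared), length(privA), length(privB))),
    stringsAsFactors = FALSE
  )
  rownames(labels) <- NULL
  list(
    labels = labels,
    percent_public = 100 * length(shared) / length(union(a, b)),
    n_public = length(shared),
    n_private_baseline = length(a) - length(shared),
    n_private_recurrence = length(b) - length(shared)
  )
}

#' Asymmetric overlap percentage between two mutation profiles
#'
#' `100 * |A n B| / |A|`: the share of the first profile's mutations also
#' found in the second. The first-profile denominator makes the ordered
#' pairwise enumeration of [buildUnmatchedNull()] well defined (and is why
#' that enumeration over N profiles has N^2 values); use
#' [classifyPrivatePublic()] for the symmetric union-based display.
#'
#' @param profileA,profileB character vectors of mutation keys.
#' @return percentage in `[0, 100]`.
#' @examples
#' overlapPercent(c("k1", "k2", "k3", "k4"), c("k1", "x"))  # 25
#' @export
overlapPercent <- function(profileA, profileB) {
  a <- unique(as.character(profileA))
  if (!length(a)) stop("overlap undefined: first profile is empty")
  100 * length(intersect(a, unique(as.character(profileB)))) / length(a)
}

#' Null distribution of mutational overlap across unmatched profiles
#'
#' Enumerates every ordered pair of profiles (optionally including
#' self-pairs) and records [overlapPercent()] for each, yielding the
#' distribution of overlap expected between tumours from unrelated
#' individuals. With self-pairs included, N profiles give N^2 values
#' (360 profiles give 129,600); excluding them gives N(N-1) and a more
#' conservative null. Internally the enumeration is a sparse-incidence
#' cross-product, so cohort-scale inputs complete in seconds.
#'
#' @param profiles list of character vectors of mutation keys.
#' @param includeSelfPairs include the (i, i) pairs (default TRUE).
#' @return an [OverlapNull-class].
#' @examples
#' null <- buildUnmatchedNull(list(c("a", "b"), c("b", "c"), c("x")))
#' null
#' @export
buildUnmatchedNull <- function(profiles, includeSelfPairs = TRUE) {
  stopifnot(is.list(profiles))
  profiles <- lapply(profiles, function(p) unique(as.character(p)))
  sizes <- lengths(profiles)
  if (any(sizes == 0L)) stop("profiles must be non-empty")
  N <- length(profiles)
  if (N < 1L || (!includeSelfPairs && N < 2L))
    stop("need at least 2 profiles (or 1 with self-pairs)")

  universe <- unique(unlist(profiles, use.names = FALSE))
  inc <- Matrix::sparseMatrix(
    i = rep.int(seq_len(N), sizes),
    j = match(unlist(profiles, use.names = FALSE), universe),
    x = 1,
    dims = c(N, length(universe))
  )
  shared <- as.matrix(Matrix::tcrossprod(inc))   # N x N intersection sizes
  ov <- 100 * shared / sizes                     # row i / |profile i|
  tm <- t(ov)                                    # row-major pair order
  values <- if (includeSelfPairs) as.numeric(tm) else
    tm[row(tm) != col(tm)]
  new("OverlapNull",
      values = values,
      n_pairs = length(values),
      includes_self_pairs = includeSelfPairs)
}

#' Test matched overlap against the unmatched null
#'
#' Two-sided tie-corrected rank-sum comparison of the matched
#' baseline/recurrence overlap percentages against the unmatched-pair
#' null distribution, reporting the direction of the effect alongside the
#' p-value. Degenerate inputs in which every value ties are reported as
#' p = 1 with a warning.
#'
#' @param matchedOverlaps numeric overlap percentages of matched pairs.
#' @param null an [OverlapNull-class] (or numeric null values).
#' @return list with `statistic`, `p.value`, `direction`
#'   (`"matched > null"` / `"matched < null"` / `"none"`),
#'   `median_matched`, `median_null`.
#' @export
compareMatchedVsNull <- function(matchedOverlaps, null) {
  vals <- if (is(null, "OverlapNull")) nullValues(null) else as.numeric(null)
  if (!length(matchedOverlaps) || !length(vals))
    stop("both the matched sample and the null must be non-empty")
  if (length(unique(c(matchedOverlaps, vals))) == 1L) {
    warning("all overlap values tie; reporting p = 1")
    return(list(statistic = NA_real_, p.value = 1, direction = "none",
                median_matched = median(matchedOverlaps),
                median_null = median(vals)))
  }
  res <- rankSumTest(matchedOverlaps, vals)
  mm <- median(matchedOverlaps); mn <- median(vals)
  list(
    statistic = res$statistic,
    p.value = res$p.value,
    direction = if (mm > mn) "matched > null" else
      if (mm < mn) "matched < null" else "none",
    median_matched = mm,
    median_null = mn,
    exact = res$exact
  )
}

#' Per-patient divergence summary for a cohort
#'
#' Convenience wrapper: splits a cohort's (filtered) variant table by
#' patient, classifies mutations private/public between baseline and
#' recurrence, and records both the union-based percent public and the
#' asymmetric baseline-denominator overlap used against the null.
#'
#' @param variants variant `data.frame` or [ClonalCohort-class].
#' @return `data.frame` with one row per patient with both timepoints.
#' @export
divergenceSummary <- function(variants) {
  if (is(variants, "ClonalCohort")) variants <- variantCalls(variants)
  keys <- mutationKey(variants)
  out <- lapply(split(seq_len(nrow(variants)), variants$patient),
    function(idx) {
      v <- variants[idx, ]
      k <- keys[idx]
      a <- k[v$timepoint == "baseline"]
      b <- k[v$timepoint == "recurrence"]
      if (!length(a) || !length(b)) return(NULL)
      cp <- classifyPrivatePublic(a, b)
      data.frame(
        patient = v$patient[1],
        n_baseline = length(unique(a)),
        n_recurrence = length(unique(b)),
        n_public = cp$n_public,
        percent_public = cp$percent_public,
        overlap_baseline_denom = overlapPercent(a, b),
        stringsAsFactors = FALSE
      )
    })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
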