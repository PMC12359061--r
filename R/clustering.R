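## Clone clustering: EM fit of a binomial mixture over alt read counts,
## with component success probabilities induced by candidate clone CCFs
## through each mutation's own purity/copy-number scaling. Model size is
## chosen by BIC over 1..maxClones (cap mirrors the 15-subclone ceiling
## used for the cohort analysis). Initialisation is by CCF quantiles, so
## the fit is deterministic for a given input ordering-independent CCF set.

.emBinomialMixture <- function(alt, depth, scale, k, maxIter = 200L,
                               tol = 1e-7) {
  n <- length(alt)
  ccfHat <- pmin(1, (alt / depth) / scale)
  centres <- unname(quantile(ccfHat, probs = (seq_len(k) - 0.5) / k,
                             type = 7))
  centres <- pmin(pmax(centres, 1e-4), 1)
  w <- rep(1 / k, k)
  ll <- -Inf
  eps <- 1e-9
  lc <- lchoose(depth, alt)
  ref <- depth - alt
  for (iter in seq_len(maxIter)) {
    ## E-step: responsibilities from binomial log-likelihoods
    P <- pmin(pmax(outer(scale, centres), eps), 1 - eps)   # n x k
    logp <- lc + alt * log(P) + ref * log1p(-P)
    logp <- sweep(logp, 2L, log(w + eps), `+`)
    mx <- logp[cbind(seq_len(n), max.col(logp, ties.method = "first"))]
    pr <- exp(logp - mx)
    rs <- rowSums(pr)
    r <- pr / rs
    llNew <- sum(mx + log(rs))
    ## M-step
    w <- colMeans(r)
    num <- colSums(r * alt)
    den <- colSums(r * depth * scale)
    upd <- den > 0
    centres[upd] <- pmin(pmax(num[upd] / den[upd], 1e-4), 1)
    if (is.finite(ll) && abs(llNew - ll) < tol * (1 + abs(llNew))) {
      ll <- llNew; break
    }
    ll <- llNew
  }
  list(centres = centres, weights = w, resp = r, logLik = ll)
}

#' Cluster mutations into clones by CCF (binomial mixture, BIC selection)
#'
#' Fits, for each candidate clone count `k = 1..maxClones`, a k-component
#' binomial mixture in which component `j` places mutation `i`'s alt count
#' at `Binomial(depth_i, ccf_j * scale_i)`, where `scale_i` is the
#' mutation's expected VAF at CCF 1 (from purity, multiplicity and copy
#' number). The clone count is chosen by BIC and each mutation is assigned
#' to its maximum-responsibility cluster. Components that end up empty are
#' dropped before reporting. The procedure is deterministic: components
#' are initialised at CCF quantiles.
#'
#' @param alt,depth alt read counts and total depths, per mutation.
#' @param scale expected VAF at CCF 1 per mutation (defaults to 0.5,
#'   i.e. a fully diploid heterozygous locus at purity 1); see
#'   [expectedVaf()].
#' @param maxClones upper limit on the number of clones (default 15).
#' @param ccf optional CCF table from [ccfTable()] — when supplied,
#'   `alt`, `depth` and `scale` are derived from it and inconsistent
#'   variants are excluded.
#' @return a [CloneSet-class].
#' @examples
#' set.seed(1)
#' depth <- rep(500L, 120)
#' truth <- rep(c(0.2, 1.0), each = 60)
#' alt <- rbinom(120, depth, truth * 0.5)
#' cs <- clusterCcfs(alt, depth)
#' nClusters(cs)
#' @export
clusterCcfs <- function(alt, depth, scale = 0.5, maxClones = 15L,
                        ccf = NULL) {
  if (!is.null(ccf)) {
    ok <- !ccf$inconsistent & !is.na(ccf$ccf)
    ccf <- ccf[ok, , drop = FALSE]
    alt <- ccf$t_alt_count
    depth <- ccf$t_ref_count + ccf$t_alt_count
    denom <- ccf$purity * (ccf$major_cn + ccf$minor_cn) +
      (1 - ccf$purity) * ccf$normal_cn
    scale <- ccf$multiplicity * ccf$purity / denom
  }
  n <- length(alt)
  if (n < 1L) stop("at least one assignable variant is required")
  stopifnot(length(depth) == n)
  scale <- rep_len(scale, n)
  maxClones <- min(as.integer(maxClones), 15L)

  ccfHat <- pmin(1, (alt / depth) / scale)
  kMax <- min(maxClones, length(unique(round(ccfHat, 6))))
  best <- NULL
  bestBic <- Inf
  for (k in seq_len(kMax)) {
    fit <- .emBinomialMixture(alt, depth, scale, k)
    bic <- -2 * fit$logLik + (2 * k - 1) * log(n)
    if (bic < bestBic - 1e-9) { bestBic <- bic; best <- fit }
  }
  assign <- if (length(best$weights) == 1L) rep(1L, n) else
    max.col(best$resp, ties.method = "first")
  used <- sort(unique(assign))
  centres <- best$centres[used]
  assign <- match(assign, used)
  frac <- tabulate(assign, length(used)) / n
  ord <- order(centres, decreasing = TRUE)
  clusters <- data.frame(
    clone_id = sprintf("clone_%d", seq_along(used)),
    ccf_centre = centres[ord],
    mutation_fraction = frac[ord]
  )
  new("CloneSet",
      clusters = clusters,
      assignments = match(assign, ord),
      logLik = best$logLik, bic = bestBic)
}
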