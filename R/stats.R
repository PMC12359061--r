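#' Two-sample rank-sum (Wilcoxon/Mann-Whitney) test
#'
#' The workhorse comparison used across the package (clonality deltas,
#' matched-vs-null overlap, neoantigen dynamics, covariate associations).
#' For small samples the null distribution of the rank-sum statistic is
#' enumerated exactly over all group assignments, which remains exact in
#' the presence of ties (midranks); for larger samples the tie-corrected
#' normal approximation of [stats::wilcox.test()] is used.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to the location of `x` relative to `y`.
#' @param exactLimit enumerate exactly when `choose(nx + ny, nx)` does not
#'   exceed this (default 2e5, i.e. total n around 20 or less).
#' @return a list with elements `statistic` (rank sum of `x`, midranks),
#'   `u` (Mann-Whitney U for `x`), `p.value`, `alternative`, `exact`
#'   (logical), and `method`.
#' @examples
#' rankSumTest(c(5, 6, 7), c(1, 2, 3), alternative = "greater")
#' @export
rankSumTest <- function(x, y,
                        alternative = c("two.sided", "less", "greater"),
                        exactLimit = 2e5) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y))
    stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))              # midranks
  W <- sum(r[seq_len(nx)])
  U <- W - nx * (nx + 1) / 2
  useExact <- is.finite(choose(n, nx)) && choose(n, nx) <= exactLimit
  if (useExact) {
    combos <- utils::combn(n, nx)
    sums <- colSums(matrix(r[combos], nrow = nx))
    eps <- 1e-9
    pLess <- mean(sums <= W + eps)
    pGreater <- mean(sums >= W - eps)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(pLess, pGreater)),
      less = pLess,
      greater = pGreater
    )
    method <- "exact rank-sum (full enumeration, midranks)"
  } else {
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = alternative, exact = FALSE,
                  correct = TRUE)
    )
    p <- wt$p.value
    method <- "rank-sum, tie-corrected normal approximation"
  }
  list(statistic = W, u = U, p.value = p, alternative = alternative,
       exact = useExact, method = method)
}

#' Fisher's exact test on a 2x2 flag-by-group table
#'
#' Compares the proportion of flagged samples between two groups with the
#' exact hypergeometric test, reporting the sample odds ratio (with the
#' Haldane 0.5 correction applied to every cell when any cell is zero).
#'
#' @param flags logical vector (e.g. carries an evasion LoF mutation).
#' @param groups factor/character with exactly two levels, parallel to
#'   `flags`.
#' @return list with `table` (2x2: groups x flagged; group order follows
#'   the factor levels, and the odds ratio is the flagged-odds of the
#'   first level relative to the second), `odds_ratio`,
#'   `p.value`, `conditional_or` (the conditional MLE reported by
#'   [stats::fisher.test()]), and `haldane_corrected` (logical).
#' @examples
#' f <- rep(c(TRUE, FALSE), c(21, 11))
#' g <- rep(c("transplant", "control"),  c(22, 10))
#' f <- c(rep(TRUE, 19), rep(FALSE, 3), rep(TRUE, 2), rep(FALSE, 8))
#' fisherGroupComparison(f, g)
#' @export
fisherGroupComparison <- function(flags, groups) {
  stopifnot(length(flags) == length(groups))
  flags <- as.logical(flags)
  groups <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  lev <- levels(groups)
  if (length(lev) != 2L)
    stop("exactly two groups required, got: ", paste(lev, collapse = ", "))
  for (g in lev) if (!sum(groups == g))
    stop("group '", g, "' is empty")
  tab <- table(group = groups, flagged = factor(flags, c(TRUE, FALSE)))
  ft <- fisher.test(tab)
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  haldane <- any(tab == 0)
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  list(
    table = tab,
    odds_ratio = (a * d) / (b * c_),
    p.value = ft$p.value,
    conditional_or = unname(ft$estimate),
    haldane_corrected = haldane
  )
}

#' Rank-sum association of a covariate with a sample flag
#'
#' Compares a per-sample covariate (mutational burden, CD8 infiltration,
#' CD8/Treg ratio, ...) between flagged and unflagged samples.
#'
#' @param flags logical vector.
#' @param values numeric covariate parallel to `flags`; `NA` pairs are
#'   dropped.
#' @param alternative passed to [rankSumTest()]; location of the flagged
#'   group relative to the unflagged.
#' @return the [rankSumTest()] result, augmented with `n_flagged`,
#'   `n_unflagged` and `median_difference` (flagged minus unflagged).
#' @export
covariateAssociation <- function(flags, values,
                                 alternative = "two.sided") {
  stopifnot(length(flags) == length(values))
  keep <- !is.na(values) & !is.na(flags)
  flags <- as.logical(flags[keep]); values <- as.numeric(values[keep])
  a <- values[flags]; b <- values[!flags]
  if (!length(a) || !length(b))
    stop("covariate must be observed in both the flagged and unflagged class")
  res <- rankSumTest(a, b, alternative = alternative)
  res$n_flagged <- length(a)
  res$n_unflagged <- length(b)
  res$median_difference <- median(a) - median(b)
  res
}
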