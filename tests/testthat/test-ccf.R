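test_that("closed-form CCFs are exact for diploid heterozygous mutations", {
  ## pure diploid clonal heterozygous: VAF 0.5 -> CCF 1
  a <- computeCcf(0.5, purity = 1.0, majorCn = 1, minorCn = 1)
  expect_equal(a$ccf, 1.0)
  expect_equal(a$multiplicity, 1L)
  ## purity 0.5 halves every expectation: VAF 0.25 -> CCF 1
  b <- computeCcf(0.25, purity = 0.5, majorCn = 1, minorCn = 1)
  expect_equal(b$ccf, 1.0)
})

test_that("multiplicity choice matches the exhaustive brute-force oracle", {
  set.seed(42)
  n <- 300
  purity <- runif(n, 0.2, 1)
  majorCn <- sample(1:4, n, replace = TRUE)
  minorCn <- vapply(majorCn, function(mc) sample(0:mc, 1), integer(1))
  vaf <- runif(n, 0.01, 0.9)
  got <- computeCcf(vaf, purity, majorCn, minorCn)

  for (i in seq_len(n)) {
    denom <- purity[i] * (majorCn[i] + minorCn[i]) + (1 - purity[i]) * 2
    best <- NULL
    for (m in seq_len(majorCn[i])) {        # scan every multiplicity
      d <- abs(m * purity[i] / denom - vaf[i])
      if (is.null(best) || d < best$d - 1e-12) best <- list(m = m, d = d)
    }
    expect_identical(got$multiplicity[i], best$m)
    expect_equal(got$ccf[i],
                 min(1, vaf[i] * denom / (purity[i] * best$m)))
  }
})

test_that("homozygous deletions are flagged inconsistent, capping is recorded", {
  del <- computeCcf(0.2, purity = 0.8, majorCn = 0, minorCn = 0)
  expect_true(del$inconsistent)
  expect_true(is.na(del$ccf))

  hot <- computeCcf(0.9, purity = 0.5, majorCn = 1, minorCn = 1)
  expect_equal(hot$ccf, 1)
  expect_gt(hot$ccf_uncapped, 1)   # kept as a purity/CN diagnostic
})

test_that("ccfTable joins segments by containment and defaults to diploid", {
  v <- makeVariants(c(0.25, 0.25))
  v$chrom <- c("1", "9")            # chromosome 9 has no segment
  segs <- data.frame(sample = "P01_B", chrom = "1", start = 1L,
                     end = 1000L, major_cn = 2L, minor_cn = 1L,
                     normal_cn = 2L)
  meta <- data.frame(patient = "P01", sample = "P01_B",
                     timepoint = "baseline", purity = 0.5)
  cc <- ccfTable(v, segs, meta)
  expect_equal(cc$major_cn, c(2L, 1L))
  expect_equal(cc$minor_cn, c(1L, 1L))
  ## unmatched variant treated as diploid m = 1: ccf = vaf * 2 / purity
  expect_equal(cc$ccf[2], min(1, 0.25 * 2 / 0.5))
  expect_error(ccfTable(v, segs, meta[0, ]), "purity missing")
})

test_that("clonality score equals the clone-weighted sum and the mean CCF", {
  expect_equal(clonalityScore(rep(1, 10)), 1.0)
  expect_equal(clonalityScore(c(0.2, 0.2, 0.8, 0.8)), 0.5)
  expect_error(clonalityScore(numeric()), "undefined")
  expect_error(clonalityScore(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(3)
  ccf <- runif(200)
  ## invariant to mutation ordering
  expect_identical(clonalityScore(ccf), clonalityScore(rev(ccf)))

  ## clone-weighted sum == mutation-level mean, and invariant to relabelling
  assign <- sample(1:4, 200, replace = TRUE)
  centres <- tapply(ccf, assign, mean)
  frac <- tabulate(assign, 4) / 200
  cs <- new("CloneSet",
            clusters = data.frame(clone_id = paste0("c", 1:4),
                                  ccf_centre = as.numeric(centres),
                                  mutation_fraction = frac),
            assignments = assign, logLik = 0, bic = 0)
  perMutation <- centres[assign]
  expect_equal(clonalityScore(cs), mean(perMutation))
  perm <- sample(4)
  csPerm <- new("CloneSet",
                clusters = cs@clusters[perm, ],
                assignments = match(assign, perm), logLik = 0, bic = 0)
  expect_equal(clonalityScore(csPerm), clonalityScore(cs))
})

test_that("delta clonality is recurrence minus baseline with exclusions", {
  scores <- data.frame(
    patient = rep(c("P1", "P2", "P3"), each = 2),
    timepoint = rep(c("baseline", "recurrence"), 3),
    score = c(0.4, 0.7, 0.5, 0.5, 0.2, 0.9),
    immune_group = rep(c("immunocompromised", "immunocompromised",
                         "immunocompetent"), each = 2)
  )
  dc <- deltaClonality(scores)
  expect_equal(dc$deltas$delta[dc$deltas$patient == "P1"], 0.3)
  expect_equal(dc$deltas$delta[dc$deltas$patient == "P2"], 0)

  expect_warning(dc2 <- deltaClonality(scores[-6, ]), "P3")
  expect_equal(nrow(dc2$deltas), 2L)
})

test_that("delta clonality group comparison matches the exact oracle", {
  scores <- data.frame(
    patient = rep(sprintf("P%02d", 1:10), each = 2),
    timepoint = rep(c("baseline", "recurrence"), 10),
    score = c(rbind(rep(0.4, 10),
                    0.4 + c(0.30, 0.25, 0.28, 0.31, 0.27,
                            0.05, 0.02, 0.08, 0.01, 0.04))),
    immune_group = rep(rep(c("immunocompromised", "immunocompetent"),
                           each = 5), each = 2)
  )
  dc <- deltaClonality(scores)
  a <- dc$deltas$delta[dc$deltas$immune_group == dc$group_test$groups[1]]
  b <- dc$deltas$delta[dc$deltas$immune_group == dc$group_test$groups[2]]
  expect_equal(dc$group_test$p.value, oracleRankSumP(a, b))
})
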