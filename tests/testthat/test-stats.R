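test_that("small-sample rank-sum p-values match the enumeration oracle", {
  cases <- list(
    list(x = c(90, 80, 85), y = c(1, 2, 3, 0, 5)),
    list(x = c(5, 6, 7), y = c(1, 2, 3)),
    list(x = c(1, 2, 2, 3), y = c(2, 2, 4, 5)),        # ties
    list(x = c(0.1, 0.2), y = c(0.2, 0.2, 0.3, 0.1)),  # heavy ties
    list(x = rnorm(6), y = rnorm(6))
  )
  set.seed(1)
  for (cs in cases) {
    for (alt in c("two.sided", "less", "greater")) {
      got <- rankSumTest(cs$x, cs$y, alternative = alt)
      expect_true(got$exact)
      expect_equal(got$p.value, oracleRankSumP(cs$x, cs$y, alt),
                   tolerance = 1e-12,
                   info = paste("alt =", alt))
    }
  }
})

test_that("tie-free exact p-values agree with wilcox.test's exact method", {
  x <- c(3.1, 4.5, 0.2, 9.9)
  y <- c(1.1, 2.2, 5.5, 7.7, 8.8)
  expect_equal(rankSumTest(x, y)$p.value,
               wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  set.seed(2)
  x <- rnorm(60); y <- rnorm(80, 0.3)
  got <- rankSumTest(x, y)
  expect_false(got$exact)
  expect_equal(got$p.value,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
})

test_that("identical samples give p = 1", {
  expect_equal(rankSumTest(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_error(rankSumTest(numeric(), 1:3), "non-empty")
})

test_that("Fisher comparisons match the hypergeometric oracle", {
  ## the transplant vs immunocompetent evasion-LoF proportions: 19/22 vs 2/10
  flags <- c(rep(TRUE, 19), rep(FALSE, 3), rep(TRUE, 2), rep(FALSE, 8))
  groups <- factor(rep(c("transplant", "resection"), c(22, 10)),
                   levels = c("transplant", "resection"))
  res <- fisherGroupComparison(flags, groups)
  expect_equal(res$p.value, oracleFisherP(res$table), tolerance = 1e-9)
  expect_equal(res$odds_ratio, (19 * 8) / (3 * 2))
  expect_false(res$haldane_corrected)
  expect_lt(res$p.value, 0.05)

  ## no association
  f2 <- rep(c(TRUE, FALSE, TRUE, FALSE), c(5, 5, 5, 5))
  g2 <- rep(c("a", "b"), each = 10)
  res2 <- fisherGroupComparison(f2, g2)
  expect_equal(res2$odds_ratio, 1)
  expect_equal(res2$p.value, 1)

  ## extreme table with a zero cell: Haldane-corrected odds ratio
  f3 <- rep(c(TRUE, FALSE), c(10, 10))
  g3 <- rep(c("a", "b"), each = 10)
  res3 <- fisherGroupComparison(f3, g3)
  expect_true(res3$haldane_corrected)
  expect_equal(res3$p.value, oracleFisherP(res3$table), tolerance = 1e-9)
  expect_equal(res3$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))

  expect_error(fisherGroupComparison(TRUE, "a"), "two groups")
})

test_that("Fisher p agrees with the oracle on all 2x2 tables with margins <= 12", {
  for (r1 in 0:6) for (r2 in 0:6) for (a in 0:r1) for (c_ in 0:r2) {
    if (r1 == 0 || r2 == 0) next
    tab <- matrix(c(a, r1 - a, c_, r2 - c_), 2, byrow = TRUE)
    if (sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0) next
    expect_equal(fisher.test(tab)$p.value, oracleFisherP(tab),
                 tolerance = 1e-9,
                 info = paste(a, r1, c_, r2))
  }
})

test_that("covariate associations match the exact oracle and detect shifts", {
  res <- covariateAssociation(c(rep(TRUE, 3), rep(FALSE, 3)),
                              c(5, 6, 7, 1, 2, 3))
  expect_equal(res$p.value, oracleRankSumP(c(5, 6, 7), c(1, 2, 3)))
  expect_equal(res$median_difference, 4)

  same <- covariateAssociation(c(TRUE, TRUE, FALSE, FALSE),
                               c(2, 2, 2, 2))
  expect_equal(same$p.value, 1)

  expect_error(covariateAssociation(c(TRUE, TRUE), c(1, 2)), "both")

  ## rejection rate rises with the flagged-class shift
  rate <- function(shift) {
    mean(vapply(seq_len(60), function(i) {
      set.seed(1000 + i)
      flags <- rep(c(TRUE, FALSE), each = 15)
      vals <- rnorm(30) + shift * flags
      covariateAssociation(flags, vals)$p.value < 0.05
    }, logical(1)))
  }
  expect_gt(rate(2), rate(0))
  expect_gte(rate(2), 0.8)
})
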