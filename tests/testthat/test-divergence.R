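test_that("private/public classification follows set membership", {
  same <- classifyPrivatePublic(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(same$percent_public, 100)

  disj <- classifyPrivatePublic(c("a", "b"), c("c", "d"))
  expect_equal(disj$percent_public, 0)
  expect_equal(sort(unique(disj$labels$status)),
               c("private_baseline", "private_recurrence"))

  ## |A| = 6, |B| = 6, |A n B| = 2 -> 2/10 of the union
  a <- paste0("m", 1:6)
  b <- c(paste0("m", 1:2), paste0("x", 1:4))
  mix <- classifyPrivatePublic(a, b)
  expect_equal(mix$percent_public,
               100 * length(intersect(a, b)) / length(union(a, b)))
  expect_equal(mix$percent_public, 20)
  expect_error(classifyPrivatePublic(character(), character()), "undefined")
})

test_that("overlap percent is first-profile-denominator and asymmetric", {
  expect_equal(overlapPercent(c("a", "b"), c("a", "b")), 100)
  expect_equal(overlapPercent(c("a", "b"), c("x", "y")), 0)
  expect_equal(overlapPercent(paste0("k", 1:4), c("k1", "zz")), 25)
  expect_error(overlapPercent(character(), "a"), "empty")

  a <- paste0("m", 1:8)
  b <- paste0("m", 1:2)
  expect_false(overlapPercent(a, b) == overlapPercent(b, a))
  ## percent public is symmetric where overlapPercent is not
  expect_equal(classifyPrivatePublic(a, b)$percent_public,
               classifyPrivatePublic(b, a)$percent_public)
})

test_that("null size follows the ordered-pair law for N = 1..20", {
  for (N in 1:20) {
    profiles <- lapply(seq_len(N), function(i) paste0("p", i, "_", 1:3))
    withSelf <- buildUnmatchedNull(profiles, includeSelfPairs = TRUE)
    expect_equal(withSelf@n_pairs, N * N)
    if (N >= 2) {
      noSelf <- buildUnmatchedNull(profiles, includeSelfPairs = FALSE)
      expect_equal(noSelf@n_pairs, N * (N - 1L))
    }
  }
  one <- buildUnmatchedNull(list(c("a", "b")), includeSelfPairs = TRUE)
  expect_equal(nullValues(one), 100)
  expect_error(buildUnmatchedNull(list(c("a")), includeSelfPairs = FALSE),
               "at least 2")
})

test_that("null values equal the brute-force double loop", {
  profiles <- list(c("a", "b", "c"), c("b", "c", "d", "e"), c("x", "b"))
  null <- buildUnmatchedNull(profiles, includeSelfPairs = TRUE)
  brute <- c()
  for (i in 1:3) for (j in 1:3)
    brute <- c(brute, overlapPercent(profiles[[i]], profiles[[j]]))
  expect_equal(nullValues(null), brute)

  noSelf <- buildUnmatchedNull(profiles, includeSelfPairs = FALSE)
  brute2 <- c()
  for (i in 1:3) for (j in 1:3)
    if (i != j)
      brute2 <- c(brute2, overlapPercent(profiles[[i]], profiles[[j]]))
  expect_equal(nullValues(noSelf), brute2)
})

test_that("matched-vs-null comparison reports direction and exact p-values", {
  null <- new("OverlapNull", values = c(1, 2, 3, 0, 5), n_pairs = 5L,
              includes_self_pairs = FALSE)
  res <- compareMatchedVsNull(c(90, 80, 85), null)
  expect_equal(res$p.value,
               oracleRankSumP(c(90, 80, 85), c(1, 2, 3, 0, 5)))
  expect_equal(res$direction, "matched > null")

  idr <- compareMatchedVsNull(c(10, 20, 30), c(10, 20, 30))
  expect_equal(idr$p.value, 1)

  expect_warning(tied <- compareMatchedVsNull(c(5, 5), c(5, 5, 5)),
                 "tie")
  expect_equal(tied$p.value, 1)
})

test_that("adding a shared mutation never decreases percent public", {
  set.seed(20)
  for (i in 1:25) {
    a <- paste0("m", sample(50, sample(3:20, 1)))
    b <- paste0("m", sample(50, sample(3:20, 1)))
    before <- classifyPrivatePublic(a, b)$percent_public
    new <- paste0("new", i)
    after <- classifyPrivatePublic(c(a, new), c(b, new))$percent_public
    expect_gte(after, before)
  }
})
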