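test_that("promoter summaries average qualifying probes only", {
  beta <- matrix(c(0.42, 0.2, 0.4, 0.9), 4, 1,
                 dimnames = list(c("cg1", "cg2", "cg3", "cg4"), "S1"))
  ann <- data.frame(
    probe = c("cg1", "cg2", "cg3", "cg4"),
    gene_symbol = c("A", "B", "B", "B"),
    region_class = c("TSS200", "TSS1500", "1stExon", "other")
  )
  s <- summarisePromoters(beta, ann)
  expect_equal(s$mean_beta[s$gene_symbol == "A"], 0.42)
  expect_equal(s$median_beta[s$gene_symbol == "A"], 0.42)
  ## the "other" probe (0.9) never contributes
  expect_equal(s$mean_beta[s$gene_symbol == "B"], 0.3)
  expect_equal(s$median_beta[s$gene_symbol == "B"], 0.3)
  expect_equal(s$n_probes[s$gene_symbol == "B"], 2L)
})

test_that("other-only genes are omitted, unannotated probes counted", {
  beta <- matrix(runif(6), 3, 2,
                 dimnames = list(c("cg1", "cg2", "cgX"), c("S1", "S2")))
  ann <- data.frame(probe = c("cg1", "cg2"),
                    gene_symbol = c("A", "B"),
                    region_class = c("other", "TSS200"))
  s <- summarisePromoters(beta, ann)
  expect_false("A" %in% s$gene_symbol)
  expect_true("B" %in% s$gene_symbol)
  expect_equal(attr(s, "n_unannotated_probes"), 1L)
  expect_error(summarisePromoters(beta * 2, ann), "\\[0, 1\\]")
})

test_that("summaries are invariant to probe order; shared probes count twice", {
  set.seed(41)
  beta <- matrix(runif(20), 10, 2,
                 dimnames = list(paste0("cg", 1:10), c("S1", "S2")))
  ann <- data.frame(
    probe = c(paste0("cg", 1:10), "cg1"),     # cg1 maps to two genes
    gene_symbol = c(rep(c("A", "B"), each = 5), "B"),
    region_class = "TSS200"
  )
  s1 <- summarisePromoters(beta, ann)
  shuffle <- sample(10)
  s2 <- summarisePromoters(beta[shuffle, ], ann)
  expect_equal(s1[order(s1$sample, s1$gene_symbol), ],
               s2[order(s2$sample, s2$gene_symbol), ],
               ignore_attr = TRUE)
  expect_equal(s1$n_probes[s1$gene_symbol == "B"][1], 6L)
})

test_that("identical timepoints give all-zero shifts", {
  beta <- matrix(runif(12), 3, 4,
                 dimnames = list(paste0("cg", 1:3),
                                 c("P1_B", "P1_R", "P2_B", "P2_R")))
  beta[, "P1_R"] <- beta[, "P1_B"]
  beta[, "P2_R"] <- beta[, "P2_B"]
  ann <- data.frame(probe = paste0("cg", 1:3),
                    gene_symbol = c("A", "A", "B"),
                    region_class = c("TSS200", "1stExon", "TSS1500"))
  samples <- data.frame(
    sample = colnames(beta),
    patient = rep(c("P1", "P2"), each = 2),
    timepoint = rep(c("baseline", "recurrence"), 2),
    immune_group = rep("immunocompromised", 4)
  )
  res <- compareShifts(summarisePromoters(beta, ann), samples,
                       neoantigenGenes = "A")
  expect_true(all(res$shifts$shift == 0))
  expect_equal(res$overall$median_difference, 0)
})

test_that("the shift test is calibrated under the null and powered under shift", {
  runOnce <- function(seed, shift) {
    co <- simulateCohort(simulationConfig(n_patients = 3, seed = seed,
                                          ffpe_artifact_rate = 0))
    meth <- simulatePromoterMethylation(co, shift = shift, maxGenes = 120,
                                        seed = seed + 5000)
    summ <- summarisePromoters(meth$beta, meth$annotation)
    res <- compareShifts(summ, sampleMeta(co), meth$neoantigen_genes)
    res$overall$p.value
  }
  pNull <- vapply(1:60, runOnce, numeric(1), shift = 0)
  pShift <- vapply(1:60, function(i) runOnce(i + 200, shift = 1),
                   numeric(1))
  rateNull <- mean(pNull < 0.05)
  rateShift <- mean(pShift < 0.05)
  expect_lte(rateNull, 0.15)        # near-nominal under the null
  expect_gt(rateShift, rateNull)    # power grows with effect size
  expect_gte(rateShift, 0.6)
})
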