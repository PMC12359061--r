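test_that("invalid simulation configurations are rejected", {
  expect_error(simulationConfig(trunk_shared_fraction = 1.5), "trunk")
  expect_error(simulationConfig(ffpe_artifact_rate = -1), "non-negative")
  expect_error(simulationConfig(selection_coefficient_s = 1.2),
               "selection_coefficient_s")
  expect_error(simulationConfig(purity_range = c(0, 0.5)), "purity")
  expect_error(simulationConfig(mutations_per_sample_range = c(50, 10)),
               "interval")
})

test_that("coverage defaults are 100x tumour and 50x normal", {
  cfg <- simulationConfig()
  expect_equal(cfg@tumour_depth_mean, 100)
  expect_equal(cfg@normal_depth_mean, 50)
})

test_that("identical config and seed reproduce the cohort byte for byte", {
  cfg <- simulationConfig(n_patients = 4, seed = 33)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(variantCalls(a), variantCalls(b))
  expect_identical(truthLabels(a), truthLabels(b))
  expect_identical(segmentTable(a), segmentTable(b))
  expect_identical(sampleMeta(a), sampleMeta(b))
})

test_that("observed VAF matches the CCF/purity/copy-number expectation", {
  ## clonal mutations, purity 0.5, diploid, m = 1: expected VAF 0.25
  cfg <- simulationConfig(
    n_patients = 50, trunk_shared_fraction = 1,
    shared_subclone_fraction = 0,
    mutations_per_sample_range = c(100L, 100L),
    purity_range = c(0.5, 0.5), cn_profile = "diploid",
    ffpe_artifact_rate = 0, seed = 101
  )
  v <- variantCalls(simulateCohort(cfg))
  expect_gte(nrow(v), 9900)
  expect_lt(abs(mean(v$vaf) - expectedVaf(1, 0.5, 1, 2, 2)), 0.005)
})

test_that("full trunk sharing yields 100% public mutations per patient", {
  cfg <- simulationConfig(
    n_patients = 5, trunk_shared_fraction = 1,
    shared_subclone_fraction = 0,
    mutations_per_sample_range = c(100L, 100L),
    purity_range = c(0.9, 0.9), tumour_depth_mean = 250,
    cn_profile = "diploid", ffpe_artifact_rate = 0, seed = 7
  )
  ds <- divergenceSummary(simulateCohort(cfg))
  expect_equal(ds$percent_public, rep(100, 5))
})

test_that("artefact injection is Poisson with the configured rate, C>T/G>A only", {
  co <- simulateCohort(simulationConfig(n_patients = 1, seed = 12,
                                        ffpe_artifact_rate = 0))
  v <- variantCalls(co)
  one <- v[v$sample == v$sample[1], ]

  out0 <- injectFfpeArtifacts(one, rate = 0)
  expect_identical(out0$variants, one)
  expect_equal(nrow(out0$artifact_truth), 0L)

  counts <- vapply(seq_len(200), function(i) {
    nrow(injectFfpeArtifacts(one, rate = 20, seed = i)$artifact_truth)
  }, numeric(1))
  se <- sqrt(20 / 200)
  expect_lt(abs(mean(counts) - 20), 3 * se)

  out <- injectFfpeArtifacts(one, rate = 50, seed = 4)
  art <- out$artifact_truth
  expect_true(all((art$ref == "C" & art$alt == "T") |
                    (art$ref == "G" & art$alt == "A")))
  expect_true(all(out$variants$t_alt_count >= 1))
})

test_that("truth artefact flags exactly partition injected and original calls", {
  co <- simulateCohort(simulationConfig(n_patients = 3, seed = 21,
                                        ffpe_artifact_rate = 15))
  tr <- truthLabels(co)
  v <- variantCalls(co)
  artKeys <- paste(tr$patient, tr$mutation_id)[tr$is_artifact]
  cloneKeys <- paste(tr$patient, tr$mutation_id)[!tr$is_artifact]
  expect_length(intersect(artKeys, cloneKeys), 0L)
  expect_true(all(paste(v$patient, mutationKey(v)) %in%
                    c(artKeys, cloneKeys)))
  ## artefacts carry no clone membership
  expect_true(all(is.na(tr$clone_id[tr$is_artifact])))
})

test_that("immunoediting selection scales neoantigen recurrence CCFs by 1 - s", {
  co <- simulateCohort(simulationConfig(n_patients = 4, seed = 5,
                                        ffpe_artifact_rate = 0))
  tr0 <- truthLabels(co)

  expect_identical(truthLabels(applyImmunoediting(co, 0)), tr0)
  expect_error(applyImmunoediting(co, 1.5), "\\[0, 1\\]")

  tr1 <- truthLabels(applyImmunoediting(co, 1, seed = 1))
  expect_true(all(tr1$ccf_recurrence[tr1$is_neoantigen] == 0))
  expect_identical(tr1$ccf_recurrence[!tr1$is_neoantigen],
                   tr0$ccf_recurrence[!tr0$is_neoantigen])

  ## analytic expectation at s = 0.5 on truth deltas
  big <- simulateCohort(simulationConfig(
    n_patients = 40, seed = 6, ffpe_artifact_rate = 0,
    neoantigen_fraction = 0.3, selection_coefficient_s = 0.5
  ))
  tr <- truthLabels(big)
  dNeo <- tr$ccf_recurrence[tr$is_neoantigen] -
    tr$ccf_baseline[tr$is_neoantigen]
  dOther <- tr$ccf_recurrence[!tr$is_neoantigen] -
    tr$ccf_baseline[!tr$is_neoantigen]
  expected <- -0.5 * mean(tr$ccf_baseline[tr$is_neoantigen])
  expect_lt(abs((mean(dNeo) - mean(dOther)) - expected), 0.05)
})

test_that("simulated promoter betas are bounded and reproducible", {
  co <- simulateCohort(simulationConfig(n_patients = 3, seed = 8))
  m1 <- simulatePromoterMethylation(co, seed = 99)
  m2 <- simulatePromoterMethylation(co, seed = 99)
  expect_identical(m1$beta, m2$beta)
  expect_true(all(m1$beta >= 0 & m1$beta <= 1))
  expect_true(all(m1$annotation$region_class %in%
                    c("TSS200", "TSS1500", "1stExon", "other")))
  expect_error(simulatePromoterMethylation(co, probeClasses = "Body"),
               "unknown probe classes")
})
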