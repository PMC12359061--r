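test_that("MAF-style tables are read with VAF recomputed from counts", {
  v <- makeVariants(c(0.10, 0.30))
  v$vaf <- c(0.5, 0.5)  # stale values must be recomputed
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- readVariantTable(path, "maf_tsv")
  expect_equal(got$vaf, c(0.10, 0.30))
  expect_equal(got$t_alt_count, c(10L, 30L))
})

test_that("missing required columns and malformed rows are reported", {
  v <- makeVariants(c(0.2, 0.3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(v[, setdiff(names(v), "t_alt_count")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readVariantTable(path, "maf_tsv"), "t_alt_count")

  v2 <- makeVariants(c(0.2, 0.3, 0.4))
  v2$pos[2] <- -5L
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(v2, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(got <- readVariantTable(path2, "maf_tsv"), "line 3")
  expect_equal(nrow(got), 2L)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_warning(got <- readVariantTable(empty, "maf_tsv"), "empty")
  expect_equal(nrow(got), 0L)
})

test_that("VCF records are split per allele with VAF from AD", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeTestVcf(path)
  v <- readVariantTable(path, "vcf", patient = "P1", sample = "S1")
  expect_equal(nrow(v), 4L)  # one multi-allelic record split in two
  expect_equal(v$vaf[v$pos == 100], 0.20)
  expect_equal(sort(v$alt[v$pos == 200]), c("G", "T"))
  expect_equal(v$vaf[v$pos == 200 & v$alt == "T"], 30 / 90,
               tolerance = 1e-6)
  expect_equal(v$filter_flags[v$pos == 300], "ffpe_artifact")
})

test_that("the 10% VAF boundary is strict-below", {
  v <- makeVariants(c(0.09, 0.10, 0.50))
  out <- applyArtifactFilters(v, vafThreshold = 0.10)
  expect_equal(out$variants$vaf, c(0.10, 0.50))
  expect_equal(out$report@n_removed_vaf, 1L)
  expect_equal(retentionRate(out$report), 2 / 3)
})

test_that("signature stage precedes the VAF stage and counts reconcile", {
  v <- rbind(
    makeVariants(0.04, ref = "C", alt = "T"),   # signature (flag-less path)
    makeVariants(0.04, ref = "A", alt = "T"),   # VAF only
    makeVariants(0.30, ref = "C", alt = "T"),   # retained
    makeVariants(0.30, ref = "A", alt = "G")    # retained
  )
  out <- applyArtifactFilters(v)
  expect_equal(out$report@n_removed_signature, 1L)
  expect_equal(out$report@n_removed_vaf, 1L)
  expect_equal(out$report@n_retained, 2L)
  expect_equal(out$report@n_input, 4L)

  ## with caller flags present, the signature stage uses them instead
  vf <- rbind(
    makeVariants(0.30, ref = "C", alt = "T", flags = "ffpe_artifact"),
    makeVariants(0.30, ref = "C", alt = "T"),
    makeVariants(0.30, ref = "G", alt = "A", flags = "orientation_bias")
  )
  outf <- applyArtifactFilters(vf)
  expect_equal(outf$report@n_removed_signature, 2L)
  expect_equal(outf$report@n_retained, 1L)

  ## switched off entirely
  expect_equal(
    applyArtifactFilters(vf, signatureFilter = FALSE)$report@n_retained, 3L)
})

test_that("raising the VAF threshold never increases the retained count", {
  co <- simulateCohort(simulationConfig(n_patients = 3, seed = 13))
  v <- variantCalls(co)
  retained <- vapply(seq(0, 0.4, by = 0.02), function(thr) {
    applyArtifactFilters(v, vafThreshold = thr)$report@n_retained
  }, integer(1))
  expect_true(all(diff(retained) <= 0L))
})

test_that("filtering is idempotent at fixed settings", {
  co <- simulateCohort(simulationConfig(n_patients = 2, seed = 14))
  once <- applyArtifactFilters(variantCalls(co))
  twice <- applyArtifactFilters(once$variants)
  expect_equal(twice$report@n_removed_signature, 0L)
  expect_equal(twice$report@n_removed_vaf, 0L)
  expect_identical(twice$variants, once$variants)
})

test_that("retention rate handles the degenerate cases", {
  mk <- function(nin, nret) new("FilterReport", n_input = nin,
                                n_removed_signature = 0L,
                                n_removed_vaf = nin - nret,
                                n_retained = nret)
  expect_equal(retentionRate(mk(100L, 100L)), 1.0)
  expect_equal(retentionRate(mk(100L, 0L)), 0.0)
  expect_equal(retentionRate(mk(80L, 60L)), 0.75)
  expect_error(retentionRate(mk(0L, 0L)), "undefined")
  expect_error(new("FilterReport", n_input = 5L, n_removed_signature = 1L,
                   n_removed_vaf = 1L, n_retained = 1L), "reconcile")
})

test_that("the filter recovers most injected truth artefacts", {
  co <- simulateCohort(simulationConfig(n_patients = 10, seed = 15,
                                        ffpe_artifact_rate = 25))
  v <- variantCalls(co)
  tr <- truthLabels(co)
  out <- applyArtifactFilters(v)
  keptKeys <- paste(out$variants$sample, mutationKey(out$variants))
  art <- tr[tr$is_artifact, ]
  artKeys <- paste(art$artifact_sample, art$mutation_id)
  recall <- mean(!artKeys %in% keptKeys)
  expect_gte(recall, 0.8)
  ## artefacts drawn below the threshold are almost all recovered
  low <- artKeys[art$artifact_vaf_drawn < 0.10]
  expect_gte(mean(!low %in% keptKeys), 0.9)
})
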