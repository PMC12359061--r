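## Synthetic paired-tumour cohort generator.
##
## The generator uses a flat clone model (CCF clusters, no phylogeny): each
## patient carries a truncal clone at CCF 1 in both samples, one shared
## subclone with independent CCFs at the two timepoints, and
## timepoint-private clones. Private mutations are truly absent (CCF 0) at
## the other timepoint, not merely undetected. Copy-number profiles are
## drawn per patient and shared across timepoints so that a mutation keeps
## one multiplicity.

.CLASS_PROBS <- c(
  missense = 0.55, silent = 0.20, nonsense = 0.06, frameshift_del = 0.05,
  frameshift_ins = 0.04, in_frame_indel = 0.03, splice = 0.04,
  nonstop = 0.01, other = 0.02
)

.LOF_CLASSES <- c("nonsense", "frameshift_ins", "frameshift_del",
                  "in_frame_indel", "nonstop")

## copy-number states as (major, minor) with sampling weights
.CN_STATES <- list(c(1L, 1L), c(2L, 1L), c(2L, 2L), c(3L, 1L), c(1L, 0L))
.CN_WEIGHTS <- c(0.70, 0.12, 0.08, 0.05, 0.05)

.GENE_POOL_SIZE <- 2000L
.EVASION_GENE_PROB <- 0.03

## depth with a floor of 10 reads (failed loci are re-captured in practice)
.drawDepth <- function(n, mean) pmax(10L, rpois(n, mean))

## uniform draw from an integer interval, safe for degenerate intervals
.sampleRange <- function(range, n = 1L) {
  if (range[1] == range[2]) rep(range[1], n) else
    sample(range[1]:range[2], n, replace = TRUE)
}

## one patient's clone structure, mutation attributes and truth CCFs
.simulatePatient <- function(pid, config, catalogGenes) {
  mr <- config@mutations_per_sample_range
  kr <- config@clones_per_sample_range
  m_b <- .sampleRange(mr)
  m_r <- .sampleRange(mr)
  nShared <- as.integer(round(config@trunk_shared_fraction * min(m_b, m_r)))
  nPrivB <- m_b - nShared
  nPrivR <- m_r - nShared
  kB <- .sampleRange(kr)
  kR <- .sampleRange(kr)

  ## clone table: truncal, shared subclone, then private clones
  cloneId <- c("truncal", "shared_sub")
  ccfB <- c(1, runif(1, 0.2, 0.9))
  ccfR <- c(1, runif(1, 0.2, 0.9))
  nClB <- max(kB - 2L, 1L)
  nClR <- max(kR - 2L, 1L)
  cloneId <- c(cloneId, sprintf("base_priv_%d", seq_len(nClB)),
               sprintf("rec_priv_%d", seq_len(nClR)))
  ccfB <- c(ccfB, runif(nClB, 0.1, 0.9), rep(0, nClR))
  ccfR <- c(ccfR, rep(0, nClB), runif(nClR, 0.1, 0.9))

  nTot <- nShared + nPrivB + nPrivR
  assign <- integer(nTot)
  if (nShared > 0)
    assign[seq_len(nShared)] <-
      ifelse(runif(nShared) < config@shared_subclone_fraction, 2L, 1L)
  if (nPrivB > 0)
    assign[nShared + seq_len(nPrivB)] <- 2L + sample.int(nClB, nPrivB,
                                                         replace = TRUE)
  if (nPrivR > 0)
    assign[nShared + nPrivB + seq_len(nPrivR)] <-
      2L + nClB + sample.int(nClR, nPrivR, replace = TRUE)

  ## per-patient copy-number profile (one segment per autosome)
  if (config@cn_profile == "diploid") {
    states <- rep(1L, 22L)
  } else {
    states <- sample.int(length(.CN_STATES), 22L, replace = TRUE,
                         prob = .CN_WEIGHTS)
  }
  majorCn <- vapply(.CN_STATES[states], `[`, integer(1), 1L)
  minorCn <- vapply(.CN_STATES[states], `[`, integer(1), 2L)

  ## mutation attributes
  chromIdx <- sample.int(22L, nTot, replace = TRUE)
  pos <- 1000000L + sample.int(240000000L, nTot)   # unique within patient
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nTot, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  useEvasion <- length(catalogGenes) > 0 & runif(nTot) < .EVASION_GENE_PROB
  gene <- sprintf("GENE%04d", sample.int(.GENE_POOL_SIZE, nTot,
                                         replace = TRUE))
  if (any(useEvasion))
    gene[useEvasion] <- sample(catalogGenes, sum(useEvasion), replace = TRUE)
  vclass <- sample(names(.CLASS_PROBS), nTot, replace = TRUE,
                   prob = .CLASS_PROBS)
  isNeo <- vclass != "silent" & runif(nTot) < config@neoantigen_fraction
  affinity <- ifelse(isNeo,
                     10^runif(nTot, log10(5), log10(500)),
                     10^runif(nTot, log10(600), 4.7))
  isEvasionLof <- gene %in% catalogGenes & vclass %in% .LOF_CLASSES

  ## multiplicity: mostly one mutant copy, occasionally on the amplified allele
  major <- majorCn[chromIdx]
  m <- rep(1L, nTot)
  amp <- major >= 2L & runif(nTot) > 0.75
  if (any(amp))
    m[amp] <- vapply(major[amp],
                     function(mc) sample(2:mc, 1L), integer(1))

  ## truth CCFs with immunoediting selection on recurrence neoantigens
  s <- config@selection_coefficient_s
  tB <- ccfB[assign]
  tR <- ccfR[assign]
  tR[isNeo] <- tR[isNeo] * (1 - s)

  purity <- runif(2, config@purity_range[1], config@purity_range[2])
  group <- if (pid <= round(2 / 3 * config@n_patients))
    "immunocompromised" else "immunocompetent"
  patient <- sprintf("P%02d", pid)
  sampleIds <- paste0(patient, c("_B", "_R"))

  cnt <- (majorCn + minorCn)[chromIdx]
  key <- mutationKey(chrom = as.character(chromIdx), pos = pos,
                     ref = ref, alt = alt)

  drawSample <- function(which) {
    ccf <- if (which == 1L) tB else tR
    present <- which(ccf > 0)
    if (!length(present)) return(NULL)
    depth <- .drawDepth(length(present), config@tumour_depth_mean)
    ev <- expectedVaf(ccf[present], purity[which], m[present], cnt[present])
    altReads <- rbinom(length(present), depth, ev)
    keep <- altReads > 0L
    if (config@detection_limit > 0)
      keep <- keep & altReads / depth >= config@detection_limit
    present <- present[keep]
    if (!length(present)) return(NULL)
    depth <- depth[keep]; altReads <- altReads[keep]
    data.frame(
      patient = patient, sample = sampleIds[which],
      timepoint = c("baseline", "recurrence")[which],
      chrom = as.character(chromIdx[present]), pos = pos[present],
      ref = ref[present], alt = alt[present],
      t_ref_count = depth - altReads, t_alt_count = altReads,
      vaf = altReads / depth,
      variant_classification = vclass[present],
      gene_symbol = gene[present], filter_flags = "",
      stringsAsFactors = FALSE
    )
  }

  variants <- rbind(drawSample(1L), drawSample(2L))

  segments <- data.frame(
    sample = rep(sampleIds, each = 22L),
    chrom = as.character(rep(1:22, 2L)),
    start = 1L, end = 250000000L,
    major_cn = rep(majorCn, 2L), minor_cn = rep(minorCn, 2L),
    normal_cn = 2L, stringsAsFactors = FALSE
  )

  samples <- data.frame(
    patient = patient, sample = sampleIds,
    timepoint = c("baseline", "recurrence"),
    purity = purity, ploidy = mean(majorCn + minorCn),
    immune_group = group, stringsAsFactors = FALSE
  )

  truth <- data.frame(
    patient = patient, mutation_id = key,
    chrom = as.character(chromIdx), pos = pos, ref = ref, alt = alt,
    gene_symbol = gene, variant_classification = vclass,
    clone_id = cloneId[assign], multiplicity = m,
    ccf_baseline = tB, ccf_recurrence = tR,
    is_artifact = FALSE, is_neoantigen = isNeo,
    is_evasion_lof = isEvasionLof,
    affinity_nm = affinity, stringent_pass = isNeo,
    artifact_sample = NA_character_,
    artifact_vaf_drawn = NA_real_, stringsAsFactors = FALSE
  )

  list(variants = variants, segments = segments, samples = samples,
       truth = truth)
}

## artefact rows for one sample; returns NULL or list(variants, truth)
.drawArtifactRows <- function(patient, sampleId, timepoint, n, config) {
  if (n < 1L) return(NULL)
  shp <- config@artifact_vaf_beta_params
  vafTrue <- rbeta(n, shp[1], shp[2])
  depth <- .drawDepth(n, config@tumour_depth_mean)
  altReads <- pmax(1L, rbinom(n, depth, vafTrue))  # an artefact is a call
  ct <- runif(n) < 0.5
  ref <- ifelse(ct, "C", "G")
  alt <- ifelse(ct, "T", "A")
  chrom <- as.character(sample.int(22L, n, replace = TRUE))
  pos <- sample.int(250000000L, n)
  vclass <- sample(names(.CLASS_PROBS), n, replace = TRUE,
                   prob = .CLASS_PROBS)
  gene <- sprintf("GENE%04d", sample.int(.GENE_POOL_SIZE, n, replace = TRUE))
  key <- mutationKey(chrom = chrom, pos = pos, ref = ref, alt = alt)
  variants <- data.frame(
    patient = patient, sample = sampleId, timepoint = timepoint,
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    t_ref_count = depth - altReads, t_alt_count = altReads,
    vaf = altReads / depth, variant_classification = vclass,
    gene_symbol = gene, filter_flags = "", stringsAsFactors = FALSE
  )
  truth <- data.frame(
    patient = patient, mutation_id = key,
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene_symbol = gene, variant_classification = vclass,
    clone_id = NA_character_, multiplicity = 1L,
    ccf_baseline = 0, ccf_recurrence = 0,
    is_artifact = TRUE, is_neoantigen = FALSE, is_evasion_lof = FALSE,
    affinity_nm = NA_real_, stringent_pass = FALSE,
    artifact_sample = sampleId,
    artifact_vaf_drawn = vafTrue, stringsAsFactors = FALSE
  )
  list(variants = variants, truth = truth)
}

#' Simulate a paired baseline/recurrence tumour cohort with known truth
#'
#' Generates, per patient, a baseline and a recurrence somatic variant
#' profile from a flat clone model: a truncal clone (CCF 1 at both
#' timepoints), a shared subclone with independent CCFs, and
#' timepoint-private clones. The fraction of mutations shared between
#' timepoints is governed by `trunk_shared_fraction`. Observed alt read
#' counts are drawn as `Binomial(depth, expectedVaf(ccf, purity, m, CNt))`
#' with depths Poisson around the configured means (floored at 10 reads);
#' mutations whose draws yield zero alt reads are not emitted (they were
#' not called). FFPE artefacts (low-VAF C>T/G>A calls) are injected at the
#' configured Poisson rate, and immunoediting selection scales recurrence
#' CCFs of neoantigen mutations by `1 - s` before read sampling.
#'
#' @param config a [SimulationConfig-class].
#' @return a [ClonalCohort-class] with truth labels.
#' @examples
#' cohort <- simulateCohort(simulationConfig(n_patients = 3, seed = 11))
#' cohort
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  catal <- catalogGenes(readEvasionCatalog())
  P <- config@n_patients
  parts <- vector("list", P)
  for (p in seq_len(P))
    parts[[p]] <- .simulatePatient(p, config, catal)

  variants <- do.call(rbind, lapply(parts, `[[`, "variants"))
  segments <- do.call(rbind, lapply(parts, `[[`, "segments"))
  samples <- do.call(rbind, lapply(parts, `[[`, "samples"))
  truth <- do.call(rbind, lapply(parts, `[[`, "truth"))

  if (config@ffpe_artifact_rate > 0) {
    counts <- rpois(nrow(samples), config@ffpe_artifact_rate)
    art <- vector("list", nrow(samples))
    for (i in seq_len(nrow(samples)))
      art[[i]] <- .drawArtifactRows(samples$patient[i], samples$sample[i],
                                    samples$timepoint[i], counts[i], config)
    art <- art[!vapply(art, is.null, logical(1))]
    if (length(art)) {
      variants <- rbind(variants, do.call(rbind, lapply(art, `[[`, "variants")))
      truth <- rbind(truth, do.call(rbind, lapply(art, `[[`, "truth")))
    }
  }
  rownames(variants) <- rownames(segments) <- NULL
  rownames(samples) <- rownames(truth) <- NULL
  new("ClonalCohort", variants = variants, segments = segments,
      samples = samples, truth = truth, config = config)
}

#' Inject FFPE deamination artefacts into a variant profile
#'
#' Adds `Poisson(rate)` artefactual calls to one sample's variant table.
#' Artefacts are C>T (or G>A) substitutions whose underlying VAF is drawn
#' from a low-VAF Beta distribution, emulating formalin-induced cytosine
#' deamination; read counts are then sampled binomially at the given mean
#' depth (at least one alt read, since an artefact is by definition a
#' call that was made). The truth of which rows were injected is returned
#' separately rather than written into the variant table, so that
#' downstream filters cannot see it.
#'
#' @param variants a variant `data.frame` for a single sample (the
#'   canonical MAF-like columns; see [variantCalls()]).
#' @param rate expected artefact count (Poisson rate, must be >= 0).
#' @param vafShape Beta shape1/shape2 for artefact VAFs.
#' @param depthMean mean sequencing depth for the artefact loci.
#' @param seed optional integer seed.
#' @return list with `variants` (input rows plus injected rows) and
#'   `artifact_truth` (truth rows for the injected artefacts; zero rows
#'   when `rate` is 0 or no artefact was drawn).
#' @examples
#' cohort <- simulateCohort(simulationConfig(n_patients = 1, seed = 2,
#'                                           ffpe_artifact_rate = 0))
#' v <- variantCalls(cohort)
#' one <- v[v$sample == v$sample[1], ]
#' out <- injectFfpeArtifacts(one, rate = 5, seed = 3)
#' nrow(out$artifact_truth)
#' @export
injectFfpeArtifacts <- function(variants, rate, vafShape = c(1.5, 30),
                                depthMean = 100, seed = NULL) {
  if (rate < 0) stop("artefact rate must be non-negative")
  stopifnot(all(.VARIANT_COLUMNS %in% names(variants)))
  if (!is.null(seed)) set.seed(seed)
  sampleId <- unique(variants$sample)
  if (length(sampleId) != 1L)
    stop("injectFfpeArtifacts expects a single-sample variant table")
  cfg <- simulationConfig(artifact_vaf_beta_params = vafShape,
                          tumour_depth_mean = depthMean)
  n <- if (rate > 0) rpois(1L, rate) else 0L
  rows <- .drawArtifactRows(variants$patient[1], sampleId,
                            variants$timepoint[1], n, cfg)
  if (is.null(rows))
    return(list(variants = variants,
                artifact_truth = .emptyArtifactTruth()))
  out <- rbind(variants, rows$variants)
  rownames(out) <- NULL
  list(variants = out, artifact_truth = rows$truth)
}

.emptyArtifactTruth <- function() {
  data.frame(
    patient = character(), mutation_id = character(), chrom = character(),
    pos = integer(), ref = character(), alt = character(),
    gene_symbol = character(), variant_classification = character(),
    clone_id = character(), multiplicity = integer(),
    ccf_baseline = numeric(), ccf_recurrence = numeric(),
    is_artifact = logical(), is_neoantigen = logical(),
    is_evasion_lof = logical(), affinity_nm = numeric(),
    stringent_pass = logical(), artifact_sample = character(),
    artifact_vaf_drawn = numeric(), stringsAsFactors = FALSE
  )
}

#' Apply immunoediting selection to a simulated cohort
#'
#' Multiplies the recurrence truth CCF of every (non-artefact) neoantigen
#' mutation by `1 - s` and re-draws the recurrence samples' read counts
#' from the edited truth. `s = 0` leaves the truth untouched (the
#' immune-escape null); `s = 1` eliminates all neoantigen mutations from
#' the recurrence.
#'
#' @param cohort a simulated [ClonalCohort-class] with truth labels.
#' @param s selection coefficient in `[0, 1]`.
#' @param seed optional seed for the read re-draw.
#' @return the edited `ClonalCohort`.
#' @export
applyImmunoediting <- function(cohort, s, seed = NULL) {
  stopifnot(is(cohort, "ClonalCohort"))
  if (!is.finite(s) || s < 0 || s > 1)
    stop("selection coefficient s must lie in [0, 1]")
  truth <- truthLabels(cohort)
  if (!nrow(truth))
    stop("applyImmunoediting requires a cohort with truth labels")
  if (!is.null(seed)) set.seed(seed)
  edit <- truth$is_neoantigen & !truth$is_artifact
  truth$ccf_recurrence[edit] <- truth$ccf_recurrence[edit] * (1 - s)
  if (s == 0) {
    cohort@truth <- truth
    return(cohort)
  }

  config <- cohort@config
  samples <- sampleMeta(cohort)
  segs <- segmentTable(cohort)
  variants <- variantCalls(cohort)
  variants <- variants[variants$timepoint != "recurrence", , drop = FALSE]

  recSamples <- samples[samples$timepoint == "recurrence", , drop = FALSE]
  newRows <- vector("list", nrow(recSamples))
  for (i in seq_len(nrow(recSamples))) {
    sm <- recSamples[i, ]
    tr <- truth[truth$patient == sm$patient & !truth$is_artifact &
                  truth$ccf_recurrence > 0, , drop = FALSE]
    if (!nrow(tr)) next
    seg <- segs[segs$sample == sm$sample, , drop = FALSE]
    cnt <- (seg$major_cn + seg$minor_cn)[match(tr$chrom, seg$chrom)]
    cnt[is.na(cnt)] <- 2L
    depth <- .drawDepth(nrow(tr), config@tumour_depth_mean)
    ev <- expectedVaf(tr$ccf_recurrence, sm$purity, tr$multiplicity, cnt)
    altReads <- rbinom(nrow(tr), depth, ev)
    ok <- altReads > 0L
    if (config@detection_limit > 0)
      ok <- ok & altReads / depth >= config@detection_limit
    if (!any(ok)) next
    newRows[[i]] <- data.frame(
      patient = sm$patient, sample = sm$sample, timepoint = "recurrence",
      chrom = tr$chrom[ok], pos = tr$pos[ok], ref = tr$ref[ok],
      alt = tr$alt[ok], t_ref_count = depth[ok] - altReads[ok],
      t_alt_count = altReads[ok], vaf = altReads[ok] / depth[ok],
      variant_classification = tr$variant_classification[ok],
      gene_symbol = tr$gene_symbol[ok], filter_flags = "",
      stringsAsFactors = FALSE
    )
  }
  ## re-inject this sample's artefacts unchanged (they are fixation events,
  ## not tumour cells, and are unaffected by selection)
  artRows <- variantCalls(cohort)
  artKeys <- truth$mutation_id[truth$is_artifact &
                                 !is.na(truth$artifact_sample)]
  artRows <- artRows[artRows$timepoint == "recurrence" &
                       mutationKey(artRows) %in% artKeys, , drop = FALSE]
  variants <- rbind(variants, do.call(rbind, newRows), artRows)
  rownames(variants) <- NULL
  cohort@variants <- variants
  cohort@truth <- truth
  validObject(cohort)
  cohort
}

#' Simulate promoter methylation beta values for a cohort
#'
#' Emulates an Illumina-style array restricted to a gene panel drawn from
#' the cohort's mutated genes: each gene gets a handful of probes whose
#' region classes are drawn from the upstream regulatory designations
#' (TSS200, TSS1500, 1stExon) plus gene-body/"other" probes, and beta
#' values are logit-normal around a per-gene baseline. An optional
#' `shift` (logit scale) hypermethylates neoantigen-bearing genes in
#' recurrence samples, for power testing of [compareShifts()]; `shift = 0`
#' is the calibration null.
#'
#' @param cohort a simulated [ClonalCohort-class].
#' @param probeClasses classes probes are drawn from.
#' @param probesPerGeneRange integer range of probes per gene.
#' @param shift logit-scale methylation shift applied to neoantigen genes
#'   in recurrence samples.
#' @param maxGenes cap on the gene panel size.
#' @param seed optional integer seed.
#' @return list with `beta` (probes x samples matrix in `[0, 1]`),
#'   `annotation` (probe, gene_symbol, region_class) and
#'   `neoantigen_genes` (character; genes carrying a stringent-pass
#'   neoantigen mutation in truth).
#' @export
simulatePromoterMethylation <- function(cohort,
                                        probeClasses = c("TSS200", "TSS1500",
                                                         "1stExon", "other"),
                                        probesPerGeneRange = c(2L, 6L),
                                        shift = 0,
                                        maxGenes = 300L,
                                        seed = NULL) {
  stopifnot(is(cohort, "ClonalCohort"))
  bad <- setdiff(probeClasses, c("TSS200", "TSS1500", "1stExon", "other"))
  if (length(bad))
    stop("unknown probe classes: ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  samples <- sampleMeta(cohort)
  genes <- sort(unique(variantCalls(cohort)$gene_symbol))
  if (length(genes) > maxGenes) genes <- genes[seq_len(maxGenes)]
  truth <- truthLabels(cohort)
  neoGenes <- if (nrow(truth))
    sort(unique(truth$gene_symbol[truth$stringent_pass %in% TRUE]))
  else character()

  nProbes <- .sampleRange(probesPerGeneRange, length(genes))
  gene <- rep(genes, nProbes)
  probe <- sprintf("cg%07d", seq_along(gene))
  regionClass <- sample(probeClasses, length(gene), replace = TRUE)
  annotation <- data.frame(probe = probe, gene_symbol = gene,
                           region_class = regionClass,
                           stringsAsFactors = FALSE)

  mu <- rbeta(length(genes), 2, 2)
  mu <- pmin(pmax(mu, 0.02), 0.98)
  geneLogit <- qlogis(mu)[match(gene, genes)]
  probeEff <- rnorm(length(gene), 0, 0.3)
  base <- geneLogit + probeEff

  beta <- matrix(NA_real_, nrow = length(gene), ncol = nrow(samples),
                 dimnames = list(probe, samples$sample))
  shiftGene <- gene %in% neoGenes
  for (j in seq_len(nrow(samples))) {
    eff <- base + rnorm(length(gene), 0, 0.2)
    if (shift != 0 && samples$timepoint[j] != "baseline")
      eff[shiftGene] <- eff[shiftGene] + shift
    beta[, j] <- plogis(eff)
  }
  list(beta = beta, annotation = annotation, neoantigen_genes = neoGenes)
}
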