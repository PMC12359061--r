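#' Assemble a run configuration for [runPipeline()]
#'
#' Precedence is caller arguments > file values > defaults: pass a YAML
#' file via `file` and override any field by naming it directly.
#'
#' @param file optional YAML file of fields (read with the yaml package
#'   when installed).
#' @param simulation a [SimulationConfig-class] for simulation mode, or
#'   `NULL` to read tables from `variants_path`/`segments_path`/
#'   `samples_path`.
#' @param variants_path,segments_path,samples_path input TSVs (ignored in
#'   simulation mode).
#' @param stages character subset of
#'   `c("simulate","filter","ccf","divergence","neoantigen","evasion",
#'   "methylation")`; later stages reuse earlier stages' outputs.
#' @param out_dir output directory; each run gets a fresh versioned
#'   subdirectory (`run-001`, `run-002`, ...) so reruns never overwrite.
#' @param seed integer seed governing every stochastic step.
#' @param vaf_threshold,signature_filter filter settings.
#' @param strong_nm,weak_nm binder tier boundaries (nM).
#' @param alpha nominal test level recorded in the summary.
#' @return a named list (class `"runConfig"`).
#' @export
runConfig <- function(file = NULL,
                      simulation = simulationConfig(),
                      variants_path = NULL, segments_path = NULL,
                      samples_path = NULL,
                      stages = c("simulate", "filter", "ccf", "divergence",
                                 "neoantigen", "evasion", "methylation"),
                      out_dir = tempfile("clonal_divergence_run_"),
                      seed = 1L,
                      vaf_threshold = 0.10, signature_filter = TRUE,
                      strong_nm = 100, weak_nm = 500, alpha = 0.05) {
  cfg <- list(simulation = simulation, variants_path = variants_path,
              segments_path = segments_path, samples_path = samples_path,
              stages = stages, out_dir = out_dir, seed = as.integer(seed),
              vaf_threshold = vaf_threshold,
              signature_filter = signature_filter,
              strong_nm = strong_nm, weak_nm = weak_nm, alpha = alpha)
  if (!is.null(file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the yaml package")
    fromFile <- yaml::read_yaml(file)
    given <- names(as.list(match.call()))[-1]
    for (nm in setdiff(intersect(names(fromFile), names(cfg)), given))
      cfg[[nm]] <- fromFile[[nm]]
  }
  known <- c("simulate", "filter", "ccf", "divergence", "neoantigen",
             "evasion", "methylation")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$simulation) &&
      any(c("simulate") %in% cfg$stages))
    stop("the simulate stage requires a simulation config")
  if (is.null(cfg$simulation)) {
    for (p in c("variants_path", "segments_path", "samples_path"))
      if (is.null(cfg[[p]]) || !file.exists(cfg[[p]]))
        stop("with simulation off, ", p, " must point to an existing file")
  }
  class(cfg) <- "runConfig"
  cfg
}

.nextRunDir <- function(outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  existing <- list.dirs(outDir, recursive = FALSE, full.names = FALSE)
  n <- suppressWarnings(max(0L,
    as.integer(sub("^run-", "", grep("^run-\\d+$", existing, value = TRUE)))))
  runDir <- file.path(outDir, sprintf("run-%03d", n + 1L))
  dir.create(runDir)
  runDir
}

.logStage <- function(stage, ...) {
  message(sprintf("[%s] stage=%s %s",
                  format(Sys.time(), "%H:%M:%S"), stage,
                  paste(..., collapse = " ")))
}

#' Run the full paired-tumour divergence pipeline
#'
#' Orchestrates simulate -> filter -> CCF/clonality -> divergence ->
#' neoantigen dynamics -> immune evasion -> methylation from a single
#' [runConfig()]. Each stage writes its tables (TSV) and test results
#' (JSON) into a fresh versioned run directory together with a manifest
#' (package version, seed, config hash) and a human-readable summary.
#' The run is deterministic given the seed; any stage error aborts the
#' downstream stages.
#'
#' @param config a [runConfig()] list (or a [SimulationConfig-class],
#'   taken as a simulation-mode run with default settings).
#' @return (invisibly) list with `run_dir`, `manifest`, and the per-stage
#'   result objects.
#' @examples
#' \donttest{
#' cfg <- runConfig(simulation = simulationConfig(n_patients = 3, seed = 2),
#'                  stages = c("simulate", "filter"))
#' res <- runPipeline(cfg)
#' list.files(res$run_dir)
#' }
#' @export
runPipeline <- function(config) {
  if (is(config, "SimulationConfig"))
    config <- runConfig(simulation = config)
  stopifnot(inherits(config, "runConfig"))
  runDir <- .nextRunDir(config$out_dir)
  set.seed(config$seed)
  results <- list()
  on <- function(stage) stage %in% config$stages

  ## ---- inputs -----------------------------------------------------------
  if (on("simulate")) {
    .logStage("simulate", "seed =", config$seed)
    sim <- config$simulation
    sim@seed <- config$seed
    cohort <- simulateCohort(sim)
    .writeTsv(variantCalls(cohort), file.path(runDir, "variants.tsv"))
    .writeTsv(segmentTable(cohort), file.path(runDir, "segments.tsv"))
    .writeTsv(sampleMeta(cohort), file.path(runDir, "samples.tsv"))
    .writeTsv(truthLabels(cohort), file.path(runDir, "truth.tsv"))
    variants <- variantCalls(cohort)
    segments <- segmentTable(cohort)
    samples <- sampleMeta(cohort)
    results$cohort <- cohort
  } else if (any(c("filter", "ccf", "divergence", "neoantigen",
                   "evasion", "methylation") %in% config$stages)) {
    variants <- readVariantTable(config$variants_path, "maf_tsv")
    segments <- read.delim(config$segments_path, stringsAsFactors = FALSE)
    segments$chrom <- as.character(segments$chrom)
    samples <- read.delim(config$samples_path, stringsAsFactors = FALSE)
    cohort <- NULL
  } else {
    variants <- NULL; cohort <- NULL
  }

  ## ---- filter -----------------------------------------------------------
  if (on("filter")) {
    flt <- applyArtifactFilters(variants,
                                vafThreshold = config$vaf_threshold,
                                signatureFilter = config$signature_filter)
    .logStage("filter", sprintf("in=%d retained=%d",
                                flt$report@n_input, flt$report@n_retained))
    variants <- flt$variants
    .writeTsv(variants, file.path(runDir, "variants_filtered.tsv"))
    .writeTsv(filterReportTable(flt$report),
              file.path(runDir, "filter_report.tsv"))
    jsonlite::write_json(filterReportTable(flt$report),
                         file.path(runDir, "filter_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    results$filter_report <- flt$report
  }

  ## ---- ccf / clonality --------------------------------------------------
  if (on("ccf")) {
    .logStage("ccf", "estimating CCFs and clustering clones")
    cc <- ccfTable(variants, segments, samples)
    .writeTsv(cc, file.path(runDir, "ccf_table.tsv"))
    clusterRows <- list(); scoreRows <- list()
    for (s in unique(cc$sample)) {
      sub <- cc[cc$sample == s & !cc$inconsistent, , drop = FALSE]
      if (!nrow(sub)) next
      cs <- clusterCcfs(NULL, NULL, ccf = sub)
      cl <- cloneClusters(cs)
      cl$sample <- s
      clusterRows[[s]] <- cl
      scoreRows[[s]] <- data.frame(
        sample = s,
        patient = samples$patient[match(s, samples$sample)],
        timepoint = samples$timepoint[match(s, samples$sample)],
        immune_group = if ("immune_group" %in% names(samples))
          samples$immune_group[match(s, samples$sample)] else NA,
        score = clonalityScore(sub$ccf),
        score_clusterwise = clonalityScore(cs),
        n_clusters = nClusters(cs),
        stringsAsFactors = FALSE
      )
    }
    clusters <- do.call(rbind, clusterRows)
    scores <- do.call(rbind, scoreRows)
    rownames(clusters) <- rownames(scores) <- NULL
    .writeTsv(clusters, file.path(runDir, "clone_clusters.tsv"))
    .writeTsv(scores, file.path(runDir, "clonality_scores.tsv"))
    dc <- tryCatch(deltaClonality(scores), warning = function(w) {
      suppressWarnings(deltaClonality(scores))
    })
    jsonlite::write_json(
      list(deltas = dc$deltas,
           group_test = if (!is.null(dc$group_test))
             dc$group_test[c("statistic", "p.value", "alternative")]),
      file.path(runDir, "delta_clonality.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    results$ccf <- cc; results$scores <- scores
    results$delta_clonality <- dc
  }

  ## ---- divergence -------------------------------------------------------
  if (on("divergence")) {
    .logStage("divergence", "private/public + unmatched null")
    ds <- divergenceSummary(variants)
    .writeTsv(ds, file.path(runDir, "divergence_summary.tsv"))
    keys <- mutationKey(variants)
    profiles <- split(keys, variants$sample)
    profiles <- profiles[lengths(profiles) > 0]
    null <- buildUnmatchedNull(unname(profiles))
    .writeTsv(data.frame(overlap_percent = nullValues(null)),
              file.path(runDir, "unmatched_null.tsv"))
    cmp <- compareMatchedVsNull(ds$overlap_baseline_denom, null)
    jsonlite::write_json(cmp, file.path(runDir, "matched_vs_null.json"),
                         auto_unbox = TRUE, digits = NA)
    results$divergence <- ds; results$null_test <- cmp
  }

  ## ---- neoantigen dynamics ---------------------------------------------
  if (on("neoantigen")) {
    if (!on("ccf")) stop("the neoantigen stage requires the ccf stage")
    .logStage("neoantigen", "delta-CCF dynamics")
    cc <- results$ccf
    recs <- list()
    for (p in unique(cc$patient)) {
      b <- cc[cc$patient == p & cc$timepoint == "baseline", ]
      r <- cc[cc$patient == p & cc$timepoint == "recurrence", ]
      if (!nrow(b) || !nrow(r)) next
      d <- computeDeltaCcf(b, r)
      d$patient <- p
      recs[[p]] <- d
    }
    recs <- do.call(rbind, recs)
    if (!is.null(cohort) && nrow(truthLabels(cohort))) {
      ann <- neoantigenAnnotations(cohort)
      ann <- classifyBinders(ann)
      idx <- match(paste(recs$patient, recs$mutation_id),
                   paste(ann$patient, ann$mutation_id))
      recs$is_neoantigen <- !is.na(idx) & ann$stringent_pass[idx]
      recs$tier <- ifelse(is.na(idx), "unknown", ann$tier[idx])
    } else {
      recs$is_neoantigen <- FALSE
      recs$tier <- "unknown"
    }
    rownames(recs) <- NULL
    .writeTsv(recs, file.path(runDir, "delta_ccf.tsv"))
    dyn <- tryCatch(
      suppressWarnings(compareDynamics(recs)),
      error = function(e) NULL
    )
    if (!is.null(dyn))
      jsonlite::write_json(
        dyn[c("per_patient", "pooled_p", "pooled_median_difference",
              "method", "alternative")],
        file.path(runDir, "neoantigen_dynamics.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    results$delta_ccf <- recs; results$dynamics <- dyn
  }

  ## ---- immune evasion ---------------------------------------------------
  if (on("evasion")) {
    .logStage("evasion", "catalogue LoF flags")
    flags <- flagSamples(variants)
    flags <- merge(flags, samples[, c("sample", "patient", "timepoint",
                                      intersect("immune_group",
                                                names(samples)))],
                   by = "sample", all.x = TRUE)
    .writeTsv(flags, file.path(runDir, "evasion_flags.tsv"))
    ftest <- NULL
    if ("immune_group" %in% names(flags) &&
        length(unique(flags$immune_group)) == 2L) {
      ftest <- fisherGroupComparison(flags$has_evasion_lof,
                                     flags$immune_group)
      jsonlite::write_json(
        list(odds_ratio = ftest$odds_ratio, p.value = ftest$p.value,
             haldane_corrected = ftest$haldane_corrected),
        file.path(runDir, "evasion_fisher.json"),
        auto_unbox = TRUE, digits = NA)
    }
    results$evasion_flags <- flags; results$evasion_fisher <- ftest
  }

  ## ---- methylation ------------------------------------------------------
  if (on("methylation")) {
    if (is.null(cohort))
      stop("the methylation stage requires simulation mode")
    .logStage("methylation", "promoter summaries and shift tests")
    meth <- simulatePromoterMethylation(cohort, seed = config$seed)
    summ <- summarisePromoters(meth$beta, meth$annotation)
    .writeTsv(summ, file.path(runDir, "promoter_summaries.tsv"))
    shifts <- compareShifts(summ, sampleMeta(cohort),
                            meth$neoantigen_genes)
    jsonlite::write_json(
      list(overall = if (!is.null(shifts$overall))
             shifts$overall[c("statistic", "p.value",
                              "median_difference")],
           n_unpaired = shifts$n_unpaired),
      file.path(runDir, "methylation_shifts.json"),
      auto_unbox = TRUE, digits = NA)
    results$methylation <- shifts
  }

  ## ---- manifest + summary ----------------------------------------------
  cfgDump <- config
  cfgDump$simulation <- if (!is.null(config$simulation)) {
    sim <- config$simulation
    setNames(lapply(slotNames(sim), function(s) slot(sim, s)),
             slotNames(sim))
  } else NULL
  cfgFile <- file.path(runDir, "config.json")
  jsonlite::write_json(
    lapply(cfgDump, function(x) if (is.atomic(x) || is.list(x)) x else
      format(x)),
    cfgFile, auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(
    package = "ClonalDivergence",
    version = as.character(packageVersion("ClonalDivergence")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    stages = config$stages,
    config_md5 = unname(tools::md5sum(cfgFile)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(runDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  summaryLines <- c(
    sprintf("ClonalDivergence run (%s)", basename(runDir)),
    sprintf("seed: %d; stages: %s", config$seed,
            paste(config$stages, collapse = ", ")),
    if (!is.null(results$filter_report))
      sprintf("filter: %d -> %d variants retained",
              results$filter_report@n_input,
              results$filter_report@n_retained),
    if (!is.null(results$divergence))
      sprintf("divergence: median percent public %.1f%%; matched vs null p = %.3g",
              median(results$divergence$percent_public),
              results$null_test$p.value),
    if (!is.null(results$scores))
      sprintf("clonality: scores %.2f-%.2f",
              min(results$scores$score), max(results$scores$score)),
    if (!is.null(results$dynamics))
      sprintf("neoantigen dynamics: pooled p = %.3g",
              results$dynamics$pooled_p),
    if (!is.null(results$evasion_fisher))
      sprintf("evasion LoF: OR %.2f, p = %.3g",
              results$evasion_fisher$odds_ratio,
              results$evasion_fisher$p.value)
  )
  writeLines(summaryLines, file.path(runDir, "summary.txt"))
  invisible(c(list(run_dir = runDir, manifest = manifest), results))
}
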