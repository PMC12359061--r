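## Shared fixtures and independent brute-force oracles. The oracles
## deliberately use a different computational route than the package
## (pairwise-comparison U statistics, hypergeometric sums) so that
## agreement is a genuine cross-check.

## exact rank-sum p by enumerating every group assignment and counting
## pairwise wins (Mann-Whitney U with 0.5 per tie)
oracleRankSumP <- function(x, y, alternative = "two.sided") {
  nx <- length(x)
  pool <- c(x, y)
  n <- length(pool)
  uStat <- function(idx) {
    a <- pool[idx]
    b <- pool[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u <- uStat(seq_len(nx))
  us <- utils::combn(n, nx, uStat)
  eps <- 1e-9
  pl <- mean(us <= u + eps)
  pg <- mean(us >= u - eps)
  switch(alternative,
         two.sided = min(1, 2 * min(pl, pg)),
         less = pl,
         greater = pg)
}

## exact two-sided Fisher p: hypergeometric mass of all tables with the
## observed margins that are no more probable than the observed table
oracleFisherP <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ])
  k <- sum(tab[, 1])
  n <- sum(tab)
  support <- max(0, k - (n - m)):min(m, k)
  probs <- stats::dhyper(support, m, n - m, k)
  p0 <- stats::dhyper(a, m, n - m, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

## minimal canonical variant table
makeVariants <- function(vaf, ref = "A", alt = "T", patient = "P01",
                         sample = "P01_B", timepoint = "baseline",
                         classification = "missense", gene = "GENE0001",
                         flags = "", depth = 100L) {
  n <- length(vaf)
  altc <- as.integer(round(vaf * depth))
  data.frame(patient = patient, sample = sample, timepoint = timepoint,
             chrom = "1", pos = seq_len(n) * 100L,
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             t_ref_count = depth - altc, t_alt_count = altc,
             vaf = altc / depth,
             variant_classification = rep_len(classification, n),
             gene_symbol = rep_len(gene, n),
             filter_flags = rep_len(flags, n),
             stringsAsFactors = FALSE)
}

writeTestVcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FILTER=<ID=ffpe_artifact,Description=\"FFPE orientation bias\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR", sep = "\t"),
    paste("1", "100", ".", "A", "T", ".", "PASS", ".", "GT:AD",
          "0/1:80,20", sep = "\t"),
    paste("2", "200", ".", "C", "T,G", ".", "PASS", ".", "GT:AD",
          "0/1:60,30,10", sep = "\t"),
    paste("3", "300", ".", "G", "A", ".", "ffpe_artifact", ".", "GT:AD",
          "0/1:95,5", sep = "\t")
  ), path)
  path
}

## full immunoediting detector: simulate -> filter -> CCF -> delta-CCF ->
## neoantigen-vs-control rank-sum; returns the pooled p-value
dynamicsDetector <- function(seed, s, alternative = "two.sided") {
  cfg <- simulationConfig(n_patients = 15, seed = seed,
                          selection_coefficient_s = s)
  co <- simulateCohort(cfg)
  v <- applyArtifactFilters(variantCalls(co))$variants
  cc <- ccfTable(v, segmentTable(co), sampleMeta(co))
  ann <- neoantigenAnnotations(co)
  recs <- do.call(rbind, lapply(split(cc, cc$patient), function(d) {
    b <- d[d$timepoint == "baseline", ]
    r <- d[d$timepoint == "recurrence", ]
    if (!nrow(b) || !nrow(r)) return(NULL)
    x <- computeDeltaCcf(b, r)
    x$patient <- d$patient[1]
    x
  }))
  idx <- match(paste(recs$patient, recs$mutation_id),
               paste(ann$patient, ann$mutation_id))
  recs$is_neoantigen <- !is.na(idx) & ann$stringent_pass[idx]
  suppressWarnings(compareDynamics(recs, alternative = alternative)$pooled_p)
}
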