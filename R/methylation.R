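#' Summarise promoter methylation per gene over upstream regulatory probes
#'
#' For each gene and sample, averages (mean and median) the beta values of
#' probes annotated to the gene's upstream regulatory region — the
#' Illumina designations TSS200, TSS1500 and 1stExon, which associate with
#' repression of expression. Gene-body/"other" probes never contribute.
#' Probes present in the matrix but absent from the annotation are
#' ignored (their count is reported in an attribute); genes with no
#' qualifying probe are omitted.
#'
#' @param beta numeric matrix of beta values in `[0, 1]`, probes x samples
#'   (rownames = probe ids).
#' @param annotation `data.frame` with `probe, gene_symbol, region_class`;
#'   a probe annotated to several genes contributes to each.
#' @param promoterClasses region classes counted as promoter.
#' @return `data.frame` with `sample, gene_symbol, mean_beta, median_beta,
#'   n_probes`; attribute `n_unannotated_probes` counts ignored probes.
#' @examples
#' beta <- matrix(c(0.2, 0.4), 2, 1,
#'                dimnames = list(c("cg1", "cg2"), "S1"))
#' ann <- data.frame(probe = c("cg1", "cg2"), gene_symbol = "TP53",
#'                   region_class = c("TSS200", "1stExon"))
#' summarisePromoters(beta, ann)
#' @export
summarisePromoters <- function(beta, annotation,
                               promoterClasses = c("TSS200", "TSS1500",
                                                   "1stExon")) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)),
            all(c("probe", "gene_symbol", "region_class") %in%
                  names(annotation)))
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  nUnannotated <- sum(!rownames(beta) %in% annotation$probe)
  ann <- annotation[annotation$region_class %in% promoterClasses &
                      annotation$probe %in% rownames(beta), , drop = FALSE]
  out <- lapply(split(ann$probe, ann$gene_symbol), function(probes) {
    sub <- beta[probes, , drop = FALSE]
    data.frame(
      sample = colnames(beta),
      mean_beta = colMeans(sub, na.rm = TRUE),
      median_beta = apply(sub, 2L, median, na.rm = TRUE),
      n_probes = length(probes),
      stringsAsFactors = FALSE
    )
  })
  genes <- rep(names(out), vapply(out, nrow, integer(1)))
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(sample = character(), mean_beta = numeric(),
                      median_beta = numeric(), n_probes = integer())
  out$gene_symbol <- genes
  out <- out[, c("sample", "gene_symbol", "mean_beta", "median_beta",
                 "n_probes")]
  rownames(out) <- NULL
  attr(out, "n_unannotated_probes") <- nUnannotated
  out
}

#' Compare promoter methylation shifts by neoantigen status
#'
#' Computes, per patient and gene, the recurrence-minus-baseline shift in
#' the promoter summary and compares shifts between neoantigen-bearing
#' genes (any stringent-pass neoantigen mutation makes a gene
#' neoantigen-bearing) and all other genes, with a tie-corrected rank-sum
#' test — overall and stratified by immune group when available.
#'
#' @param summaries output of [summarisePromoters()].
#' @param samples sample metadata (`sample, patient, timepoint`, optional
#'   `immune_group`).
#' @param neoantigenGenes character vector of neoantigen-bearing genes.
#' @param statistic `"mean_beta"` (primary) or `"median_beta"`.
#' @param alternative passed to [rankSumTest()] (location of neoantigen
#'   genes' shifts relative to others).
#' @return list with `shifts` (`data.frame`: patient, gene_symbol, shift,
#'   is_neoantigen_gene, immune_group), `overall` (rank-sum result or
#'   `NULL` if a group is empty), `by_group` (named list per immune
#'   group), and `n_unpaired` (gene/patient combinations lacking a
#'   timepoint).
#' @export
compareShifts <- function(summaries, samples, neoantigenGenes,
                          statistic = c("mean_beta", "median_beta"),
                          alternative = "two.sided") {
  statistic <- match.arg(statistic)
  stopifnot(all(c("sample", "patient", "timepoint") %in% names(samples)))
  d <- merge(summaries, samples, by = "sample")
  d <- d[d$timepoint %in% c("baseline", "recurrence"), , drop = FALSE]
  wide <- split(d, list(d$patient, d$gene_symbol), drop = TRUE)
  nUnpaired <- 0L
  rows <- lapply(wide, function(x) {
    b <- x[[statistic]][x$timepoint == "baseline"]
    r <- x[[statistic]][x$timepoint == "recurrence"]
    if (length(b) != 1L || length(r) != 1L) {
      nUnpaired <<- nUnpaired + 1L
      return(NULL)
    }
    data.frame(
      patient = x$patient[1],
      gene_symbol = x$gene_symbol[1],
      shift = r - b,
      is_neoantigen_gene = x$gene_symbol[1] %in% neoantigenGenes,
      immune_group = if ("immune_group" %in% names(x))
        x$immune_group[1] else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  shifts <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(shifts) || !nrow(shifts))
    stop("no gene has paired baseline/recurrence summaries")
  rownames(shifts) <- NULL

  runTest <- function(x) {
    a <- x$shift[x$is_neoantigen_gene]
    b <- x$shift[!x$is_neoantigen_gene]
    if (!length(a) || !length(b)) return(NULL)
    res <- rankSumTest(a, b, alternative = alternative)
    res$n_neoantigen_genes <- length(a)
    res$n_other_genes <- length(b)
    res$median_difference <- median(a) - median(b)
    res
  }
  byGroup <- NULL
  grp <- unique(shifts$immune_group[!is.na(shifts$immune_group)])
  if (length(grp))
    byGroup <- lapply(setNames(grp, grp), function(g)
      runTest(shifts[shifts$immune_group == g, , drop = FALSE]))
  list(shifts = shifts, overall = runTest(shifts), by_group = byGroup,
       n_unpaired = nUnpaired)
}
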