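#' Run the full rare-CNV association pipeline
#'
#' Orchestrates the stages end to end: sample/call quality control,
#' excluded-region filtering, rare-set derivation (segmental-duplication
#' and frequency filters), the stratified global burden table, the
#' gene-count burden, and the region-level (CNVR) association. Each stage
#' is also exported individually, so stages can be re-run on intermediate
#' objects; composing them here equals running them one by one. The result
#' is deterministic given `seed`.
#'
#' @param x a [CnvDataset-class] of raw calls, or a list as returned by
#'   [simulateCnvDataset()] (its tracks are then used as defaults).
#' @param genes optional gene annotation `GRanges` (with `label`).
#' @param segdups optional segmental-duplication track.
#' @param exclusions optional exclusion-region track.
#' @param thresholds a [qcThresholds()].
#' @param rarity a [rarityConfig()].
#' @param strata burden strata (default [defaultStrata()]).
#' @param n_perm permutations for every empirical p (default 100,000).
#' @param seed RNG seed controlling all permutation streams.
#' @param flank_bp gene flank for the gene-count burden.
#' @param out_dir optional directory; when given, each report is written
#'   there as a tab-separated file with header, plus the provenance log.
#' @return list with elements `qc` (the filtered dataset), `rare` (the
#'   rare-set dataset), `burden` (stratified burden table), `gene_burden`
#'   (when `genes` given), `regions` (region association table), and
#'   `provenance`.
#' @export
runCnvPipeline <- function(x, genes = NULL, segdups = NULL,
                           exclusions = NULL,
                           thresholds = qcThresholds(),
                           rarity = rarityConfig(),
                           strata = defaultStrata(),
                           n_perm = 100000L, seed = 1L,
                           flank_bp = 20000L, out_dir = NULL) {
  if (is.list(x) && !is(x, "CnvDataset") && "dataset" %in% names(x)) {
    if (is.null(genes)) genes <- x$genes
    if (is.null(segdups)) segdups <- x$segdups
    if (is.null(exclusions)) exclusions <- x$exclusions
    x <- x$dataset
  }
  stopifnot(is(x, "CnvDataset"))
  qc <- applyQcFilters(x, thresholds, exclusions)
  rare <- deriveRareSet(qc, segdups, rarity)
  samples <- sampleInfo(rare)
  calls <- cnvCalls(rare)
  set.seed(seed)
  burden <- burdenTable(calls, samples, strata, n_perm = n_perm,
                        frac = rarity$occurrence_overlap_frac)
  gene_res <- if (!is.null(genes)) {
    geneBurden(calls, genes, samples, flank_bp, n_perm = n_perm)
  } else NULL
  regions <- cnvrAssociation(rare, genes = genes, n_perm = n_perm)
  out <- list(qc = qc, rare = rare, burden = burden,
              gene_burden = gene_res, regions = regions,
              provenance = provenance(rare))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) {
      if (!is.null(df)) {
        utils::write.table(df, file.path(out_dir, name), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }
    writeCnvCalls(calls, file.path(out_dir, "rare_calls.tsv"), "tabular")
    wt(out$burden, "burden_table.tsv")
    wt(out$gene_burden, "gene_burden.tsv")
    wt(out$regions, "region_association.tsv")
    wt(out$provenance, "provenance.tsv")
  }
  out
}
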