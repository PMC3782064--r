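#' Rarity-filter configuration
#'
#' @param segdup_overlap_frac remove a call when segmental-duplication union
#'   coverage exceeds this fraction of its length (strict >, default 0.5).
#' @param freq_threshold frequency threshold (default 0.01, i.e. 1%).
#' @param freq_mode `"conjunctive_by_group"` (default) removes a call only
#'   when its occurrence count exceeds the threshold in cases AND in
#'   controls (the reading under which a case-only recurrent locus carried
#'   by >1% of cases survives); `"dataset_wide"` removes a call whose
#'   occurrence count exceeds the threshold applied to the total sample.
#' @param occurrence_overlap_frac fraction of the focal call's length a
#'   partner call must cover to count as an occurrence (default 0.5).
#' @return a `RarityConfig` list.
#' @export
rarityConfig <- function(segdup_overlap_frac = 0.5, freq_threshold = 0.01,
                         freq_mode = c("conjunctive_by_group",
                                       "dataset_wide"),
                         occurrence_overlap_frac = 0.5) {
  freq_mode <- match.arg(freq_mode)
  stopifnot(segdup_overlap_frac > 0, segdup_overlap_frac <= 1,
            freq_threshold > 0, freq_threshold <= 1,
            occurrence_overlap_frac > 0, occurrence_overlap_frac <= 1)
  structure(list(segdup_overlap_frac = segdup_overlap_frac,
                 freq_threshold = freq_threshold, freq_mode = freq_mode,
                 occurrence_overlap_frac = occurrence_overlap_frac),
            class = "RarityConfig")
}

#' Remove calls lying mostly in segmental duplications
#'
#' A call is removed when more than `frac` of its length is covered by the
#' union of the segmental-duplication track. The inequality is strict
#' (exactly 50% covered is kept), unlike the excluded-region filter.
#'
#' @param x a [CnvDataset-class].
#' @param segdup_track `GRanges` of segmental duplications.
#' @param frac coverage fraction (default 0.5).
#' @return the filtered `CnvDataset`.
#' @export
filterSegdups <- function(x, segdup_track, frac = 0.5) {
  calls <- cnvCalls(x)
  if (length(calls) == 0L || length(segdup_track) == 0L) {
    return(.logFilter(x, "filterSegdups", "segdup_overlap", 0L, 0L))
  }
  cov <- coverageFraction(calls, segdup_track)
  drop <- cov > frac
  x <- .logFilter(x, "filterSegdups", "segdup_overlap", 0L, sum(drop))
  x@calls <- calls[!drop]
  x
}

# For each focal call, the number of partner calls whose overlap covers at
# least (or strictly more than, when strict) `frac` of the focal call's
# length. Directional: the denominator is always the focal call's length.
# `exclude_self` removes identity hits when focal and partners index the
# same call set.
.partnerCounts <- function(focal, partners, frac, strict = FALSE,
                           exclude_self = FALSE) {
  n <- length(focal)
  if (n == 0L) return(integer(0))
  counts <- integer(n)
  if (length(partners) == 0L) return(counts)
  hits <- GenomicRanges::findOverlaps(.strip(focal), .strip(partners),
                                      ignore.strand = TRUE)
  if (exclude_self) {
    hits <- hits[S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)]
  }
  if (length(hits) == 0L) return(counts)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  w <- pmin(GenomicRanges::end(focal)[qh], GenomicRanges::end(partners)[sh]) -
    pmax(GenomicRanges::start(focal)[qh],
         GenomicRanges::start(partners)[sh]) + 1L
  fr <- as.numeric(w) / GenomicRanges::width(focal)[qh]
  ok <- if (strict) fr > frac else fr >= frac
  agg <- tapply(ok, qh, sum)
  counts[as.integer(names(agg))] <- as.integer(agg)
  counts
}

#' Occurrence count of each call in a call set
#'
#' The occurrence count of a call is 1 (itself) plus the number of *other*
#' calls — any sample, any CNV type unless the caller pre-restricts the set —
#' whose overlap covers at least `frac` of the focal call's length. The
#' fraction is directional: a 100 kb call fully inside a 1 Mb call counts
#' the large call as a partner, but not vice versa.
#'
#' @param calls `GRanges` of calls.
#' @param frac overlap fraction of the focal call's length (default 0.5).
#' @return integer vector of occurrence counts (each >= 1).
#' @export
countOccurrences <- function(calls, frac = 0.5) {
  1L + .partnerCounts(calls, calls, frac, exclude_self = TRUE)
}

#' Remove calls too frequent to be rare
#'
#' Occurrence counts (see [countOccurrences()]) are compared to
#' `freq_threshold` times the relevant sample count. In
#' `conjunctive_by_group` mode (default) a call is removed only when its
#' occurrence count among case calls exceeds `threshold * n_cases` AND its
#' occurrence count among control calls exceeds `threshold * n_controls` —
#' so a locus recurrent in cases but absent from controls is retained. In
#' `dataset_wide` mode a call is removed when its total occurrence count
#' exceeds `threshold * n_samples`. The active mode is logged in provenance.
#'
#' @param x a [CnvDataset-class].
#' @param config a [rarityConfig()].
#' @return the filtered `CnvDataset` (the rare set).
#' @export
filterByFrequency <- function(x, config = rarityConfig()) {
  calls <- cnvCalls(x)
  s <- sampleInfo(x)
  if (length(calls) == 0L) {
    return(.logFilter(x, "filterByFrequency", config$freq_mode, 0L, 0L))
  }
  thr <- config$freq_threshold
  frac <- config$occurrence_overlap_frac
  if (config$freq_mode == "conjunctive_by_group") {
    n_case <- sum(s$status == "case")
    n_ctrl <- sum(s$status == "control")
    if (n_case == 0L || n_ctrl == 0L) {
      stop("conjunctive_by_group mode needs both cases and controls")
    }
    status <- s$status[match(calls$sample_id, s$sample_id)]
    is_case <- status == "case"
    # self-hits are kept: a case call counts itself among case occurrences
    occ_case <- .partnerCounts(calls, calls[is_case], frac)
    occ_ctrl <- .partnerCounts(calls, calls[!is_case], frac)
    drop <- occ_case > thr * n_case & occ_ctrl > thr * n_ctrl
  } else {
    occ <- countOccurrences(calls, frac)
    drop <- occ > thr * nrow(s)
  }
  x <- .logFilter(x, "filterByFrequency", config$freq_mode, 0L, sum(drop),
                  detail = sprintf("threshold=%g", thr))
  x@calls <- calls[!drop]
  x
}

#' Derive the rare CNV set
#'
#' Applies the segmental-duplication filter then the frequency filter, the
#' two steps that turn the QC-passed call set into the rare set used by all
#' burden and region analyses.
#'
#' @param x a QC-filtered [CnvDataset-class].
#' @param segdup_track `GRanges` of segmental duplications (`NULL` skips).
#' @param config a [rarityConfig()].
#' @return the rare-set `CnvDataset`.
#' @export
deriveRareSet <- function(x, segdup_track = NULL, config = rarityConfig()) {
  if (!is.null(segdup_track)) {
    x <- filterSegdups(x, segdup_track, config$segdup_overlap_frac)
  }
  filterByFrequency(x, config)
}
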