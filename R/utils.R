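#' Normalize chromosome labels
#'
#' Strips a leading "chr" prefix so that "chr12" and "12" refer to the same
#' chromosome internally. Downstream analyses are restricted to the autosomes
#' 1-22; sex chromosomes and contigs are representable here but are removed
#' by [filterCalls()].
#'
#' @param x character vector of chromosome labels.
#' @return character vector of un-prefixed labels.
#' @export
normalizeChrom <- function(x) {
  sub("^chr", "", as.character(x))
}

.isAutosome <- function(x) {
  normalizeChrom(x) %in% as.character(1:22)
}

#' Directional overlap fraction between two interval sets
#'
#' Computes, element-wise, the fraction of the *first* interval's length that
#' is covered by the second interval. The fraction is directional, not
#' reciprocal: `overlapFraction(a, b)` uses `length(a)` as the denominator,
#' matching the filtering convention "by >= 50% of its length". Intervals on
#' different chromosomes have fraction 0.
#'
#' @param a,b `GRanges` of equal length (or either of length 1, recycled).
#' @return numeric vector of fractions in `[0, 1]`.
#' @examples
#' a <- GenomicRanges::GRanges("1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("1", IRanges::IRanges(51, 200))
#' overlapFraction(a, b)  # 0.5
#' @export
overlapFraction <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  if (n == 0L) return(numeric(0))
  same <- normalizeChrom(GenomicRanges::seqnames(a)) ==
    normalizeChrom(GenomicRanges::seqnames(b))
  lo <- pmax(GenomicRanges::start(a), GenomicRanges::start(b))
  hi <- pmin(GenomicRanges::end(a), GenomicRanges::end(b))
  w <- pmax(0L, hi - lo + 1L)
  as.numeric(w) * as.numeric(same) / GenomicRanges::width(a)
}

#' Per-base union coverage fraction of intervals by a track
#'
#' For each query interval, the fraction of its bases covered by the union of
#' the track intervals. Track records may overlap each other; bases covered by
#' several records count once (union coverage, not best single overlap).
#'
#' @param query `GRanges` of intervals to assess.
#' @param track `GRanges` covering track (e.g. segmental duplications or
#'   exclusion regions).
#' @return numeric vector, one fraction in `[0, 1]` per query interval.
#' @export
coverageFraction <- function(query, track) {
  if (length(query) == 0L) return(numeric(0))
  if (length(track) == 0L) return(numeric(length(query)))
  red <- GenomicRanges::reduce(.strip(track))
  q <- .strip(query)
  hits <- GenomicRanges::findOverlaps(q, red, ignore.strand = TRUE)
  covered <- numeric(length(query))
  if (length(hits) > 0L) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    w <- pmin(GenomicRanges::end(q)[qh], GenomicRanges::end(red)[sh]) -
      pmax(GenomicRanges::start(q)[qh], GenomicRanges::start(red)[sh]) + 1L
    agg <- tapply(w, qh, sum)
    covered[as.integer(names(agg))] <- as.numeric(agg)
  }
  covered / GenomicRanges::width(query)
}

# Rebuild a GRanges with bare normalized seqnames on a shared seqlevels
# universe, so tracks and calls from different sources are comparable
# without seqinfo merge chatter.
.strip <- function(gr) {
  sn <- normalizeChrom(GenomicRanges::seqnames(gr))
  lv <- unique(c(as.character(1:22), "X", "Y", sn))
  GenomicRanges::GRanges(
    seqnames = factor(sn, levels = lv),
    ranges = IRanges::IRanges(GenomicRanges::start(gr),
                              GenomicRanges::end(gr))
  )
}

# population (divide-by-n) standard deviation
.popSd <- function(x) sqrt(mean((x - mean(x))^2))
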