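#' Quality-control thresholds
#'
#' Bundles every tunable threshold of the QC cascade. The defaults are the
#' stringent array-CNV criteria the package implements: a sample fails on
#' array call rate < 99.8%, log R ratio SD > 0.27, B allele frequency SD
#' > 0.17 or |wave factor| > 0.04; a call fails on < 5 probes, < 100 kb
#' length, confidence < 10 or a non-autosomal chromosome. Inequalities are
#' strict in the stated direction: a sample at exactly the threshold passes.
#'
#' @param min_call_rate fail sample when call_rate < this (default 0.998).
#' @param max_lrr_sd fail sample when lrr_sd > this (default 0.27).
#' @param max_baf_sd fail sample when baf_sd > this (default 0.17).
#' @param max_abs_wave fail sample when |wave_factor| > this (default 0.04).
#' @param min_probes fail call when num_probes < this (default 5).
#' @param min_length_bp fail call when length < this (default 100,000).
#' @param min_confidence fail call when confidence < this (default 10).
#' @param region_overlap_frac remove a call when excluded-track union
#'   coverage is >= this fraction of its length (default 0.5).
#' @param outlier_sd_mult remove a sample when its CNV count exceeds the
#'   mean by more than this many (population) SDs (default 3).
#' @param max_cnv_length_bp remove any sample carrying a call longer than
#'   this (default 7,500,000; such calls likely reflect karyotype
#'   abnormalities).
#' @param max_cnv_count optional absolute per-sample CNV-count cutoff
#'   (remove when count > this), applied alongside the mean + SD rule;
#'   `NULL` disables it.
#' @return a `QcThresholds` list.
#' @export
qcThresholds <- function(min_call_rate = 0.998, max_lrr_sd = 0.27,
                         max_baf_sd = 0.17, max_abs_wave = 0.04,
                         min_probes = 5L, min_length_bp = 100000L,
                         min_confidence = 10, region_overlap_frac = 0.5,
                         outlier_sd_mult = 3, max_cnv_length_bp = 7500000,
                         max_cnv_count = NULL) {
  th <- list(min_call_rate = min_call_rate, max_lrr_sd = max_lrr_sd,
             max_baf_sd = max_baf_sd, max_abs_wave = max_abs_wave,
             min_probes = min_probes, min_length_bp = min_length_bp,
             min_confidence = min_confidence,
             region_overlap_frac = region_overlap_frac,
             outlier_sd_mult = outlier_sd_mult,
             max_cnv_length_bp = max_cnv_length_bp,
             max_cnv_count = max_cnv_count)
  num <- unlist(th[!vapply(th, is.null, TRUE)])
  if (any(num <= 0)) stop("all QC thresholds must be strictly positive")
  structure(th, class = "QcThresholds")
}

#' Remove samples failing array-level QC
#'
#' A sample is removed (with all its calls) if `call_rate < min_call_rate`,
#' `lrr_sd > max_lrr_sd`, `baf_sd > max_baf_sd` or
#' `|wave_factor| > max_abs_wave`. A metric whose column is absent or `NA`
#' skips that rule for the sample, with a warning. Removal is attributed to
#' the first failing rule in the order above, and logged in provenance.
#'
#' @param x a [CnvDataset-class].
#' @param thresholds a [qcThresholds()] list.
#' @return the filtered `CnvDataset`.
#' @export
filterSamples <- function(x, thresholds = qcThresholds()) {
  s <- as.data.frame(sampleInfo(x))
  rules <- list(
    call_rate = function(v) v < thresholds$min_call_rate,
    lrr_sd = function(v) v > thresholds$max_lrr_sd,
    baf_sd = function(v) v > thresholds$max_baf_sd,
    wave_factor = function(v) abs(v) > thresholds$max_abs_wave
  )
  fail_rule <- rep(NA_character_, nrow(s))
  for (metric in names(rules)) {
    if (!metric %in% colnames(s) || all(is.na(s[[metric]]))) {
      warning("sample metric '", metric, "' absent; rule skipped")
      next
    }
    v <- s[[metric]]
    if (anyNA(v)) {
      warning("sample metric '", metric, "' missing for ",
              sum(is.na(v)), " sample(s); rule skipped for those")
    }
    bad <- !is.na(v) & rules[[metric]](v)
    fail_rule[bad & is.na(fail_rule)] <- metric
  }
  drop <- which(!is.na(fail_rule))
  if (length(drop) == 0L) {
    return(.logFilter(x, "filterSamples", "none", 0L, 0L))
  }
  .dropSamples(x, s$sample_id[drop], "filterSamples", fail_rule[drop])
}

#' Remove calls failing call-level QC
#'
#' A call is removed if it spans fewer than `min_probes` probes, is shorter
#' than `min_length_bp`, has confidence below `min_confidence`, or lies on a
#' non-autosomal chromosome. Each removed call is attributed to the first
#' failing rule in that order; per-rule counts are logged.
#'
#' @inheritParams filterSamples
#' @return the filtered `CnvDataset`.
#' @export
filterCalls <- function(x, thresholds = qcThresholds()) {
  calls <- cnvCalls(x)
  if (length(calls) == 0L) {
    return(.logFilter(x, "filterCalls", "none", 0L, 0L))
  }
  rule <- rep(NA_character_, length(calls))
  conf <- calls$confidence
  checks <- list(
    probes = calls$num_probes < thresholds$min_probes,
    length = GenomicRanges::width(calls) < thresholds$min_length_bp,
    confidence = !is.na(conf) & conf < thresholds$min_confidence,
    autosome = !.isAutosome(GenomicRanges::seqnames(calls))
  )
  for (r in names(checks)) {
    rule[checks[[r]] & is.na(rule)] <- r
  }
  for (r in names(checks)) {
    x <- .logFilter(x, "filterCalls", r, 0L, sum(rule == r, na.rm = TRUE))
  }
  x@calls <- calls[is.na(rule)]
  x
}

#' Remove calls lying in excluded genomic regions
#'
#' A call is removed when the per-base union coverage of its interval by the
#' exclusion track (centromeric/telomeric and immunoglobulin regions prone
#' to false-positive calls) is at least `frac` of the call's length. Note
#' the boundary is inclusive (>=), unlike the segmental-duplication filter.
#'
#' @inheritParams filterSamples
#' @param exclusion_track `GRanges` of excluded regions.
#' @param frac coverage fraction threshold (default from `thresholds`).
#' @return the filtered `CnvDataset`.
#' @export
filterExcludedRegions <- function(x, exclusion_track,
                                  thresholds = qcThresholds(),
                                  frac = thresholds$region_overlap_frac) {
  calls <- cnvCalls(x)
  if (length(calls) == 0L || length(exclusion_track) == 0L) {
    return(.logFilter(x, "filterExcludedRegions", "region_overlap", 0L, 0L))
  }
  cov <- coverageFraction(calls, exclusion_track)
  drop <- cov >= frac
  x <- .logFilter(x, "filterExcludedRegions", "region_overlap", 0L,
                  sum(drop))
  x@calls <- calls[!drop]
  x
}

#' Remove samples with outlying CNV loads
#'
#' Removes every sample whose CNV count exceeds `mean + outlier_sd_mult * SD`
#' (population SD, both computed once over all current samples before any
#' removal — a single cutoff, not an iterative trim), every sample whose
#' count exceeds the optional absolute `max_cnv_count`, and every sample
#' carrying any call longer than `max_cnv_length_bp`. Samples with zero
#' calls count 0. With fewer than 3 samples the count rule is skipped with
#' a warning (the dispersion is meaningless); the long-call rule still
#' applies.
#'
#' @inheritParams filterSamples
#' @return the filtered `CnvDataset`.
#' @export
removeOutlierSamples <- function(x, thresholds = qcThresholds()) {
  s <- sampleInfo(x)
  calls <- cnvCalls(x)
  counts <- table(factor(calls$sample_id, levels = s$sample_id))
  counts <- as.numeric(counts)
  fail_rule <- rep(NA_character_, nrow(s))
  if (nrow(s) >= 3L) {
    cutoff <- mean(counts) + thresholds$outlier_sd_mult * .popSd(counts)
    fail_rule[counts > cutoff] <- "cnv_count_outlier"
  } else {
    warning("fewer than 3 samples; CNV-count outlier rule skipped")
  }
  if (!is.null(thresholds$max_cnv_count)) {
    bad <- counts > thresholds$max_cnv_count
    fail_rule[bad & is.na(fail_rule)] <- "cnv_count_absolute"
  }
  long_ids <- unique(calls$sample_id[
    GenomicRanges::width(calls) > thresholds$max_cnv_length_bp])
  bad <- s$sample_id %in% long_ids
  fail_rule[bad & is.na(fail_rule)] <- "long_cnv"
  drop <- which(!is.na(fail_rule))
  if (length(drop) == 0L) {
    return(.logFilter(x, "removeOutlierSamples", "none", 0L, 0L))
  }
  .dropSamples(x, s$sample_id[drop], "removeOutlierSamples",
               fail_rule[drop])
}

#' Run the full QC cascade
#'
#' Applies, in order: sample-level metric filters, call-level filters,
#' excluded-region filtering (when a track is given), and outlier-sample
#' removal. Each stage logs its removal counts in the provenance.
#'
#' @inheritParams filterSamples
#' @param exclusion_track optional `GRanges` of excluded regions.
#' @return the filtered `CnvDataset`.
#' @export
applyQcFilters <- function(x, thresholds = qcThresholds(),
                           exclusion_track = NULL) {
  x <- filterSamples(x, thresholds)
  x <- filterCalls(x, thresholds)
  if (!is.null(exclusion_track)) {
    x <- filterExcludedRegions(x, exclusion_track, thresholds)
  }
  removeOutlierSamples(x, thresholds)
}
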