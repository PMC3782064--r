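#' @import methods
#' @importFrom S4Vectors DataFrame queryHits subjectHits
NULL

#' CnvDataset: CNV calls plus sample manifest with filter provenance
#'
#' The central container of the package. Holds the CNV call set as a
#' `GRanges` (1-based inclusive coordinates, un-prefixed autosome-style
#' seqnames) with per-call metadata columns, the sample manifest as a
#' `DataFrame`, and an append-only provenance log recording every filter
#' applied with its removal counts.
#'
#' Call metadata columns: `sample_id`, `num_probes`, `copy_number`,
#' `confidence`, plus the derived `cnv_type` ("deletion" if copy number < 2,
#' "duplication" if > 2) and `zygosity` ("homozygous" for copy number 0 or 4,
#' "heterozygous" for 1 or 3). Copy number 2 (diploid) is invalid in a call
#' set and is rejected by the validity method.
#'
#' Sample columns: `sample_id`, `status` ("case"/"control"), and optionally
#' `sex`, `call_rate`, `lrr_sd`, `baf_sd`, `wave_factor`, `age`,
#' `family_history`. Missing QC metric columns cause the corresponding
#' sample-level filters to be skipped with a warning.
#'
#' @slot calls `GRanges` of CNV calls.
#' @slot samples `DataFrame` of samples.
#' @slot provenance `data.frame` log with columns `step`, `rule`,
#'   `removed_samples`, `removed_calls`, `detail`.
#'
#' @seealso [CnvDataset()] constructor, [cnvCalls()], [sampleInfo()],
#'   [provenance()]
#' @export
setClass("CnvDataset",
  representation(
    calls = "GRanges",
    samples = "DataFrame",
    provenance = "data.frame"
  )
)

.CALL_COLS <- c("sample_id", "num_probes", "copy_number", "confidence")

setValidity("CnvDataset", function(object) {
  msgs <- character(0)
  calls <- object@calls
  samples <- object@samples
  miss <- setdiff(.CALL_COLS, colnames(S4Vectors::mcols(calls)))
  if (length(miss)) {
    msgs <- c(msgs, paste0("calls lack metadata column(s): ",
                           paste(miss, collapse = ", ")))
  }
  if (!all(c("sample_id", "status") %in% colnames(samples))) {
    msgs <- c(msgs, "samples must have 'sample_id' and 'status' columns")
  } else {
    if (anyDuplicated(samples$sample_id)) {
      msgs <- c(msgs, "duplicated sample_id in sample manifest")
    }
    if (!all(samples$status %in% c("case", "control"))) {
      msgs <- c(msgs, "sample status must be 'case' or 'control'")
    }
    if (length(miss) == 0L &&
        !all(calls$sample_id %in% samples$sample_id)) {
      msgs <- c(msgs, "every call's sample_id must exist in the manifest")
    }
  }
  if (length(miss) == 0L && length(calls) > 0L) {
    if (any(calls$copy_number == 2L)) {
      msgs <- c(msgs, "copy_number 2 (diploid) is not a CNV call")
    }
    if (any(calls$copy_number < 0L | calls$copy_number > 4L)) {
      msgs <- c(msgs, "copy_number must be in 0..4 (clamp on read)")
    }
    if (any(calls$num_probes < 1L)) {
      msgs <- c(msgs, "num_probes must be >= 1")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CnvDataset
#'
#' @param calls `GRanges` with metadata columns `sample_id`, `num_probes`,
#'   `copy_number`, `confidence` (see [makeCnvCalls()]); derived `cnv_type`
#'   and `zygosity` columns are added if absent.
#' @param samples sample manifest: a `data.frame` or `DataFrame` with at
#'   least `sample_id` and `status` ("case"/"control").
#' @param provenance optional existing provenance log.
#' @return a [CnvDataset-class] object.
#' @examples
#' calls <- fixtureTable6Ovos2()
#' samples <- data.frame(sample_id = unique(calls$sample_id), status = "case")
#' CnvDataset(calls, samples)
#' @export
CnvDataset <- function(calls, samples, provenance = NULL) {
  if (is.data.frame(samples)) samples <- S4Vectors::DataFrame(samples)
  samples$sample_id <- as.character(samples$sample_id)
  samples$status <- as.character(samples$status)
  calls <- .deriveCallColumns(calls)
  if (is.null(provenance)) {
    provenance <- data.frame(step = character(0), rule = character(0),
                             removed_samples = integer(0),
                             removed_calls = integer(0),
                             detail = character(0),
                             stringsAsFactors = FALSE)
  }
  new("CnvDataset", calls = calls, samples = samples,
      provenance = provenance)
}

# cnv_type and zygosity are pure functions of copy_number
.deriveCallColumns <- function(calls) {
  if (length(calls) > 0L) {
    cn <- calls$copy_number
    calls$cnv_type <- ifelse(cn < 2L, "deletion", "duplication")
    calls$zygosity <- ifelse(cn %in% c(0L, 4L), "homozygous", "heterozygous")
  } else {
    calls$cnv_type <- character(0)
    calls$zygosity <- character(0)
  }
  calls
}

#' @describeIn CnvDataset-class the CNV calls as a `GRanges`.
#' @param x a `CnvDataset`.
#' @export
cnvCalls <- function(x) {
  stopifnot(is(x, "CnvDataset"))
  x@calls
}

#' @describeIn CnvDataset-class the sample manifest as a `DataFrame`.
#' @export
sampleInfo <- function(x) {
  stopifnot(is(x, "CnvDataset"))
  x@samples
}

#' @describeIn CnvDataset-class the filter provenance log.
#' @export
provenance <- function(x) {
  stopifnot(is(x, "CnvDataset"))
  x@provenance
}

# append one provenance row; provenance grows monotonically
.logFilter <- function(x, step, rule, removed_samples, removed_calls,
                       detail = "") {
  x@provenance <- rbind(
    x@provenance,
    data.frame(step = step, rule = rule,
               removed_samples = as.integer(removed_samples),
               removed_calls = as.integer(removed_calls),
               detail = detail, stringsAsFactors = FALSE)
  )
  x
}

# drop the named samples and every call they carry, logging one row per rule
.dropSamples <- function(x, drop_ids, step, rules_per_sample, detail = "") {
  calls <- x@calls
  samples <- x@samples
  for (rule in unique(rules_per_sample)) {
    ids <- drop_ids[rules_per_sample == rule]
    x <- .logFilter(x, step, rule,
                    removed_samples = length(ids),
                    removed_calls = sum(calls$sample_id %in% ids),
                    detail = paste(ids, collapse = ","))
  }
  keep <- !(samples$sample_id %in% drop_ids)
  x@samples <- samples[keep, , drop = FALSE]
  x@calls <- calls[!(calls$sample_id %in% drop_ids)]
  x
}

setMethod("show", "CnvDataset", function(object) {
  s <- object@samples
  n_case <- sum(s$status == "case")
  n_ctrl <- sum(s$status == "control")
  cat("CnvDataset:", length(object@calls), "CNV calls in",
      nrow(s), "samples (", n_case, "cases /", n_ctrl, "controls )\n")
  if (length(object@calls) > 0L) {
    cat("  deletions:", sum(object@calls$cnv_type == "deletion"),
        " duplications:", sum(object@calls$cnv_type == "duplication"), "\n")
  }
  if (nrow(object@provenance) > 0L) {
    cat("  provenance:", nrow(object@provenance), "filter step(s),",
        sum(object@provenance$removed_calls), "calls and",
        sum(object@provenance$removed_samples), "samples removed\n")
  }
})
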