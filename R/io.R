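#' Build a CNV call GRanges from vectors
#'
#' Low-level constructor used by the readers, the simulator and the packaged
#' fixtures. Coordinates are 1-based inclusive, so the length of a call is
#' `end - start + 1`.
#'
#' @param chrom chromosome labels ("12" or "chr12"; normalized).
#' @param start,end 1-based inclusive positions.
#' @param sample_id sample identifiers.
#' @param num_probes number of array probes spanned by each call.
#' @param copy_number integer copy-number state; 2 is rejected (a CNV call
#'   cannot be the diploid state) and states above 4 are clamped to 4 with a
#'   warning.
#' @param confidence PennCNV-style confidence: the difference in log
#'   likelihood between the called state and the next most likely state.
#' @return `GRanges` with the call metadata columns.
#' @export
makeCnvCalls <- function(chrom, start, end, sample_id, num_probes,
                         copy_number, confidence) {
  copy_number <- as.integer(copy_number)
  if (any(copy_number == 2L)) {
    stop("rejected record: copy_number 2 (diploid state) is not a CNV")
  }
  if (any(copy_number > 4L)) {
    warning("copy_number states > 4 clamped to 4")
    copy_number[copy_number > 4L] <- 4L
  }
  if (any(copy_number < 0L)) stop("copy_number must be >= 0")
  gr <- GenomicRanges::GRanges(
    seqnames = normalizeChrom(chrom),
    ranges = IRanges::IRanges(start = as.integer(start),
                              end = as.integer(end))
  )
  gr$sample_id <- as.character(sample_id)
  gr$num_probes <- as.integer(num_probes)
  gr$copy_number <- copy_number
  gr$confidence <- as.numeric(confidence)
  .deriveCallColumns(gr)
}

.emptyCalls <- function() {
  makeCnvCalls(character(0), integer(0), integer(0), character(0),
               integer(0), integer(0), numeric(0))
}

#' Read a CNV call table
#'
#' Two dialects are supported. `penncnv` is the whitespace-separated PennCNV
#' output format, e.g.
#' `chr12:31152226-31300846 numsnp=33 length=148,621 state5,cn=3 PD18 startsnp=rs1 endsnp=rs2 conf=84.3`
#' (the `startsnp=`/`endsnp=` tokens are optional; the sample identifier is
#' the first token containing no `=`, after the region). `tabular` is a
#' tab-separated file with header columns `sample_id`, `chrom`, `start`,
#' `end`, `num_probes`, `copy_number`, `confidence` (1-based inclusive).
#'
#' @param path file path.
#' @param dialect `"penncnv"` or `"tabular"`.
#' @return `GRanges` of calls (see [makeCnvCalls()]); empty for an empty file.
#' @export
readCnvCalls <- function(path, dialect = c("penncnv", "tabular")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "tabular") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (nrow(df) == 0L) return(.emptyCalls())
    need <- c("sample_id", "chrom", "start", "end", "num_probes",
              "copy_number", "confidence")
    miss <- setdiff(need, colnames(df))
    if (length(miss)) stop("tabular call file lacks column(s): ",
                           paste(miss, collapse = ", "))
    return(makeCnvCalls(df$chrom, df$start, df$end, df$sample_id,
                        df$num_probes, df$copy_number, df$confidence))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) return(.emptyCalls())
  rows <- lapply(seq_along(lines), function(i) .parsePenncnvLine(lines[i], i))
  do.call(makeCnvCalls, list(
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, `[[`, 0, "start"),
    end = vapply(rows, `[[`, 0, "end"),
    sample_id = vapply(rows, `[[`, "", "sample_id"),
    num_probes = vapply(rows, `[[`, 0, "num_probes"),
    copy_number = vapply(rows, `[[`, 0, "copy_number"),
    confidence = vapply(rows, `[[`, 0, "confidence")
  ))
}

.parsePenncnvLine <- function(line, lineno) {
  fail <- function(why) stop("malformed PennCNV line ", lineno, ": ", why)
  tok <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(tok) < 4L) fail("fewer than 4 fields")
  m <- regmatches(tok[1],
                  regexec("^(chr)?([^:]+):([0-9]+)-([0-9]+)$", tok[1]))[[1]]
  if (length(m) == 0L) fail(paste0("bad region '", tok[1], "'"))
  ns <- grep("^numsnp=", tok, value = TRUE)
  if (length(ns) != 1L) fail("missing numsnp= token")
  cn <- grep("^state[0-9]+,cn=[0-9]+$", tok, value = TRUE)
  if (length(cn) != 1L) fail("missing state,cn= token")
  cn_val <- as.integer(sub("^state[0-9]+,cn=", "", cn))
  if (cn_val == 2L) {
    stop("rejected record at line ", lineno,
         ": copy_number 2 (diploid state) is not a CNV")
  }
  conf <- grep("^conf=", tok, value = TRUE)
  conf_val <- if (length(conf) >= 1L) {
    as.numeric(sub("^conf=", "", conf[1]))
  } else NA_real_
  rest <- tok[-1]
  sample <- rest[!grepl("=", rest)]
  if (length(sample) < 1L) fail("missing sample identifier")
  start <- as.numeric(m[4])
  end <- as.numeric(m[5])
  if (end < start) fail("end < start")
  list(chrom = m[3], start = start, end = end, sample_id = sample[1],
       num_probes = as.numeric(sub("^numsnp=", "", ns)),
       copy_number = cn_val, confidence = conf_val)
}

#' Write a CNV call table
#'
#' Round-trips with [readCnvCalls()]: reading the written file reproduces all
#' call fields.
#'
#' @param calls `GRanges` of calls.
#' @param path output file path.
#' @param dialect `"penncnv"` or `"tabular"`.
#' @return `path`, invisibly.
#' @export
writeCnvCalls <- function(calls, path, dialect = c("penncnv", "tabular")) {
  dialect <- match.arg(dialect)
  if (dialect == "tabular") {
    df <- data.frame(
      sample_id = if (length(calls)) calls$sample_id else character(0),
      chrom = as.character(GenomicRanges::seqnames(calls)),
      start = GenomicRanges::start(calls),
      end = GenomicRanges::end(calls),
      num_probes = if (length(calls)) calls$num_probes else integer(0),
      copy_number = if (length(calls)) calls$copy_number else integer(0),
      confidence = if (length(calls)) calls$confidence else numeric(0),
      stringsAsFactors = FALSE
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    state <- c(`0` = 1L, `1` = 2L, `3` = 5L, `4` = 6L)
    lines <- if (length(calls)) {
      sprintf("chr%s:%d-%d numsnp=%d length=%s state%d,cn=%d %s conf=%s",
              as.character(GenomicRanges::seqnames(calls)),
              GenomicRanges::start(calls), GenomicRanges::end(calls),
              calls$num_probes,
              formatC(GenomicRanges::width(calls), big.mark = ",",
                      format = "d"),
              state[as.character(calls$copy_number)], calls$copy_number,
              calls$sample_id, format(calls$confidence))
    } else character(0)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read genomic intervals
#'
#' `bed` input is 0-based half-open and is converted to the internal 1-based
#' inclusive convention on read (BED `(chrom, s, e)` becomes `chrom:(s+1)-e`);
#' [writeIntervalsBed()] inverts the conversion so BED round-trips exactly.
#' `tabular` input is whitespace-separated lines of either
#' `chrom:start-end [label]` (1-based) or `chrom start end [label]` columns.
#'
#' @param path file path.
#' @param format `"bed"` or `"tabular"`.
#' @return `GRanges` with an optional `label` metadata column.
#' @export
readIntervals <- function(path, format = c("bed", "tabular")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    out <- .strip(gr)
    out$label <- if ("name" %in% colnames(S4Vectors::mcols(gr))) {
      as.character(gr$name)
    } else NA_character_
    if (any(GenomicRanges::width(out) < 1L)) {
      stop("interval with end <= start after BED conversion")
    }
    return(out)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    g <- GenomicRanges::GRanges()
    g$label <- character(0)
    return(g)
  }
  parts <- strsplit(trimws(lines), "\\s+")
  one <- function(tok, i) {
    if (grepl(":", tok[1])) {
      m <- regmatches(tok[1],
                      regexec("^(chr)?([^:]+):([0-9]+)-([0-9]+)$",
                              tok[1]))[[1]]
      if (length(m) == 0L) stop("malformed interval line ", i)
      c(m[3], m[4], m[5], if (length(tok) > 1L) tok[2] else NA)
    } else {
      if (length(tok) < 3L) stop("malformed interval line ", i)
      c(tok[1], tok[2], tok[3], if (length(tok) > 3L) tok[4] else NA)
    }
  }
  m <- t(mapply(one, parts, seq_along(parts)))
  start <- as.integer(m[, 2])
  end <- as.integer(m[, 3])
  if (any(end < start) || any(start < 1L)) {
    stop("interval with end < start or start < 1")
  }
  gr <- GenomicRanges::GRanges(normalizeChrom(m[, 1]),
                               IRanges::IRanges(start, end))
  gr$label <- as.character(m[, 4])
  gr
}

#' Write intervals as BED (0-based half-open)
#'
#' @param gr `GRanges` (1-based inclusive, as used throughout the package).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeIntervalsBed <- function(gr, path) {
  df <- data.frame(
    chrom = paste0("chr", normalizeChrom(GenomicRanges::seqnames(gr))),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if ("label" %in% colnames(S4Vectors::mcols(gr)) &&
      !all(is.na(gr$label))) {
    df$name <- gr$label
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read or write a sample manifest
#'
#' Tab-separated with header; required columns `sample_id` and `status`
#' ("case"/"control"), optional `sex`, `call_rate`, `lrr_sd`, `baf_sd`,
#' `wave_factor`, `age`, `family_history`.
#'
#' @param path file path.
#' @return `DataFrame` of samples.
#' @export
readSampleManifest <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% colnames(df))) {
    stop("sample manifest needs 'sample_id' and 'status' columns")
  }
  if (!all(df$status %in% c("case", "control"))) {
    stop("sample status must be 'case' or 'control'")
  }
  S4Vectors::DataFrame(df)
}

#' @rdname readSampleManifest
#' @param samples `DataFrame` or `data.frame` of samples.
#' @export
writeSampleManifest <- function(samples, path) {
  utils::write.table(as.data.frame(samples), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
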