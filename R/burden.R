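#' Classify rare calls by occurrence frequency
#'
#' Partitions calls into `single`, `two_to_six` and `above_six` classes. A
#' call is a *single occurrence* when no other call covers strictly more
#' than `frac` of its length. A non-single call is `two_to_six` when it is
#' overlapped by six or fewer other calls by at least `frac` of its length,
#' and `above_six` otherwise.
#'
#' For type-restricted classifications (`cnv_type = "deletions"` or
#' `"duplications"`) only same-type calls count as overlap partners: a
#' deletion remains a single occurrence even when a duplication covers more
#' than half of it. Calls of the other type get `NA`. Consequently the
#' type-restricted single-occurrence counts need not sum to the both-types
#' count.
#'
#' @param calls `GRanges` of rare calls (with `cnv_type` column).
#' @param cnv_type `"all"`, `"deletions"` or `"duplications"` — which calls
#'   to classify and which partners to count.
#' @param frac overlap fraction of the focal call's length (default 0.5).
#' @return factor with levels `single`, `two_to_six`, `above_six` (NA for
#'   calls outside a type-restricted classification).
#' @export
classifyFrequency <- function(calls,
                              cnv_type = c("all", "deletions",
                                           "duplications"),
                              frac = 0.5) {
  cnv_type <- match.arg(cnv_type)
  lev <- c("single", "two_to_six", "above_six")
  out <- factor(rep(NA_character_, length(calls)), levels = lev)
  if (length(calls) == 0L) return(out)
  in_set <- switch(cnv_type,
    all = rep(TRUE, length(calls)),
    deletions = calls$cnv_type == "deletion",
    duplications = calls$cnv_type == "duplication")
  set <- calls[in_set]
  if (length(set) == 0L) return(out)
  over_half <- .partnerCounts(set, set, frac, strict = TRUE,
                              exclude_self = TRUE)
  at_least_half <- .partnerCounts(set, set, frac, strict = FALSE,
                                  exclude_self = TRUE)
  cls <- ifelse(over_half == 0L, "single",
                ifelse(at_least_half <= 6L, "two_to_six", "above_six"))
  out[in_set] <- factor(cls, levels = lev)
  out
}

#' Table-4-style burden strata
#'
#' The default stratification: each row fixes a CNV type (`all`,
#' `deletions`, `duplications`), an occurrence-frequency class (`all`,
#' `single`, `two_to_six`) and a size class (`all`, `100-500kb`, `ge500kb`,
#' `ge1Mb`). The size rows overlap by construction (`ge500kb` contains
#' `ge1Mb`) and are computed independently, not as a partition.
#'
#' @return data.frame with columns `cnv_type`, `freq_class`, `size_class`.
#' @export
defaultStrata <- function() {
  type3 <- c("all", "deletions", "duplications")
  rows <- rbind(
    data.frame(cnv_type = type3, freq_class = "all", size_class = "all"),
    data.frame(cnv_type = rep(type3, each = 2),
               freq_class = rep(c("single", "two_to_six"), 3),
               size_class = "all"),
    data.frame(cnv_type = rep(type3, each = 3),
               freq_class = "all",
               size_class = rep(c("100-500kb", "ge500kb", "ge1Mb"), 3))
  )
  rownames(rows) <- NULL
  rows
}

# logical index of calls belonging to one stratum
.stratumIndex <- function(calls, cnv_type = "all", freq_class = "all",
                          size_class = "all", frac = 0.5) {
  keep <- rep(TRUE, length(calls))
  if (cnv_type == "deletions") keep <- keep & calls$cnv_type == "deletion"
  if (cnv_type == "duplications") {
    keep <- keep & calls$cnv_type == "duplication"
  }
  if (freq_class != "all") {
    cls <- classifyFrequency(calls, cnv_type, frac)
    keep <- keep & !is.na(cls) & cls == freq_class
  }
  w <- GenomicRanges::width(calls)
  keep & switch(size_class,
    all = TRUE,
    `100-500kb` = w < 500000,
    ge500kb = w >= 500000,
    ge1Mb = w >= 1e6,
    stop("unknown size_class '", size_class, "'"))
}

# Per-sample summaries of a stratum's calls, aligned to the sample manifest
# (samples without calls contribute zeros). kb is the summed call length in
# kilobases per sample.
.perSample <- function(calls, samples) {
  ids <- samples$sample_id
  ct <- as.integer(table(factor(calls$sample_id, levels = ids)))
  kb <- numeric(length(ids))
  if (length(calls) > 0L) {
    agg <- tapply(GenomicRanges::width(calls) / 1000,
                  factor(calls$sample_id, levels = ids), sum)
    kb <- as.numeric(ifelse(is.na(agg), 0, agg))
  }
  list(ct = ct, kb = kb, carrier = as.integer(ct > 0L))
}

# The four burden statistics of one group given per-sample vectors and the
# member index of the group. avg is the mean call size (kb), i.e. total kb
# over number of calls, 0 when the group has no stratum calls.
.groupStats <- function(ps, idx) {
  n <- length(idx)
  ctot <- sum(ps$ct[idx])
  ktot <- sum(ps$kb[idx])
  c(rate = ctot / n,
    sample_proportion = sum(ps$carrier[idx]) / n,
    total_size = ktot / n,
    avg_size = if (ctot > 0) ktot / ctot else 0)
}

#' Burden statistics for one stratum
#'
#' Computes, per group, the four burden measures: CNV rate (calls per
#' sample), CNV sample proportion (fraction of samples with at least one
#' stratum call), total CNV size (mean per-sample summed kb, zeros
#' included — a per-sample scale, invariant to group size), and average CNV
#' size (mean size in kb of the group's stratum calls). Ratios are
#' case/control; a zero control value yields an `NA` ratio (reported N/A).
#'
#' @param calls `GRanges` of rare calls.
#' @param samples sample manifest (`DataFrame`/`data.frame` with
#'   `sample_id`, `status`).
#' @param cnv_type,freq_class,size_class stratum axes (see
#'   [defaultStrata()]).
#' @param frac occurrence-overlap fraction for frequency classification.
#' @return one-row data.frame with case/control counts and, per statistic,
#'   `<stat>_case`, `<stat>_control`, `<stat>_ratio`.
#' @export
burdenStatistics <- function(calls, samples, cnv_type = "all",
                             freq_class = "all", size_class = "all",
                             frac = 0.5) {
  stopifnot(all(c("case", "control") %in% samples$status))
  idx <- .stratumIndex(calls, cnv_type, freq_class, size_class, frac)
  sc <- calls[idx]
  ps <- .perSample(sc, samples)
  case_i <- which(samples$status == "case")
  ctrl_i <- which(samples$status == "control")
  cs <- .groupStats(ps, case_i)
  xs <- .groupStats(ps, ctrl_i)
  out <- data.frame(cnv_type = cnv_type, freq_class = freq_class,
                    size_class = size_class,
                    case_cnv_count = sum(ps$ct[case_i]),
                    control_cnv_count = sum(ps$ct[ctrl_i]),
                    stringsAsFactors = FALSE)
  for (stat in names(cs)) {
    out[[paste0(stat, "_case")]] <- cs[[stat]]
    out[[paste0(stat, "_control")]] <- xs[[stat]]
    out[[paste0(stat, "_ratio")]] <-
      if (xs[[stat]] > 0) cs[[stat]] / xs[[stat]] else NA_real_
  }
  out
}

# Core label-permutation engine. ps: per-sample vectors; status: character
# vector aligned to samples. Returns the empirical p per statistic using the
# add-one estimator (R+1)/(N+1); exhaustive mode enumerates every
# case-assignment of size n_case and returns the exact permutation p
# (#{stat >= observed} / #labelings, the observed labeling included).
.permuteStats <- function(ps, status, n_perm, alternative = "greater",
                          exhaustive = FALSE) {
  n <- length(status)
  case_i <- which(status == "case")
  n_case <- length(case_i)
  obs <- .groupStats(ps, case_i)
  tol <- 1e-9 * pmax(1, abs(obs))
  if (exhaustive) {
    combos <- utils::combn(n, n_case)
    stats <- apply(combos, 2L, function(idx) .groupStats(ps, idx))
    p_ge <- rowMeans(stats >= obs - tol)
    p_le <- rowMeans(stats <= obs + tol)
  } else {
    if (n_perm < 1L) stop("n_perm must be >= 1")
    ge <- le <- numeric(4)
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n, n_case)
      st <- .groupStats(ps, idx)
      ge <- ge + (st >= obs - tol)
      le <- le + (st <= obs + tol)
    }
    p_ge <- (1 + ge) / (1 + n_perm)
    p_le <- (1 + le) / (1 + n_perm)
  }
  p <- switch(alternative,
    greater = p_ge,
    less = p_le,
    two.sided = pmin(1, 2 * pmin(p_ge, p_le)),
    stop("unknown alternative"))
  names(p) <- names(obs)
  list(observed = obs, p = p)
}

#' Permutation p-values for one stratum's burden statistics
#'
#' Case/control labels are randomly reassigned preserving group sizes; the
#' statistic of each permutation is the case-group value. The one-sided
#' (default) empirical p is `(1 + #{perm >= observed}) / (1 + n_perm)` — the
#' add-one estimator, whose minimum attainable value is `1/(n_perm + 1)`.
#' The one-sided direction is "cases show greater burden"; `alternative`
#' allows `"less"` or `"two.sided"`. With `exhaustive = TRUE` all
#' `choose(n, n_cases)` labelings are enumerated and the exact permutation
#' p is returned instead (small samples only).
#'
#' @inheritParams burdenStatistics
#' @param n_perm number of label permutations (default 100,000).
#' @param seed optional RNG seed for a reproducible permutation stream.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param exhaustive enumerate all labelings instead of sampling.
#' @return one-row data.frame: the [burdenStatistics()] columns plus
#'   `<stat>_p` per statistic.
#' @export
permuteBurden <- function(calls, samples, cnv_type = "all",
                          freq_class = "all", size_class = "all",
                          n_perm = 100000L, seed = NULL,
                          alternative = c("greater", "less", "two.sided"),
                          exhaustive = FALSE, frac = 0.5) {
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  res <- burdenStatistics(calls, samples, cnv_type, freq_class, size_class,
                          frac)
  idx <- .stratumIndex(calls, cnv_type, freq_class, size_class, frac)
  ps <- .perSample(calls[idx], samples)
  pp <- .permuteStats(ps, samples$status, n_perm, alternative, exhaustive)
  for (stat in names(pp$p)) res[[paste0(stat, "_p")]] <- pp$p[[stat]]
  res
}

#' Full stratified burden report
#'
#' Runs [permuteBurden()] over every stratum, producing the report shape of
#' a global rare-CNV burden table: per stratum the case/control call
#' counts, and for each of the four statistics the case/control ratio, the
#' control baseline and the empirical p-value. Deterministic given `seed`.
#'
#' @inheritParams permuteBurden
#' @param strata data.frame of strata (default [defaultStrata()]).
#' @return data.frame, one row per stratum.
#' @export
burdenTable <- function(calls, samples, strata = defaultStrata(),
                        n_perm = 100000L, seed = NULL,
                        alternative = c("greater", "less", "two.sided"),
                        frac = 0.5) {
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    permuteBurden(calls, samples,
                  cnv_type = strata$cnv_type[i],
                  freq_class = strata$freq_class[i],
                  size_class = strata$size_class[i],
                  n_perm = n_perm, seed = NULL,
                  alternative = alternative, frac = frac)
  })
  do.call(rbind, rows)
}
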