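#' Merge overlapping rare CNVs into nonredundant regions (CNVRs)
#'
#' Connected components of same-chromosome overlap (at least 1 bp, the
#' transitive closure: if A overlaps B and B overlaps C, all three merge
#' even when A and C are disjoint). Each region's interval runs from the
#' minimum start to the maximum end over its member calls. Output is
#' deterministically ordered by chromosome then start.
#'
#' @param calls `GRanges` of rare calls.
#' @param samples optional sample manifest; when given, per-region carrier
#'   sets are split into case and control carriers.
#' @param genes optional gene annotation (`GRanges` with `label`); region
#'   rows gain a comma-separated `genes` column of overlapping gene labels.
#' @param merge_frac optional fraction: merge two calls only when their
#'   overlap covers at least this fraction of the shorter call's length
#'   (default 0, i.e. any 1 bp overlap merges).
#' @return `GRanges` of regions with metadata columns `n_calls`,
#'   `carriers` (CharacterList of distinct sample ids) and, when `samples`
#'   is given, `case_carriers`/`control_carriers` counts.
#' @export
buildCnvrs <- function(calls, samples = NULL, genes = NULL,
                       merge_frac = 0) {
  if (length(calls) == 0L) {
    out <- GenomicRanges::GRanges()
    out$n_calls <- integer(0)
    return(out)
  }
  q <- .strip(calls)
  if (merge_frac <= 0) {
    red <- GenomicRanges::reduce(q, min.gapwidth = 0L)
    comp <- S4Vectors::subjectHits(
      GenomicRanges::findOverlaps(q, red, ignore.strand = TRUE))
  } else {
    # union-find over qualifying pairwise overlaps
    hits <- GenomicRanges::findOverlaps(q, q, ignore.strand = TRUE)
    hits <- hits[S4Vectors::queryHits(hits) < S4Vectors::subjectHits(hits)]
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    w <- pmin(GenomicRanges::end(q)[qh], GenomicRanges::end(q)[sh]) -
      pmax(GenomicRanges::start(q)[qh], GenomicRanges::start(q)[sh]) + 1L
    shorter <- pmin(GenomicRanges::width(q)[qh],
                    GenomicRanges::width(q)[sh])
    ok <- as.numeric(w) / shorter >= merge_frac
    parent <- seq_along(q)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (k in which(ok)) {
      a <- find(qh[k]); b <- find(sh[k])
      if (a != b) parent[b] <- a
    }
    comp <- vapply(seq_along(q), find, 0L)
    comp <- match(comp, unique(comp))
  }
  starts <- tapply(GenomicRanges::start(q), comp, min)
  ends <- tapply(GenomicRanges::end(q), comp, max)
  chroms <- tapply(as.character(GenomicRanges::seqnames(q)), comp,
                   function(v) v[1])
  out <- GenomicRanges::GRanges(as.character(chroms),
                                IRanges::IRanges(as.integer(starts),
                                                 as.integer(ends)))
  out$n_calls <- unname(as.integer(tapply(comp, comp, length)))
  carriers <- tapply(calls$sample_id, comp, function(v) sort(unique(v)),
                     simplify = FALSE)
  names(carriers) <- NULL
  out$carriers <- IRanges::CharacterList(carriers)
  chr_num <- suppressWarnings(as.integer(as.character(
    GenomicRanges::seqnames(out))))
  ord <- order(chr_num, as.character(GenomicRanges::seqnames(out)),
               GenomicRanges::start(out), na.last = TRUE)
  out <- out[ord]
  if (!is.null(samples)) {
    status <- as.character(samples$status)
    names(status) <- as.character(samples$sample_id)
    out$case_carriers <- unname(vapply(out$carriers, function(v) {
      sum(status[v] == "case", na.rm = TRUE)
    }, 0L))
    out$control_carriers <- unname(vapply(out$carriers, function(v) {
      sum(status[v] == "control", na.rm = TRUE)
    }, 0L))
  }
  if (!is.null(genes)) {
    hits <- GenomicRanges::findOverlaps(.strip(out), .strip(genes),
                                        ignore.strand = TRUE)
    lab <- rep(NA_character_, length(out))
    if (length(hits) > 0L) {
      agg <- tapply(genes$label[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits),
                    function(v) paste(sort(unique(v)), collapse = ","))
      lab[as.integer(names(agg))] <- as.character(agg)
    }
    out$genes <- lab
  }
  out
}

#' Fisher exact test on a region carrier table
#'
#' Tests the 2x2 table (case carriers, case non-carriers; control carriers,
#' control non-carriers). The default is the one-sided "cases enriched"
#' test, the convention used throughout the region association analysis;
#' `alternative = "two.sided"` gives the classical two-sided exact test
#' (the sum of all tables with point probability at most the observed
#' one). Degenerate margins (no carriers at all) give p = 1.
#'
#' @param case_with,case_without,control_with,control_without the four
#'   cell counts (vectorized).
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return numeric vector of exact p-values.
#' @examples
#' regionFisher(7, 254, 0, 171)   # 0.0284
#' regionFisher(5, 256, 0, 171)   # 0.0793
#' @export
regionFisher <- function(case_with, case_without, control_with,
                         control_without,
                         alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  mapply(function(a, b, c, d) {
    if (a + c == 0L) return(1.0)
    stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                       alternative = alternative)$p.value
  }, case_with, case_without, control_with, control_without)
}

# Fisher p lookup for a region with m carriers under every possible split:
# entry k+1 is the p-value when k of the m carriers fall in the case group.
.fisherLookup <- function(m, n_case, n_ctrl, alternative = "greater") {
  vapply(0:m, function(k) {
    regionFisher(k, n_case - k, m - k, n_ctrl - (m - k), alternative)
  }, 0)
}

#' Per-region empirical and family-wise permutation p-values
#'
#' Case/control labels are reassigned preserving group sizes; carrier sets
#' stay fixed. The per-region statistic is the number of carriers assigned
#' to the case group, so the per-region empirical p is the add-one fraction
#' of permutations with at least as many case carriers as observed (for a
#' region whose carriers are all cases this converges to the one-sided
#' hypergeometric tail). The family-wise corrected p is the min-p
#' procedure: the add-one fraction of permutations in which the minimum
#' one-sided Fisher p across all regions is at most the region's observed
#' Fisher p. With `exhaustive = TRUE` every case-assignment is enumerated
#' and exact probabilities are returned (no add-one).
#'
#' @param regions `GRanges` from [buildCnvrs()] (needs the `carriers`
#'   column).
#' @param samples sample manifest.
#' @param n_perm number of permutations (default 100,000).
#' @param seed optional RNG seed.
#' @param exhaustive enumerate all labelings (small samples only).
#' @return data.frame, one row per region: coordinates, the four carrier
#'   table counts, `fisher_p` (one-sided), `empirical_p`, `corrected_p`.
#' @export
regionPermutation <- function(regions, samples, n_perm = 100000L,
                              seed = NULL, exhaustive = FALSE) {
  if (!exhaustive && n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ids <- as.character(samples$sample_id)
  status <- as.character(samples$status)
  n <- length(ids)
  n_case <- sum(status == "case")
  n_ctrl <- n - n_case
  carrier_idx <- lapply(regions$carriers, function(v) {
    ii <- match(v, ids)
    ii[!is.na(ii)]
  })
  m <- lengths(carrier_idx)
  is_case <- status == "case"
  k_obs <- vapply(carrier_idx, function(ii) sum(is_case[ii]), 0L)
  lookup <- lapply(m, .fisherLookup, n_case = n_case, n_ctrl = n_ctrl)
  fisher_obs <- mapply(function(tab, k) tab[k + 1L], lookup, k_obs)
  nreg <- length(regions)
  tol <- 1e-12
  draw_k <- function(z) {
    vapply(carrier_idx, function(ii) sum(z[ii]), 0L)
  }
  if (exhaustive) {
    combos <- utils::combn(n, n_case)
    total <- ncol(combos)
    ge_emp <- ge_corr <- numeric(nreg)
    for (j in seq_len(total)) {
      z <- logical(n)
      z[combos[, j]] <- TRUE
      k <- draw_k(z)
      ge_emp <- ge_emp + (k >= k_obs)
      minp <- min(mapply(function(tab, kk) tab[kk + 1L], lookup, k))
      ge_corr <- ge_corr + (minp <= fisher_obs + tol)
    }
    empirical_p <- ge_emp / total
    corrected_p <- ge_corr / total
  } else {
    ge_emp <- ge_corr <- numeric(nreg)
    for (b in seq_len(n_perm)) {
      z <- logical(n)
      z[sample.int(n, n_case)] <- TRUE
      k <- draw_k(z)
      ge_emp <- ge_emp + (k >= k_obs)
      minp <- min(mapply(function(tab, kk) tab[kk + 1L], lookup, k))
      ge_corr <- ge_corr + (minp <= fisher_obs + tol)
    }
    empirical_p <- (1 + ge_emp) / (1 + n_perm)
    corrected_p <- (1 + ge_corr) / (1 + n_perm)
  }
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions),
    end = GenomicRanges::end(regions),
    case_with = k_obs, case_without = n_case - k_obs,
    control_with = m - k_obs,
    control_without = n_ctrl - (m - k_obs),
    fisher_p = as.numeric(fisher_obs),
    empirical_p = empirical_p, corrected_p = corrected_p,
    stringsAsFactors = FALSE)
}

#' Region-level case-control association
#'
#' The full region analysis: merge rare calls into CNVRs, count distinct
#' case and control carriers per region, test each region with the
#' one-sided Fisher exact test, and attach per-region empirical and
#' family-wise min-p corrected permutation p-values. Carrier status ignores
#' CNV type (a deletion carrier and a duplication carrier both count);
#' `split_by_type = TRUE` instead analyses deletions and duplications as
#' separate region sets, flagged by a `cnv_type` column.
#'
#' @param x a [CnvDataset-class] holding the rare set.
#' @param genes optional gene annotation (`GRanges` with `label`).
#' @param n_perm number of permutations (default 100,000).
#' @param seed optional RNG seed.
#' @param merge_frac merge criterion passed to [buildCnvrs()].
#' @param split_by_type analyse each CNV type separately.
#' @return data.frame, one row per region, ordered by `fisher_p`.
#' @export
cnvrAssociation <- function(x, genes = NULL, n_perm = 100000L, seed = NULL,
                            merge_frac = 0, split_by_type = FALSE) {
  samples <- sampleInfo(x)
  run_one <- function(calls, type_label) {
    regions <- buildCnvrs(calls, samples, genes, merge_frac)
    if (length(regions) == 0L) return(NULL)
    res <- regionPermutation(regions, samples, n_perm)
    res$n_calls <- regions$n_calls
    if (!is.null(genes)) res$genes <- regions$genes
    res$cnv_type <- type_label
    res
  }
  if (!is.null(seed)) set.seed(seed)
  if (split_by_type) {
    calls <- cnvCalls(x)
    out <- rbind(
      run_one(calls[calls$cnv_type == "deletion"], "deletion"),
      run_one(calls[calls$cnv_type == "duplication"], "duplication"))
  } else {
    out <- run_one(cnvCalls(x), "any")
  }
  if (is.null(out)) return(out)
  out <- out[order(out$fisher_p, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
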