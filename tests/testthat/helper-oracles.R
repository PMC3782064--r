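# quick builders -------------------------------------------------------

mkCalls <- function(chrom, start, end, sample_id, cn = 1L,
                    probes = 50L, conf = 50) {
  n <- length(start)
  calls <- makeCnvCalls(rep_len(chrom, n), start, end,
                        rep_len(sample_id, n), rep_len(probes, n),
                        rep_len(cn, n), rep_len(conf, n))
  # shared seqlevels so fixtures from different chromosomes concatenate
  GenomeInfoDb::seqlevels(calls) <-
    union(GenomeInfoDb::seqlevels(calls), c(as.character(1:22), "X"))
  calls
}

mkSamples <- function(case_ids, ctrl_ids, call_rate = 0.999,
                      lrr_sd = 0.15, baf_sd = 0.05, wave_factor = 0.01) {
  ids <- c(case_ids, ctrl_ids)
  data.frame(sample_id = ids,
             status = rep(c("case", "control"),
                          c(length(case_ids), length(ctrl_ids))),
             call_rate = call_rate, lrr_sd = lrr_sd, baf_sd = baf_sd,
             wave_factor = wave_factor, stringsAsFactors = FALSE)
}

mkInterval <- function(chrom, start, end, label = NA_character_) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  gr$label <- label
  gr
}

# brute-force oracles ---------------------------------------------------

# per-base union coverage by looping over individual bases (small coords!)
bruteCoverageFraction <- function(q_start, q_end, t_starts, t_ends) {
  bases <- q_start:q_end
  covered <- vapply(bases, function(b) {
    any(t_starts <= b & t_ends >= b)
  }, TRUE)
  mean(covered)
}

# exhaustive label-permutation p for the four burden statistics, written
# independently of the package engine (plain formulas over combn subsets)
brutePermBurden <- function(ct, kb, n_case) {
  n <- length(ct)
  stats4 <- function(idx) {
    tot <- sum(ct[idx])
    c(rate = sum(ct[idx]) / length(idx),
      sample_proportion = mean(ct[idx] > 0),
      total_size = sum(kb[idx]) / length(idx),
      avg_size = if (tot > 0) sum(kb[idx]) / tot else 0)
  }
  obs <- stats4(seq_len(n_case))
  combos <- utils::combn(n, n_case)
  all_stats <- apply(combos, 2, stats4)
  rowMeans(all_stats >= obs - 1e-9)
}

# exhaustive min-p region permutation oracle: carrier index sets, direct
# fisher.test calls, enumeration over all case assignments
bruteRegionPerm <- function(carrier_sets, n, n_case) {
  combos <- utils::combn(n, n_case)
  obs_case <- seq_len(n_case)
  k_of <- function(case_set) {
    vapply(carrier_sets, function(s) sum(s %in% case_set), 0L)
  }
  fish <- function(k, m) {
    stats::fisher.test(matrix(c(k, n_case - k, m - k,
                                (n - n_case) - (m - k)), 2, byrow = TRUE),
                      alternative = "greater")$p.value
  }
  m <- lengths(carrier_sets)
  k_obs <- k_of(obs_case)
  f_obs <- mapply(fish, k_obs, m)
  ge_emp <- ge_corr <- numeric(length(carrier_sets))
  for (j in seq_len(ncol(combos))) {
    k <- k_of(combos[, j])
    ge_emp <- ge_emp + (k >= k_obs)
    minp <- min(mapply(fish, k, m))
    ge_corr <- ge_corr + (minp <= f_obs + 1e-12)
  }
  list(empirical = ge_emp / ncol(combos),
       corrected = ge_corr / ncol(combos), fisher = f_obs)
}

# union-find connected components of >=1 bp overlap (oracle for CNVR
# merging), independent of GenomicRanges::reduce
bruteComponents <- function(chrom, start, end) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && chrom[i] == chrom[j] &&
        start[i] <= end[j] && end[i] >= start[j]) {
      parent[find(j)] <- find(i)
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  match(comp, unique(comp))
}
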