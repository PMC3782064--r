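test_that("overlapping recurrent-locus calls merge into one region", {
  ds <- fixtureOvos2Dataset()
  r <- buildCnvrs(cnvCalls(ds), sampleInfo(ds))
  expect_length(r, 1)
  expect_equal(as.character(GenomicRanges::seqnames(r)), "12")
  expect_equal(GenomicRanges::start(r), 31152226L)
  expect_equal(GenomicRanges::end(r), 31300846L)
  expect_equal(GenomicRanges::width(r), 148621L)
  expect_equal(r$case_carriers, 7L)
  expect_equal(r$control_carriers, 0L)
  expect_length(r$carriers[[1]], 7)
})

test_that("merging is transitive, order-invariant and idempotent", {
  # chain: A-B overlap, B-C overlap, A-C disjoint -> one region
  chain <- mkCalls("9", c(1e6, 1.4e6, 1.9e6),
                   c(1.5e6, 2.0e6, 2.4e6), c("A", "B", "C"))
  r <- buildCnvrs(chain)
  expect_length(r, 1)
  expect_equal(GenomicRanges::start(r), 1000000L)
  expect_equal(GenomicRanges::end(r), 2400000L)

  # two disjoint calls on one chromosome -> two regions
  expect_length(buildCnvrs(mkCalls("9", c(1e6, 5e6), c(1.2e6, 5.2e6),
                                   c("A", "B"))), 2)

  # random sets agree with a union-find oracle and are order-invariant
  set.seed(47)
  for (i in 1:10) {
    n <- 20
    chrom <- sample(c("3", "4"), n, replace = TRUE)
    st <- sample.int(5e6, n)
    en <- st + sample.int(8e5, n) + 1e5
    calls <- mkCalls(chrom, st, en, paste0("S", 1:n))
    r1 <- buildCnvrs(calls)
    expect_length(r1, max(bruteComponents(chrom, st, en)))
    perm <- sample(n)
    r2 <- buildCnvrs(calls[perm])
    expect_equal(GenomicRanges::start(r1), GenomicRanges::start(r2))
    expect_equal(GenomicRanges::end(r1), GenomicRanges::end(r2))
    # idempotence: merging the (disjoint) region spans changes nothing
    spans <- mkCalls(as.character(GenomicRanges::seqnames(r1)),
                     GenomicRanges::start(r1), GenomicRanges::end(r1),
                     paste0("R", seq_along(r1)))
    expect_length(buildCnvrs(spans), length(r1))
  }
})

test_that("a fractional merge criterion splits weak overlaps", {
  # two ~1 Mb calls sharing only ~10 kb: the default 1 bp rule merges
  # them, a 50%-of-the-shorter criterion does not
  weak <- mkCalls("5", c(1e6, 1.99e6), c(2e6, 3e6), c("A", "B"))
  expect_length(buildCnvrs(weak), 1)
  expect_length(buildCnvrs(weak, merge_frac = 0.5), 2)
})

test_that("region Fisher tests match closed-form tail probabilities", {
  # all-case carrier tables: one-sided p equals the hypergeometric tail
  # prod_{i<k}(n_case - i)/(n - i), an independent closed form
  tail_p <- function(k, n_case, n) prod((n_case - 0:(k - 1)) / (n - 0:(k - 1)))
  for (k in c(3, 5, 7)) {
    expect_equal(regionFisher(k, 261 - k, 0, 171),
                 tail_p(k, 261, 432), tolerance = 1e-10)
  }
  # a perfectly balanced table: two-sided p is 1, one-sided is 5/6
  expect_equal(regionFisher(1, 1, 1, 1, alternative = "two.sided"), 1.0)
  expect_equal(regionFisher(1, 1, 1, 1), 5 / 6)
  expect_equal(regionFisher(0, 261, 0, 171), 1.0)  # degenerate margin
})

test_that("region permutation matches exhaustive enumeration exactly", {
  # 3 regions, 6 samples (3 cases), enumerable labelings
  carriers <- list(c(1L, 2L), c(1L, 4L, 5L), 6L)
  calls <- c(mkCalls("1", c(1e6, 1.05e6), c(1.2e6, 1.25e6),
                     c("S1", "S2")),
             mkCalls("2", c(1e6, 1.1e6, 1.05e6), c(1.3e6, 1.4e6, 1.35e6),
                     c("S1", "S4", "S5")),
             mkCalls("3", 1e6, 1.2e6, "S6"))
  samples <- mkSamples(paste0("S", 1:3), paste0("S", 4:6))
  regions <- buildCnvrs(calls, samples)
  res <- regionPermutation(regions, samples, exhaustive = TRUE)
  oracle <- bruteRegionPerm(carriers, n = 6, n_case = 3)
  expect_equal(res$fisher_p, oracle$fisher)
  expect_equal(res$empirical_p, oracle$empirical)
  expect_equal(res$corrected_p, oracle$corrected)
  # family-wise ordering holds
  expect_true(all(res$corrected_p >= res$empirical_p - 1e-12))
})

test_that("a single-region family needs no correction", {
  ds <- fixtureOvos2Dataset()
  r <- buildCnvrs(cnvCalls(ds), sampleInfo(ds))
  res <- regionPermutation(r, sampleInfo(ds), n_perm = 3000, seed = 21)
  expect_equal(res$corrected_p, res$empirical_p)
  expect_gte(res$empirical_p, 1 / 3001)
})

test_that("all-case carrier permutation converges to the analytic tail", {
  ds <- fixtureOvos2Dataset()
  r <- buildCnvrs(cnvCalls(ds), sampleInfo(ds))
  res <- regionPermutation(r, sampleInfo(ds), n_perm = 20000, seed = 8)
  analytic <- prod((261 - 0:6) / (432 - 0:6))
  se <- sqrt(analytic * (1 - analytic) / 20000)
  expect_lt(abs(res$empirical_p - analytic), 3 * se + 2 / 20001)
})

test_that("the region association table is complete and ordered", {
  sim <- simulateCnvDataset(simConfig(n_cases = 30, n_controls = 20,
                                      seed = 53,
                                      planted_loci =
                                        plantedRecurrentLocus(4, 0)))
  res <- cnvrAssociation(sim$dataset, genes = sim$genes, n_perm = 500,
                         seed = 2)
  expect_false(is.unsorted(res$fisher_p))
  expect_true(all(res$case_with + res$case_without == 30))
  expect_true(all(res$control_with + res$control_without == 20))
  expect_true(all(res$empirical_p > 0 & res$empirical_p <= 1))
  expect_true(all(res$corrected_p >= res$empirical_p - 1e-12))
  # the planted locus is the top region with 4 case carriers
  expect_equal(res$case_with[1], 4L)
  expect_equal(res$chrom[1], "12")
})
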