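# one call per sample so sample filters are visible in call counts
qcFixture <- function(n = 6) {
  ids <- paste0("S", seq_len(n))
  calls <- mkCalls("2", seq(1e6, by = 2e6, length.out = n),
                   seq(1e6, by = 2e6, length.out = n) + 149999, ids)
  list(calls = calls,
       samples = mkSamples(ids[seq_len(ceiling(n / 2))],
                           ids[-seq_len(ceiling(n / 2))]))
}

test_that("sample metric thresholds fail on the quoted side only", {
  fx <- qcFixture(6)
  s <- fx$samples
  s$call_rate[1] <- 0.997    # below 99.8% -> removed
  s$call_rate[2] <- 0.998    # exactly at threshold -> kept
  s$lrr_sd[3] <- 0.27        # exactly 0.27 -> kept (strict >)
  s$baf_sd[4] <- 0.171       # above 0.17 -> removed
  s$wave_factor[5] <- -0.041 # |wave| > 0.04 -> removed
  s$wave_factor[6] <- 0.04   # exactly 0.04 -> kept
  out <- filterSamples(CnvDataset(fx$calls, s))
  kept <- sampleInfo(out)$sample_id
  expect_setequal(kept, c("S2", "S3", "S6"))
  # removed samples take their calls with them
  expect_true(all(cnvCalls(out)$sample_id %in% kept))
  # nominal dataset is a no-op
  clean <- filterSamples(CnvDataset(fx$calls, fx$samples))
  expect_equal(nrow(sampleInfo(clean)), 6)
})

test_that("absent sample metrics skip their rule with a warning", {
  fx <- qcFixture(2)
  s <- fx$samples[, c("sample_id", "status", "call_rate")]
  w <- capture_warnings(out <- filterSamples(CnvDataset(fx$calls, s)))
  expect_true(any(grepl("lrr_sd", w)))
  expect_true(any(grepl("wave_factor", w)))
  expect_equal(nrow(sampleInfo(out)), 2)
})

test_that("call-level thresholds respect their boundaries", {
  ids <- paste0("S", 1:5)
  calls <- makeCnvCalls(
    chrom = c("3", "3", "3", "3", "X"),
    start = rep(1e6, 5),
    end = 1e6 + c(149999, 99998, 99999, 149999, 149999),
    sample_id = ids,
    num_probes = c(4L, 50L, 50L, 50L, 50L),   # call 1: too few probes
    copy_number = rep(1L, 5),
    confidence = c(50, 50, 50, 9.999, 50))    # call 4: low confidence
  # call 2 has length 99,999 (removed); call 3 exactly 100,000 (kept)
  ds <- filterCalls(CnvDataset(calls, mkSamples(ids[1:3], ids[4:5])))
  expect_equal(cnvCalls(ds)$sample_id, "S3")
  prov <- provenance(ds)
  expect_equal(prov$removed_calls[match(c("probes", "length", "confidence",
                                          "autosome"), prov$rule)],
               c(1L, 1L, 1L, 1L))
})

test_that("excluded-region filter uses union coverage with inclusive boundary", {
  ids <- c("A", "B", "C")
  calls <- mkCalls("1", c(100001, 300001, 500001),
                   c(200000, 400000, 600000), ids)
  track <- GenomicRanges::GRanges("1", IRanges::IRanges(
    c(150001, 350002, 500001, 530001),
    c(200000, 400000, 535000, 555000)))
  # A: exactly 50,000/100,000 covered -> removed (>= boundary)
  # B: 49,999/100,000 -> kept
  # C: two overlapping records covering 55,000 distinct bases -> removed
  ds <- filterExcludedRegions(CnvDataset(calls, mkSamples(ids[1:2],
                                                          ids[3])),
                              track)
  expect_equal(cnvCalls(ds)$sample_id, "B")
})

test_that("union coverage matches a per-base brute-force oracle", {
  set.seed(11)
  for (i in 1:20) {
    qs <- sample.int(500, 1)
    qe <- qs + sample.int(400, 1)
    n_t <- sample.int(4, 1)
    ts <- sample.int(900, n_t)
    te <- ts + sample.int(300, n_t)
    q <- mkInterval("9", qs, qe)
    track <- GenomicRanges::GRanges("9", IRanges::IRanges(ts, te))
    expect_equal(coverageFraction(q, track),
                 bruteCoverageFraction(qs, qe, ts, te))
  }
})

test_that("outlier samples are removed by count and by giant calls", {
  # 20 samples with 4 calls each and one with 40
  ids <- paste0("S", 1:21)
  n_calls <- c(rep(4, 20), 40)
  chrom <- rep("6", sum(n_calls))
  st <- seq(1e6, by = 2e5, length.out = sum(n_calls))
  calls <- mkCalls(chrom, st, st + 120000, rep(ids, n_calls))
  ds <- CnvDataset(calls, mkSamples(ids[1:10], ids[11:21]))
  out <- removeOutlierSamples(ds)
  expect_false("S21" %in% sampleInfo(out)$sample_id)
  expect_equal(nrow(sampleInfo(out)), 20)

  # identical counts: SD = 0 but count == mean, nobody removed
  even <- CnvDataset(mkCalls("6", seq(1e6, by = 2e5, length.out = 21),
                             seq(1e6, by = 2e5, length.out = 21) + 120000,
                             ids),
                     mkSamples(ids[1:10], ids[11:21]))
  expect_equal(nrow(sampleInfo(removeOutlierSamples(even))), 21)

  # one 8 Mb duplication removes its carrier regardless of count
  giant <- CnvDataset(
    c(mkCalls("6", 1e6, 9e6, "S1", cn = 3L),
      mkCalls("6", c(2e7, 3e7), c(2.01e7, 3.01e7), c("S2", "S3"))),
    mkSamples(c("S1", "S2"), "S3"))
  out2 <- removeOutlierSamples(giant)
  expect_setequal(sampleInfo(out2)$sample_id, c("S2", "S3"))

  # fewer than 3 samples: count rule skipped with warning
  tiny <- CnvDataset(mkCalls("6", 1e6, 1.2e6, "S1"),
                     mkSamples("S1", "S2"))
  expect_warning(out3 <- removeOutlierSamples(tiny), "fewer than 3")
  expect_equal(nrow(sampleInfo(out3)), 2)
})

test_that("threshold filters are idempotent and provenance adds up", {
  set.seed(23)
  sim <- simulateCnvDataset(simConfig(
    n_cases = 25, n_controls = 25, seed = 23,
    frac_fail_probes = 0.05, frac_fail_conf = 0.05, frac_in_segdup = 0.05))
  ds <- sim$dataset
  # the deterministic threshold filters are closed under re-application
  # (the statistical outlier cutoff, recomputed on the filtered data, is
  # deliberately a single-pass rule and is exercised separately above)
  once <- filterExcludedRegions(filterCalls(filterSamples(ds)),
                                sim$exclusions)
  twice <- filterExcludedRegions(filterCalls(filterSamples(once)),
                                 sim$exclusions)
  expect_equal(length(cnvCalls(twice)), length(cnvCalls(once)))
  expect_equal(sampleInfo(twice)$sample_id, sampleInfo(once)$sample_id)

  prov <- provenance(once)
  expect_equal(length(cnvCalls(ds)),
               length(cnvCalls(once)) + sum(prov$removed_calls))
  once <- removeOutlierSamples(once)

  # post-condition sweep: no surviving call violates any threshold
  calls <- cnvCalls(once)
  th <- qcThresholds()
  expect_true(all(calls$num_probes >= th$min_probes))
  expect_true(all(GenomicRanges::width(calls) >= th$min_length_bp))
  expect_true(all(calls$confidence >= th$min_confidence))
  expect_true(all(as.character(GenomicRanges::seqnames(calls)) %in%
                    as.character(1:22)))
  expect_true(all(coverageFraction(calls, sim$exclusions) <
                    th$region_overlap_frac))
})
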