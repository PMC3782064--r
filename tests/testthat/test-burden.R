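test_that("frequency classification is type-aware", {
  # isolated call: single under every classification
  lone <- mkCalls("1", 10e6, 10.2e6, "S1")
  expect_equal(as.character(classifyFrequency(lone)), "single")

  # deletion covered >50% by one duplication: not single in the
  # both-types classification, single in the deletions-only one
  del <- mkCalls("2", 1e6, 1.2e6, "S1", cn = 1L)
  dup <- mkCalls("2", 1e6, 1.3e6, "S2", cn = 3L)
  pair <- c(del, dup)
  both <- classifyFrequency(pair, "all")
  expect_equal(as.character(both), c("two_to_six", "two_to_six"))
  delsOnly <- classifyFrequency(pair, "deletions")
  expect_equal(as.character(delsOnly), c("single", NA))

  # three mutually >=50%-overlapping duplications: each two_to_six
  trio <- mkCalls("3", c(1e6, 1.05e6, 1.1e6), c(1.5e6, 1.55e6, 1.6e6),
                  c("A", "B", "C"), cn = 3L)
  expect_equal(as.character(classifyFrequency(trio, "duplications")),
               rep("two_to_six", 3))

  # the both-types classification is an exhaustive partition
  set.seed(13)
  sim <- simulateCnvDataset(simConfig(n_cases = 20, n_controls = 20,
                                      seed = 13))
  cls <- classifyFrequency(cnvCalls(sim$dataset), "all")
  expect_false(anyNA(cls))
})

test_that("burden statistics match hand-computed values", {
  # cases: A one 300 kb deletion, B none; controls: C and D one 100 kb each
  calls <- makeCnvCalls(c("5", "5", "5"),
                        c(1e6, 5e6, 8e6),
                        c(1e6 + 299999, 5e6 + 99999, 8e6 + 99999),
                        c("A", "C", "D"), 30L, 1L, 50)
  samples <- mkSamples(c("A", "B"), c("C", "D"))
  b <- burdenStatistics(calls, samples)
  expect_equal(b$rate_ratio, 0.5)
  expect_equal(b$sample_proportion_ratio, 0.5)
  expect_equal(b$total_size_ratio, 1.5)
  expect_equal(b$avg_size_ratio, 3)
  expect_equal(b$case_cnv_count, 1L)
  expect_equal(b$control_cnv_count, 2L)

  # two cases and two controls carrying one identical 200 kb call each
  sym <- mkCalls("5", rep(1e6, 4), rep(1.2e6 - 1, 4),
                 c("A", "B", "C", "D"))
  bs <- burdenStatistics(sym, samples)
  for (col in grep("_ratio$", names(bs), value = TRUE)) {
    expect_equal(bs[[col]], 1.0)
  }

  # stratum empty in controls: ratio is NA, values zero
  big <- mkCalls("5", 1e6, 2.1e6 - 1, "A")
  bb <- burdenStatistics(c(calls, big), samples, size_class = "ge1Mb")
  expect_equal(bb$total_size_control, 0)
  expect_true(is.na(bb$total_size_ratio))
})

test_that("permutation p-values behave at the degenerate extremes", {
  samples <- mkSamples(c("A", "B"), c("C", "D"))
  # identical samples: every labeling gives the same statistic, p = 1
  sym <- mkCalls("5", rep(1e6, 4), rep(1.2e6 - 1, 4),
                 c("A", "B", "C", "D"))
  p <- permuteBurden(sym, samples, n_perm = 50, seed = 3)
  for (col in grep("_p$", names(p), value = TRUE)) {
    expect_equal(p[[col]], 1.0)
  }
  # add-one estimator lower bound
  expect_error(permuteBurden(sym, samples, n_perm = 0), "n_perm")
})

test_that("exhaustive permutation equals an independent enumeration oracle", {
  set.seed(41)
  ids <- paste0("S", 1:7)
  n_calls <- c(2L, 0L, 1L, 3L, 0L, 1L, 1L)
  st <- seq(1e6, by = 5e5, length.out = sum(n_calls))
  widths <- sample(100000:400000, sum(n_calls))
  calls <- mkCalls("7", st, st + widths - 1, rep(ids, n_calls))
  samples <- mkSamples(ids[1:3], ids[4:7])
  res <- permuteBurden(calls, samples, exhaustive = TRUE, n_perm = 1)
  ps <- cnvburden:::.perSample(calls, samples)
  oracle <- brutePermBurden(ps$ct, ps$kb, n_case = 3)
  expect_equal(res$rate_p, oracle[["rate"]])
  expect_equal(res$sample_proportion_p, oracle[["sample_proportion"]])
  expect_equal(res$total_size_p, oracle[["total_size"]])
  expect_equal(res$avg_size_p, oracle[["avg_size"]])

  # sampled estimate converges to the exhaustive value (4 samples, all 6
  # labelings known): agreement within Monte-Carlo error
  ids4 <- c("A", "B", "C", "D")
  calls4 <- mkCalls("7", c(1e6, 3e6), c(1.4e6, 3.1e6), c("A", "C"))
  s4 <- mkSamples(ids4[1:2], ids4[3:4])
  exact <- permuteBurden(calls4, s4, exhaustive = TRUE,
                         n_perm = 1)$total_size_p
  mc <- permuteBurden(calls4, s4, n_perm = 50000, seed = 9)$total_size_p
  se <- sqrt(exact * (1 - exact) / 50000)
  expect_lt(abs(mc - exact), 3 * se + 2 / 50001)
})

test_that("swapping all labels inverts ratios", {
  set.seed(17)
  sim <- simulateCnvDataset(simConfig(n_cases = 15, n_controls = 10,
                                      seed = 17))
  calls <- cnvCalls(sim$dataset)
  s <- as.data.frame(sampleInfo(sim$dataset))
  b1 <- burdenStatistics(calls, s)
  s2 <- s
  s2$status <- ifelse(s$status == "case", "control", "case")
  b2 <- burdenStatistics(calls, s2)
  for (col in grep("_ratio$", names(b1), value = TRUE)) {
    expect_equal(b2[[col]], 1 / b1[[col]])
  }
})

test_that("the stratified table composes the single-stratum results", {
  set.seed(19)
  sim <- simulateCnvDataset(simConfig(n_cases = 20, n_controls = 15,
                                      seed = 19))
  calls <- cnvCalls(sim$dataset)
  s <- sampleInfo(sim$dataset)
  one <- data.frame(cnv_type = "deletions", freq_class = "all",
                    size_class = "all")
  tab <- burdenTable(calls, s, strata = one, n_perm = 200, seed = 77)
  direct <- permuteBurden(calls, s, cnv_type = "deletions",
                          n_perm = 200, seed = 77)
  expect_equal(tab, direct)

  # size strata overlap by construction: ge500kb contains ge1Mb
  idx5 <- cnvburden:::.stratumIndex(calls, size_class = "ge500kb")
  idx1 <- cnvburden:::.stratumIndex(calls, size_class = "ge1Mb")
  expect_true(all(which(idx1) %in% which(idx5)))
})
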