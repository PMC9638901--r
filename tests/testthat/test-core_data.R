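test_that("aggregation groups reads by gene, channel and mutations per read", {
  des <- tilacDesign("s1", "forward")

  # a single read lands in one group per channel
  one <- aggregateReads(toy_tally(y_TC = 2, y_GA = 0), des)
  cnt <- countTable(one)
  expect_equal(nrow(cnt), 2L)
  expect_equal(cnt$n_reads[cnt$mut_type == "TC" & cnt$n_mut == 2], 1L)
  expect_equal(cnt$n_reads[cnt$mut_type == "GA" & cnt$n_mut == 0], 1L)

  # toy tabulation: y_TC = (0, 0, 2) collapses to {0: 2 reads, 2: 1 read}
  x <- aggregateReads(toy_tally(y_TC = c(0, 0, 2)), des)
  tc <- countTable(x)[countTable(x)$mut_type == "TC", ]
  expect_equal(tc$n_reads[tc$n_mut == 0], 2L)
  expect_equal(tc$n_reads[tc$n_mut == 2], 1L)

  # both channels tally every read: totals per channel equal the input size
  ga <- countTable(x)[countTable(x)$mut_type == "GA", ]
  expect_equal(sum(tc$n_reads), 3L)
  expect_equal(sum(ga$n_reads), 3L)
})

test_that("aggregation is permutation-invariant and rejects malformed tallies", {
  des <- std_design()
  sim <- simulateReads(c(0.5, 1, 2), des, reads_per_transcript = 50, seed = 5)
  tl <- sim$tallies
  shuf <- tl[sample(nrow(tl)), ]
  expect_equal(countTable(aggregateReads(shuf, des)),
               countTable(aggregateReads(tl, des)))

  bad <- toy_tally(y_TC = 5, n_U = 3L)
  expect_error(aggregateReads(bad, tilacDesign("s1", "forward")),
               "malformed")
})

test_that("coverage filter keeps genes with >= min_reads in >= min_samples", {
  des <- std_design()
  # gene A: 200 reads in two samples (boundary, kept); gene B: 10 everywhere
  tl <- rbind(
    toy_tally(rep(0, 200), gene = "A", sample = "fwd1"),
    toy_tally(rep(0, 200), gene = "A", sample = "rev1"),
    toy_tally(rep(0, 10), gene = "A", sample = "unl1"),
    toy_tally(rep(0, 10), gene = "B", sample = "fwd1"),
    toy_tally(rep(0, 10), gene = "B", sample = "rev1"))
  x <- aggregateReads(tl, des)
  kept <- filterLowCoverage(x, min_reads = 200, min_samples = 2)
  expect_equal(unique(countTable(kept)$gene_id), "A")

  # empty table stays empty; invalid configuration errors
  empty <- filterLowCoverage(aggregateReads(tl[0, ], des))
  expect_equal(nrow(countTable(empty)), 0L)
  expect_error(filterLowCoverage(x, min_reads = 0), "min_reads")
})

test_that("raw mutation rates are mutations per observed base", {
  # hand arithmetic: 125 T-to-C over 2500 covered T positions -> 0.05
  tl <- toy_tally(y_TC = rep(c(1, 0), c(125, 125)), n_U = 10L, n_G = 10L)
  r <- rawMutationRates(tl, min_reads = 100)
  expect_equal(r$rate_TC, 125 / 2500)
  expect_equal(r$rate_GA, 0)

  # genes below the read threshold are omitted
  expect_equal(nrow(rawMutationRates(tl, min_reads = 300)), 0L)

  # exonic and intronic strata are separate
  tl2 <- rbind(toy_tally(y_TC = rep(1, 30), feature = "exonic"),
               toy_tally(y_TC = rep(0, 30), feature = "intronic"))
  r2 <- rawMutationRates(tl2, min_reads = 10)
  expect_equal(sort(r2$feature_class), c("exonic", "intronic"))
  expect_equal(r2$rate_TC[r2$feature_class == "exonic"], 1 / 50)

  # zero observed bases: stratum omitted, never reported as 0/0
  tl3 <- toy_tally(y_TC = rep(0, 20), n_U = 0L)
  tl3$y_TC <- 0L
  expect_equal(nrow(rawMutationRates(tl3, min_reads = 5)), 0L)
})

test_that("raw rates on simulator output converge to the generative rates", {
  des <- tilacDesign("u1", "unlabelled")
  sim <- suppressWarnings(
    simulateReads(1, des, reads_per_transcript = 2e4, seed = 42))
  r <- rawMutationRates(sim$tallies, min_reads = 200)
  n_U_tot <- sum(sim$tallies$n_U)
  se_tc <- sqrt(0.001 * 0.999 / n_U_tot)
  expect_lt(abs(r$rate_TC - 0.001), 3 * se_tc)
  se_ga <- sqrt(0.004 * 0.996 / sum(sim$tallies$n_G))
  expect_lt(abs(r$rate_GA - 0.004), 3 * se_ga)
})

test_that("count tables and tallies round-trip through TSV exactly", {
  des <- std_design()
  sim <- simulateReads(c(0.2, 1, 5), des, reads_per_transcript = 80, seed = 9)
  tmp <- tempfile(); sheet <- tempfile()
  writeCountTable(sim$counts, tmp, sheet)
  back <- readCountTable(tmp, sheet)
  expect_equal(countTable(back), countTable(sim$counts))
  expect_equal(sampleDesign(back), sampleDesign(sim$counts))

  tfile <- tempfile()
  writeTallyFile(sim$tallies, tfile)
  expect_equal(readTallyFile(tfile), sim$tallies)
})

test_that("design constructor enforces the labelling scheme invariants", {
  des <- tilacDesign(c("a", "b"), c("forward", "unlabelled"), c(1L, 1L))
  expect_equal(des$labelled, c(1L, 0L))
  expect_error(tilacDesign(c("a", "a"), c("forward", "reverse")), "duplicate")
  expect_error(tilacDesign("a", "sideways"), "arg")
})
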