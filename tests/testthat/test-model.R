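test_that("per-read mixture log-likelihood matches direct pmf arithmetic", {
  # pure background, zero count: log pmf = -lambda_u
  expect_equal(readLogLikelihood(0, theta = 0, lambda_l = 2.5,
                                 lambda_u = 0.05), -0.05)
  # unlabelled control (I = 0) ignores theta entirely
  expect_equal(readLogLikelihood(3, theta = 0.7, lambda_l = 2.5,
                                 lambda_u = 0.05, labelled = 0),
               dpois(3, 0.05, log = TRUE))
  # degenerate mixture theta = 1 is the labelled Poisson
  expect_equal(readLogLikelihood(4, theta = 1, lambda_l = 2.5,
                                 lambda_u = 0.05),
               dpois(4, 2.5, log = TRUE))
  # frozen oracle: y = 2, theta = 0.5, lambda_l = 2.5, lambda_u = 0.05
  expect_equal(readLogLikelihood(2, 0.5, 2.5, 0.05), -2.04908826878,
               tolerance = 1e-10)
  expect_error(readLogLikelihood(1, theta = 1.2, 2.5, 0.05), "theta")
})

test_that("dataset log-likelihood weights groups and routes by combination", {
  rates <- default_rates()
  des <- std_design()
  sim <- simulateReads(c(0.5, 2), des, reads_per_transcript = 40, seed = 2)
  th <- data.frame(gene_id = sim$truth$gene_id,
                   theta_exp = c(0.3, 0.6), theta_cntl = c(0.6, 0.3))

  # empty table scores zero
  empty <- aggregateReads(sim$tallies[0, ], des)
  expect_equal(datasetLogLikelihood(empty, th, rates), 0)

  # a group of k identical reads scores k times the single-read value
  one <- aggregateReads(toy_tally(y_TC = 2, y_GA = 0),
                        tilacDesign("s1", "forward"))
  kk <- aggregateReads(toy_tally(y_TC = rep(2, 7), y_GA = 0),
                       tilacDesign("s1", "forward"))
  th1 <- data.frame(gene_id = "g1", theta_exp = 0.4, theta_cntl = 0.2)
  expect_equal(datasetLogLikelihood(kk, th1, rates),
               7 * datasetLogLikelihood(one, th1, rates))

  # forward vs reverse designs differ unless the theta pair is swapped
  fwd <- aggregateReads(toy_tally(y_TC = c(0, 3), y_GA = c(1, 0)),
                        tilacDesign("s1", "forward"))
  rev <- aggregateReads(toy_tally(y_TC = c(0, 3), y_GA = c(1, 0)),
                        tilacDesign("s1", "reverse"))
  th_swap <- data.frame(gene_id = "g1", theta_exp = 0.2, theta_cntl = 0.4)
  expect_false(isTRUE(all.equal(datasetLogLikelihood(fwd, th1, rates),
                                datasetLogLikelihood(rev, th1, rates))))
  expect_equal(datasetLogLikelihood(fwd, th1, rates),
               datasetLogLikelihood(rev, th_swap, rates))
})

test_that("dataset likelihood peaks near the simulation truth on a grid", {
  des <- std_design()
  sim <- simulateReads(4, des, reads_per_transcript = 2000, seed = 31,
                       theta_noise_sd = 0)
  rates <- default_rates()
  grid <- seq(0.05, 0.95, by = 0.05)
  ll <- vapply(grid, function(te)
    datasetLogLikelihood(sim$counts,
      data.frame(gene_id = sim$truth$gene_id, theta_exp = te,
                 theta_cntl = sim$truth$theta_cntl), rates), numeric(1))
  expect_equal(grid[which.max(ll)], sim$truth$theta_exp, tolerance = 0.06)
})

test_that("the TILAC ratio is theta_exp over theta_cntl", {
  expect_equal(tilacRatio(0.6, 0.3)$ratio, 2)
  expect_equal(tilacRatio(0.6, 0.3)$log2_ratio, 1)
  expect_equal(tilacRatio(0.25, 0.25)$log2_ratio, 0)
  expect_error(tilacRatio(0.5, 0), "undefined")
})

test_that("quadrature posterior reduces to the prior with no reads and is grid-stable", {
  des <- std_design()
  # a gene with a single zero-information read in each direction
  tl <- rbind(toy_tally(0, sample = "fwd1"), toy_tally(0, sample = "rev1"))
  x <- aggregateReads(tl, des)
  rates <- data.frame(mut_type = c("TC", "GA"), lambda_u = c(1, 1),
                      lambda_l = c(1, 1))  # labelled = background: no signal
  g <- gridPosterior(x, rates)
  expect_equal(g$log2_ratio_mean, 0, tolerance = 1e-8)  # prior symmetry

  g2 <- gridPosterior(x, rates, tol = 1e-6)
  expect_lt(abs(g2$log2_ratio_mean - g$log2_ratio_mean), 1e-3)
})

test_that("sampler agrees with the quadrature oracle on a strong single gene", {
  des <- std_design()
  rates <- default_rates()
  sim <- simulateReads(2, des, reads_per_transcript = 1000, seed = 17,
                       theta_noise_sd = 0)  # theta_exp 2/3... rescaled pair
  fit <- fitTilac(sim$counts, seed = 5, fixed_rates = rates)
  g <- gridPosterior(sim$counts, rates)
  s <- posteriorSummary(fit)
  mcse <- s$log2_ratio_sd / sqrt(s$n_eff_min)
  expect_lt(abs(s$log2_ratio_mean - g$log2_ratio_mean), 3 * mcse + 1e-3)
  expect_equal(2^s$log2_ratio_mean, 2, tolerance = 0.15)
})

test_that("fitting refuses designs without a background anchor", {
  des <- tilacDesign(c("f1", "r1"), c("forward", "reverse"))
  sim <- simulateReads(1, des, reads_per_transcript = 50, seed = 3)
  expect_error(fitTilac(sim$counts, seed = 1), "unlabelled")
  # fixing the background restores fittability
  expect_s4_class(
    quick_fit(sim$counts, seed = 1,
              fixed_background = c(TC = 0.05, GA = 0.2)), "TilacFit")
})

test_that("background rate is identified from unlabelled controls", {
  des <- std_design()
  sim <- simulateReads(rep(1, 30), des, reads_per_transcript = 300, seed = 23)
  fit <- quick_fit(sim$counts, seed = 7)
  r <- globalRates(fit)
  tl <- sim$tallies[sim$tallies$sample_id == "unl1", ]
  emp <- c(mean(tl$y_TC), mean(tl$y_GA))
  expect_true(all(abs(r$lambda_u_mean - emp) <= 3 * r$lambda_u_sd + 0.02))
})

test_that("swapping forward and reverse labels negates the log2 ratio", {
  des <- std_design()
  sim <- simulateReads(c(0.3, 1, 3), des, reads_per_transcript = 400,
                       seed = 19)
  fit1 <- quick_fit(sim$counts, seed = 4)
  des_swap <- tilacDesign(c("fwd1", "rev1", "unl1"),
                          c("reverse", "forward", "unlabelled"))
  swapped <- aggregateReads(sim$tallies, des_swap)
  fit2 <- quick_fit(swapped, seed = 4)
  s1 <- posteriorSummary(fit1); s2 <- posteriorSummary(fit2)
  tol <- 2 * pmax(s1$log2_ratio_sd, s2$log2_ratio_sd)
  expect_true(all(abs(s1$log2_ratio_mean + s2$log2_ratio_mean) <= tol))
})

test_that("posterior summaries round-trip to TSV for downstream testing", {
  des <- std_design()
  sim <- simulateReads(c(1, 8), des, reads_per_transcript = 300, seed = 29)
  fit <- quick_fit(sim$counts, seed = 2)
  tmp <- tempfile(); meta <- tempfile(fileext = ".json")
  writePosterior(fit, tmp, meta)
  back <- readPosterior(tmp)
  expect_equal(posteriorSummary(back)$log2_ratio_mean,
               posteriorSummary(fit)$log2_ratio_mean)
  expect_true(jsonlite::read_json(meta)$chains == 2)
  tests <- callSignificance(back)
  expect_s4_class(tests, "TilacTests")
})
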