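test_that("bin_midpoints honors half-open bin boundaries and counts", {
  gm <- tiny_genome(1e4)
  frags <- data.frame(
    chrom = "chrT",
    start = c(998, 1000, rep(200, 10)),
    end = c(1000, 1001, rep(300, 10)),   # midpoints 999, 1000, 250 x10
    sample = "rep1",
    condition = "E")
  bc <- bin_midpoints(frags, gm)
  expect_equal(bc$counts[1, "E", 1], 11)   # midpoint 999 and the 10 at 250
  expect_equal(bc$counts[2, "E", 1], 1)    # midpoint 1000 -> [1000, 2000)
  # off-chromosome midpoint goes to the reject log, not dropped silently
  frags2 <- rbind(frags, data.frame(chrom = "chrT", start = 99999,
                                    end = 100005, sample = "rep1",
                                    condition = "E"))
  bc2 <- bin_midpoints(frags2, gm)
  expect_equal(attr(bc2, "rejects"), 1)
  expect_equal(sum(bc2$counts), sum(bc$counts))
})

test_that("timing_score matches the dense-grid oracle and the prior", {
  gm <- tiny_genome(3000)      # exactly one 3 kb window
  # all samples at y = m/2: symmetric likelihood, theta = 0
  ts0 <- timing_score(uniform_counts(gm, y = 5, m = 10, n_samples = 2))
  expect_equal(ts0$theta, 0, tolerance = 1e-12)

  # no data: prior mean 0, flagged
  ts_e <- timing_score(uniform_counts(gm, y = 0, m = 0))
  expect_equal(ts_e$theta, 0)
  expect_true(ts_e$no_data)

  # single sample y=9, m=10 in one bin: 1e5-node oracle within 1e-4
  bins <- replichrom:::make_bins(gm, 1000)
  counts <- array(0, dim = c(3, 4, 1),
                  dimnames = list(NULL, c("E", "EM", "LM", "L"), "rep1"))
  counts[1, "E", 1] <- 9
  counts[1, "L", 1] <- 1
  bc <- binned_fraction_counts(bins, counts,
                               size_factor = matrix(1, 1, 4))
  ts <- timing_score(bc, tau = 2)
  expect_equal(ts$theta, oracle_posterior_mean(9, 10, tau = 2),
               tolerance = 1e-4)
  expect_error(timing_score(bc, tau = 0), "tau")
})

test_that("theta is antisymmetric under early/late swap", {
  gm <- tiny_genome(9000)
  set.seed(21)
  bins <- replichrom:::make_bins(gm, 1000)
  counts <- array(rpois(9 * 4 * 2, 20), dim = c(9, 4, 2),
                  dimnames = list(NULL, c("E", "EM", "LM", "L"),
                                  c("rep1", "rep2")))
  sf <- matrix(1, 2, 4)
  fwd <- timing_score(binned_fraction_counts(bins, counts,
                                             size_factor = sf))
  swapped <- counts[, c("LM", "L", "E", "EM"), ]
  dimnames(swapped)[[2]] <- c("E", "EM", "LM", "L")
  rev <- timing_score(binned_fraction_counts(bins, swapped,
                                             size_factor = sf))
  expect_equal(fwd$theta, -rev$theta, tolerance = 1e-10)
})

test_that("quadrature agrees with the dense oracle over random configs", {
  set.seed(101)
  m <- rpois(100, 40) + 1
  y <- rbinom(100, m, runif(100))
  post <- replichrom:::logit_posterior(y, m, tau = 2)
  oracle <- mapply(oracle_posterior_mean, y, m)
  expect_lt(max(abs(post$mean - oracle)), 1e-4)
})

test_that("bayes_factor behaves at the reference configurations", {
  gm <- tiny_genome(3000)
  # no data on either side: K = 1
  bf0 <- bayes_factor(uniform_counts(gm, 0, 0), uniform_counts(gm, 0, 0))
  expect_equal(bf0$k, 1, tolerance = 1e-6)

  # identical symmetric high-depth data: Occam penalty, K < 1
  # (the single 3 kb window sums its 3 bins: y = 450 of m = 900 per side)
  bf_same <- bayes_factor(uniform_counts(gm, 150, 300),
                          uniform_counts(gm, 150, 300))
  expect_lt(bf_same$k, 1)
  # grid-integration oracle agreement
  log_k_oracle <- 2 * oracle_log_marginal(450, 900) -
    oracle_log_marginal(900, 1800)
  expect_equal(bf_same$log_k, log_k_oracle, tolerance = 1e-6)

  # opposite extremes: strong evidence, K > 100
  bf_opp <- bayes_factor(uniform_counts(gm, 300, 300),
                         uniform_counts(gm, 0, 300))
  expect_gt(bf_opp$k, 100)
  expect_equal(bf_opp$log_k,
               oracle_log_marginal(900, 900) + oracle_log_marginal(0, 900) -
                 oracle_log_marginal(900, 1800),
               tolerance = 1e-6)
  expect_gt(bf_opp$delta, 0)
  expect_true(is.finite(bf_opp$log_k))
})

test_that("size factors depth-normalize unbalanced libraries", {
  # composition-balanced truth (half the genome early at +1, half late at
  # -1) under strongly unbalanced library sizes: normalization must keep
  # the recovered window scores near the truth in both halves
  gm <- tiny_genome(2e5)
  bins <- replichrom:::make_bins(gm, 1000)
  th <- rep(c(1, -1), each = 100)
  tr <- timing_truth(bins, th)
  cnt <- simulate_repliseq(gm, tr, "A", depth_per_sample = 100,
                           n_replicates = 2, libsize_sdlog = 0.5,
                           seed = 31)
  ts <- timing_score(cnt)
  interior_early <- ts$start < 90000
  interior_late <- ts$start >= 103000
  expect_equal(mean(ts$theta[interior_early]), 1, tolerance = 0.15)
  expect_equal(mean(ts$theta[interior_late]), -1, tolerance = 0.15)
})
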