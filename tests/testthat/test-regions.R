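# synthetic Bayes-factor track builder: windows of 3 kb span at 1 kb step
bf_track <- function(k, delta, chrom = "chrT") {
  n <- length(k)
  structure(data.frame(chrom = chrom, start = seq(0, by = 1000,
                                                  length.out = n),
                       end = seq(3000, by = 1000, length.out = n),
                       log_k = log(k), k = k, delta = delta,
                       theta_a = delta / 2, theta_b = -delta / 2,
                       stringsAsFactors = FALSE),
            class = c("differential_test_track", "data.frame"))
}

test_that("call_differential_regions applies nested thresholds", {
  # nothing exceeds the extension threshold: empty call set
  quiet <- bf_track(rep(2, 100), rep(0.5, 100))
  expect_equal(nrow(call_differential_regions(quiet)), 0)

  # a 30-window strong run flanked by extension-level windows
  k <- rep(0.5, 100)
  k[30:59] <- 50          # seeds
  k[25:29] <- 5           # left extension
  k[60:64] <- 5           # right extension
  regs <- call_differential_regions(bf_track(k, rep(1, 100)))
  expect_equal(nrow(regs), 1)
  expect_equal(regs$direction, "A-earlier")
  expect_equal(regs$start, 24000)
  expect_equal(regs$end, 66000)     # window 64 spans [63000, 66000)
  expect_gte(regs$width, 20000)
  # peak is the seed-level run
  expect_equal(regs$peak_start, 29000)
  expect_equal(regs$peak_end, 61000)

  # a significant but short run (< 20 kb) is discarded
  k2 <- rep(0.5, 100)
  k2[40:49] <- 50         # 10 windows: 13 kb span < 20 kb
  expect_equal(nrow(call_differential_regions(bf_track(k2, rep(1, 100)))),
               0)

  # runs of opposite delta sign are never merged
  k3 <- rep(0.5, 200)
  k3[50:90] <- 50
  k3[91:130] <- 50
  d3 <- rep(1, 200); d3[91:130] <- -1
  regs3 <- call_differential_regions(bf_track(k3, d3))
  expect_equal(nrow(regs3), 2)
  expect_setequal(regs3$direction, c("A-earlier", "B-earlier"))
})

test_that("gap merging joins nearby same-direction runs", {
  k <- rep(0.5, 100)
  k[20:44] <- 50
  k[48:72] <- 50          # 3 kb gap between window 44 end and 48 start
  regs <- call_differential_regions(bf_track(k, rep(1, 100)), gap = 3000)
  expect_equal(nrow(regs), 1)
  regs2 <- call_differential_regions(bf_track(k, rep(1, 100)), gap = 0)
  expect_equal(nrow(regs2), 2)
})

test_that("loess_smooth is exact on constants and lines", {
  gm <- tiny_genome(3e5)
  bins <- replichrom:::make_bins(gm, 1000)
  n <- nrow(bins) - 2
  track <- structure(data.frame(chrom = "chrT",
                                start = bins$start[1:n],
                                end = bins$end[3:(n + 2)],
                                theta = rep(2, n), no_data = FALSE),
                     class = c("timing_track", "data.frame"))
  expect_equal(loess_smooth(track)$theta, rep(2, n), tolerance = 1e-12)

  x <- (track$start + track$end) / 2
  track$theta <- 0.5 + 3e-5 * x
  expect_equal(loess_smooth(track)$theta, track$theta, tolerance = 1e-9)
})

test_that("loess_smooth matches a direct weighted-regression oracle", {
  gm <- tiny_genome(3e5)
  bins <- replichrom:::make_bins(gm, 1000)
  n <- nrow(bins) - 2
  x <- (bins$start[1:n] + bins$end[3:(n + 2)]) / 2
  set.seed(5)
  y <- sin(x / 3e4) + rnorm(n, 0, 0.3)
  track <- structure(data.frame(chrom = "chrT", start = bins$start[1:n],
                                end = bins$end[3:(n + 2)], theta = y,
                                no_data = FALSE),
                     class = c("timing_track", "data.frame"))
  sm <- loess_smooth(track, span_bp = 5e4)
  # independent oracle: per-point tricube-weighted lm fit
  h <- 2.5e4
  oracle <- vapply(seq_len(n), function(j) {
    w <- (1 - pmin(abs(x - x[j]) / h, 1)^3)^3
    keep <- w > 0
    unname(stats::lm(y ~ x, weights = w, subset = keep)$fitted.values[
      which(which(keep) == j)])
  }, numeric(1))
  expect_equal(sm$theta, oracle, tolerance = 1e-8)
  # recovered sine close to truth
  expect_lt(sqrt(mean((sm$theta - sin(x / 3e4))^2)), 0.1)

  # chromosome shorter than span: global linear fallback with a warning
  short <- track[1:20, ]
  expect_warning(loess_smooth(short, span_bp = 1e5), "global linear")
})

test_that("rt_zscore standardizes exactly and is affine invariant", {
  gm <- tiny_genome(1e5)
  bins <- replichrom:::make_bins(gm, 1000)
  n <- nrow(bins) - 2
  set.seed(9)
  mk <- function(theta) structure(
    data.frame(chrom = "chrT", start = bins$start[1:n],
               end = bins$end[3:(n + 2)], theta = theta,
               no_data = FALSE),
    class = c("timing_track", "data.frame"))
  th <- rnorm(n)
  z <- rt_zscore(mk(th))
  expect_lt(abs(mean(z$z)), 1e-9)
  expect_lt(abs(sqrt(mean((z$z - mean(z$z))^2)) - 1), 1e-9)
  z2 <- rt_zscore(mk(2.5 * th + 7))
  expect_equal(z$z, z2$z, tolerance = 1e-9)
  expect_error(rt_zscore(mk(rep(1, n))), "variance")
})

test_that("rt_zscore on the toy vector uses the population convention", {
  track <- structure(data.frame(chrom = "chrT", start = c(0, 1000, 2000),
                                end = c(3000, 4000, 5000),
                                theta = c(1, 2, 3), no_data = FALSE),
                     class = c("timing_track", "data.frame"))
  z <- rt_zscore(track)
  expect_equal(z$z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
})

test_that("region_summary averages by window midpoint and labels", {
  gm <- tiny_genome(1e5)
  regions <- data.frame(region_id = c("left", "right"), chrom = "chrT",
                        start = c(0, 50000), end = c(50000, 100000),
                        class = "arm")
  n <- 98
  z <- structure(data.frame(chrom = "chrT",
                            start = seq(0, by = 1000, length.out = n),
                            end = seq(3000, by = 1000, length.out = n),
                            z = rep(c(0.7, -0.7), c(49, 49))),
                 class = c("z_track", "data.frame"))
  out <- region_summary(z, regions)
  # windows assigned by midpoint: the boundary window averages in
  expect_equal(out$label, c("Early", "Late"))
  expect_equal(out$mean_z[1], 0.7, tolerance = 0.03)
  # a region with no windows warns and stays NA
  regions2 <- rbind(regions, data.frame(region_id = "none", chrom = "chrT",
                                        start = 0, end = 0.5,
                                        class = "arm"))
  expect_warning(out2 <- region_summary(z, regions2), "no windows")
  expect_true(is.na(out2$mean_z[3]))
})

test_that("earlier_size_summary sums widths and fractions per domain", {
  regions <- data.frame(region_id = "dom", chrom = "chrT", start = 0,
                        end = 1e5, class = "arm")
  called <- data.frame(chrom = "chrT", start = 10000, end = 30000,
                       direction = "A-earlier", width = 20000,
                       mean_delta = 1, max_k = 50, peak_start = 15000,
                       peak_end = 20000)
  out <- earlier_size_summary(called, regions)
  expect_equal(out$kb_a_earlier, 20)
  expect_equal(out$fraction_a, 0.2)
  expect_equal(out$kb_b_earlier, 0)
  empty <- called[0, ]
  out0 <- earlier_size_summary(empty, regions)
  expect_equal(out0$kb_a_earlier, 0)
})
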