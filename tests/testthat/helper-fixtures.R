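# Shared fixtures and independent oracles, built in code at test time.

# tiny one-chromosome genome for unit tests
tiny_genome <- function(size = 100000, name = "chrT") {
  genome_model(stats::setNames(size, name),
               data.frame(region_id = name, chrom = name, start = 0,
                          end = size, class = "whole-chromosome"))
}

# binned fraction counts with a single sample and uniform totals, where the
# early-half count is y out of m in every bin
uniform_counts <- function(genome, y, m, n_samples = 1, bin = 1000) {
  bins <- replichrom:::make_bins(genome, bin)
  counts <- array(0, dim = c(nrow(bins), 4, n_samples),
                  dimnames = list(NULL, c("E", "EM", "LM", "L"),
                                  paste0("rep", seq_len(n_samples))))
  counts[, "E", ] <- floor(y / 2); counts[, "EM", ] <- ceiling(y / 2)
  counts[, "LM", ] <- floor((m - y) / 2)
  counts[, "L", ] <- ceiling((m - y) / 2)
  binned_fraction_counts(bins, counts,
                         size_factor = matrix(1, n_samples, 4))
}

# independent dense-grid oracle for the posterior mean of a binomial logit
# parameter under a Normal(0, tau^2) prior (1e5 nodes)
oracle_posterior_mean <- function(y, m, tau = 2, nodes = 1e5) {
  th <- seq(-12, 12, length.out = nodes)
  lp <- y * th - m * log1p(exp(th)) + stats::dnorm(th, 0, tau, log = TRUE)
  w <- exp(lp - max(lp))
  sum(w * th) / sum(w)
}

# independent dense-grid oracle for the log marginal likelihood
oracle_log_marginal <- function(y, m, tau = 2, nodes = 1e5) {
  th <- seq(-12, 12, length.out = nodes)
  h <- th[2] - th[1]
  lp <- y * th - m * log1p(exp(th)) + stats::dnorm(th, 0, tau, log = TRUE)
  mx <- max(lp)
  w <- exp(lp - mx)
  w[c(1, nodes)] <- w[c(1, nodes)] / 2
  mx + log(sum(w) * h)
}

# flat (null) timing truth over a genome
flat_truth <- function(genome, theta = 0) {
  bins <- replichrom:::make_bins(genome, 1000)
  timing_truth(bins, rep(theta, nrow(bins)), rep(theta, nrow(bins)))
}
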