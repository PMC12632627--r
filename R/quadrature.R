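# 1-D quadrature machinery for logit-scale posteriors.
#
# Every Bayesian piece of the package (timing scores, Bayes factors,
# shrunken expression fold changes) reduces to integrals of
#   exp( y*theta - m*log(1 + e^theta) ) * Normal(theta; 0, tau^2)
# over a single logit parameter, because the binomial likelihood in theta
# depends on the counts only through the success/total sums. All integrals
# are trapezoid sums on a fixed grid, computed in log space.

#' Quadrature grid for logit-scale posteriors
#'
#' @param lower,upper Integration bounds on the logit scale.
#' @param nodes Number of equally spaced nodes (>= 3).
#' @return List with `theta` (nodes) and `logw` (log trapezoid weights).
#' @keywords internal
logit_grid <- function(lower = -12, upper = 12, nodes = 2001L) {
  stopifnot(nodes >= 3, upper > lower)
  theta <- seq(lower, upper, length.out = nodes)
  h <- theta[2] - theta[1]
  w <- rep(h, nodes)
  w[c(1, nodes)] <- h / 2
  list(theta = theta, logw = log(w))
}

# log f(theta) up to the binomial coefficient: y*theta - m*log1p(e^theta),
# numerically stable for large |theta|.
binom_loglik_grid <- function(y, m, theta) {
  # returns matrix [length(y) x length(theta)]
  lse <- ifelse(theta > 0, theta + log1p(exp(-theta)), log1p(exp(theta)))
  outer(y, theta) - outer(m, lse)
}

log_prior_grid <- function(theta, tau) {
  stats::dnorm(theta, 0, tau, log = TRUE)
}

log_sum_exp_rows <- function(lp) {
  mx <- apply(lp, 1, max)
  mx + log(rowSums(exp(lp - mx)))
}

#' Posterior summaries of a binomial logit parameter
#'
#' For sufficient statistics `y` successes of `m` trials per unit and a
#' Normal(0, tau^2) prior on the log-odds, computes by trapezoid quadrature
#' the posterior mean, the log marginal likelihood (binomial coefficient
#' omitted), and the posterior probability of a non-positive parameter.
#' Vectorized over units; work is chunked to bound memory.
#'
#' @param y,m Numeric vectors of equal length (depth-normalized counts are
#'   accepted; they need not be integers).
#' @param tau Prior standard deviation on the logit scale (> 0).
#' @param grid A grid from [logit_grid()].
#' @return data.frame with columns `mean`, `log_marginal`, `p_le0`.
#' @keywords internal
logit_posterior <- function(y, m, tau = 2,
                            grid = logit_grid()) {
  if (tau <= 0) stop("prior sd tau must be positive")
  n <- length(y)
  stopifnot(length(m) == n)
  theta <- grid$theta
  lp0 <- log_prior_grid(theta, tau) + grid$logw
  out_mean <- numeric(n); out_lm <- numeric(n); out_ple <- numeric(n)
  chunk <- max(1L, floor(5e6 / length(theta)))
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(n, i0 + chunk - 1L)
    lp <- binom_loglik_grid(y[idx], m[idx], theta)
    lp <- sweep(lp, 2, lp0, "+")
    mx <- apply(lp, 1, max)
    w <- exp(lp - mx)
    z <- rowSums(w)
    out_mean[idx] <- as.vector(w %*% theta) / z
    out_lm[idx] <- mx + log(z)
    le <- theta <= 0
    out_ple[idx] <- rowSums(w[, le, drop = FALSE]) / z
  }
  data.frame(mean = out_mean, log_marginal = out_lm, p_le0 = out_ple)
}
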