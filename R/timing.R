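FRACTIONS <- c("E", "EM", "LM", "L")

#' Binned Repli-seq fraction counts
#'
#' Container for midpoint counts of Repli-seq fragments in non-overlapping
#' 1 kb bins, split by S-phase fraction (E, EM, LM, L) and replicate sample.
#'
#' @param bins data.frame with columns `chrom`, `start`, `end`; bins must
#'   tile each chromosome contiguously without overlap.
#' @param counts 3-d array `[bin, fraction, sample]` of non-negative counts;
#'   the second dimension is named E, EM, LM, L.
#' @param size_factor Matrix `[sample, fraction]` of positive depth factors;
#'   computed from the counts when `NULL` (per-(sample,fraction) totals over
#'   the median of those totals).
#' @param cell_type Label carried through to downstream tracks.
#' @return Object of class `binned_fraction_counts`.
#' @export
binned_fraction_counts <- function(bins, counts, size_factor = NULL,
                                   cell_type = "A") {
  stopifnot(all(c("chrom", "start", "end") %in% names(bins)))
  if (length(dim(counts)) != 3) stop("counts must be [bin, fraction, sample]")
  if (dim(counts)[1] != nrow(bins)) stop("bins/counts row mismatch")
  if (is.null(dimnames(counts)[[2]])) dimnames(counts)[[2]] <- FRACTIONS
  if (!identical(dimnames(counts)[[2]], FRACTIONS))
    stop("fractions must be E, EM, LM, L")
  if (any(counts < 0)) stop("counts must be non-negative")
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (any(b$start[-1] != b$end[-nrow(b)]) && nrow(b) > 1)
      stop("bins must tile chromosome ", ch, " contiguously")
  }
  if (is.null(size_factor)) {
    tot <- apply(counts, c(3, 2), sum)   # [sample, fraction]
    med <- stats::median(tot)
    if (med <= 0) med <- 1
    size_factor <- tot / med
    size_factor[size_factor <= 0] <- 1   # guard empty libraries
  }
  if (any(size_factor <= 0)) stop("size factors must be positive")
  structure(list(bins = bins, counts = counts, size_factor = size_factor,
                 cell_type = cell_type),
            class = "binned_fraction_counts")
}

#' @export
print.binned_fraction_counts <- function(x, ...) {
  cat("binned_fraction_counts:", nrow(x$bins), "bins x 4 fractions x",
      dim(x$counts)[3], "samples, cell type", x$cell_type, "\n")
  invisible(x)
}

make_bins <- function(genome, bin = 1000) {
  pieces <- lapply(names(genome$chrom_sizes), function(ch) {
    size <- genome$chrom_sizes[[ch]]
    starts <- seq(0, size - 1, by = bin)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin, size), stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Bin Repli-seq fragment midpoints into 1 kb fraction counts
#'
#' Each fragment contributes one count to the bin containing its midpoint
#' `floor((start + end) / 2)` for its (fraction, sample) pair. Fragments
#' whose midpoint falls off any chromosome are tallied in a reject report
#' (attribute `rejects`), never silently dropped.
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`,
#'   `sample`, and `condition` holding the S-phase fraction (E, EM, LM, L).
#' @param genome A [genome_model()].
#' @param bin Bin width in bp (default 1000).
#' @param cell_type Label for the resulting counts.
#' @return A [binned_fraction_counts()] object with size factors set to the
#'   per-(sample, fraction) totals over their median.
#' @export
bin_midpoints <- function(fragments, genome, bin = 1000, cell_type = "A") {
  stopifnot(all(c("chrom", "start", "end", "sample", "condition")
                %in% names(fragments)))
  if (!all(fragments$condition %in% FRACTIONS))
    stop("condition must be an S-phase fraction: E, EM, LM, L")
  bins <- make_bins(genome, bin)
  samples <- sort(unique(fragments$sample))
  counts <- array(0L, dim = c(nrow(bins), 4, length(samples)),
                  dimnames = list(NULL, FRACTIONS, samples))
  mid <- floor((fragments$start + fragments$end) / 2)
  n_rej <- 0L
  offset <- c(0, cumsum(table(factor(bins$chrom,
                                     levels = unique(bins$chrom)))))
  names(offset) <- c(unique(bins$chrom), "END")
  for (s in samples) for (f in FRACTIONS) {
    sel <- fragments$sample == s & fragments$condition == f
    if (!any(sel)) next
    ch <- fragments$chrom[sel]
    md <- mid[sel]
    ok <- ch %in% names(genome$chrom_sizes)
    ok[ok] <- md[ok] >= 0 & md[ok] < genome$chrom_sizes[ch[ok]]
    n_rej <- n_rej + sum(!ok)
    if (!any(ok)) next
    idx <- offset[ch[ok]] + floor(md[ok] / bin) + 1
    counts[, f, s] <- counts[, f, s] +
      tabulate(idx, nbins = nrow(bins))
  }
  out <- binned_fraction_counts(bins, counts, cell_type = cell_type)
  attr(out, "rejects") <- n_rej
  out
}

# Per-window sufficient statistics: depth-normalized, rounded counts summed
# over the 3 bins of the window; y = early half (E+EM), m = all fractions.
window_sufficient_stats <- function(counts, window = 3L) {
  bins <- counts$bins
  sf <- counts$size_factor   # [sample, fraction]
  nt <- counts$counts
  for (s in seq_len(dim(nt)[3])) for (f in 1:4)
    nt[, f, s] <- round(nt[, f, s] / sf[s, f])
  early <- nt[, "E", , drop = FALSE] + nt[, "EM", , drop = FALSE]
  total <- early + nt[, "LM", , drop = FALSE] + nt[, "L", , drop = FALSE]
  y_bin <- rowSums(early, dims = 1)
  m_bin <- rowSums(total, dims = 1)
  # sliding sum of `window` consecutive bins within each chromosome
  win <- NULL
  for (ch in unique(bins$chrom)) {
    i <- which(bins$chrom == ch)
    if (length(i) < window) next
    k <- length(i) - window + 1L
    cy <- cumsum(c(0, y_bin[i])); cm <- cumsum(c(0, m_bin[i]))
    win_ch <- data.frame(
      chrom = ch,
      start = bins$start[i[1:k]],
      end = bins$end[i[window:length(i)]],
      y = cy[(window + 1):(length(i) + 1)] - cy[1:k],
      m = cm[(window + 1):(length(i) + 1)] - cm[1:k],
      stringsAsFactors = FALSE)
    win <- rbind(win, win_ch)
  }
  if (is.null(win)) stop("no chromosome holds a full window")
  win
}

#' Posterior logit timing scores in 3 kb sliding windows
#'
#' For each 3 kb window (3 consecutive 1 kb bins, 1 kb step) the model
#' treats the depth-normalized early-half count (E + EM fractions) as
#' binomial successes out of the window's total count, with a
#' Normal(0, tau^2) prior on the log-odds theta. A positive posterior mean
#' means early replication, a negative one late. Windows with no data keep
#' the prior mean 0 and are flagged `no_data`.
#'
#' @param counts A [binned_fraction_counts()] object.
#' @param window Number of consecutive bins per window (default 3).
#' @param tau Prior standard deviation on the logit scale (default 2).
#' @param nodes Quadrature nodes on theta in \[-12, 12\] (default 2001).
#' @return A `timing_track` data.frame: `chrom`, `start`, `end`, `theta`,
#'   `n_eff`, `no_data`; attribute `cell_type`.
#' @export
timing_score <- function(counts, window = 3L, tau = 2, nodes = 2001L) {
  if (tau <= 0) stop("prior sd tau must be positive")
  win <- window_sufficient_stats(counts, window)
  post <- logit_posterior(win$y, win$m, tau = tau,
                          grid = logit_grid(nodes = nodes))
  out <- data.frame(chrom = win$chrom, start = win$start, end = win$end,
                    theta = post$mean, n_eff = win$m,
                    no_data = win$m == 0, stringsAsFactors = FALSE)
  out$theta[out$no_data] <- 0
  attr(out, "cell_type") <- counts$cell_type
  class(out) <- c("timing_track", "data.frame")
  out
}

#' Bayes-factor test for differential replication timing
#'
#' Compares, window by window, a full model with independent logit timing
#' parameters per cell type (each with a Normal(0, tau^2) prior) against a
#' reduced model sharing one parameter. Marginal likelihoods are computed by
#' quadrature in log space; the full model factorizes into two 1-D
#' integrals. The Bayes factor K = m_full / m_reduced exceeds 1 when the
#' data favour distinct timing. Binomial coefficients cancel between the
#' models.
#'
#' @param counts_a,counts_b [binned_fraction_counts()] for the two cell
#'   types, on identical bin grids.
#' @param window Bins per window (default 3).
#' @param tau Prior sd on the logit scale (default 2).
#' @param nodes Quadrature nodes (default 2001).
#' @return A `differential_test_track` data.frame with columns `chrom`,
#'   `start`, `end`, `log_k` (natural log of K), `k`, `delta`
#'   (posterior-mean theta_A minus theta_B), `theta_a`, `theta_b`.
#' @export
bayes_factor <- function(counts_a, counts_b, window = 3L, tau = 2,
                         nodes = 2001L) {
  win_a <- window_sufficient_stats(counts_a, window)
  win_b <- window_sufficient_stats(counts_b, window)
  if (!identical(win_a[c("chrom", "start", "end")],
                 win_b[c("chrom", "start", "end")]))
    stop("window grids of the two cell types do not match")
  grid <- logit_grid(nodes = nodes)
  pa <- logit_posterior(win_a$y, win_a$m, tau, grid)
  pb <- logit_posterior(win_b$y, win_b$m, tau, grid)
  pr <- logit_posterior(win_a$y + win_b$y, win_a$m + win_b$m, tau, grid)
  log_k <- pa$log_marginal + pb$log_marginal - pr$log_marginal
  out <- data.frame(chrom = win_a$chrom, start = win_a$start,
                    end = win_a$end, log_k = log_k, k = exp(log_k),
                    delta = pa$mean - pb$mean,
                    theta_a = pa$mean, theta_b = pb$mean,
                    stringsAsFactors = FALSE)
  attr(out, "cell_types") <- c(counts_a$cell_type, counts_b$cell_type)
  class(out) <- c("differential_test_track", "data.frame")
  out
}
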