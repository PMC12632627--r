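#' Call differential replication-timing regions by nested thresholding
#'
#' Two-threshold ("nested") peak calling on a Bayes-factor track: seed
#' windows with K >= `k_seed` are extended through contiguous windows with
#' K >= `k_extend` sharing the sign of the timing difference `delta`;
#' same-direction runs separated by at most `gap` bp are merged; regions
#' narrower than `min_width` are discarded (differential timing calls are
#' only trusted at >= 20 kb). The peak of a region is the contiguous
#' seed-level sub-run containing its strongest window.
#'
#' @param test A `differential_test_track` from [bayes_factor()].
#' @param k_seed Seed Bayes-factor threshold (default 10).
#' @param k_extend Extension threshold (default 3).
#' @param gap Maximum bp between merged same-direction runs (default 3000).
#' @param min_width Minimum region width in bp (default 20000).
#' @return data.frame of regions: `chrom`, `start`, `end`, `direction`
#'   (`"A-earlier"`/`"B-earlier"`), `width`, `mean_delta`, `max_k`,
#'   `peak_start`, `peak_end`.
#' @export
call_differential_regions <- function(test, k_seed = 10, k_extend = 3,
                                      gap = 3000, min_width = 20000) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      width = numeric(), mean_delta = numeric(),
                      max_k = numeric(), peak_start = numeric(),
                      peak_end = numeric(), stringsAsFactors = FALSE)
  if (nrow(test) == 0) return(empty)
  out <- empty
  for (ch in unique(test$chrom)) {
    tr <- test[test$chrom == ch, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    ext <- tr$k >= k_extend & tr$delta != 0
    if (!any(ext)) next
    sgn <- sign(tr$delta)
    # runs of contiguous extension-level windows with constant sign
    run_id <- cumsum(c(TRUE, !(ext[-1] & ext[-nrow(tr)] &
                               sgn[-1] == sgn[-nrow(tr)])))
    runs <- NULL
    for (r in unique(run_id[ext])) {
      i <- which(run_id == r & ext)
      if (!length(i)) next
      runs <- rbind(runs, data.frame(
        start = tr$start[min(i)], end = tr$end[max(i)],
        sgn = sgn[i[1]], has_seed = any(tr$k[i] >= k_seed),
        i0 = min(i), i1 = max(i)))
    }
    if (is.null(runs)) next
    runs <- runs[order(runs$start), , drop = FALSE]
    # merge same-direction runs separated by <= gap
    grp <- cumsum(c(TRUE, runs$start[-1] - runs$end[-nrow(runs)] > gap |
                          runs$sgn[-1] != runs$sgn[-nrow(runs)]))
    for (g in unique(grp)) {
      rg <- runs[grp == g, , drop = FALSE]
      if (!any(rg$has_seed)) next
      start <- min(rg$start); end <- max(rg$end)
      if (end - start < min_width) next
      members <- unlist(mapply(seq, rg$i0, rg$i1, SIMPLIFY = FALSE))
      mean_delta <- mean(tr$delta[members])
      # peak: contiguous seed-level sub-run around the max-K window
      seed_i <- members[tr$k[members] >= k_seed]
      imax <- seed_i[which.max(tr$k[seed_i])]
      lo <- imax; hi <- imax
      while ((lo - 1) %in% seed_i) lo <- lo - 1
      while ((hi + 1) %in% seed_i) hi <- hi + 1
      out <- rbind(out, data.frame(
        chrom = ch, start = start, end = end,
        direction = if (mean_delta > 0) "A-earlier" else "B-earlier",
        width = end - start, mean_delta = mean_delta,
        max_k = tr$k[imax],
        peak_start = tr$start[lo], peak_end = tr$end[hi],
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' LOESS-smooth a timing track
#'
#' Local weighted linear regression with tricube weights in a fixed
#' genomic bandwidth, applied per chromosome (no smoothing across
#' boundaries). At each window center the fit uses windows within
#' `span_bp / 2`, weighted by `(1 - (d / h)^3)^3`. A chromosome shorter
#' than the span falls back to a single global linear fit, with a warning.
#'
#' @param track A `timing_track` from [timing_score()] (or any track with
#'   `chrom`, `start`, `end` and a `theta` column).
#' @param span_bp Smoothing span in bp (default 1e5).
#' @param degree Local polynomial degree; only 1 is supported.
#' @return The track with `theta` replaced by its smoothed values.
#' @export
loess_smooth <- function(track, span_bp = 1e5, degree = 1) {
  if (degree != 1) stop("only degree-1 local fits are supported")
  h <- span_bp / 2
  out <- track
  for (ch in unique(track$chrom)) {
    i <- which(track$chrom == ch)
    x <- (track$start[i] + track$end[i]) / 2
    y <- track$theta[i]
    if (span_bp < 3 * stats::median(diff(sort(x))))
      stop("span must cover at least 3 windows")
    if (diff(range(x)) < span_bp) {
      warning("chromosome ", ch, " shorter than span; global linear fit")
      fit <- stats::lm.fit(cbind(1, x), y)
      out$theta[i] <- fit$fitted.values
      next
    }
    out$theta[i] <- tricube_local_linear(x, y, h)
  }
  out
}

# direct local linear fit at every x with tricube weights in half-width h
tricube_local_linear <- function(x, y, h) {
  n <- length(x)
  fitted <- numeric(n)
  ord <- order(x)
  xo <- x[ord]; yo <- y[ord]
  lo <- 1L; hi <- 1L
  fo <- numeric(n)
  for (j in seq_len(n)) {
    while (lo <= n && xo[lo] < xo[j] - h) lo <- lo + 1L
    while (hi < n && xo[hi + 1] <= xo[j] + h) hi <- hi + 1L
    idx <- lo:hi
    d <- abs(xo[idx] - xo[j]) / h
    w <- (1 - pmin(d, 1)^3)^3
    xs <- xo[idx] - xo[j]
    sw <- sum(w); swx <- sum(w * xs); swxx <- sum(w * xs^2)
    swy <- sum(w * yo[idx]); swxy <- sum(w * xs * yo[idx])
    det <- sw * swxx - swx^2
    fo[j] <- if (det > 1e-12 * sw^2 * max(h^2, 1)) {
      (swxx * swy - swx * swxy) / det
    } else swy / sw
  }
  fitted[ord] <- fo
  fitted
}

#' Standardize timing tracks to RT Z-scores
#'
#' Within each cell type, theta is centered and scaled over all windows
#' with data (no-data windows are excluded from the mean/sd and carry NA),
#' giving genome-wide mean 0 and unit standard deviation under the
#' population convention (divisor n). Z-scores make timing comparable
#' across cell types with different dynamic ranges; the transform is
#' invariant to positive affine rescaling of theta.
#'
#' @param tracks A `timing_track` or list of them.
#' @return A `z_track` data.frame (or list of them) with column `z`.
#' @export
rt_zscore <- function(tracks) {
  one <- function(track) {
    ok <- !track$no_data
    th <- track$theta[ok]
    s <- sqrt(mean((th - mean(th))^2))
    if (!is.finite(s) || s == 0) stop("zero variance timing track")
    out <- data.frame(chrom = track$chrom, start = track$start,
                      end = track$end, z = NA_real_,
                      stringsAsFactors = FALSE)
    out$z[ok] <- (th - mean(th)) / s
    attr(out, "cell_type") <- attr(track, "cell_type")
    class(out) <- c("z_track", "data.frame")
    out
  }
  if (is.data.frame(tracks)) one(tracks) else lapply(tracks, one)
}

#' Summarize RT Z-scores over chromosomal domains
#'
#' Averages window Z-scores (windows assigned by midpoint) within each
#' configured chromosomal domain and attaches a categorical timing label.
#'
#' @param z A `z_track` from [rt_zscore()].
#' @param regions Region map data.frame (`region_id`, `chrom`, `start`,
#'   `end`, `class`), e.g. from [load_region_config()].
#' @param breaks Label boundaries: Early when z > `breaks[2]`, Early-Mid in
#'   (`breaks[1]`, `breaks[2]`\], Late-Mid in (-`breaks[1]`..\], Late at or
#'   below -`breaks[2]`. Defaults c(0, 0.5).
#' @return data.frame: `region_id`, `mean_z`, `label`, `n_windows`.
#' @export
region_summary <- function(z, regions, breaks = c(0, 0.5)) {
  mid <- (z$start + z$end) / 2
  out <- data.frame(region_id = regions$region_id,
                    mean_z = NA_real_, label = NA_character_,
                    n_windows = 0L, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(regions))) {
    sel <- z$chrom == regions$chrom[j] & mid >= regions$start[j] &
      mid < regions$end[j] & !is.na(z$z)
    out$n_windows[j] <- sum(sel)
    if (!any(sel)) {
      warning("region ", regions$region_id[j], " holds no windows")
      next
    }
    mz <- mean(z$z[sel])
    out$mean_z[j] <- mz
    out$label[j] <- if (mz > breaks[2]) "Early"
      else if (mz > breaks[1]) "Early-Mid"
      else if (mz > -breaks[2]) "Late-Mid"
      else "Late"
  }
  out
}

#' Total earlier-replicating size per chromosomal domain
#'
#' Sums called differential-region widths per domain and direction and
#' expresses them as fractions of the domain width, mirroring per-domain
#' "kb earlier in each cell type" summaries.
#'
#' @param regions_called data.frame from [call_differential_regions()].
#' @param regions Domain map (`region_id`, `chrom`, `start`, `end`, ...).
#' @return data.frame: `region_id`, `kb_a_earlier`, `kb_b_earlier`,
#'   `fraction_a`, `fraction_b`.
#' @export
earlier_size_summary <- function(regions_called, regions) {
  out <- data.frame(region_id = regions$region_id,
                    kb_a_earlier = 0, kb_b_earlier = 0,
                    fraction_a = 0, fraction_b = 0,
                    stringsAsFactors = FALSE)
  dom_w <- regions$end - regions$start
  for (j in seq_len(nrow(regions))) {
    sel <- regions_called$chrom == regions$chrom[j]
    if (!any(sel)) next
    rc <- regions_called[sel, , drop = FALSE]
    ov <- pmin(rc$end, regions$end[j]) - pmax(rc$start, regions$start[j])
    ov <- pmax(ov, 0)
    a <- rc$direction == "A-earlier"
    out$kb_a_earlier[j] <- sum(ov[a]) / 1000
    out$kb_b_earlier[j] <- sum(ov[!a]) / 1000
  }
  out$fraction_a <- out$kb_a_earlier * 1000 / dom_w
  out$fraction_b <- out$kb_b_earlier * 1000 / dom_w
  out
}
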