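#' Pseudobulk counts-per-million by cluster
#'
#' Sums (optionally cell-weighted) counts over the cells of each cluster
#' and scales each cluster's gene totals to one million, the pseudobulk
#' expression unit used for all on/off and category calls. `log_cpm` is
#' `log10(cpm + pseudocount)`.
#'
#' @param counts Cell x gene count matrix (cells in rows; genes must be
#'   named columns).
#' @param clusters Cluster label per cell.
#' @param weights Optional positive weight per cell (e.g. from
#'   [cellcycle_weights()]); default 1.
#' @param pseudocount Added inside the log (default 1).
#' @return A `pseudobulk_table`: list with matrices `cpm` and `log_cpm`
#'   (gene x cluster).
#' @export
pseudobulk_cpm <- function(counts, clusters, weights = NULL,
                           pseudocount = 1) {
  counts <- as.matrix(counts)
  if (length(clusters) != nrow(counts))
    stop("every cell needs a cluster label")
  if (is.null(weights)) weights <- rep(1, nrow(counts))
  if (any(weights <= 0)) stop("weights must be positive")
  cl <- sort(unique(as.character(clusters)))
  cpm <- matrix(NA_real_, ncol(counts), length(cl),
                dimnames = list(colnames(counts), cl))
  for (k in cl) {
    w <- weights * (as.character(clusters) == k)
    tot <- as.vector(crossprod(counts, w))
    if (sum(tot) <= 0) stop("cluster ", k, " has zero total counts")
    cpm[, k] <- tot / sum(tot) * 1e6
  }
  structure(list(cpm = cpm, log_cpm = log10(cpm + pseudocount)),
            class = "pseudobulk_table")
}

#' Classify genes as on/off and into expression categories
#'
#' A gene is `on` in a cluster when its CPM is strictly above `on_thr`
#' (default 5); `on` genes are split into `low` / `medium` / `high` by
#' tertiles of their log CPM within the cluster.
#'
#' @param cpm Gene x cluster CPM matrix (or a `pseudobulk_table`).
#' @param on_thr On/off CPM threshold, strict (default 5).
#' @return List of gene x cluster character matrices `status` ("on"/"off")
#'   and `category` ("off"/"low"/"medium"/"high").
#' @export
classify_on_off <- function(cpm, on_thr = 5) {
  if (inherits(cpm, "pseudobulk_table")) cpm <- cpm$cpm
  status <- ifelse(cpm > on_thr, "on", "off")
  category <- matrix("off", nrow(cpm), ncol(cpm), dimnames = dimnames(cpm))
  for (k in seq_len(ncol(cpm))) {
    on <- status[, k] == "on"
    if (!any(on)) next
    lc <- log10(cpm[on, k] + 1)
    cuts <- stats::quantile(lc, c(1 / 3, 2 / 3), names = FALSE, type = 7)
    category[on, k] <- ifelse(lc <= cuts[1], "low",
                              ifelse(lc <= cuts[2], "medium", "high"))
  }
  list(status = status, category = category)
}

#' Cell weights equalizing cell-cycle phase composition
#'
#' Within each cluster, reweights cells so each phase (G1, S, G2M)
#' contributes exactly one third of the weighted mass, removing
#' cell-cycle-composition bias from pseudobulk comparisons.
#'
#' @param phases Phase label per cell; must take the three values
#'   `"G1"`, `"S"`, `"G2M"` within every cluster.
#' @param clusters Cluster label per cell.
#' @return Numeric weight per cell; weighted phase shares are 1/3 each.
#' @export
cellcycle_weights <- function(phases, clusters) {
  phases <- as.character(phases)
  need <- c("G1", "S", "G2M")
  w <- numeric(length(phases))
  for (k in unique(as.character(clusters))) {
    sel <- as.character(clusters) == k
    miss <- setdiff(need, unique(phases[sel]))
    if (length(miss))
      stop("cluster ", k, " is missing phase ", paste(miss, collapse = ", "))
    frac <- table(factor(phases[sel], levels = need)) / sum(sel)
    w[sel] <- (1 / 3) / as.numeric(frac[phases[sel]])
  }
  w
}

#' Shrunken log2 fold changes with s-values
#'
#' Posterior log2 fold change of cluster A over cluster B per gene, with a
#' Normal(0, tau^2) prior on the log2 effect. The likelihood is the two
#' Poisson gene totals conditioned on their sum, i.e. a binomial with
#' log-odds `log(lib_a / lib_b) + beta * log(2)` — equivalent to the
#' Poisson-with-offsets model. The s-value is the posterior probability
#' that the sign of the effect is wrong,
#' `min(P(beta <= 0), P(beta >= 0))`, capped at 0.5. A gene is selected
#' when its posterior fold change exceeds `fc_thr` on the linear scale and
#' its s-value is below `s_thr`.
#'
#' @param counts_a,counts_b Per-gene total counts in each cluster.
#' @param lib_a,lib_b Library sizes (total counts) of the two clusters.
#' @param tau Prior sd of the log2 fold change (default 1).
#' @param fc_thr Linear fold-change selection threshold (default 1.5).
#' @param s_thr s-value selection threshold (default 1e-4).
#' @param nodes Quadrature nodes (default 2001).
#' @return data.frame: `l2fc_post`, `s_value`, `selected`, `skipped`
#'   (genes with zero counts in both clusters, reported not tested).
#' @export
shrunken_lfc <- function(counts_a, counts_b, lib_a = sum(counts_a),
                         lib_b = sum(counts_b), tau = 1, fc_thr = 1.5,
                         s_thr = 1e-4, nodes = 2001L) {
  stopifnot(length(counts_a) == length(counts_b))
  if (lib_a <= 0 || lib_b <= 0) stop("library sizes must be positive")
  n <- length(counts_a)
  out <- data.frame(l2fc_post = NA_real_, s_value = NA_real_,
                    selected = FALSE, skipped = counts_a + counts_b == 0)
  test <- !out$skipped
  if (any(test)) {
    off <- log(lib_a / lib_b)
    # grid on beta (log2 scale); theta = off + beta*log2 enters the binomial
    grid <- logit_grid(lower = -12, upper = 12, nodes = nodes)
    beta <- grid$theta / log(2)   # prior N(0, tau^2) applied on beta scale
    lp0 <- stats::dnorm(beta, 0, tau, log = TRUE) + grid$logw
    y <- counts_a[test]; m <- (counts_a + counts_b)[test]
    eta <- off + grid$theta
    lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
    l2 <- numeric(sum(test)); sv <- numeric(sum(test))
    chunk <- max(1L, floor(5e6 / nodes))
    for (i0 in seq(1L, length(y), by = chunk)) {
      idx <- i0:min(length(y), i0 + chunk - 1L)
      lp <- outer(y[idx], eta) - outer(m[idx], lse)
      lp <- sweep(lp, 2, lp0, "+")
      mx <- apply(lp, 1, max)
      w <- exp(lp - mx)
      z <- rowSums(w)
      l2[idx] <- as.vector(w %*% beta) / z
      ple <- rowSums(w[, beta <= 0, drop = FALSE]) / z
      pge <- rowSums(w[, beta >= 0, drop = FALSE]) / z
      sv[idx] <- pmin(pmin(ple, pge), 0.5)
    }
    out$l2fc_post[test] <- l2
    out$s_value[test] <- sv
    out$selected[test] <- abs(l2) > log2(fc_thr) & sv < s_thr
  }
  out
}

#' X-to-autosome expression ratio
#'
#' Ratio of the median CPM of expressed ('on') X-linked genes to the median
#' CPM of expressed autosomal genes, per cluster; a ratio near 1 indicates
#' dosage compensation, near 0.5 its absence in male cells.
#'
#' @param cpm Gene x cluster CPM matrix (or `pseudobulk_table`).
#' @param gene_chrom Chromosome per gene (aligned with rows).
#' @param status Optional on/off matrix from [classify_on_off()]; computed
#'   at the default threshold when missing.
#' @param x_chrom Name(s) of the X chromosome (default "chrX").
#' @param exclude Chromosomes that are neither X nor autosome
#'   (default Y and the rDNA contig).
#' @return Named numeric vector of X:A ratios per cluster (NA when a
#'   cluster has no expressed X-linked gene).
#' @export
xa_ratio <- function(cpm, gene_chrom, status = NULL, x_chrom = "chrX",
                     exclude = c("chrY", "rDNA")) {
  if (inherits(cpm, "pseudobulk_table")) cpm <- cpm$cpm
  if (is.null(status)) status <- classify_on_off(cpm)$status
  is_x <- gene_chrom %in% x_chrom
  is_auto <- !is_x & !(gene_chrom %in% exclude)
  ratios <- stats::setNames(rep(NA_real_, ncol(cpm)), colnames(cpm))
  for (k in seq_len(ncol(cpm))) {
    on <- status[, k] == "on"
    xs <- cpm[is_x & on, k]; as_ <- cpm[is_auto & on, k]
    if (!length(xs) || !length(as_)) next
    ratios[k] <- stats::median(xs) / stats::median(as_)
  }
  ratios
}
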