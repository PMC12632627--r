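#' Filter ChIC fragments by mapping quality and length
#'
#' Keeps uniquely mapped fragments (MAPQ >= `mapq_min`, default 20) with a
#' mononucleosomal insert length inside `len_range` (inclusive). Fragment
#' order is preserved; a per-rule removal report is attached as attribute
#' `filter_report` (a fragment failing MAPQ is charged to the MAPQ rule
#' only).
#'
#' @param fragments data.frame with `chrom`, `start`, `end`, `mapq`, plus
#'   tag columns (`sample`, `condition`).
#' @param mapq_min Minimum MAPQ (default 20).
#' @param len_range Inclusive fragment-length bounds in bp
#'   (default c(120, 200)).
#' @return The passing fragments, with attribute `filter_report` listing
#'   `n_input`, `fail_mapq`, `fail_length`, `n_retained`.
#' @export
filter_fragments <- function(fragments, mapq_min = 20,
                             len_range = c(120, 200)) {
  len <- fragments$end - fragments$start
  ok_mapq <- fragments$mapq >= mapq_min
  ok_len <- len >= len_range[1] & len <= len_range[2]
  keep <- ok_mapq & ok_len
  out <- fragments[keep, , drop = FALSE]
  attr(out, "filter_report") <- c(
    n_input = nrow(fragments),
    fail_mapq = sum(!ok_mapq),
    fail_length = sum(ok_mapq & !ok_len),
    n_retained = sum(keep))
  out
}

#' Bin fragment midpoints into 20 bp steps by condition and replicate
#'
#' @param fragments Filtered fragments with `chrom`, `start`, `end`,
#'   `condition`, `sample`.
#' @param genome A [genome_model()].
#' @param bin Bin width in bp (default 20).
#' @return List: `bins` (data.frame chrom/start/end), `counts` (matrix
#'   bins x groups), `groups` (data.frame condition/sample per column).
#'   Total binned counts equal the number of in-bounds fragments.
#' @export
bin_midpoints_20 <- function(fragments, genome, bin = 20) {
  bins <- make_bins(genome, bin)
  groups <- unique(fragments[, c("condition", "sample")])
  groups <- groups[order(groups$condition, groups$sample), , drop = FALSE]
  rownames(groups) <- NULL
  counts <- matrix(0L, nrow(bins), nrow(groups))
  colnames(counts) <- paste(groups$condition, groups$sample, sep = ".")
  mid <- floor((fragments$start + fragments$end) / 2)
  offset <- cumsum(c(0, table(factor(bins$chrom,
                                     levels = unique(bins$chrom)))))
  names(offset) <- c(unique(bins$chrom), "END")
  n_bins_chrom <- table(factor(bins$chrom, levels = unique(bins$chrom)))
  for (g in seq_len(nrow(groups))) {
    sel <- fragments$condition == groups$condition[g] &
      fragments$sample == groups$sample[g]
    ch <- fragments$chrom[sel]; md <- mid[sel]
    ok <- ch %in% names(genome$chrom_sizes)
    ok[ok] <- md[ok] >= 0 & md[ok] < genome$chrom_sizes[ch[ok]]
    idx <- offset[ch[ok]] + floor(md[ok] / bin) + 1
    counts[, g] <- tabulate(idx, nbins = nrow(bins))
  }
  list(bins = bins, counts = counts, groups = groups)
}

# moment estimator of a shared NB dispersion from replicated input counts:
# with counts k ~ NB(sf*mu, alpha), normalized x = k/sf has
# Var(x) = mu * E[1/sf] + alpha * mu^2.
estimate_dispersion <- function(counts, size_factors, floor = 1e-8) {
  if (ncol(counts) < 2) return(floor)
  x <- sweep(counts, 2, size_factors, "/")
  mbar <- rowMeans(x)
  v <- apply(x, 1, stats::var)
  keep <- mbar > 0
  if (!any(keep)) return(floor)
  cbar <- mean(1 / size_factors)
  alpha <- sum(v[keep] - mbar[keep] * cbar) / sum(mbar[keep]^2)
  max(alpha, floor)
}

# Vectorized Newton MLE of eta = log(mu) for one NB group per bin:
# k_r ~ NB(mean = sf_r * exp(eta), dispersion alpha). At alpha -> 0 this is
# the Poisson closed form sum(k)/sum(sf).
nb_group_mle <- function(counts, size_factors, alpha, iter = 30,
                         tol = 1e-10) {
  tot <- rowSums(counts)
  sf_tot <- sum(size_factors)
  eta <- log(pmax(tot / sf_tot, 1e-12))
  nz <- tot > 0
  if (alpha < 1e-12 || !any(nz)) return(eta)
  inv_a <- 1 / alpha
  for (it in seq_len(iter)) {
    mu <- exp(eta[nz]) %o% size_factors     # [bin, rep]
    denom <- mu + inv_a
    score <- rowSums(counts[nz, , drop = FALSE] -
                       (counts[nz, , drop = FALSE] + inv_a) * mu / denom)
    info <- rowSums((counts[nz, , drop = FALSE] + inv_a) *
                      mu * inv_a / denom^2)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -2), 2)
    eta[nz] <- eta[nz] + step
    if (max(abs(step)) < tol) break
  }
  eta
}

#' Negative-binomial enrichment regression per 20 bp bin
#'
#' Fits, independently per bin, the count model
#' `log mu = beta0 + log(2) * l2fc * 1[IP] + log sf` with a shared
#' genome-wide NB dispersion estimated by method of moments on the input
#' replicates (floored at 1e-8; the model collapses to Poisson there).
#' `beta0` is the H3 (input) abundance intercept; `l2fc` is the IP-vs-input
#' log2 fold-change coefficient. Bins where both conditions are all-zero
#' are flagged and carry NA coefficients.
#'
#' @param ip_counts,input_counts Matrices `[bin, replicate]`.
#' @param size_factors List with numeric vectors `ip` and `input`
#'   (default all 1).
#' @param dispersion Optional fixed dispersion; estimated when `NULL`.
#' @return An `enrichment_track` data.frame with `intercept`, `l2fc`,
#'   `flagged`; attribute `dispersion`.
#' @export
nb_regression <- function(ip_counts, input_counts, size_factors = NULL,
                          dispersion = NULL) {
  ip_counts <- as.matrix(ip_counts); input_counts <- as.matrix(input_counts)
  if (nrow(ip_counts) != nrow(input_counts)) stop("bin grids differ")
  if (is.null(size_factors))
    size_factors <- list(ip = rep(1, ncol(ip_counts)),
                         input = rep(1, ncol(input_counts)))
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(input_counts, size_factors$input)
  eta_in <- nb_group_mle(input_counts, size_factors$input, dispersion)
  eta_ip <- nb_group_mle(ip_counts, size_factors$ip, dispersion)
  flagged <- rowSums(ip_counts) == 0 & rowSums(input_counts) == 0
  out <- data.frame(intercept = eta_in,
                    l2fc = (eta_ip - eta_in) / log(2),
                    flagged = flagged)
  out$intercept[flagged] <- NA_real_
  out$l2fc[flagged] <- NA_real_
  # one empty condition gives an unbounded contrast; flag it too
  half <- xor(rowSums(ip_counts) == 0, rowSums(input_counts) == 0)
  out$l2fc[half] <- NA_real_
  attr(out, "dispersion") <- dispersion
  class(out) <- c("enrichment_track", "data.frame")
  out
}

#' Gaussian-kernel density smoothing of a binned track
#'
#' Discrete convolution with a Gaussian kernel (sd `sigma_bp`, truncated at
#' four standard deviations, normalized to sum 1), applied per chromosome
#' with reflecting boundaries so total mass is conserved. With the default
#' 20 bp bins and sigma = 40 bp the kernel sd is 2 bins.
#'
#' @param values Numeric vector of per-bin values.
#' @param chrom Optional chromosome id per bin; smoothing never crosses a
#'   chromosome boundary.
#' @param sigma_bp Kernel standard deviation in bp (default 40).
#' @param bin_bp Bin width in bp (default 20).
#' @return Smoothed numeric vector of the same length.
#' @export
gaussian_smooth <- function(values, chrom = NULL, sigma_bp = 40,
                            bin_bp = 20) {
  if (sigma_bp <= 0) stop("sigma must be positive")
  s <- sigma_bp / bin_bp
  half <- ceiling(4 * s)
  kern <- stats::dnorm(-half:half, 0, s)
  kern <- kern / sum(kern)
  smooth_one <- function(v) {
    n <- length(v)
    if (n == 1) return(v)
    # reflecting pad; recycle if chromosome shorter than the kernel arm
    pad_l <- rev(v[seq_len(min(half, n))])
    pad_r <- rev(v[(n - min(half, n) + 1):n])
    while (length(pad_l) < half) pad_l <- c(rev(pad_l), pad_l)[1:half]
    while (length(pad_r) < half) pad_r <- c(pad_r, rev(pad_r))[1:half]
    ext <- c(pad_l, v, pad_r)
    out <- stats::filter(ext, kern, method = "convolution", sides = 2)
    as.numeric(out[(half + 1):(half + n)])
  }
  if (is.null(chrom)) return(smooth_one(values))
  out <- values
  for (ch in unique(chrom)) {
    i <- chrom == ch
    out[i] <- smooth_one(values[i])
  }
  out
}

#' Log2 fold enrichment of IP density over input density
#'
#' Computes `log2((ip + floor) / (input + floor))` per bin. With
#' `normalize = TRUE` (the default) both densities are first rescaled to a
#' common genome-wide mass (their mean total), the minimal depth
#' correction of IP against input; set `normalize = FALSE` to compare
#' tracks already on a common scale.
#'
#' @param ip_density,input_density Numeric vectors on matched bins.
#' @param floor Density floor preventing infinite enrichment in empty
#'   regions (default 1e-6).
#' @param normalize Equal-mass rescaling before the ratio (default TRUE).
#' @return Numeric vector of per-bin log2 fold enrichment.
#' @export
l2fe <- function(ip_density, input_density, floor = 1e-6,
                 normalize = TRUE) {
  if (length(ip_density) != length(input_density)) stop("bin grids differ")
  if (normalize) {
    target <- (sum(ip_density) + sum(input_density)) / 2
    if (sum(ip_density) > 0) ip_density <- ip_density * target / sum(ip_density)
    if (sum(input_density) > 0)
      input_density <- input_density * target / sum(input_density)
  }
  log2((ip_density + floor) / (input_density + floor))
}

#' Average signal profile around transcription start sites
#'
#' Averages a binned track in a window around each gene's TSS, per
#' expression category, flipping minus-strand genes so downstream of the
#' TSS is always to the right. Flank positions falling off a chromosome are
#' dropped for that gene (averages use the genes with data at each
#' position).
#'
#' @param values Per-bin track values.
#' @param bins Bin table (`chrom`, `start`, `end`) matching `values`.
#' @param genes data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @param categories Named character vector (or factor) of categories per
#'   gene, aligned with `genes` rows.
#' @param window Half-width around the TSS in bp (default 1000).
#' @param bin_bp Track bin width (default 20).
#' @return A `meta_profile` data.frame: `category`, `position`, `mean`,
#'   `n_genes`.
#' @export
tss_metaprofile <- function(values, bins, genes, categories,
                            window = 1000, bin_bp = 20) {
  stopifnot(nrow(genes) == length(categories))
  offsets <- seq(-window, window, by = bin_bp)
  chrom_levels <- unique(bins$chrom)
  offset_tbl <- cumsum(c(0, table(factor(bins$chrom, levels = chrom_levels))))
  names(offset_tbl) <- c(chrom_levels, "END")
  n_chrom_bins <- table(factor(bins$chrom, levels = chrom_levels))
  out <- NULL
  for (cat in unique(as.character(categories))) {
    gi <- which(as.character(categories) == cat)
    if (!length(gi)) next
    acc <- matrix(NA_real_, length(gi), length(offsets))
    for (k in seq_along(gi)) {
      g <- genes[gi[k], ]
      if (!g$chrom %in% chrom_levels) next
      pos <- if (g$strand == "-") g$tss - offsets else g$tss + offsets
      bin_i <- floor(pos / bin_bp)
      ok <- bin_i >= 0 & bin_i < n_chrom_bins[[g$chrom]]
      acc[k, ok] <- values[offset_tbl[[g$chrom]] + bin_i[ok] + 1]
    }
    n_used <- sum(rowSums(!is.na(acc)) > 0)
    if (n_used == 0) { warning("empty category ", cat, " dropped"); next }
    out <- rbind(out, data.frame(
      category = cat, position = offsets,
      mean = colMeans(acc, na.rm = TRUE), n_genes = n_used,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  class(out) <- c("meta_profile", "data.frame")
  out
}

#' Mean enrichment over gene bodies
#'
#' Length-weighted mean of a binned track over each gene body
#' `[start, end)`, yielding one scalar per gene.
#'
#' @param values Per-bin track values.
#' @param bins Bin table matching `values`.
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param bin_bp Track bin width (default 20).
#' @return data.frame: `gene_id`, `mean_l2fe`.
#' @export
gene_body_enrichment <- function(values, bins, genes, bin_bp = 20) {
  if (any(genes$end <= genes$start)) stop("zero-length gene body")
  chrom_levels <- unique(bins$chrom)
  offset_tbl <- cumsum(c(0, table(factor(bins$chrom, levels = chrom_levels))))
  names(offset_tbl) <- c(chrom_levels, "END")
  n_chrom_bins <- table(factor(bins$chrom, levels = chrom_levels))
  res <- numeric(nrow(genes))
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    b0 <- floor(g$start / bin_bp)
    b1 <- ceiling(g$end / bin_bp) - 1
    b0 <- max(b0, 0); b1 <- min(b1, n_chrom_bins[[g$chrom]] - 1)
    bi <- b0:b1
    idx <- offset_tbl[[g$chrom]] + bi + 1
    w <- pmin(bins$end[idx], g$end) - pmax(bins$start[idx], g$start)
    res[k] <- sum(values[idx] * w) / sum(w)
  }
  data.frame(gene_id = genes$gene_id, mean_l2fe = res,
             stringsAsFactors = FALSE)
}

#' Classify loci with cell-type-specific histone-mark enrichment
#'
#' A bin is called specific to cell type A when its log2 fold enrichment is
#' above `thr` in A and below `-thr` in B (and mirrored for B), the
#' opposite-sign rule used for cell-type-specific chromatin. Per-domain
#' percentages of labeled bp are reported.
#'
#' @param l2fe_a,l2fe_b Per-bin L2FE for the two cell types, matched bins.
#' @param bins Bin table matching the tracks.
#' @param regions Domain map (`region_id`, `chrom`, `start`, `end`).
#' @param thr Enrichment threshold (default 0.2).
#' @return List: `labels` (character per bin: "A-specific", "B-specific"
#'   or NA) and `percent` (data.frame `region_id`, `pct_a`, `pct_b`).
#' @export
celltype_enrichment_classification <- function(l2fe_a, l2fe_b, bins,
                                               regions, thr = 0.2) {
  if (length(l2fe_a) != length(l2fe_b)) stop("bin grids differ")
  labels <- rep(NA_character_, length(l2fe_a))
  labels[!is.na(l2fe_a) & !is.na(l2fe_b) &
           l2fe_a > thr & l2fe_b < -thr] <- "A-specific"
  labels[!is.na(l2fe_a) & !is.na(l2fe_b) &
           l2fe_b > thr & l2fe_a < -thr] <- "B-specific"
  mid <- (bins$start + bins$end) / 2
  w <- bins$end - bins$start
  percent <- data.frame(region_id = regions$region_id,
                        pct_a = 0, pct_b = 0, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(regions))) {
    sel <- bins$chrom == regions$chrom[j] & mid >= regions$start[j] &
      mid < regions$end[j]
    dw <- regions$end[j] - regions$start[j]
    percent$pct_a[j] <- 100 * sum(w[sel][labels[sel] %in% "A-specific"]) / dw
    percent$pct_b[j] <- 100 * sum(w[sel][labels[sel] %in% "B-specific"]) / dw
  }
  list(labels = labels, percent = percent)
}
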