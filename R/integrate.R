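#' Assign replication timing and timing quadrants to genes
#'
#' Reads each gene's logit timing score from the window whose center is
#' nearest the TSS (ties to the left window) in each of two cell types and
#' labels the gene with a timing quadrant by the sign pair: positive theta
#' is early, negative late, exact zero a boundary. Genes whose TSS lands
#' in a no-data window are flagged.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `tss`.
#' @param track_a,track_b `timing_track`s from [timing_score()] for cell
#'   types A and B, on the same window grid.
#' @return data.frame: `gene_id`, `theta_a`, `theta_b`, `quadrant`
#'   (e.g. "Early-A/Late-B"), `no_data`.
#' @export
assign_gene_rt <- function(genes, track_a, track_b) {
  if (!identical(track_a[c("chrom", "start", "end")],
                 track_b[c("chrom", "start", "end")]))
    stop("timing tracks are on different window grids")
  out <- data.frame(gene_id = genes$gene_id,
                    theta_a = NA_real_, theta_b = NA_real_,
                    quadrant = NA_character_, no_data = TRUE,
                    stringsAsFactors = FALSE)
  centers <- (track_a$start + track_a$end) / 2
  for (k in seq_len(nrow(genes))) {
    i <- which(track_a$chrom == genes$chrom[k])
    if (!length(i)) next
    d <- abs(centers[i] - genes$tss[k])
    # nearest window center; ties resolved to the left (earlier) window
    j <- i[which(d == min(d))[1]]
    if (track_a$no_data[j] || track_b$no_data[j]) next
    ta <- track_a$theta[j]; tb <- track_b$theta[j]
    lab <- function(t, s) {
      if (t > 0) paste0("Early-", s) else if (t < 0) paste0("Late-", s)
      else paste0("Boundary-", s)
    }
    out$theta_a[k] <- ta
    out$theta_b[k] <- tb
    out$quadrant[k] <- paste(lab(ta, "A"), lab(tb, "B"), sep = "/")
    out$no_data[k] <- FALSE
  }
  out
}

#' Histone-mark enrichment at differential replication-timing regions
#'
#' Summarizes per-region, per-mark, per-cell-type log2 fold enrichment
#' (length-weighted mean and quartiles over the bins of the region) and
#' emits the paired A-minus-B difference per region for downstream testing.
#'
#' @param l2fe_tracks Nested list: `l2fe_tracks[[cell_type]][[mark]]` is a
#'   per-bin L2FE vector; all on the bin grid `bins`.
#' @param bins Bin table (`chrom`, `start`, `end`).
#' @param regions data.frame of differential regions
#'   (from [call_differential_regions()]).
#' @return data.frame with one row per region x mark x cell type:
#'   `region`, `chrom`, `start`, `end`, `direction`, `mark`, `cell_type`,
#'   `mean_l2fe`, `q25`, `median`, `q75`, plus `diff_ab` (repeated per
#'   pair) on the rows of the first cell type.
#' @export
enrichment_at_regions <- function(l2fe_tracks, bins, regions) {
  cell_types <- names(l2fe_tracks)
  marks <- names(l2fe_tracks[[1]])
  out <- NULL
  if (nrow(regions) == 0) {
    return(data.frame(region = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      direction = character(), mark = character(),
                      cell_type = character(), mean_l2fe = numeric(),
                      q25 = numeric(), median = numeric(), q75 = numeric(),
                      diff_ab = numeric(), stringsAsFactors = FALSE))
  }
  mid <- (bins$start + bins$end) / 2
  w <- bins$end - bins$start
  for (r in seq_len(nrow(regions))) {
    sel <- bins$chrom == regions$chrom[r] & mid >= regions$start[r] &
      mid < regions$end[r]
    if (!any(sel)) stop("region ", r, " lies outside the track")
    for (mk in marks) {
      means <- numeric(length(cell_types))
      rows <- NULL
      for (ci in seq_along(cell_types)) {
        v <- l2fe_tracks[[cell_types[ci]]][[mk]][sel]
        ok <- is.finite(v)
        means[ci] <- sum(v[ok] * w[sel][ok]) / sum(w[sel][ok])
        qs <- stats::quantile(v[ok], c(0.25, 0.5, 0.75), names = FALSE)
        rows <- rbind(rows, data.frame(
          region = r, chrom = regions$chrom[r], start = regions$start[r],
          end = regions$end[r], direction = regions$direction[r],
          mark = mk, cell_type = cell_types[ci], mean_l2fe = means[ci],
          q25 = qs[1], median = qs[2], q75 = qs[3],
          stringsAsFactors = FALSE))
      }
      rows$diff_ab <- NA_real_
      rows$diff_ab[1] <- means[1] - means[2]
      out <- rbind(out, rows)
    }
  }
  rownames(out) <- NULL
  out
}

#' Correlation of chromosomal-domain timing profiles across cell types
#'
#' Pearson correlation matrix of the per-domain mean RT Z-score vectors of
#' two or more cell types; the workhorse behind "which cell types share a
#' replication-timing architecture".
#'
#' @param summaries Named list of [region_summary()] tables, one per cell
#'   type, over the same region set.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
region_profile_correlation <- function(summaries) {
  if (length(summaries) < 2) stop("need at least two cell types")
  ids <- summaries[[1]]$region_id
  for (s in summaries)
    if (!identical(s$region_id, ids))
      stop("summaries cover different region sets")
  mat <- sapply(summaries, function(s) s$mean_z)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(mat) < 3) stop("need at least 3 regions for a stable correlation")
  cc <- stats::cor(mat, method = "pearson")
  diag(cc) <- 1
  cc
}

#' Rank-sum test helper for paired region-level enrichment differences
#'
#' Thin wrapper around a Wilcoxon test on the per-region paired A-minus-B
#' L2FE differences emitted by [enrichment_at_regions()], for users who
#' want a significance call on the asymmetry.
#'
#' @param diff_ab Numeric vector of paired differences (NA rows dropped).
#' @param alternative Passed to [stats::wilcox.test()].
#' @return The `htest` object.
#' @export
region_ranksum <- function(diff_ab, alternative = "two.sided") {
  diff_ab <- diff_ab[is.finite(diff_ab)]
  stats::wilcox.test(diff_ab, alternative = alternative, exact = FALSE)
}
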