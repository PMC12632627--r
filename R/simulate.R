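# Synthetic-data generators. Every generator is a pure function of its
# arguments and seed, and every planted truth object is returned alongside
# the data so downstream recovery tests never re-derive truth.

#' Simulate a small genome with a 12-domain region map
#'
#' Builds a genome in the image of the fly karyotype: autosomal arms named
#' `chr2L/chr2R/chr3L/chr3R` are each split into a euchromatic arm and a
#' centromere-proximal pericentromeric block (L arms at their right end,
#' R arms at their left end); `chr4`, `chrX` and `chrY` are single
#' whole-chromosome domains; one rDNA repeat-unit contig is appended. The
#' default sizes give 12 domains over ~5 Mb.
#'
#' @param sizes Named chromosome sizes in bp (each >= 1e5).
#' @param pericentromere_fraction Fraction of each split autosome assigned
#'   to the pericentromeric block (default 0.3).
#' @param rdna_size Size of the appended rDNA repeat-unit contig
#'   (default 8000, one transcriptional unit).
#' @param seed Accepted for interface uniformity; the construction is
#'   deterministic arithmetic.
#' @return A [genome_model()].
#' @export
simulate_genome <- function(sizes = c(chr2L = 1e6, chr2R = 1e6,
                                      chr3L = 8e5, chr3R = 1.2e6,
                                      chr4 = 3e5, chrX = 5e5, chrY = 2e5),
                            pericentromere_fraction = 0.3,
                            rdna_size = 8000, seed = NULL) {
  if (any(sizes < 1e5)) stop("chromosome sizes must be at least 100 kb")
  if (pericentromere_fraction <= 0 || pericentromere_fraction >= 1)
    stop("pericentromere_fraction must be in (0, 1)")
  chrom_sizes <- c(sizes, rDNA = rdna_size)
  regions <- NULL
  for (ch in names(sizes)) {
    size <- sizes[[ch]]
    if (grepl("^chr[0-9]+[LR]$", ch)) {
      peri <- round(size * pericentromere_fraction)
      if (grepl("L$", ch)) {          # centromere at the right end
        arm <- data.frame(region_id = paste0(ch, "_arm"), chrom = ch,
                          start = 0, end = size - peri, class = "arm")
        pc <- data.frame(region_id = paste0(ch, "_peri"), chrom = ch,
                         start = size - peri, end = size,
                         class = "pericentromeric")
      } else {                        # centromere at the left end
        pc <- data.frame(region_id = paste0(ch, "_peri"), chrom = ch,
                         start = 0, end = peri, class = "pericentromeric")
        arm <- data.frame(region_id = paste0(ch, "_arm"), chrom = ch,
                          start = peri, end = size, class = "arm")
      }
      regions <- rbind(regions, arm, pc)
    } else {
      regions <- rbind(regions, data.frame(
        region_id = ch, chrom = ch, start = 0, end = size,
        class = "whole-chromosome"))
    }
  }
  regions <- rbind(regions, data.frame(
    region_id = "rDNA_unit", chrom = "rDNA", start = 0, end = rdna_size,
    class = "rDNA-unit"))
  genome_model(chrom_sizes, regions)
}

#' Construct a replication-timing truth directly
#'
#' Low-level constructor for a `timing_truth` object from explicit per-bin
#' true logit timing scores; [simulate_timing_truth()] is the generative
#' front end.
#'
#' @param bins Bin table (`chrom`, `start`, `end`), 1 kb tiling.
#' @param theta_a,theta_b True per-bin logit timing scores per cell type.
#' @param blocks Optional data.frame of planted differential blocks
#'   (`chrom`, `start`, `end`, `direction`).
#' @return A `timing_truth` list.
#' @export
timing_truth <- function(bins, theta_a, theta_b = theta_a, blocks = NULL) {
  stopifnot(length(theta_a) == nrow(bins), length(theta_b) == nrow(bins),
            all(is.finite(theta_a)), all(is.finite(theta_b)))
  if (is.null(blocks))
    blocks <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), direction = character(),
                         stringsAsFactors = FALSE)
  structure(list(bins = bins, theta_a = theta_a, theta_b = theta_b,
                 blocks = blocks),
            class = "timing_truth")
}

# smooth random field on a 1 kb grid: Gaussian-smoothed white noise with a
# given correlation length, rescaled to the requested sd
smooth_field <- function(n, corr_bins, sd_target) {
  if (n == 1) return(stats::rnorm(1, 0, sd_target))
  z <- stats::rnorm(n + 2 * corr_bins * 4)
  z <- gaussian_smooth(z, sigma_bp = corr_bins, bin_bp = 1)
  z <- z[(corr_bins * 4 + 1):(corr_bins * 4 + n)]
  s <- stats::sd(z)
  if (!is.finite(s) || s == 0) s <- 1
  z / s * sd_target
}

#' Simulate a replication-timing truth with planted differential blocks
#'
#' Generates smooth per-1kb-bin true logit timing scores for two cell
#' types, A and B. Shared structure: a smooth field over the arms (sd ~1.2,
#' ~50 kb correlation length), late pericentromeres and chrY
#' (theta* shifted to about -2). Cell-type structure: in cell A the
#' pericentromeric blocks, chr4 and the rDNA unit replicate early
#' (theta* about +1.5), emulating the early heterochromatin replication of
#' germline stem cells; planted differential blocks of a configurable
#' width force theta*_A - theta*_B = +/- 3 with a tagged direction.
#' Scores are clamped to \[-3, 3\].
#'
#' @param genome A [genome_model()].
#' @param bin Bin width in bp (default 1000).
#' @param diff_blocks Optional data.frame (`chrom`, `start`, `end`,
#'   `direction` in "A-earlier"/"B-earlier"); when `NULL`, one 50 kb
#'   A-earlier and one 50 kb B-earlier block are planted on the largest
#'   arm domains.
#' @param block_delta Half-separation of planted blocks: theta* is set to
#'   +`block_delta`/2 in the earlier cell type and -`block_delta`/2 in the
#'   other (default 3).
#' @param early_het_in_a Plant early pericentromere/chr4/rDNA in cell A
#'   (default TRUE).
#' @param seed Random seed.
#' @return A `timing_truth` list: `bins`, `theta_a`, `theta_b`, `blocks`.
#' @export
simulate_timing_truth <- function(genome, bin = 1000, diff_blocks = NULL,
                                  block_delta = 3, early_het_in_a = TRUE,
                                  seed = 1) {
  set.seed(seed)
  bins <- make_bins(genome, bin)
  n <- nrow(bins)
  base <- numeric(n)
  for (ch in unique(bins$chrom)) {
    i <- which(bins$chrom == ch)
    base[i] <- smooth_field(length(i), corr_bins = 50, sd_target = 1.2)
  }
  theta_a <- base
  theta_b <- base
  mid <- (bins$start + bins$end) / 2
  late_classes <- c("pericentromeric")
  for (j in seq_len(nrow(genome$regions))) {
    r <- genome$regions[j, ]
    sel <- bins$chrom == r$chrom & mid >= r$start & mid < r$end
    het <- r$class %in% late_classes || r$chrom == "chrY"
    early_a <- r$class %in% c("pericentromeric", "rDNA-unit") ||
      r$chrom == "chr4"
    if (het) {
      theta_a[sel] <- theta_a[sel] - 2
      theta_b[sel] <- theta_b[sel] - 2
    }
    if (early_het_in_a && early_a) theta_a[sel] <- base[sel] + 1.5
  }
  if (is.null(diff_blocks)) {
    arms <- genome$regions[genome$regions$class == "arm", , drop = FALSE]
    arms <- arms[order(arms$end - arms$start, decreasing = TRUE), ]
    mk <- function(r, dir) {
      c0 <- round((r$start + r$end) / 2 / bin) * bin
      data.frame(chrom = r$chrom, start = c0 - 25000, end = c0 + 25000,
                 direction = dir, stringsAsFactors = FALSE)
    }
    diff_blocks <- rbind(mk(arms[1, ], "A-earlier"),
                         mk(arms[2, ], "B-earlier"))
  }
  for (j in seq_len(nrow(diff_blocks))) {
    b <- diff_blocks[j, ]
    sel <- bins$chrom == b$chrom & mid >= b$start & mid < b$end
    s <- if (b$direction == "A-earlier") 1 else -1
    theta_a[sel] <- s * block_delta / 2
    theta_b[sel] <- -s * block_delta / 2
  }
  theta_a <- pmin(pmax(theta_a, -3), 3)
  theta_b <- pmin(pmax(theta_b, -3), 3)
  structure(list(bins = bins, theta_a = theta_a, theta_b = theta_b,
                 blocks = diff_blocks),
            class = "timing_truth")
}

#' Simulate binned Repli-seq fraction counts from a timing truth
#'
#' Per bin and replicate, the per-fraction counts are Poisson with mean
#' `depth * libfac * p_f`, where the early half probability
#' `p = logistic(theta*)` is split evenly between E and EM (and `1 - p`
#' between LM and L) — conditional on the bin total this is the stated
#' multinomial split. Per-(sample, fraction) library-size factors are
#' log-normal (sdlog 0.2) to exercise depth normalization.
#'
#' @param genome A [genome_model()].
#' @param truth A `timing_truth` from [simulate_timing_truth()].
#' @param cell_type `"A"` or `"B"` — which truth column generates counts.
#' @param depth_per_sample Expected reads per bin per replicate (> 0).
#' @param n_replicates Replicates (default 2, so 4 fractions x 2 = 8
#'   samples).
#' @param within_half_split Fraction of the early half assigned to E
#'   (default 0.5), and of the late half to LM.
#' @param libsize_sdlog sdlog of the log-normal library factors
#'   (default 0.2).
#' @param seed Random seed.
#' @return A [binned_fraction_counts()] object.
#' @export
simulate_repliseq <- function(genome, truth, cell_type = c("A", "B"),
                              depth_per_sample = 50, n_replicates = 2,
                              within_half_split = 0.5,
                              libsize_sdlog = 0.2, seed = 1) {
  cell_type <- match.arg(cell_type)
  if (depth_per_sample <= 0) stop("depth must be positive")
  if (!identical(dim(truth$bins), dim(make_bins(genome, 1000))) ||
      nrow(truth$bins) == 0)
    stop("truth bins do not match the genome")
  set.seed(seed + ifelse(cell_type == "A", 0L, 10000L))
  theta <- if (cell_type == "A") truth$theta_a else truth$theta_b
  p <- stats::plogis(theta)
  probs <- cbind(E = p * within_half_split,
                 EM = p * (1 - within_half_split),
                 LM = (1 - p) * within_half_split,
                 L = (1 - p) * (1 - within_half_split))
  n <- nrow(truth$bins)
  counts <- array(0L, dim = c(n, 4, n_replicates),
                  dimnames = list(NULL, FRACTIONS,
                                  paste0("rep", seq_len(n_replicates))))
  libfac <- matrix(stats::rlnorm(4 * n_replicates, 0, libsize_sdlog),
                   n_replicates, 4)
  for (s in seq_len(n_replicates)) for (f in 1:4)
    counts[, f, s] <- stats::rpois(n, depth_per_sample * libfac[s, f] *
                                     probs[, f])
  binned_fraction_counts(truth$bins, counts, cell_type = cell_type)
}

#' Simulate a chromatin truth: nucleosome map and mark enrichments
#'
#' Lays phased nucleosomes along every chromosome (spacing ~185 bp) and
#' builds true per-20bp-bin enrichment fields lambda for three marks with
#' distinct spatial patterns: a promoter-peaked mark enriched at the +1/+2
#' nucleosomes of expressed genes (H3K4me3-like), a gene-body-broad mark
#' (H3K27me3-like, enriched along configured gene bodies), and a
#' domain-broad mark filling pericentromeric/chrY heterochromatin
#' (H3K9me3-like). Blocks can also be planted directly.
#'
#' @param genome A [genome_model()].
#' @param genes Optional gene table (`chrom`, `tss`, `strand`, `start`,
#'   `end`) with a logical `expressed` column; used for the
#'   promoter/body patterns.
#' @param enrichment_blocks Optional data.frame (`chrom`, `start`, `end`,
#'   `mark`, `fold`) of rectangular enrichment blocks planted on top.
#' @param spacing Nucleosome spacing in bp (default 185).
#' @param phasing_sd Positional jitter sd in bp (default 20).
#' @param dispersion True NB dispersion of IP counts (default 0.1).
#' @param marks Mark names (default H3K4me3, H3K27me3, H3K9me3).
#' @param fold Enrichment fold of each mark's pattern over baseline 1
#'   (default 4).
#' @param seed Random seed.
#' @return A `chromatin_truth` list: `centers` (data.frame chrom/pos),
#'   `phasing_sd`, `dispersion`, `bins` (20 bp), `lambda` (named list of
#'   per-bin enrichment vectors, baseline 1).
#' @export
simulate_chromatin_truth <- function(genome, genes = NULL,
                                     enrichment_blocks = NULL,
                                     spacing = 185, phasing_sd = 20,
                                     dispersion = 0.1,
                                     marks = c("H3K4me3", "H3K27me3",
                                               "H3K9me3"),
                                     fold = 4, seed = 1) {
  set.seed(seed)
  centers <- NULL
  for (ch in names(genome$chrom_sizes)) {
    pos <- seq(spacing / 2, genome$chrom_sizes[[ch]] - spacing / 2,
               by = spacing)
    centers <- rbind(centers, data.frame(chrom = ch, pos = round(pos),
                                         stringsAsFactors = FALSE))
  }
  if (nrow(centers) == 0) stop("empty nucleosome map")
  bins <- make_bins(genome, 20)
  mid <- (bins$start + bins$end) / 2
  lambda <- stats::setNames(
    lapply(marks, function(m) rep(1, nrow(bins))), marks)
  if (!is.null(genes)) {
    expressed <- if ("expressed" %in% names(genes)) genes$expressed
      else rep(TRUE, nrow(genes))
    for (k in which(expressed)) {
      g <- genes[k, ]
      sel_chrom <- bins$chrom == g$chrom
      dstream <- if (g$strand == "-") g$tss - mid else mid - g$tss
      # +1/+2 nucleosome zone of expressed genes
      if (length(marks) >= 1) {
        sel <- sel_chrom & dstream >= 50 & dstream < 400
        lambda[[1]][sel] <- fold
      }
      # broad body enrichment
      if (length(marks) >= 2 && all(c("start", "end") %in% names(g))) {
        sel <- sel_chrom & mid >= g$start & mid < g$end
        lambda[[2]][sel] <- pmax(lambda[[2]][sel], fold / 2)
      }
    }
  }
  if (length(marks) >= 3) {
    for (j in seq_len(nrow(genome$regions))) {
      r <- genome$regions[j, ]
      if (r$class == "pericentromeric" || r$chrom == "chrY") {
        sel <- bins$chrom == r$chrom & mid >= r$start & mid < r$end
        lambda[[3]][sel] <- fold
      }
    }
  }
  if (!is.null(enrichment_blocks)) {
    for (j in seq_len(nrow(enrichment_blocks))) {
      b <- enrichment_blocks[j, ]
      sel <- bins$chrom == b$chrom & mid >= b$start & mid < b$end
      lambda[[b$mark]][sel] <- b$fold
    }
  }
  structure(list(centers = centers, phasing_sd = phasing_sd,
                 dispersion = dispersion, bins = bins, lambda = lambda),
            class = "chromatin_truth")
}

r_truncnorm <- function(n, mean, sd, lower, upper) {
  u <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(u, mean, sd)
}

place_fragments <- function(centers_i, truth, len_mean, len_sd, len_range,
                            condition, sample, mapq_fail_frac) {
  n <- length(centers_i)
  ctr <- truth$centers$pos[centers_i] +
    round(stats::rnorm(n, 0, truth$phasing_sd))
  len <- round(r_truncnorm(n, len_mean, len_sd, len_range[1], len_range[2]))
  start <- ctr - floor(len / 2)
  fail <- stats::runif(n) < mapq_fail_frac
  mapq <- ifelse(fail, sample.int(20, n, replace = TRUE) - 1L,
                 19L + sample.int(41, n, replace = TRUE))
  data.frame(chrom = truth$centers$chrom[centers_i], start = start,
             end = start + len, mapq = mapq, sample = sample,
             condition = condition, stringsAsFactors = FALSE)
}

#' Simulate ChIC-ChIP fragment sets (IP plus H3 input)
#'
#' Input (H3) fragments are placed around the true nucleosome centers with
#' phasing jitter and mononucleosomal lengths (truncated normal, mean 150,
#' sd 15, bounds 100-220 bp). For each mark, per-nucleosome IP fragment
#' counts are negative-binomial with mean proportional to the mark's true
#' enrichment lambda at the nucleosome and the planted dispersion, so the
#' per-bin IP/input count ratio recovers lambda in expectation. A
#' configurable fraction of fragments gets MAPQ < 20 to exercise
#' filtering.
#'
#' @param genome A [genome_model()] (bounds for placed fragments).
#' @param truth A `chromatin_truth` from [simulate_chromatin_truth()].
#' @param depth_per_nucleosome Expected input fragments per nucleosome per
#'   replicate (default 10).
#' @param n_replicates Replicates per condition (default 2).
#' @param marks Marks to emit (default: all marks in the truth).
#' @param mapq_fail_frac Fraction of fragments assigned MAPQ < 20
#'   (default 0.05).
#' @param len_mean,len_sd,len_range Fragment-length model (150, 15,
#'   100-220 bp).
#' @param seed Random seed.
#' @return data.frame of fragments (`chrom`, `start`, `end`, `mapq`,
#'   `sample`, `condition`) with condition "H3-input" or a mark name.
#' @export
simulate_chic <- function(genome, truth, depth_per_nucleosome = 10,
                          n_replicates = 2, marks = names(truth$lambda),
                          mapq_fail_frac = 0.05, len_mean = 150,
                          len_sd = 15, len_range = c(100, 220), seed = 1) {
  if (nrow(truth$centers) == 0) stop("empty nucleosome map")
  set.seed(seed)
  nn <- nrow(truth$centers)
  # lambda at each nucleosome center, per mark
  bin_idx <- local({
    chrom_levels <- unique(truth$bins$chrom)
    off <- cumsum(c(0, table(factor(truth$bins$chrom,
                                    levels = chrom_levels))))
    names(off) <- c(chrom_levels, "END")
    off[truth$centers$chrom] + floor(truth$centers$pos / 20) + 1
  })
  out <- vector("list", n_replicates * (1 + length(marks)))
  oi <- 1
  for (s in seq_len(n_replicates)) {
    sample_id <- paste0("rep", s)
    k_in <- stats::rpois(nn, depth_per_nucleosome)
    idx <- rep(seq_len(nn), k_in)
    out[[oi]] <- place_fragments(idx, truth, len_mean, len_sd, len_range,
                                 "H3-input", sample_id, mapq_fail_frac)
    oi <- oi + 1
    for (m in marks) {
      lam <- truth$lambda[[m]][bin_idx]
      k_ip <- stats::rnbinom(nn, mu = depth_per_nucleosome * lam,
                             size = 1 / truth$dispersion)
      idx <- rep(seq_len(nn), k_ip)
      out[[oi]] <- place_fragments(idx, truth, len_mean, len_sd, len_range,
                                   m, sample_id, mapq_fail_frac)
      oi <- oi + 1
    }
  }
  frags <- do.call(rbind, out)
  rownames(frags) <- NULL
  frags
}

#' Simulate a gene annotation on a synthetic genome
#'
#' Non-overlapping genes of 2-6 kb are placed uniformly per chromosome
#' with random strand, a TSS at the strand-appropriate end, and a biotype.
#'
#' @param genome A [genome_model()].
#' @param genes_per_mb Gene density (default 60, fly-like).
#' @param seed Random seed.
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`, `biotype`.
#' @export
simulate_genes <- function(genome, genes_per_mb = 60, seed = 1) {
  set.seed(seed)
  out <- NULL
  gid <- 0
  for (ch in names(genome$chrom_sizes)) {
    size <- genome$chrom_sizes[[ch]]
    n <- max(1, round(size / 1e6 * genes_per_mb))
    slot <- floor(size / n)
    if (slot < 3000) { n <- max(1, floor(size / 3000)); slot <- floor(size / n) }
    len <- pmin(round(stats::runif(n, 2000, 6000)), slot - 500)
    start <- (seq_len(n) - 1) * slot +
      round(stats::runif(n, 0, pmax(slot - len - 1, 1)))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    out <- rbind(out, data.frame(
      gene_id = sprintf("g%05d", gid + seq_len(n)), chrom = ch,
      start = start, end = start + len, strand = strand,
      tss = ifelse(strand == "+", start, start + len),
      biotype = sample(c("protein_coding", "ncRNA"), n, replace = TRUE,
                       prob = c(0.85, 0.15)),
      stringsAsFactors = FALSE))
    gid <- gid + n
  }
  rownames(out) <- NULL
  out
}

#' Simulate an expression truth with planted differential genes
#'
#' True per-gene mean expression for two clusters: log-normal baseline
#' means, a configurable fraction of genes off (zero mean) per cluster,
#' planted differentially expressed genes with a given true log2 fold
#' change, X-linked genes at half the autosomal mean in cluster A
#' (germline-like, no dosage compensation), and per-cluster cell-cycle
#' phase mixtures.
#'
#' @param genes Gene table from [simulate_genes()] (needs `gene_id`,
#'   `chrom`).
#' @param n_de Planted DE genes per direction (default 30).
#' @param de_l2fc True |log2 fold change| of planted genes (default 2).
#' @param off_frac Fraction of genes off in each cluster (default 0.3,
#'   independent draws, so some genes are cluster-specifically off).
#' @param x_halved_in_a Halve X-linked means in cluster A (default TRUE).
#' @param phase_fracs 2x3 matrix of G1/S/G2M fractions per cluster
#'   (defaults differ between clusters to exercise reweighting).
#' @param seed Random seed.
#' @return An `expression_truth` list: `gene_id`, `chrom`, `mean_a`,
#'   `mean_b`, `de` (data.frame gene_id/true_l2fc/direction),
#'   `phase_fracs`.
#' @export
simulate_expression_truth <- function(genes, n_de = 30, de_l2fc = 2,
                                      off_frac = 0.3, x_halved_in_a = TRUE,
                                      phase_fracs = rbind(
                                        A = c(G1 = 0.25, S = 0.5, G2M = 0.25),
                                        B = c(G1 = 0.4, S = 0.3, G2M = 0.3)),
                                      seed = 1) {
  set.seed(seed)
  n <- nrow(genes)
  base <- stats::rlnorm(n, meanlog = 3, sdlog = 1.2)
  mean_a <- base * stats::rlnorm(n, 0, 0.1)
  mean_b <- base * stats::rlnorm(n, 0, 0.1)
  off_a <- stats::runif(n) < off_frac
  off_b <- stats::runif(n) < off_frac
  mean_a[off_a] <- 0
  mean_b[off_b] <- 0
  on_both <- which(!off_a & !off_b)
  de_idx <- sample(on_both, min(2 * n_de, length(on_both)))
  up_a <- de_idx[seq_len(length(de_idx) / 2)]
  up_b <- setdiff(de_idx, up_a)
  mean_a[up_a] <- mean_a[up_a] * 2^de_l2fc
  mean_b[up_b] <- mean_b[up_b] * 2^de_l2fc
  if (x_halved_in_a) {
    xsel <- genes$chrom == "chrX" & !seq_len(n) %in% de_idx
    mean_a[xsel] <- mean_a[xsel] / 2
  }
  de <- data.frame(
    gene_id = genes$gene_id[c(up_a, up_b)],
    true_l2fc = c(rep(de_l2fc, length(up_a)), rep(-de_l2fc, length(up_b))),
    direction = c(rep("A", length(up_a)), rep("B", length(up_b))),
    stringsAsFactors = FALSE)
  structure(list(gene_id = genes$gene_id, chrom = genes$chrom,
                 mean_a = mean_a, mean_b = mean_b, de = de,
                 phase_fracs = phase_fracs),
            class = "expression_truth")
}

#' Simulate a cell x gene count matrix with cluster and phase labels
#'
#' Per cell, a Poisson library size around `depth_per_cell` is distributed
#' multinomially over genes in proportion to the cluster's true means;
#' each cell's cell-cycle phase is drawn from its cluster's phase mixture
#' (phase does not modulate the means — it exists to exercise
#' compositional reweighting).
#'
#' @param truth An `expression_truth`.
#' @param n_cells_per_cluster Cells per cluster (default 500).
#' @param depth_per_cell Expected total counts per cell (> 0,
#'   default 5000).
#' @param seed Random seed.
#' @return List: `counts` (cell x gene integer matrix), `labels`
#'   (data.frame `cell_id`, `cluster`, `phase`).
#' @export
simulate_pseudobulk <- function(truth, n_cells_per_cluster = 500,
                                depth_per_cell = 5000, seed = 1) {
  if (depth_per_cell <= 0) stop("depth must be positive")
  set.seed(seed)
  clusters <- rownames(truth$phase_fracs)
  if (length(clusters) < 2) stop("need at least 2 clusters")
  n_genes <- length(truth$gene_id)
  n_cells <- n_cells_per_cluster * length(clusters)
  counts <- matrix(0L, n_cells, n_genes,
                   dimnames = list(NULL, truth$gene_id))
  labels <- data.frame(cell_id = sprintf("cell%05d", seq_len(n_cells)),
                       cluster = rep(clusters, each = n_cells_per_cluster),
                       phase = NA_character_, stringsAsFactors = FALSE)
  rownames(counts) <- labels$cell_id
  for (ci in seq_along(clusters)) {
    mu <- if (clusters[ci] == clusters[1]) truth$mean_a else truth$mean_b
    pr <- mu / sum(mu)
    rows <- (ci - 1) * n_cells_per_cluster + seq_len(n_cells_per_cluster)
    depth <- stats::rpois(n_cells_per_cluster, depth_per_cell)
    counts[rows, ] <- t(vapply(
      depth, function(d) stats::rmultinom(1, d, pr)[, 1],
      integer(n_genes)))
    labels$phase[rows] <- sample(colnames(truth$phase_fracs),
                                 n_cells_per_cluster, replace = TRUE,
                                 prob = truth$phase_fracs[ci, ])
  }
  list(counts = counts, labels = labels)
}
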