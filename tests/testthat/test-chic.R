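test_that("filter_fragments applies MAPQ and length rules with a report", {
  frags <- data.frame(chrom = "chrT",
                      start = c(0, 0, 0, 0),
                      end = c(150, 150, 300, 150),
                      mapq = c(19, 30, 30, 20),
                      sample = "rep1", condition = "H3K4me3")
  out <- filter_fragments(frags)
  rep <- attr(out, "filter_report")
  expect_equal(nrow(out), 2)            # mapq 19 out; length 300 out
  expect_equal(unname(rep["fail_mapq"]), 1)
  expect_equal(unname(rep["fail_length"]), 1)
  expect_equal(unname(rep["n_retained"] + rep["fail_mapq"] +
                        rep["fail_length"]), nrow(frags))
  empty <- filter_fragments(frags[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(unname(attr(empty, "filter_report")["n_input"]), 0)
})

test_that("bin_midpoints_20 uses half-open 20 bp bins and conserves counts", {
  gm <- tiny_genome(1e5)
  frags <- data.frame(chrom = "chrT",
                      start = c(9, 10, 100), end = c(29, 30, 140),
                      mapq = 30, sample = "rep1", condition = "H3")
  b <- bin_midpoints_20(frags, gm)
  expect_equal(unname(b$counts[1, 1]), 1)    # midpoint 19 -> [0, 20)
  expect_equal(unname(b$counts[2, 1]), 1)    # midpoint 20 -> [20, 40)
  expect_equal(unname(b$counts[7, 1]), 1)    # midpoint 120 -> [120, 140)
  expect_equal(sum(b$counts), nrow(frags))
})

test_that("nb_regression hits the identity and Poisson-limit closed forms", {
  set.seed(3)
  x <- matrix(rpois(400, 50), 100, 4)
  fit <- nb_regression(x, x)
  expect_equal(fit$l2fc, rep(0, 100), tolerance = 1e-8)

  # alpha -> 0: l2fc is log2 of the mean ratio exactly
  ip <- matrix(rpois(400, 80), 100, 4)
  inp <- matrix(rpois(400, 20), 100, 4)
  fit0 <- nb_regression(ip, inp, dispersion = 1e-8)
  expect_equal(fit0$l2fc, log2(rowMeans(ip) / rowMeans(inp)),
               tolerance = 1e-4)
  expect_equal(fit0$intercept, log(rowMeans(inp)), tolerance = 1e-4)

  # all-zero bins flagged with missing coefficients
  ip[1, ] <- 0; inp[1, ] <- 0
  fitz <- nb_regression(ip, inp, dispersion = 1e-8)
  expect_true(fitz$flagged[1])
  expect_true(is.na(fitz$l2fc[1]))
})

test_that("nb_regression recovers a planted l2fc = 2 at alpha = 0.1", {
  set.seed(11)
  n <- 500
  inp <- matrix(rnbinom(n * 4, mu = 100, size = 10), n, 4)
  ip <- matrix(rnbinom(n * 4, mu = 400, size = 10), n, 4)
  fit <- nb_regression(ip, inp)
  expect_equal(stats::median(fit$l2fc), 2, tolerance = 0.1)
  expect_equal(attr(fit, "dispersion"), 0.1, tolerance = 0.05)
})

test_that("gaussian_smooth reproduces the kernel, conserves mass, linear", {
  v <- rep(0, 201); v[101] <- 1
  sv <- gaussian_smooth(v, sigma_bp = 40, bin_bp = 20)
  # impulse response is the sigma = 2-bin truncated normalized kernel
  kern <- dnorm(-8:8, 0, 2); kern <- kern / sum(kern)
  expect_equal(sv[93:109], kern, tolerance = 1e-12)
  expect_lt(abs(sum(sv) - 1), 1e-9)

  # mass conservation with boundary reflection on arbitrary input
  set.seed(2)
  w <- rexp(500)
  expect_lt(abs(sum(gaussian_smooth(w)) - sum(w)), 1e-9)

  # linearity: two impulses 80 bp (4 bins) apart superpose
  v2 <- rep(0, 201); v2[105] <- 1
  both <- v + v2
  expect_equal(gaussian_smooth(both), gaussian_smooth(v) +
                 gaussian_smooth(v2), tolerance = 1e-12)
  # commutes with scalar multiplication
  expect_equal(gaussian_smooth(3.7 * w), 3.7 * gaussian_smooth(w),
               tolerance = 1e-9)

  # no bleed across chromosome boundaries
  chrom <- rep(c("c1", "c2"), each = 100)
  u <- c(rep(0, 99), 1, rep(0, 100))
  su <- gaussian_smooth(u, chrom = chrom)
  expect_equal(sum(su[101:200]), 0)
})

test_that("l2fe matches the identity, scale and planted-block examples", {
  base <- rep(10, 1000)
  expect_equal(l2fe(base, base), rep(0, 1000), tolerance = 1e-9)
  # a global 2x is a depth difference under equal-mass normalization...
  expect_equal(l2fe(2 * base, base), rep(0, 1000), tolerance = 1e-9)
  # ...and a true +1 enrichment without it
  expect_equal(l2fe(2 * base, base, normalize = FALSE), rep(1, 1000),
               tolerance = 1e-6)

  # planted 4x block on a long baseline: block mean within 0.2 of 2
  ip <- base; ip[401:440] <- 40
  out <- l2fe(ip, base)
  expect_equal(mean(out[401:440]), 2, tolerance = 0.2)
})

test_that("tss_metaprofile is strand-aware and category-resolved", {
  gm <- tiny_genome(1e5)
  bins <- replichrom:::make_bins(gm, 20)
  values <- seq_len(nrow(bins))   # strictly increasing track
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chrT",
                      tss = c(40000, 40000), strand = c("+", "-"))
  prof <- tss_metaprofile(values, bins, genes, c("plus", "minus"))
  plus <- prof[prof$category == "plus", ]
  minus <- prof[prof$category == "minus", ]
  # one plus-strand gene: profile equals the track slice around the TSS
  expect_equal(plus$mean,
               values[(40000 - 1000) / 20 + 1 + 0:100])
  # minus-strand gene: the same slice reversed
  expect_equal(minus$mean, rev(plus$mean))
  expect_true(all(prof$position == rep(seq(-1000, 1000, 20), 2)))

  # a symmetric signal around a TSS at a bin midpoint gives a symmetric
  # profile
  gsym <- data.frame(gene_id = "gs", chrom = "chrT", tss = 40010,
                     strand = "+")
  sym <- dnorm(abs((bins$start + 10) - 40010), 0, 200)
  prof2 <- tss_metaprofile(sym, bins, gsym, "on")
  expect_equal(prof2$mean, rev(prof2$mean), tolerance = 1e-12)
})

test_that("gene_body_enrichment is the length-weighted body mean", {
  gm <- tiny_genome(1e5)
  bins <- replichrom:::make_bins(gm, 20)
  const <- rep(3.3, nrow(bins))
  genes <- data.frame(gene_id = c("a", "b"), chrom = "chrT",
                      start = c(1000, 2000), end = c(2000, 2040))
  out <- gene_body_enrichment(const, bins, genes)
  expect_equal(out$mean_l2fe, c(3.3, 3.3))

  # gene covering two bins with values 1 and 3 at equal widths
  v <- const; v[bins$start == 2000] <- 1; v[bins$start == 2020] <- 3
  out2 <- gene_body_enrichment(v, bins, genes[2, ])
  expect_equal(out2$mean_l2fe, 2)
  expect_error(gene_body_enrichment(const, bins,
                                    data.frame(gene_id = "z",
                                               chrom = "chrT",
                                               start = 10, end = 10)),
               "zero-length")
})

test_that("cell-type-specific enrichment needs opposite signs beyond 0.2", {
  gm <- tiny_genome(1e5)
  bins <- replichrom:::make_bins(gm, 20)
  n <- nrow(bins)
  regions <- data.frame(region_id = "dom", chrom = "chrT", start = 0,
                        end = 1e5, class = "arm")
  a <- rep(0, n); b <- rep(0, n)
  a[1:100] <- 0.3; b[1:100] <- -0.3          # A-specific
  a[101:200] <- 0.3; b[101:200] <- 0.1       # same sign: unlabeled
  a[201:300] <- -0.25; b[201:300] <- 0.4     # B-specific
  out <- celltype_enrichment_classification(a, b, bins, regions)
  expect_equal(out$labels[1], "A-specific")
  expect_true(is.na(out$labels[150]))
  expect_equal(out$labels[250], "B-specific")
  expect_equal(out$percent$pct_a, 100 * 100 * 20 / 1e5)
  expect_equal(out$percent$pct_b, 100 * 100 * 20 / 1e5)
  zero <- celltype_enrichment_classification(rep(0, n), rep(0, n), bins,
                                             regions)
  expect_equal(zero$percent$pct_a, 0)
})

test_that("three planted spatial mark patterns are recovered in L2FE", {
  gm <- simulate_genome(sizes = c(chr2L = 2e5, chr2R = 2e5, chr3L = 1e5,
                                  chr3R = 1e5, chr4 = 1e5, chrX = 1e5,
                                  chrY = 1e5))
  genes <- simulate_genes(gm, genes_per_mb = 30, seed = 41)
  genes$expressed <- rep(c(TRUE, FALSE), length.out = nrow(genes))
  truth <- simulate_chromatin_truth(gm, genes, seed = 42)
  frags <- simulate_chic(gm, truth, depth_per_nucleosome = 8,
                         n_replicates = 2, seed = 43)
  filt <- filter_fragments(frags)
  binned <- bin_midpoints_20(filt, gm)
  inp <- binned$counts[, binned$groups$condition == "H3-input",
                       drop = FALSE]
  tracks <- lapply(names(truth$lambda), function(m) {
    ip <- binned$counts[, binned$groups$condition == m, drop = FALSE]
    l2fe(gaussian_smooth(rowMeans(ip), binned$bins$chrom),
         gaussian_smooth(rowMeans(inp), binned$bins$chrom))
  })
  names(tracks) <- names(truth$lambda)

  on_genes <- genes[genes$expressed, ]
  off_genes <- genes[!genes$expressed, ]
  # promoter-peaked mark: +1 nucleosome peak downstream of expressed TSSs
  prof_on <- tss_metaprofile(tracks$H3K4me3, binned$bins, on_genes,
                             rep("on", nrow(on_genes)))
  prof_off <- tss_metaprofile(tracks$H3K4me3, binned$bins, off_genes,
                              rep("off", nrow(off_genes)))
  peak_pos <- prof_on$position[which.max(prof_on$mean)]
  expect_gt(peak_pos, 0)
  expect_lt(peak_pos, 500)
  expect_gt(max(prof_on$mean), max(prof_off$mean) + 0.5)

  # body-broad mark: expressed gene bodies beat silent ones
  body_on <- gene_body_enrichment(tracks$H3K27me3, binned$bins, on_genes)
  body_off <- gene_body_enrichment(tracks$H3K27me3, binned$bins, off_genes)
  expect_gt(mean(body_on$mean_l2fe), mean(body_off$mean_l2fe) + 0.3)

  # domain-broad mark: pericentromeric/chrY mean beats the arms
  peri <- gm$regions$class == "pericentromeric"
  mid <- (binned$bins$start + binned$bins$end) / 2
  in_peri <- rep(FALSE, nrow(binned$bins))
  for (j in which(peri))
    in_peri <- in_peri | (binned$bins$chrom == gm$regions$chrom[j] &
                            mid >= gm$regions$start[j] &
                            mid < gm$regions$end[j])
  arm <- binned$bins$chrom %in% c("chr2L", "chr2R") & !in_peri
  expect_gt(mean(tracks$H3K9me3[in_peri]), mean(tracks$H3K9me3[arm]) + 1)
})
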