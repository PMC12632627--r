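#' Default pipeline configuration
#'
#' All tunable thresholds of the pipeline in one nested list, with the
#' package's stated defaults: the timing prior and quadrature, the nested
#' Bayes-factor region-calling thresholds (minimum width 20 kb), the ChIC
#' filters and kernel, the expression on/off and DEG selection rules, and
#' the synthetic-data settings. Override entries by name in
#' [run_pipeline()].
#'
#' @return Nested named list of configuration values.
#' @export
rc_config <- function() {
  list(
    timing = list(bin = 1000, window = 3L, tau = 2, nodes = 2001L,
                  loess_span_bp = 1e5),
    diffrt = list(k_seed = 10, k_extend = 3, gap = 3000,
                  min_width = 20000),
    zscore = list(label_breaks = c(0, 0.5)),
    chic = list(mapq_min = 20, len_range = c(120, 200), bin = 20,
                sigma_bp = 40, l2fe_floor = 1e-6, specific_thr = 0.2),
    expr = list(on_thr = 5, pseudocount = 1, tau = 1, fc_thr = 1.5,
                s_thr = 1e-4),
    simulate = list(depth_per_sample = 50, n_replicates = 2,
                    depth_per_nucleosome = 10, n_cells_per_cluster = 500,
                    depth_per_cell = 5000, mapq_fail_frac = 0.05)
  )
}

modify_list <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- modify_list(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full synthetic pipeline end to end
#'
#' Simulates a genome with planted timing, chromatin and expression truth,
#' then runs every analysis stage: timing scores for both cell types,
#' Bayes-factor differential testing and region calling, RT Z-scores and
#' 12-domain summaries, ChIC enrichment tracks (NB regression, Gaussian
#' smoothing, L2FE) for each mark in both cell types, pseudobulk
#' expression with cell-cycle reweighting and shrunken fold changes, and
#' the three-layer integration (gene timing quadrants, enrichment at
#' differential regions, cross-cell-type domain correlation). Optionally
#' writes bedGraph/BED/TSV outputs.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param config Optional overrides merged over [rc_config()].
#' @param genome Optional pre-built [genome_model()]; simulated by default.
#' @param out_dir Optional output directory for track/table files.
#' @param marks Marks simulated and profiled for both cell types
#'   (default H3K4me3 only, for speed; the generator supports three).
#' @return Named list with the truth objects and every stage's result.
#' @export
run_pipeline <- function(seed = 1, config = list(), genome = NULL,
                         out_dir = NULL, marks = "H3K4me3") {
  cfg <- modify_list(rc_config(), config)
  if (is.null(genome)) genome <- simulate_genome()
  genes <- simulate_genes(genome, seed = seed + 1)

  ## --- timing layer
  truth_rt <- simulate_timing_truth(genome, seed = seed + 2)
  counts_a <- simulate_repliseq(genome, truth_rt, "A",
                                cfg$simulate$depth_per_sample,
                                cfg$simulate$n_replicates, seed = seed + 3)
  counts_b <- simulate_repliseq(genome, truth_rt, "B",
                                cfg$simulate$depth_per_sample,
                                cfg$simulate$n_replicates, seed = seed + 4)
  track_a <- timing_score(counts_a, cfg$timing$window, cfg$timing$tau,
                          cfg$timing$nodes)
  track_b <- timing_score(counts_b, cfg$timing$window, cfg$timing$tau,
                          cfg$timing$nodes)
  test <- bayes_factor(counts_a, counts_b, cfg$timing$window,
                       cfg$timing$tau, cfg$timing$nodes)
  regions_called <- call_differential_regions(
    test, cfg$diffrt$k_seed, cfg$diffrt$k_extend, cfg$diffrt$gap,
    cfg$diffrt$min_width)
  z_a <- rt_zscore(track_a)
  z_b <- rt_zscore(track_b)
  summary_a <- region_summary(z_a, genome$regions,
                              cfg$zscore$label_breaks)
  summary_b <- region_summary(z_b, genome$regions,
                              cfg$zscore$label_breaks)
  size_summary <- earlier_size_summary(regions_called, genome$regions)

  ## --- expression layer (needed before chic: categories feed profiles)
  truth_expr <- simulate_expression_truth(genes, seed = seed + 5)
  pb <- simulate_pseudobulk(truth_expr, cfg$simulate$n_cells_per_cluster,
                            cfg$simulate$depth_per_cell, seed = seed + 6)
  weights <- cellcycle_weights(pb$labels$phase, pb$labels$cluster)
  cpm <- pseudobulk_cpm(pb$counts, pb$labels$cluster, weights,
                        cfg$expr$pseudocount)
  onoff <- classify_on_off(cpm, cfg$expr$on_thr)
  tot_a <- colSums(pb$counts[pb$labels$cluster == "A", , drop = FALSE])
  tot_b <- colSums(pb$counts[pb$labels$cluster == "B", , drop = FALSE])
  de <- shrunken_lfc(tot_a, tot_b, tau = cfg$expr$tau,
                     fc_thr = cfg$expr$fc_thr, s_thr = cfg$expr$s_thr)
  de$gene_id <- truth_expr$gene_id
  xa <- xa_ratio(cpm, truth_expr$chrom, onoff$status)

  ## --- chromatin layer: marks enriched where each cell type expresses,
  ##     plus co-enrichment at that cell type's earlier-replicating blocks
  chic <- list()
  for (ct in c("A", "B")) {
    expressed <- onoff$status[, ct] == "on"
    blocks <- truth_rt$blocks
    blocks <- blocks[blocks$direction == paste0(ct, "-earlier"), ,
                     drop = FALSE]
    eb <- if (nrow(blocks)) data.frame(chrom = blocks$chrom,
                                       start = blocks$start,
                                       end = blocks$end,
                                       mark = marks[1], fold = 4)
      else NULL
    truth_ch <- simulate_chromatin_truth(
      genome, cbind(genes, expressed = expressed),
      enrichment_blocks = eb, marks = marks,
      seed = seed + 7 + (ct == "B"))
    frags <- simulate_chic(genome, truth_ch,
                           cfg$simulate$depth_per_nucleosome,
                           n_replicates = 2, marks = marks,
                           mapq_fail_frac = cfg$simulate$mapq_fail_frac,
                           seed = seed + 9 + (ct == "B"))
    filt <- filter_fragments(frags, cfg$chic$mapq_min, cfg$chic$len_range)
    binned <- bin_midpoints_20(filt, genome, cfg$chic$bin)
    is_input <- binned$groups$condition == "H3-input"
    input_counts <- binned$counts[, is_input, drop = FALSE]
    l2fe_tracks <- list()
    for (m in marks) {
      ip_counts <- binned$counts[, binned$groups$condition == m,
                                 drop = FALSE]
      fit <- nb_regression(ip_counts, input_counts)
      ip_d <- gaussian_smooth(rowMeans(ip_counts), binned$bins$chrom,
                              cfg$chic$sigma_bp, cfg$chic$bin)
      in_d <- gaussian_smooth(rowMeans(input_counts), binned$bins$chrom,
                              cfg$chic$sigma_bp, cfg$chic$bin)
      l2fe_tracks[[m]] <- l2fe(ip_d, in_d, cfg$chic$l2fe_floor)
    }
    chic[[ct]] <- list(truth = truth_ch, bins = binned$bins,
                       l2fe = l2fe_tracks, fit = fit,
                       filter_report = attr(filt, "filter_report"))
  }
  specific <- celltype_enrichment_classification(
    chic$A$l2fe[[marks[1]]], chic$B$l2fe[[marks[1]]], chic$A$bins,
    genome$regions, cfg$chic$specific_thr)

  ## --- integration layer
  gene_rt <- assign_gene_rt(genes, track_a, track_b)
  enr_at_regions <- enrichment_at_regions(
    list(A = chic$A$l2fe, B = chic$B$l2fe), chic$A$bins, regions_called)
  corr <- region_profile_correlation(list(A = summary_a, B = summary_b))

  res <- list(genome = genome, genes = genes, config = cfg,
              truth = list(timing = truth_rt, expression = truth_expr),
              counts = list(A = counts_a, B = counts_b),
              timing = list(A = track_a, B = track_b),
              test = test, regions = regions_called,
              z = list(A = z_a, B = z_b),
              region_summary = list(A = summary_a, B = summary_b),
              size_summary = size_summary,
              expression = list(cpm = cpm, onoff = onoff, de = de,
                                xa = xa, weights = weights,
                                labels = pb$labels),
              chic = chic, specific = specific,
              integration = list(gene_rt = gene_rt,
                                 enrichment_at_regions = enr_at_regions,
                                 correlation = corr))
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (ct in c("A", "B")) {
    tr <- res$timing[[ct]]
    write_bedgraph(data.frame(tr[c("chrom", "start", "end")],
                              value = tr$theta),
                   file.path(out_dir, paste0("theta_", ct, ".bedgraph")))
    z <- res$z[[ct]]
    zz <- z[!is.na(z$z), ]
    write_bedgraph(data.frame(zz[c("chrom", "start", "end")],
                              value = zz$z),
                   file.path(out_dir, paste0("z_", ct, ".bedgraph")))
  }
  tt <- res$test
  write_bedgraph(data.frame(tt[c("chrom", "start", "end")],
                            value = tt$log_k / log(10)),
                 file.path(out_dir, "log10_bf.bedgraph"))
  rg <- res$regions
  if (nrow(rg)) {
    bed <- sprintf("%s\t%d\t%d\t%s\t%.4f", rg$chrom, as.integer(rg$start),
                   as.integer(rg$end), rg$direction, rg$mean_delta)
    writeLines(bed, file.path(out_dir, "differential_regions.bed"))
  }
  utils::write.table(res$size_summary,
                     file.path(out_dir, "earlier_size_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$expression$de,
                     file.path(out_dir, "de_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$integration$gene_rt,
                     file.path(out_dir, "gene_rt.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
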