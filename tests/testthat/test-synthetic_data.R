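# The planted-ground-truth generator: determinism, reachability, validators.

test_that("genome simulation is deterministic, spaced, and guards density", {
  cfg <- sim_config(seed = 7, n_genes = 40, chrom_length = 2e6)
  g1 <- simulate_genome(cfg)$genes
  g2 <- simulate_genome(cfg)$genes
  expect_identical(g1, g2)
  expect_false(identical(g1, simulate_genome(sim_config(seed = 8, n_genes = 40,
                                                        chrom_length = 2e6))$genes))
  primary <- vapply(seq_len(nrow(g1)), function(i)
    if (g1$strand[i] == "+") min(g1$tss[[i]]) else max(g1$tss[[i]]), 0L)
  expect_true(all(diff(sort(primary)) >= 5000))
  single <- simulate_genome(sim_config(n_genes = 1, n_sentinels = 1,
                                       frac_causal = 1))
  expect_equal(nrow(single$genes), 1)
  expect_error(simulate_genome(sim_config(n_genes = 5000, chrom_length = 1e6)),
               "infeasible")
})

test_that("planted contacts are derivable from the emitted landscape", {
  cfg <- sim_config(seed = 7, n_sentinels = 20, n_genes = 80, n_ocrs = 200,
                    chrom_length = 5e6, n_loops_background = 10)
  genome <- simulate_genome(cfg)
  land <- simulate_regulatory_landscape(cfg, genome)
  validate_ocrs(land$ocrs)
  prom <- promoter_windows(genome$genes,
                           stats::setNames(genome$chrom_length, genome$chrom))
  contacts <- promoter_interacting_ocrs(consensus_loops(land$loops), prom,
                                        land$ocrs)
  planted_distal <- land$planted[land$planted$mechanism == "distal_contact", ]
  expect_true(all(paste(planted_distal$ocr_id, planted_distal$gene_id) %in%
                    paste(contacts$ocr_id, contacts$gene_id)))
  # promoter-proxy OCRs overlap their gene's promoter window
  prox <- land$planted[land$planted$mechanism == "promoter_proxy", ]
  for (i in seq_len(nrow(prox))) {
    pw <- prom[prom$gene_id == prox$gene_id[i], ]
    expect_true(any(pw$start < prox$ocr_end[i] & prox$ocr_start[i] < pw$end))
  }
  # loops survive a BEDPE round-trip after canonicalization
  f <- withr::local_tempfile(fileext = ".bedpe")
  write_loops_bedpe(land$loops, f)
  expect_equal(read_loops_bedpe(f)[, names(land$loops)], land$loops,
               ignore_attr = TRUE)
})

test_that("GWAS simulation plants the causal variant at the locus maximum", {
  cfg <- sim_config(seed = 7, n_sentinels = 12, n_genes = 60, n_ocrs = 150,
                    chrom_length = 5e6, n_loops_background = 5, z_noise_sd = 0)
  genome <- simulate_genome(cfg)
  land <- simulate_regulatory_landscape(cfg, genome)
  gwas <- simulate_gwas(cfg, genome, land)
  validate_summary_stats(gwas$stats)
  cs <- build_credible_sets(gwas$stats, fine_map_config())
  for (i in seq_len(nrow(gwas$truth$causal))) {
    sid <- gwas$truth$causal$sentinel_id[i]
    sub <- cs[cs$sentinel_id == sid, ]
    expect_equal(sub$variant_id[which.max(sub$pp)],
                 gwas$truth$causal$variant_id[i])
  }
  # a zero-signal locus has uniform posteriors
  null_sid <- setdiff(unique(gwas$stats$sentinel_id),
                      gwas$truth$causal$sentinel_id)[1]
  sub <- cs[cs$sentinel_id == null_sid, ]
  expect_equal(sub$pp, rep(1 / nrow(sub), nrow(sub)), tolerance = 1e-12)
  # non-causal variants sit outside every OCR
  noncausal <- gwas$stats[!gwas$stats$variant_id %in%
                            gwas$truth$causal$variant_id, ]
  vi <- data.frame(chrom = noncausal$chrom, start = noncausal$pos,
                   end = noncausal$pos + 1L)
  hits <- intersect_intervals(vi, land$ocrs, check_sorted = FALSE)
  expect_equal(nrow(hits), 0)
})

test_that("truth-set design yields the configured precision/recall exactly", {
  cfg <- sim_config(seed = 7, n_sentinels = 40, n_genes = 120, n_ocrs = 300,
                    chrom_length = 8e6, n_loops_background = 5)
  genome <- simulate_genome(cfg)
  land <- simulate_regulatory_landscape(cfg, genome)
  gwas <- simulate_gwas(cfg, genome, land)
  ts <- simulate_truth_set(cfg, gwas$truth, genome$genes)
  pr <- precision_recall(gwas$truth$effectors, ts$gene_ids)
  expect_equal(pr$precision, cfg$truth_precision)
  expect_equal(pr$recall, cfg$truth_recall)
  # all effectors, no decoys: the perfect predictor is perfect
  cfg2 <- sim_config(seed = 7, n_sentinels = 40, n_genes = 120, n_ocrs = 300,
                     chrom_length = 8e6, n_loops_background = 5,
                     truth_precision = 1, truth_recall = 1)
  ts2 <- simulate_truth_set(cfg2, gwas$truth, genome$genes)
  pr2 <- precision_recall(gwas$truth$effectors, ts2$gene_ids)
  expect_equal(c(pr2$precision, pr2$recall), c(1, 1))
  # half-coverage truth: recall of the perfect predictor is 0.5
  cfg3 <- sim_config(seed = 7, n_sentinels = 40, truth_precision = 0.5,
                     truth_recall = 1)
  ts3 <- simulate_truth_set(cfg3, gwas$truth, genome$genes)
  expect_equal(precision_recall(gwas$truth$effectors, ts3$gene_ids)$precision,
               0.5)
  # infeasible integer design errors out
  cfg_bad <- sim_config(seed = 7, n_sentinels = 50, truth_precision = 0.25,
                        truth_recall = 0.5)  # 30 effectors: 7.5 overlap
  expect_error(simulate_truth_set(cfg_bad,
                                  list(effectors = sprintf("g%d", 1:30)),
                                  genome$genes), "infeasible")
})

test_that("the written fixture round-trips through every reader", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 7, n_sentinels = 8, n_genes = 60, n_ocrs = 120,
                    chrom_length = 5e6, n_loops_background = 5,
                    n_expr_genes = 30, truth_precision = 0.2,
                    truth_recall = 0.5)
  fx <- simulate_v2g_fixture(cfg, dir)
  genes <- read_gene_table(fx$paths$genes)
  expect_equal(genes$tss, fx$genome$genes$tss, ignore_attr = TRUE)
  ocrs <- read_ocr_bed(fx$paths$ocrs)
  expect_equal(ocrs[, c("peak_id", "start", "end")],
               fx$landscape$ocrs[, c("peak_id", "start", "end")],
               ignore_attr = TRUE)
  stats <- read_summary_stats(fx$paths$stats)
  expect_equal(stats$pos, fx$gwas$stats$pos)
  loops <- read_loops_bedpe(fx$paths$loops)
  expect_equal(nrow(loops), nrow(fx$landscape$loops))
  truth <- read_truth_set(fx$paths$truth)
  expect_setequal(truth$gene_ids, fx$truth_set$gene_ids)
  expr <- read.delim(fx$paths$expression, check.names = FALSE)
  expect_equal(dim(expr), c(nrow(fx$expression$mat), 10))
})

test_that("tissue medians plant immune-specific genes", {
  cfg <- sim_config(seed = 7, n_genes = 50, chrom_length = 2e6)
  genome <- simulate_genome(cfg)
  med <- simulate_tissue_medians(cfg, genome$genes)
  s <- specificity_score(med)
  planted <- attr(med, "immune_specific")
  if (length(planted) >= 3) {
    expect_gt(median(s$score[s$gene_id %in% planted]),
              median(s$score[!s$gene_id %in% planted]))
  }
})
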