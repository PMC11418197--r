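# Planted-ground-truth synthetic fixture: a miniature single-chromosome
# multi-omic world (gene models, consensus OCRs, multi-resolution loops,
# GWAS summary statistics, truth sets, expression trajectories) built so
# that every planted variant-gene pair is recoverable by the pipeline by
# construction, and nothing else is (all non-causal variants are kept out
# of open chromatin, and background loops/OCRs are placed so they cannot
# create variant-bearing promoter contacts).

#' Synthetic-fixture configuration
#'
#' Defaults emulate the study's scale statements: ~14 proxies per sentinel,
#' a causal variant planted in a promoter-connected OCR for 60% of
#' sentinels, causal z-scores centered at 6 with unit noise, and LD decay
#' of proxy z-scores with a 20 kb length scale.
#'
#' @param seed integer master seed; each generator stage derives its own
#'   sub-seed from it
#' @param chrom,chrom_length single synthetic chromosome (default 10 Mb)
#' @param n_genes gene count (TSS spacing >= 5 kb enforced); 1-3 TSS each
#' @param n_ocrs total OCR count (planted + background), widths 200-1000 bp
#' @param n_loops_background background loops per resolution per timepoint
#' @param n_sentinels association signals (default 50)
#' @param mean_proxies mean credible-set input size per sentinel
#' @param frac_causal fraction of sentinels with a planted causal variant
#' @param frac_promoter_proxy fraction of causal variants planted inside a
#'   promoter-window OCR (the rest are distal, loop-connected)
#' @param causal_z causal z-score center (default 6)
#' @param z_noise_sd z-score noise SD; 0 gives the deterministic
#'   "noise off" world used for exact planted-recovery checks
#' @param ld_d0 LD decay length scale in bp (rho = exp(-d/d0))
#' @param truth_precision,truth_recall precision/recall the perfect
#'   predictor must achieve against the simulated truth set
#' @param expr_noise_sd per-sample expression noise SD (default 0.2)
#' @param n_expr_genes differential genes in the expression fixture
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 7, chrom = "chrS", chrom_length = 1e7,
                       n_genes = 200, n_ocrs = 1000,
                       n_loops_background = 30, n_sentinels = 50,
                       mean_proxies = 14, frac_causal = 0.6,
                       frac_promoter_proxy = 0.3, causal_z = 6,
                       z_noise_sd = 1, ld_d0 = 20000,
                       truth_precision = 0.25, truth_recall = 0.5,
                       expr_noise_sd = 0.2, n_expr_genes = 150) {
  stopifnot(n_genes >= 1, n_ocrs >= 1, n_sentinels >= 1,
            frac_causal >= 0, frac_causal <= 1,
            frac_promoter_proxy >= 0, frac_promoter_proxy <= 1,
            z_noise_sd >= 0, ld_d0 > 0)
  structure(as.list(environment()), class = "sim_config")
}

MIN_TSS_GAP <- 5000L

#' Simulate the gene annotation of the synthetic chromosome
#'
#' Primary TSS are placed with at least 5 kb spacing; each gene gets 1-3
#' TSS (extras within 2 kb downstream of the primary), a random strand and
#' a biotype (90% protein-coding). Deterministic under the config seed.
#'
#' @param config [sim_config()]
#' @return list: genes (gene table), chrom, chrom_length
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  margin <- 20000
  avail <- config$chrom_length - 2 * margin - (n - 1) * MIN_TSS_GAP
  if (avail <= 0)
    stop("infeasible gene density: n_genes x 5 kb spacing exceeds chromosome")
  u <- sort(runif(n, 0, avail))
  tss_primary <- as.integer(floor(margin + u + (seq_len(n) - 1) * MIN_TSS_GAP))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  n_tss <- sample(1:3, n, replace = TRUE)
  tss <- lapply(seq_len(n), function(i) {
    t0 <- tss_primary[i]
    extra <- if (n_tss[i] > 1) {
      off <- sample(200:2000, n_tss[i] - 1)
      if (strand[i] == "+") t0 + off else t0 - off
    } else integer(0)
    sort(unique(pmax(0L, as.integer(c(t0, extra)))))
  })
  biotype <- ifelse(runif(n) < 0.9, "protein_coding", "lincRNA")
  genes <- gene_table(sprintf("SIMG%04d", seq_len(n)),
                      sprintf("SIMG%04d", seq_len(n)),
                      rep(config$chrom, n), strand, tss, biotype)
  list(genes = genes, chrom = config$chrom,
       chrom_length = config$chrom_length)
}

# interval registry helpers: reg is a data.frame(start, end)
reg_overlaps <- function(start, end, reg) {
  nrow(reg) > 0 && any(reg$start < end & start < reg$end)
}
reg_add <- function(reg, start, end) rbind(reg, data.frame(start = start,
                                                           end = end))

#' Simulate OCRs and multi-resolution chromatin loops
#'
#' Plants, for `frac_causal` of the sentinels, either a distal OCR
#' connected to an effector gene's promoter by a bin-aligned loop (at 1, 2
#' or 4 kb resolution, sometimes duplicated at a coarser resolution to
#' exercise consensus merging) or an OCR inside the effector's promoter
#' window. Placement avoids every other promoter window and every other
#' planted element, so the planted contact list is exactly what the
#' pipeline can derive. Background OCRs avoid planted OCRs; background
#' loop anchors avoid all promoter windows.
#'
#' @param config [sim_config()]
#' @param genome output of [simulate_genome()]
#' @return list: ocrs, loops (raw calls), planted (per-effector table),
#'   effectors (gene ids)
#' @export
simulate_regulatory_landscape <- function(config, genome) {
  set.seed(config$seed + 1L)
  genes <- genome$genes
  chrom <- genome$chrom; clen <- genome$chrom_length
  prom <- promoter_windows(genes, stats::setNames(clen, chrom))
  n_causal <- round(config$frac_causal * config$n_sentinels)
  pc <- genes$gene_id[genes$biotype == "protein_coding"]
  if (n_causal > length(pc)) stop("not enough protein-coding genes to plant")
  effectors <- sample(pc, n_causal)
  n_prox <- round(config$frac_promoter_proxy * n_causal)
  mech <- c(rep("promoter_proxy", n_prox),
            rep("distal_contact", n_causal - n_prox))
  occupied <- data.frame(start = prom$start, end = prom$end)  # all promoters
  planted_reg <- data.frame(start = integer(0), end = integer(0))
  ocr_rows <- list(); loop_rows <- list(); planted <- list()
  rand_subset_tp <- function() {
    k <- sample(1:3, 1)
    sort(sample(seq_along(TIMEPOINTS), k))
  }
  for (i in seq_len(n_causal)) {
    g <- effectors[i]
    gi <- match(g, genes$gene_id)
    gprom <- prom[prom$gene_id == g, , drop = FALSE]
    own_windows <- data.frame(start = gprom$start, end = gprom$end)
    other_prom <- prom[prom$gene_id != g, , drop = FALSE]
    other_reg <- data.frame(start = other_prom$start, end = other_prom$end)
    tp_loop <- rand_subset_tp()
    tp_ocr <- sort(union(tp_loop, rand_subset_tp()))
    flags <- seq_along(TIMEPOINTS) %in% tp_ocr
    if (mech[i] == "promoter_proxy") {
      w <- sample(200:400, 1)
      win <- gprom[sample.int(nrow(gprom), 1), , drop = FALSE]
      placed <- FALSE
      for (try in 1:200) {
        if (win$end - win$start < w) { w <- win$end - win$start - 2L }
        s <- win$start + sample.int(win$end - win$start - w, 1) - 1L
        if (!reg_overlaps(s, s + w, planted_reg) &&
            !reg_overlaps(s, s + w, other_reg)) { placed <- TRUE; break }
      }
      if (!placed) stop("could not place promoter-proxy OCR")
      pid <- sprintf("pOCR%03d", i)
      ocr_rows[[length(ocr_rows) + 1L]] <- data.frame(
        peak_id = pid, chrom = chrom, start = as.integer(s),
        end = as.integer(s + w), tp_unstim = flags[1], tp_8h = flags[2],
        tp_24h = flags[3], n_reps = sample(2:3, 1),
        stringsAsFactors = FALSE)
      planted_reg <- reg_add(planted_reg, s, s + w)
      planted[[length(planted) + 1L]] <- data.frame(
        gene_id = g, mechanism = "promoter_proxy", ocr_id = pid,
        ocr_start = as.integer(s), ocr_end = as.integer(s + w),
        tss = win$tss, timepoints = paste(TIMEPOINTS[tp_ocr], collapse = ","),
        stringsAsFactors = FALSE)
    } else {
      # distal: bin-aligned loop from a promoter anchor to an OCR anchor
      t0 <- genes$tss[[gi]][sample.int(length(genes$tss[[gi]]), 1)]
      placed <- FALSE
      for (try in 1:300) {
        r <- sample(c(1000L, 2000L, 4000L), 1)
        ap_s <- (t0 %/% r) * r; ap_e <- ap_s + r
        # promoter anchor must touch only this gene's windows/elements
        if (reg_overlaps(ap_s, ap_e, other_reg) ||
            reg_overlaps(ap_s, ap_e, planted_reg)) {
          r <- 1000L; ap_s <- (t0 %/% r) * r; ap_e <- ap_s + r
          if (reg_overlaps(ap_s, ap_e, other_reg) ||
              reg_overlaps(ap_s, ap_e, planted_reg)) next
        }
        d <- sample(20000:200000, 1) * sample(c(-1L, 1L), 1)
        ao_s <- ((t0 + d) %/% r) * r; ao_e <- ao_s + r
        if (ao_s < 0 || ao_e > clen) next
        if (abs(ao_s - ap_s) < 2L * r) next
        if (reg_overlaps(ao_s, ao_e, occupied) ||
            reg_overlaps(ao_s, ao_e, planted_reg)) next
        placed <- TRUE; break
      }
      if (!placed) stop("could not place distal loop anchors")
      w <- sample(200:min(1000L, r - 2L), 1)
      s <- ao_s + sample.int(r - w, 1) - 1L
      pid <- sprintf("dOCR%03d", i)
      ocr_rows[[length(ocr_rows) + 1L]] <- data.frame(
        peak_id = pid, chrom = chrom, start = as.integer(s),
        end = as.integer(s + w), tp_unstim = flags[1], tp_8h = flags[2],
        tp_24h = flags[3], n_reps = sample(2:3, 1),
        stringsAsFactors = FALSE)
      a1 <- sort(c(ap_s, ao_s)); a1e <- a1 + r
      for (tpi in tp_loop) {
        loop_rows[[length(loop_rows) + 1L]] <- data.frame(
          loop_id = sprintf("pl%03d_%s_%dk", i, TIMEPOINTS[tpi], r %/% 1000),
          chrom = chrom, start1 = a1[1], end1 = a1e[1],
          start2 = a1[2], end2 = a1e[2], resolution = r,
          timepoint = TIMEPOINTS[tpi], qvalue = 1e-8,
          stringsAsFactors = FALSE)
      }
      # coarser duplicate of the same contact, to exercise consensus merging
      if (r < 4000L && runif(1) < 0.5) {
        r2 <- 4000L
        c1 <- ((a1[1] + r %/% 2) %/% r2) * r2
        c2 <- ((a1[2] + r %/% 2) %/% r2) * r2
        if (c1 + r2 <= c2 && c2 + r2 <= clen) {
          tpi <- tp_loop[1]
          loop_rows[[length(loop_rows) + 1L]] <- data.frame(
            loop_id = sprintf("pl%03d_%s_dup4k", i, TIMEPOINTS[tpi]),
            chrom = chrom, start1 = c1, end1 = c1 + r2,
            start2 = c2, end2 = c2 + r2, resolution = r2,
            timepoint = TIMEPOINTS[tpi], qvalue = 1e-8,
            stringsAsFactors = FALSE)
        }
      }
      planted_reg <- reg_add(planted_reg, ap_s, ap_e)
      planted_reg <- reg_add(planted_reg, ao_s, ao_e)
      planted[[length(planted) + 1L]] <- data.frame(
        gene_id = g, mechanism = "distal_contact", ocr_id = pid,
        ocr_start = as.integer(s), ocr_end = as.integer(s + w),
        tss = t0, timepoints = paste(TIMEPOINTS[tp_loop], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  planted <- do.call(rbind, planted)
  # background OCRs avoid planted OCRs (and planted anchors, conservatively)
  n_bg <- config$n_ocrs - nrow(planted)
  bg <- list()
  while (length(bg) < n_bg) {
    w <- sample(200:1000, 1)
    s <- sample.int(clen - w, 1) - 1L
    if (reg_overlaps(s, s + w, planted_reg)) next
    k <- sample(1:3, 1)
    f <- seq_along(TIMEPOINTS) %in% sample(seq_along(TIMEPOINTS), k)
    bg[[length(bg) + 1L]] <- data.frame(
      peak_id = sprintf("bgOCR%04d", length(bg) + 1L), chrom = chrom,
      start = s, end = as.integer(s + w), tp_unstim = f[1], tp_8h = f[2],
      tp_24h = f[3], n_reps = sample(2:3, 1), stringsAsFactors = FALSE)
  }
  ocrs <- do.call(rbind, c(ocr_rows, bg))
  ocrs <- ocrs[order(ocrs$start), , drop = FALSE]
  rownames(ocrs) <- NULL
  validate_ocrs(ocrs)
  # background loops: anchors avoid every promoter window
  prom_reg <- data.frame(start = prom$start, end = prom$end)
  bg_loops <- list()
  for (r in c(1000L, 2000L, 4000L)) for (tp in TIMEPOINTS) {
    made <- 0L
    while (made < config$n_loops_background) {
      a <- (sample.int(clen %/% r - 2L, 1) - 1L) * r
      gap <- sample(20000:500000, 1)
      b <- a + (gap %/% r) * r
      if (b + r > clen || b <= a) next
      if (reg_overlaps(a, a + r, prom_reg) ||
          reg_overlaps(b, b + r, prom_reg)) next
      made <- made + 1L
      bg_loops[[length(bg_loops) + 1L]] <- data.frame(
        loop_id = sprintf("bg_%s_%dk_%03d", tp, r %/% 1000, made),
        chrom = chrom, start1 = a, end1 = a + r, start2 = b, end2 = b + r,
        resolution = r, timepoint = tp, qvalue = 1e-7,
        stringsAsFactors = FALSE)
    }
  }
  loops <- do.call(rbind, c(loop_rows, bg_loops))
  rownames(loops) <- NULL
  list(ocrs = ocrs, loops = canonicalize_loops(loops), planted = planted,
       effectors = effectors)
}

#' Simulate GWAS summary statistics with planted causal variants
#'
#' Causal sentinels get their causal variant at the center of the planted
#' OCR with `z ~ Normal(causal_z, z_noise_sd)`; proxy z-scores decay with
#' distance (`rho = exp(-d / ld_d0)`) plus `sqrt(1 - rho^2)`-scaled noise.
#' Non-causal sentinels are pure noise. Every non-causal variant is placed
#' outside all OCRs, so with `z_noise_sd = 0` the accessible credible set
#' of each causal sentinel is exactly its causal variant. p-values are
#' `2 * (1 - Phi(|z|))`.
#'
#' @param config [sim_config()]
#' @param genome output of [simulate_genome()]
#' @param landscape output of [simulate_regulatory_landscape()]
#' @return list: stats (summary-stat table, 0-based pos), truth (list with
#'   causal table, pair table, effector gene ids)
#' @export
simulate_gwas <- function(config, genome, landscape) {
  set.seed(config$seed + 2L)
  chrom <- genome$chrom; clen <- genome$chrom_length
  planted <- landscape$planted
  n_causal <- nrow(planted)
  ocr_reg <- data.frame(start = landscape$ocrs$start,
                        end = landscape$ocrs$end)
  traits <- c("T1D", "RA", "IBD", "SLE", "CEL")
  rows <- list(); truth_rows <- list()
  for (i in seq_len(config$n_sentinels)) {
    sid <- sprintf("sent%03d", i)
    trait <- sample(traits, 1)
    causal <- i <= n_causal
    n_extra <- max(2L, stats::rpois(1, config$mean_proxies - 1))
    if (causal) {
      center <- (planted$ocr_start[i] + planted$ocr_end[i]) %/% 2L
      z0 <- config$causal_z + rnorm(1, 0, config$z_noise_sd)
    } else {
      center <- sample.int(clen - 100000L, 1) + 50000L
      z0 <- NA_real_
    }
    pos <- integer(0)
    while (length(pos) < n_extra) {
      p <- center + sample(-50000:50000, 1)
      if (p < 0 || p >= clen) next
      if (reg_overlaps(p, p + 1L, ocr_reg)) next
      if (p %in% pos || (causal && p == center)) next
      pos <- c(pos, p)
    }
    if (causal) {
      d <- abs(pos - center)
      rho <- exp(-d / config$ld_d0)
      z <- rho * z0 + sqrt(1 - rho^2) * rnorm(n_extra, 0, config$z_noise_sd)
      pos <- c(center, pos)
      z <- c(z0, z)
    } else {
      z <- rnorm(n_extra, 0, config$z_noise_sd)
    }
    vid <- sprintf("%s_v%02d", sid, seq_along(pos))
    p_val <- pmax(2 * pnorm(-abs(z)), 1e-300)
    rows[[i]] <- data.frame(variant_id = vid, chrom = chrom,
                            pos = as.integer(pos), p_value = p_val,
                            sentinel_id = sid, trait = trait,
                            stringsAsFactors = FALSE)
    if (causal)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        sentinel_id = sid, trait = trait, variant_id = vid[1],
        pos = as.integer(pos[1]), gene_id = planted$gene_id[i],
        evidence = planted$mechanism[i], ocr_id = planted$ocr_id[i],
        stringsAsFactors = FALSE)
  }
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  validate_summary_stats(stats)
  truth_pairs <- do.call(rbind, truth_rows)
  list(stats = stats,
       truth = list(causal = truth_pairs,
                    pairs = truth_pairs[, c("variant_id", "sentinel_id",
                                            "gene_id", "evidence")],
                    effectors = landscape$effectors))
}

#' Simulate a truth gene set with designed precision/recall
#'
#' Builds a truth set such that the perfect predictor (the full planted
#' effector set) achieves exactly the configured precision and recall:
#' `overlap = precision * n_effectors` planted genes plus
#' `overlap / recall - overlap` decoys. Errors when the targets are not
#' achievable in exact integer arithmetic.
#'
#' @param config [sim_config()]
#' @param truth ground truth from [simulate_gwas()]
#' @param genes gene table (decoys are drawn from non-effector
#'   protein-coding genes)
#' @param strict error on designs that are not exactly achievable (default);
#'   with `strict = FALSE` the overlap and truth size are rounded to the
#'   nearest feasible integers with a warning
#' @return list: name, gene_ids, n_planted_in_truth, n_decoys
#' @export
simulate_truth_set <- function(config, truth, genes, strict = TRUE) {
  set.seed(config$seed + 3L)
  eff <- unique(truth$effectors)
  n <- length(eff)
  o <- config$truth_precision * n
  if (abs(o - round(o)) > 1e-9) {
    if (strict)
      stop(sprintf("infeasible truth design: precision %.3g x %d effectors is not an integer",
                   config$truth_precision, n))
    warning(sprintf("rounding overlap %.2f to %d (design not exact)",
                    o, max(1L, as.integer(round(o)))))
  }
  o <- max(1L, as.integer(round(o)))
  nT <- o / config$truth_recall
  if (abs(nT - round(nT)) > 1e-9) {
    if (strict)
      stop("infeasible truth design: overlap / recall is not an integer")
    warning(sprintf("rounding truth size %.2f to %d (design not exact)",
                    nT, max(o, as.integer(round(nT)))))
  }
  nT <- max(o, as.integer(round(nT)))
  pool <- setdiff(genes$gene_id[genes$biotype == "protein_coding"], eff)
  if (nT - o > length(pool))
    stop("infeasible truth design: not enough decoy genes")
  gene_ids <- c(sample(eff, o), sample(pool, nT - o))
  list(name = "synthetic_truth", gene_ids = toupper(gene_ids),
       n_planted_in_truth = o, n_decoys = nT - o)
}

# the five planted trajectory archetypes: equally spaced directions on the
# circle that row-standardized 3-timepoint trajectories live on
expression_archetypes <- function() {
  e1 <- c(1, -1, 0) / sqrt(2)
  e2 <- c(1, 1, -2) / sqrt(6)
  ang <- 2 * pi * (0:4) / 5
  arch <- t(sapply(ang, function(a) cos(a) * e1 + sin(a) * e2))
  colnames(arch) <- TIMEPOINTS
  rownames(arch) <- paste0("cluster", 1:5)
  arch
}

#' Simulate the 5-archetype expression trajectory fixture
#'
#' Differential genes follow one of five planted trajectory archetypes over
#' unstim/8h/24h (three replicates each, giving 9 samples) with Gaussian
#' sample noise. Planted effector genes, when supplied, are included so the
#' dynamic-gene filter has matched inputs.
#'
#' @param config [sim_config()]
#' @param genes gene table
#' @param effectors optional effector gene ids to force into the fixture
#' @return list: mat (genes x 9 samples), archetype (named integer vector:
#'   the planted cluster of each gene), clusters (data.frame gene_id,
#'   cluster, for [dynamic_subset()])
#' @export
simulate_expression <- function(config, genes, effectors = character(0)) {
  set.seed(config$seed + 4L)
  ids <- union(effectors, sample(genes$gene_id,
                                 min(config$n_expr_genes, nrow(genes))))
  ids <- ids[seq_len(min(length(ids), nrow(genes)))]
  n <- length(ids)
  arch <- expression_archetypes()
  lab <- rep(1:5, length.out = n)[sample.int(n)]
  tp_idx <- rep(1:3, each = 3)
  mat <- t(vapply(seq_len(n), function(i)
    arch[lab[i], tp_idx] + rnorm(9, 0, config$expr_noise_sd),
    numeric(9)))
  rownames(mat) <- ids
  colnames(mat) <- paste0(rep(TIMEPOINTS, each = 3), "_r", rep(1:3, 3))
  names(lab) <- ids
  list(mat = mat, archetype = lab,
       clusters = data.frame(gene_id = ids, cluster = as.integer(lab),
                             stringsAsFactors = FALSE))
}

#' Simulate GTEx-style tissue median expression
#'
#' Whole Blood and Spleen plus eight other tissues; a planted 20% of genes
#' are immune-specific (tenfold higher immune medians).
#'
#' @param config [sim_config()]
#' @param genes gene table
#' @return data.frame gene_id + tissue median columns
#' @export
simulate_tissue_medians <- function(config, genes) {
  set.seed(config$seed + 5L)
  tissues <- c("Whole Blood", "Spleen", "Liver", "Lung", "Brain - Cortex",
               "Heart - Left Ventricle", "Kidney - Cortex", "Muscle - Skeletal",
               "Pancreas", "Skin - Sun Exposed")
  n <- nrow(genes)
  base <- matrix(stats::rlnorm(n * length(tissues), 1, 0.6), n)
  immune_specific <- runif(n) < 0.2
  base[immune_specific, 1:2] <- base[immune_specific, 1:2] * 10
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (j in seq_along(tissues)) out[[tissues[j]]] <- base[, j]
  attr(out, "immune_specific") <- genes$gene_id[immune_specific]
  out
}

#' Fixture for the permutation enrichment test
#'
#' Disjoint 1 Mb sentinel neighborhoods, each holding `universe_size` genes
#' of which exactly one is a V2G gene, and one comparison pair per
#' sentinel. With `frac_hit` of the comparison pairs set to the V2G gene
#' the expected fold enrichment is exactly
#' `frac_hit * universe_size` (the null expectation per pair is
#' `1/universe_size`). With `frac_hit = NULL` comparison genes are drawn
#' uniformly from the sentinel's universe, i.e. from the null itself
#' (calibration mode).
#'
#' @param n_sentinels sentinel count (default 200)
#' @param universe_size genes per 1 Mb neighborhood (default 20)
#' @param frac_hit fraction of comparison pairs overlapping V2G, or NULL
#'   for calibration draws
#' @param seed RNG seed
#' @return list: genes, sentinels, v2g_pairs, comparison, expected_fold
#' @export
simulate_enrichment_fixture <- function(n_sentinels = 200,
                                        universe_size = 20,
                                        frac_hit = 0.5, seed = 1) {
  set.seed(seed)
  spacing <- 3e6
  chrom <- "chrE"
  sent <- data.frame(sentinel_id = sprintf("es%03d", seq_len(n_sentinels)),
                     chrom = chrom,
                     pos = as.integer((seq_len(n_sentinels) - 1) * spacing +
                                        1.5e6),
                     stringsAsFactors = FALSE)
  offs <- as.integer(seq(-950000, 950000, length.out = universe_size))
  gid <- as.vector(t(outer(seq_len(n_sentinels), seq_len(universe_size),
                           function(i, j) sprintf("EG%03d_%02d", i, j))))
  tss <- as.vector(t(outer(sent$pos, offs, `+`)))
  genes <- gene_table(gid, gid, rep(chrom, length(gid)),
                      rep("+", length(gid)), as.list(tss),
                      rep("protein_coding", length(gid)))
  v2g <- data.frame(sentinel_id = sent$sentinel_id,
                    gene_id = sprintf("EG%03d_01", seq_len(n_sentinels)),
                    stringsAsFactors = FALSE)
  if (is.null(frac_hit)) {
    pick <- sample.int(universe_size, n_sentinels, replace = TRUE)
  } else {
    n_hit <- round(frac_hit * n_sentinels)
    pick <- c(rep(1L, n_hit),
              sample(2:universe_size, n_sentinels - n_hit, replace = TRUE))
  }
  comparison <- data.frame(sentinel_id = sent$sentinel_id,
                           gene_id = sprintf("EG%03d_%02d",
                                             seq_len(n_sentinels), pick),
                           stringsAsFactors = FALSE)
  list(genes = genes, sentinels = sent, v2g_pairs = v2g,
       comparison = comparison,
       expected_fold = if (is.null(frac_hit)) 1
                       else frac_hit * universe_size)
}

#' Write the full synthetic fixture to disk
#'
#' Emits the exact dialects the pipeline readers consume: gene table TSV,
#' OCR table, loop BEDPE, summary-stats TSV, truth-set text, expression
#' TSV and cluster assignments.
#'
#' @param config [sim_config()]
#' @param dir output directory (created if needed)
#' @return list of file paths plus the in-memory ground truth, invisibly
#' @export
simulate_v2g_fixture <- function(config = sim_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  genome <- simulate_genome(config)
  landscape <- simulate_regulatory_landscape(config, genome)
  gwas <- simulate_gwas(config, genome, landscape)
  truth_set <- simulate_truth_set(config, gwas$truth, genome$genes,
                                  strict = FALSE)
  expr <- simulate_expression(config, genome$genes, landscape$effectors)
  paths <- list(genes = file.path(dir, "genes.tsv"),
                ocrs = file.path(dir, "ocrs.tsv"),
                loops = file.path(dir, "loops.bedpe"),
                stats = file.path(dir, "sumstats.tsv"),
                truth = file.path(dir, "truth_genes.txt"),
                expression = file.path(dir, "expression.tsv"),
                clusters = file.path(dir, "clusters.tsv"))
  write_gene_table(genome$genes, paths$genes)
  write_ocr_bed(landscape$ocrs, paths$ocrs)
  write_loops_bedpe(landscape$loops, paths$loops)
  write_summary_stats(gwas$stats, paths$stats)
  writeLines(truth_set$gene_ids, paths$truth)
  em <- data.frame(gene_id = rownames(expr$mat), expr$mat,
                   check.names = FALSE)
  write.table(em, paths$expression, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(expr$clusters, paths$clusters, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(paths = paths, genome = genome, landscape = landscape,
                 gwas = gwas, truth_set = truth_set, expression = expr))
}
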