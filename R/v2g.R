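# Effector-gene nomination: accessible credible-set variants are linked to
# genes either because they sit in an OCR overlapping the gene's promoter
# window (promoter_proxy) or because they sit in an OCR at a loop anchor
# whose partner anchor touches the promoter (distal_contact), plus the
# descriptive statistics reported alongside (distance, degree, nearest-gene
# classes, stage sharing).

#' Nominate variant-gene pairs
#'
#' Union of promoter-proxy evidence (variant inside an OCR that overlaps
#' the gene's promoter window) and distal-contact evidence (variant inside
#' the OCR of a promoter-interacting contact). Pairs supported by both
#' evidence types carry both tags on a single record. Per-timepoint support
#' is recorded: promoter-proxy support follows the OCR accessibility flags,
#' distal support follows the contact flags (loop present AND OCR open).
#'
#' @param accessible accessible credible-set variants (from
#'   [constrain_to_ocr()]; columns variant_id, chrom, pos, sentinel_id,
#'   trait)
#' @param contacts promoter contacts (from [promoter_interacting_ocrs()])
#' @param promoters promoter windows of the gene universe
#' @param ocrs OCR table
#' @param genes gene table (for variant-to-gene TSS distances)
#' @return V2G pair data.frame: variant_id, sentinel_id, trait, gene_id,
#'   evidence, ev_promoter, ev_distal, tp_* flags, timepoints, distance_bp,
#'   ocr_id, loop_ids
#' @export
nominate <- function(accessible, contacts, promoters, ocrs, genes) {
  empty <- data.frame(variant_id = character(0), sentinel_id = character(0),
                      trait = character(0), gene_id = character(0),
                      evidence = character(0), ev_promoter = logical(0),
                      ev_distal = logical(0), tp_unstim = logical(0),
                      tp_8h = logical(0), tp_24h = logical(0),
                      timepoints = character(0), distance_bp = numeric(0),
                      ocr_id = character(0), loop_ids = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(accessible)) return(empty)
  vo <- intersect_intervals(variants_as_intervals(accessible), ocrs, check_sorted = FALSE)
  if (!nrow(vo)) return(empty)
  ocr_tp <- as.matrix(ocrs[, tp_cols(), drop = FALSE])
  recs <- list()
  # promoter_proxy: variant in OCR, OCR overlaps promoter window of gene
  op <- intersect_intervals(ocrs, promoters, check_sorted = FALSE)
  if (nrow(op)) {
    m <- merge(data.frame(v = vo$a_idx, o = vo$b_idx),
               data.frame(o = op$a_idx, p = op$b_idx), by = "o")
    if (nrow(m))
      recs[[length(recs) + 1L]] <- data.frame(
        v = m$v, gene_id = promoters$gene_id[m$p],
        ocr_id = ocrs$peak_id[m$o], loop_ids = "",
        ev = "promoter_proxy",
        tp_unstim = ocr_tp[m$o, 1], tp_8h = ocr_tp[m$o, 2],
        tp_24h = ocr_tp[m$o, 3], stringsAsFactors = FALSE)
  }
  # distal_contact: variant in the OCR of a promoter contact
  if (nrow(contacts)) {
    m <- merge(data.frame(v = vo$a_idx, o = vo$b_idx,
                          ocr_id = ocrs$peak_id[vo$b_idx]),
               contacts[, c("ocr_id", "gene_id", "loop_ids",
                            tp_cols())], by = "ocr_id")
    if (nrow(m))
      recs[[length(recs) + 1L]] <- data.frame(
        v = m$v, gene_id = m$gene_id, ocr_id = m$ocr_id,
        loop_ids = m$loop_ids, ev = "distal_contact",
        tp_unstim = m$tp_unstim, tp_8h = m$tp_8h, tp_24h = m$tp_24h,
        stringsAsFactors = FALSE)
  }
  if (!length(recs)) return(empty)
  raw <- do.call(rbind, recs)
  key <- paste(raw$v, raw$gene_id, sep = "\r")
  sp <- split(seq_len(nrow(raw)), key)
  gene_idx <- match(unique(raw$gene_id), genes$gene_id)
  names(gene_idx) <- unique(raw$gene_id)
  out <- do.call(rbind, lapply(sp, function(i) {
    v <- raw$v[i[1]]; g <- raw$gene_id[i[1]]
    evp <- any(raw$ev[i] == "promoter_proxy")
    evd <- any(raw$ev[i] == "distal_contact")
    flags <- c(any(raw$tp_unstim[i]), any(raw$tp_8h[i]), any(raw$tp_24h[i]))
    gi <- gene_idx[[g]]
    dist <- if (is.na(gi) || genes$chrom[gi] != accessible$chrom[v]) NA_real_
            else min(abs(as.numeric(accessible$pos[v]) -
                         as.numeric(genes$tss[[gi]])))
    data.frame(variant_id = accessible$variant_id[v],
               sentinel_id = accessible$sentinel_id[v],
               trait = accessible$trait[v], gene_id = g,
               evidence = paste(c(if (evp) "promoter_proxy",
                                  if (evd) "distal_contact"), collapse = ","),
               ev_promoter = evp, ev_distal = evd,
               tp_unstim = flags[1], tp_8h = flags[2], tp_24h = flags[3],
               timepoints = paste(TIMEPOINTS[flags], collapse = ","),
               distance_bp = dist,
               ocr_id = paste(sort(unique(raw$ocr_id[i])), collapse = ","),
               loop_ids = paste(sort(unique(setdiff(
                 unlist(strsplit(raw$loop_ids[i], ",")), ""))), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$variant_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degree and distance summaries of a V2G pair set
#'
#' Genes per variant (all evidence and distal-only, since the study's
#' per-variant degree could be read either way), variants per gene, OCRs
#' per gene, and the variant-to-TSS distance distribution of the connected
#' pairs.
#'
#' @param pairs V2G pairs from [nominate()]
#' @return list of summary statistics (medians, means, raw vectors)
#' @export
degree_and_distance <- function(pairs) {
  if (!nrow(pairs)) stop("empty pair list")
  gpv <- tapply(pairs$gene_id, pairs$variant_id,
                function(g) length(unique(g)))
  distal <- pairs[pairs$ev_distal, , drop = FALSE]
  gpv_distal <- if (nrow(distal))
    tapply(distal$gene_id, distal$variant_id,
           function(g) length(unique(g))) else integer(0)
  vpg <- tapply(pairs$variant_id, pairs$gene_id,
                function(v) length(unique(v)))
  opg <- tapply(pairs$ocr_id, pairs$gene_id, function(o)
    length(unique(setdiff(unlist(strsplit(o, ",")), ""))))
  d <- pairs$distance_bp[!is.na(pairs$distance_bp)]
  list(genes_per_variant = as.vector(gpv),
       genes_per_variant_median = median(as.vector(gpv)),
       genes_per_variant_mean = mean(as.vector(gpv)),
       genes_per_variant_distal = as.vector(gpv_distal),
       genes_per_variant_distal_median =
         if (length(gpv_distal)) median(as.vector(gpv_distal)) else NA_real_,
       variants_per_gene = as.vector(vpg),
       variants_per_gene_median = median(as.vector(vpg)),
       ocrs_per_gene = as.vector(opg),
       ocrs_per_gene_median = median(as.vector(opg)),
       distance_bp = d,
       distance_median = if (length(d)) median(d) else NA_real_,
       distance_mean = if (length(d)) mean(d) else NA_real_,
       n_pairs = nrow(pairs),
       n_variants = length(unique(pairs$variant_id)),
       n_genes = length(unique(pairs$gene_id)))
}

#' Classify each accessible variant by its relation to the nearest gene
#'
#' Four-way partition of accessible variants: contacted no gene
#' (`no_gene`), only the nearest gene (`nearest_only`), the nearest plus at
#' least one distant gene (`nearest_plus_distal`), or only distant gene(s)
#' (`distal_only`). "Nearest" is the gene with the smallest TSS distance
#' among all genes of the annotation universe (ties by gene_id).
#'
#' @param accessible accessible credible-set variants
#' @param pairs V2G pairs from [nominate()]
#' @param genes gene table defining the nearest-gene universe (apply any
#'   biotype filter before calling)
#' @return data.frame variant_id, nearest_gene, class; plus a `counts`
#'   attribute with the per-class tally
#' @export
classify_nearest <- function(accessible, pairs, genes) {
  stopifnot(nrow(accessible) >= 1)
  av <- accessible[!duplicated(accessible$variant_id), , drop = FALSE]
  nearest <- mapply(function(p, ch) nearest_gene(p, ch, genes),
                    av$pos, av$chrom)
  pair_genes <- split(pairs$gene_id, pairs$variant_id)
  cls <- vapply(seq_len(nrow(av)), function(i) {
    g <- unique(pair_genes[[av$variant_id[i]]])
    if (is.null(g) || !length(g)) return("no_gene")
    has_near <- nearest[i] %in% g
    has_far <- length(setdiff(g, nearest[i])) > 0
    if (has_near && has_far) "nearest_plus_distal"
    else if (has_near) "nearest_only"
    else "distal_only"
  }, "")
  out <- data.frame(variant_id = av$variant_id, nearest_gene = nearest,
                    class = cls, stringsAsFactors = FALSE)
  counts <- table(factor(cls, levels = c("no_gene", "nearest_only",
                                         "nearest_plus_distal", "distal_only")))
  attr(out, "counts") <- counts
  out
}

#' Stage-sharing tiers of nominated genes
#'
#' Each gene is assigned the number of timepoints at which at least one
#' supporting pair exists: 3 -> `all_stages`, 2 -> `two_stages`,
#' 1 -> `one_stage` (genes whose pairs carry no timepoint support are
#' reported as `unsupported`).
#'
#' @param pairs V2G pairs with timepoint flags
#' @return data.frame gene_id, n_stages, tier; `tier_counts` attribute
#' @export
stage_sharing <- function(pairs) {
  sp <- split(seq_len(nrow(pairs)), pairs$gene_id)
  n_stages <- vapply(sp, function(i)
    sum(c(any(pairs$tp_unstim[i]), any(pairs$tp_8h[i]),
          any(pairs$tp_24h[i]))), 0L)
  tier <- c("unsupported", "one_stage", "two_stages",
            "all_stages")[n_stages + 1L]
  out <- data.frame(gene_id = names(sp), n_stages = as.integer(n_stages),
                    tier = tier, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "tier_counts") <- table(factor(tier, levels = c(
    "all_stages", "two_stages", "one_stage", "unsupported")))
  out
}

#' Restrict pairs to dynamically regulated genes
#'
#' Keeps pairs whose gene belongs to one of the given expression clusters
#' (the activation-responsive trajectory clusters, by default 1-5). Genes
#' absent from the cluster table are treated as non-dynamic and dropped
#' with a message.
#'
#' @param pairs V2G pairs
#' @param clusters data.frame gene_id, cluster
#' @param dynamic_clusters cluster labels counting as dynamic (default 1:5)
#' @return list: `pairs` (filtered), `n_genes`, `n_pairs`,
#'   `n_missing_genes` (genes absent from the cluster table)
#' @export
dynamic_subset <- function(pairs, clusters, dynamic_clusters = 1:5) {
  cl <- clusters$cluster[match(pairs$gene_id, clusters$gene_id)]
  missing_genes <- unique(pairs$gene_id[is.na(cl)])
  if (length(missing_genes))
    message(length(missing_genes),
            " gene(s) absent from cluster table; treated as non-dynamic")
  keep <- !is.na(cl) & cl %in% dynamic_clusters
  kept <- pairs[keep, , drop = FALSE]
  list(pairs = kept, n_genes = length(unique(kept$gene_id)),
       n_pairs = nrow(kept), n_missing_genes = length(missing_genes))
}

#' Run the full variant-to-gene pipeline
#'
#' Credible sets -> open-chromatin constraint -> loop consensus -> promoter
#' contacts -> nomination, in one call. The gene universe for promoter
#' windows and nearest-gene classification is filtered by biotype (default
#' protein-coding, matching the study's emphasis).
#'
#' @param stats summary-stat table (0-based pos)
#' @param ocrs OCR table
#' @param loops raw loop calls
#' @param genes gene table
#' @param config [fine_map_config()]
#' @param biotype biotype filter for the gene universe (NULL keeps all)
#' @param chrom_lengths optional chromosome lengths for window clipping
#' @return list with every intermediate: credible (all members), accessible,
#'   shrinkage report, consensus loops, contacts, pairs, genes_used
#' @export
run_v2g <- function(stats, ocrs, loops, genes, config = fine_map_config(),
                    biotype = "protein_coding", chrom_lengths = NULL) {
  genes_used <- if (is.null(biotype)) genes
                else genes[genes$biotype %in% biotype, , drop = FALSE]
  promoters <- promoter_windows(genes_used, chrom_lengths)
  cs <- build_credible_sets(stats, config)
  acc <- constrain_to_ocr(cs, ocrs, config = config)
  cons <- consensus_loops(loops)
  contacts <- promoter_interacting_ocrs(cons, promoters, ocrs)
  pairs <- nominate(acc$accessible, contacts, promoters, ocrs, genes_used)
  list(credible = cs, accessible = acc$accessible, report = acc$report,
       consensus = cons, contacts = contacts, pairs = pairs,
       genes_used = genes_used, promoters = promoters)
}
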