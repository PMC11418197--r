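# Hi-C loop handling: loops called at 1/2/4 kb resolution per timepoint are
# canonicalized, consensus-merged with preference for the finest resolution,
# unioned across timepoints, and finally turned into OCR <-> gene-promoter
# contact pairs.

#' Canonicalize loop anchor order
#'
#' Ensures `anchor1.start < anchor2.start` on every row (swapping anchors
#' where needed); idempotent. Trans-chromosomal rows are rejected upstream
#' at parse time; anchors must not overlap.
#'
#' @param loops loop data.frame (loop_id, chrom, start1, end1, start2,
#'   end2, resolution, timepoint, qvalue)
#' @return canonical loop data.frame
#' @export
canonicalize_loops <- function(loops) {
  if (!nrow(loops)) return(loops)
  swap <- loops$start2 < loops$start1
  if (any(swap)) {
    s1 <- loops$start1[swap]; e1 <- loops$end1[swap]
    loops$start1[swap] <- loops$start2[swap]
    loops$end1[swap] <- loops$end2[swap]
    loops$start2[swap] <- s1
    loops$end2[swap] <- e1
  }
  if (any(loops$end1 > loops$start2))
    stop("loop with overlapping anchors")
  loops
}

anchor1_df <- function(loops) data.frame(chrom = loops$chrom,
                                         start = loops$start1,
                                         end = loops$end1)
anchor2_df <- function(loops) data.frame(chrom = loops$chrom,
                                         start = loops$start2,
                                         end = loops$end2)

# both-anchor (paired) overlap of candidate rows against kept rows
both_anchor_overlap_any <- function(cand, kept) {
  same <- kept$chrom == cand$chrom
  ov1 <- same & kept$start1 < cand$end1 & cand$start1 < kept$end1
  ov2 <- same & kept$start2 < cand$end2 & cand$start2 < kept$end2
  which(ov1 & ov2)
}

#' Merge loop calls across resolutions (one timepoint)
#'
#' Resolutions are processed fine to coarse: every 1 kb loop is kept; a
#' 2 kb (then 4 kb) loop is added only if no already-kept loop overlaps it
#' at BOTH anchors (paired anchor1-anchor1, anchor2-anchor2 half-open
#' overlap). Absorbed coarse calls are recorded in the `absorbed` column of
#' the representative that absorbed them. Idempotent.
#'
#' @param loops canonical loops of a single timepoint; resolutions in
#'   \{1000, 2000, 4000\}
#' @return consensus loop data.frame with an `absorbed` provenance column
#'   (comma-separated loop ids)
#' @export
merge_resolutions <- function(loops) {
  if (!nrow(loops)) { loops$absorbed <- character(0); return(loops) }
  if (!all(loops$resolution %in% c(1000L, 2000L, 4000L)))
    stop("unknown loop resolution (expected 1000, 2000 or 4000)")
  loops <- canonicalize_loops(loops)
  o <- order(loops$resolution, loops$chrom, loops$start1, loops$start2,
             loops$loop_id)
  loops <- loops[o, , drop = FALSE]
  if (!"absorbed" %in% names(loops)) loops$absorbed <- ""
  finest <- min(loops$resolution)
  keep <- loops$resolution == finest
  kept <- loops[keep, , drop = FALSE]
  rest <- loops[!keep, , drop = FALSE]
  for (i in seq_len(nrow(rest))) {
    cand <- rest[i, , drop = FALSE]
    hit <- both_anchor_overlap_any(cand, kept)
    if (length(hit)) {
      j <- hit[1]
      kept$absorbed[j] <- paste(c(strsplit(kept$absorbed[j], ",")[[1]],
                                  cand$loop_id,
                                  strsplit(cand$absorbed, ",")[[1]]),
                                collapse = ",")
      kept$absorbed[j] <- sub("^,+", "", kept$absorbed[j])
    } else {
      kept <- rbind(kept, cand)
    }
  }
  rownames(kept) <- NULL
  kept
}

#' Union per-timepoint consensus loops with both-anchor deduplication
#'
#' Loops supported at several timepoints collapse to one consensus loop
#' (finest representative kept, same paired both-anchor overlap rule as
#' [merge_resolutions()]); each consensus loop carries logical flags
#' `tp_unstim`, `tp_8h`, `tp_24h` for the timepoints supporting it.
#' Commutative in input order and idempotent.
#'
#' @param consensus_list either a named list of per-timepoint consensus loop
#'   data.frames, or a single data.frame with a `timepoint` column
#' @return consensus loop data.frame with per-timepoint flags and a
#'   `timepoints` comma-separated summary column
#' @export
union_timepoints <- function(consensus_list) {
  if (is.data.frame(consensus_list)) {
    all_loops <- consensus_list
  } else {
    all_loops <- do.call(rbind, consensus_list)
  }
  if (!nrow(all_loops)) {
    for (tc in tp_cols()) all_loops[[tc]] <- logical(0)
    all_loops$timepoints <- character(0)
    return(all_loops)
  }
  if (!all(all_loops$timepoint %in% TIMEPOINTS))
    stop("unknown timepoint label")
  if (!"absorbed" %in% names(all_loops)) all_loops$absorbed <- ""
  o <- order(all_loops$resolution, all_loops$chrom, all_loops$start1,
             all_loops$start2, match(all_loops$timepoint, TIMEPOINTS),
             all_loops$loop_id)
  all_loops <- all_loops[o, , drop = FALSE]
  kept <- all_loops[0, , drop = FALSE]
  tp_of <- list()
  src_of <- list()
  for (i in seq_len(nrow(all_loops))) {
    cand <- all_loops[i, , drop = FALSE]
    hit <- if (nrow(kept)) both_anchor_overlap_any(cand, kept) else integer(0)
    if (length(hit)) {
      j <- hit[1]
      tp_of[[j]] <- union(tp_of[[j]], cand$timepoint)
      src_of[[j]] <- union(src_of[[j]], cand$loop_id)
    } else {
      kept <- rbind(kept, cand)
      j <- nrow(kept)
      tp_of[[j]] <- cand$timepoint
      src_of[[j]] <- cand$loop_id
    }
  }
  for (k in seq_along(TIMEPOINTS))
    kept[[tp_cols()[k]]] <- vapply(tp_of, function(x) TIMEPOINTS[k] %in% x, TRUE)
  kept$timepoints <- vapply(tp_of, function(x)
    paste(TIMEPOINTS[TIMEPOINTS %in% x], collapse = ","), "")
  kept$source_loops <- vapply(src_of, paste, "", collapse = ",")
  rownames(kept) <- NULL
  kept
}

#' Consensus loops from raw multi-resolution, multi-timepoint calls
#'
#' Convenience wrapper: either merge resolutions within each timepoint and
#' then union timepoints (default, `"resolutions_then_stages"`), or union
#' timepoints within each resolution first and then merge resolutions.
#'
#' @param loops raw canonical loop calls
#' @param order merge order (see Details)
#' @return consensus loops with timepoint flags
#' @export
consensus_loops <- function(loops,
                            order = c("resolutions_then_stages",
                                      "stages_then_resolutions")) {
  order <- match.arg(order)
  if (order == "resolutions_then_stages") {
    per_tp <- lapply(split(loops, loops$timepoint), merge_resolutions)
    union_timepoints(per_tp)
  } else {
    per_res <- lapply(split(loops, loops$resolution), union_timepoints)
    merged <- do.call(rbind, lapply(per_res, function(x) x))
    # re-merge across resolutions keeping flags: treat each unioned loop as
    # a candidate with its timepoint set expanded back to rows
    rows <- merged[rep(seq_len(nrow(merged)),
                       vapply(strsplit(merged$timepoints, ","), length, 1L)), ]
    rows$timepoint <- unlist(strsplit(merged$timepoints, ","))
    rows$absorbed <- ""
    per_tp <- lapply(split(rows, rows$timepoint), merge_resolutions)
    union_timepoints(per_tp)
  }
}

#' Promoter-interacting OCR contacts
#'
#' For every consensus loop, each anchor overlapping a gene promoter window
#' is paired with every OCR overlapping the opposite anchor, yielding one
#' contact per (OCR, gene). Loops whose anchors both hit promoters emit
#' contacts in both directions. Duplicate (OCR, gene) contacts are
#' collapsed with provenance (supporting loops, union of timepoints)
#' merged. A contact is supported at a timepoint when at least one
#' supporting loop is present AND the OCR is accessible at that timepoint.
#' Contacts whose OCR overlaps the target gene's own promoter window are
#' classed `promoter-proximal`, all others `distal`.
#'
#' @param loops consensus loops with timepoint flags
#'   (from [union_timepoints()] / [consensus_loops()])
#' @param promoters promoter windows (from [promoter_windows()])
#' @param ocrs OCR table
#' @return contact data.frame: ocr_id, gene_id, tss, timepoints (csv),
#'   tp_* flags, loop_ids, class
#' @export
promoter_interacting_ocrs <- function(loops, promoters, ocrs) {
  empty <- data.frame(ocr_id = character(0), gene_id = character(0),
                      tss = integer(0), timepoints = character(0),
                      tp_unstim = logical(0), tp_8h = logical(0),
                      tp_24h = logical(0), loop_ids = character(0),
                      class = character(0), stringsAsFactors = FALSE)
  if (!nrow(loops) || !nrow(promoters) || !nrow(ocrs)) return(empty)
  if (!all(tp_cols() %in% names(loops)))
    stop("loops must carry timepoint flags; run union_timepoints() first")
  p1 <- intersect_intervals(anchor1_df(loops), promoters, check_sorted = FALSE)
  p2 <- intersect_intervals(anchor2_df(loops), promoters, check_sorted = FALSE)
  o1 <- intersect_intervals(anchor1_df(loops), ocrs, check_sorted = FALSE)
  o2 <- intersect_intervals(anchor2_df(loops), ocrs, check_sorted = FALSE)
  # promoter on anchor1 with OCR on anchor2, and the mirror image
  h1 <- {
    m <- merge(p1, o2, by = "a_idx", suffixes = c("_p", "_o"))
    if (nrow(m)) data.frame(loop_idx = m$a_idx, prom_idx = m$b_idx_p,
                            ocr_idx = m$b_idx_o) else NULL
  }
  h2 <- {
    m <- merge(p2, o1, by = "a_idx", suffixes = c("_p", "_o"))
    if (nrow(m)) data.frame(loop_idx = m$a_idx, prom_idx = m$b_idx_p,
                            ocr_idx = m$b_idx_o) else NULL
  }
  hits <- rbind(h1, h2)
  if (is.null(hits) || !nrow(hits)) return(empty)
  raw <- data.frame(ocr_id = ocrs$peak_id[hits$ocr_idx],
                    gene_id = promoters$gene_id[hits$prom_idx],
                    tss = promoters$tss[hits$prom_idx],
                    loop_id = loops$loop_id[hits$loop_idx],
                    stringsAsFactors = FALSE)
  loop_tp <- as.matrix(loops[, tp_cols(), drop = FALSE])[hits$loop_idx, ,
                                                         drop = FALSE]
  ocr_tp <- as.matrix(ocrs[, tp_cols(), drop = FALSE])[hits$ocr_idx, ,
                                                       drop = FALSE]
  supp <- loop_tp & ocr_tp
  key <- paste(raw$ocr_id, raw$gene_id, sep = "\r")
  sp <- split(seq_len(nrow(raw)), key)
  ocr_prom <- intersect_intervals(ocrs, promoters, check_sorted = FALSE)
  prox_key <- unique(paste(ocrs$peak_id[ocr_prom$a_idx],
                           promoters$gene_id[ocr_prom$b_idx], sep = "\r"))
  out <- do.call(rbind, lapply(sp, function(i) {
    flags <- colSums(supp[i, , drop = FALSE]) > 0
    k <- paste(raw$ocr_id[i[1]], raw$gene_id[i[1]], sep = "\r")
    data.frame(ocr_id = raw$ocr_id[i[1]], gene_id = raw$gene_id[i[1]],
               tss = min(raw$tss[i]),
               timepoints = paste(TIMEPOINTS[flags], collapse = ","),
               tp_unstim = flags[1], tp_8h = flags[2], tp_24h = flags[3],
               loop_ids = paste(sort(unique(raw$loop_id[i])), collapse = ","),
               class = if (k %in% prox_key) "promoter-proximal" else "distal",
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$gene_id, out$ocr_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
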