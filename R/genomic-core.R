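#' @importFrom stats qnorm pnorm rnorm runif rbinom cor kmeans median p.adjust
#' @importFrom utils read.delim write.table head
NULL

#' Canonical activation timepoints
#'
#' The three T-cell activation states used throughout the pipeline:
#' unstimulated, 8 hours and 24 hours post anti-CD3/CD28 stimulation.
#' @export
TIMEPOINTS <- c("unstim", "8h", "24h")

# column names holding per-timepoint logical flags on OCRs/loops/contacts
tp_cols <- function() paste0("tp_", c("unstim", "8h", "24h"))

#' Construct a genomic-interval table
#'
#' Intervals are 0-based half-open `[start, end)` everywhere inside the
#' package; BED is native, GTF and summary-statistic positions are converted
#' on read.
#'
#' @param chrom chromosome names (non-empty strings)
#' @param start 0-based inclusive start positions
#' @param end exclusive end positions; `end > start` required
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded)
#' @param name optional feature names
#' @return data.frame with columns chrom, start, end, strand, name
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", name = NA_character_) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), strand = strand, name = name,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' Checks the package's coordinate invariants: non-empty chromosome names,
#' integer coordinates, `0 <= start < end`.
#'
#' @param df data.frame with chrom/start/end columns
#' @param what label used in error messages
#' @return `df`, invisibly, on success
#' @export
validate_intervals <- function(df, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(is.na(df$chrom) | !nzchar(df$chrom))
  if (length(bad)) stop(sprintf("%s %d: empty chromosome name", what, bad[1]))
  if (anyNA(df$start) || anyNA(df$end))
    stop(sprintf("%s: non-integer coordinate", what))
  bad <- which(df$start < 0)
  if (length(bad)) stop(sprintf("%s %d: negative start", what, bad[1]))
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(sprintf("%s %d: start >= end (%d >= %d)", what, bad[1],
                 df$start[bad[1]], df$end[bad[1]]))
  invisible(df)
}

#' Normalize chromosome naming dialect
#'
#' @param x chromosome names
#' @param chr_prefix `"keep"` (default), `"add"` (ensure a `chr` prefix) or
#'   `"strip"` (remove it); matching elsewhere is exact string equality.
#' @return normalized names
#' @export
normalize_chrom <- function(x, chr_prefix = c("keep", "add", "strip")) {
  chr_prefix <- match.arg(chr_prefix)
  x <- as.character(x)
  if (chr_prefix == "add") {
    miss <- !startsWith(x, "chr")
    x[miss] <- paste0("chr", x[miss])
  } else if (chr_prefix == "strip") {
    x <- sub("^chr", "", x)
  }
  x
}

# 0-based half-open data.frame -> GRanges (1-based closed internally);
# `levels` fixes a common seqlevel universe so disjoint chromosome sets
# compare silently
as_granges <- function(df, levels = unique(df$chrom)) {
  GenomicRanges::GRanges(factor(df$chrom, levels = levels),
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' All overlapping pairs between two interval sets
#'
#' Overlap means at least one shared base under half-open semantics.
#' Backed by `GenomicRanges::findOverlaps()`; indices refer to the input
#' row order. Inputs are expected sorted by (chrom, start); unsorted input
#' is accepted with a warning (results are identical).
#'
#' @param a,b interval data.frames (chrom/start/end)
#' @param check_sorted warn when inputs are unsorted (internal callers that
#'   construct derived interval sets disable the check)
#' @return data.frame with columns `a_idx`, `b_idx`, ordered by `a_idx`
#'   then `b_idx`
#' @export
intersect_intervals <- function(a, b, check_sorted = TRUE) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  if (check_sorted) for (nm in c("a", "b")) {
    df <- if (nm == "a") a else b
    if (nrow(df) > 1) {
      o <- order(df$chrom, df$start)
      if (any(o != seq_along(o)))
        warning(sprintf("input '%s' is not sorted by (chrom, start); sorting internally",
                        nm))
    }
  }
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(a_idx = integer(0), b_idx = integer(0)))
  lev <- unique(c(a$chrom, b$chrom))
  hits <- GenomicRanges::findOverlaps(as_granges(a, lev), as_granges(b, lev))
  out <- data.frame(a_idx = S4Vectors::queryHits(hits),
                    b_idx = S4Vectors::subjectHits(hits))
  out[order(out$a_idx, out$b_idx), , drop = FALSE]
}

#' Construct a gene-model table
#'
#' One row per gene; `tss` is a list column of 0-based TSS positions
#' (multi-TSS genes are first-class: most human genes have several
#' alternative transcription start sites).
#'
#' @param gene_id unique stable identifiers
#' @param symbol display symbols
#' @param chrom chromosome per gene
#' @param strand `"+"` or `"-"`
#' @param tss list of integer vectors of 0-based TSS positions
#' @param biotype e.g. `"protein_coding"`
#' @return data.frame with list column `tss`
#' @export
gene_table <- function(gene_id, symbol, chrom, strand, tss, biotype) {
  if (anyDuplicated(gene_id)) stop("duplicate gene_id in annotation set")
  if (!all(strand %in% c("+", "-"))) stop("unknown strand symbol in gene table")
  tss <- lapply(tss, function(t) sort(unique(as.integer(t))))
  if (any(vapply(tss, length, 1L) == 0)) stop("gene with empty tss_list")
  df <- data.frame(gene_id = as.character(gene_id), symbol = as.character(symbol),
                   chrom = as.character(chrom), strand = strand,
                   biotype = as.character(biotype), stringsAsFactors = FALSE)
  df$tss <- I(tss)
  df
}

#' Strand-aware promoter windows around every TSS
#'
#' The promoter is the window from 1500 bp upstream to 500 bp downstream of
#' the TSS in the direction of transcription: plus-strand TSS `t` gives
#' `[t-1500, t+500)`, minus-strand gives `[t-500, t+1500)`. Windows are
#' clipped at position 0 and at the chromosome end, so length is 2000 bp
#' unless clipped. With `strand_aware = FALSE` every TSS gets
#' `[t-1500, t+500)` regardless of strand.
#'
#' @param genes gene table (see [gene_table()])
#' @param chrom_lengths optional named vector of chromosome lengths used for
#'   right clipping
#' @param upstream,downstream window extent in bp (defaults 1500/500)
#' @param strand_aware logical, default TRUE
#' @return data.frame: gene_id, tss, chrom, start, end, strand
#' @export
promoter_windows <- function(genes, chrom_lengths = NULL,
                             upstream = 1500L, downstream = 500L,
                             strand_aware = TRUE) {
  n_tss <- vapply(genes$tss, length, 1L)
  idx <- rep(seq_len(nrow(genes)), n_tss)
  tss <- unlist(genes$tss, use.names = FALSE)
  strand <- genes$strand[idx]
  minus <- strand_aware & strand == "-"
  start <- ifelse(minus, tss - downstream, tss - upstream)
  end <- ifelse(minus, tss + upstream, tss + downstream)
  start <- pmax(start, 0L)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[genes$chrom[idx]]
    end <- ifelse(is.na(lim), end, pmin(end, lim))
  }
  data.frame(gene_id = genes$gene_id[idx], tss = as.integer(tss),
             chrom = genes$chrom[idx], start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

#' Distance from a position to the nearest TSS of a gene
#'
#' Minimum absolute distance over the gene's TSS list; errors if the
#' position is on a different chromosome.
#'
#' @param pos 0-based position
#' @param chrom chromosome of `pos`
#' @param gene single-row slice of a gene table
#' @return non-negative integer distance in bp
#' @export
distance_to_tss <- function(pos, chrom, gene) {
  if (gene$chrom[1] != chrom)
    stop(sprintf("chromosome mismatch: %s vs gene %s on %s",
                 chrom, gene$gene_id[1], gene$chrom[1]))
  min(abs(as.numeric(pos) - as.numeric(gene$tss[[1]])))
}

# vectorized min |pos - tss| for one tss vector
min_tss_dist <- function(pos, tss_vec) {
  vapply(pos, function(p) min(abs(as.numeric(p) - as.numeric(tss_vec))), 0)
}

#' Nearest gene to a position
#'
#' Gene minimizing the TSS distance on the same chromosome; ties are broken
#' by lexicographically smallest `gene_id`.
#'
#' @inheritParams distance_to_tss
#' @param genes gene table
#' @return the winning `gene_id`
#' @export
nearest_gene <- function(pos, chrom, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) stop(sprintf("no genes on chromosome %s", chrom))
  d <- vapply(g$tss, function(t) min(abs(as.numeric(pos) - as.numeric(t))), 0)
  cand <- g$gene_id[d == min(d)]
  sort(cand)[1]
}

# variants (pos column) as 1-bp intervals [pos, pos+1)
variants_as_intervals <- function(df) {
  data.frame(chrom = df$chrom, start = as.integer(df$pos),
             end = as.integer(df$pos) + 1L, stringsAsFactors = FALSE)
}
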