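# File I/O for the standard dialects the pipeline consumes and emits.
# All readers are gzip-transparent (base R connections decompress on read).

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read a BED3/BED6 file
#'
#' BED's native 0-based half-open coordinates are preserved verbatim.
#' Columns beyond the sixth are ignored; column 4 becomes `name`, 5 `score`,
#' 6 `strand`. Malformed lines (non-integer coordinates, `start >= end`)
#' raise an error naming the line number. Lines starting with `track`,
#' `browser` or `#` are skipped.
#'
#' @param path BED file (optionally gzipped)
#' @return interval data.frame (chrom, start, end, name, score, strand)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3))
    stop(sprintf("BED parse error at line %d: fewer than 3 fields",
                 lineno[which(ncols < 3)[1]]))
  chrom <- vapply(parts, `[[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("BED parse error at line %d: non-integer coordinate", lineno[bad[1]]))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("BED parse error at line %d: start >= end", lineno[bad[1]]))
  bad <- which(start < 0)
  if (length(bad))
    stop(sprintf("BED parse error at line %d: negative start", lineno[bad[1]]))
  get_col <- function(k, default) {
    vapply(parts, function(p) if (length(p) >= k) p[[k]] else default, "")
  }
  data.frame(chrom = chrom, start = start, end = end,
             name = get_col(4, NA_character_),
             score = suppressWarnings(as.numeric(get_col(5, NA_character_))),
             strand = get_col(6, "*"),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' Emits BED3 when no name is present, BED6 otherwise; round-trips
#' byte-identically with [read_bed()] for canonical input.
#'
#' @param df interval data.frame
#' @param path output path
#' @export
write_bed <- function(df, path) {
  validate_intervals(df, "bed record")
  has6 <- !is.null(df$name) && any(!is.na(df$name))
  if (has6) {
    score <- if (is.null(df$score)) 0 else ifelse(is.na(df$score), 0, df$score)
    strand <- if (is.null(df$strand)) "*" else df$strand
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", df$chrom, df$start, df$end,
                     df$name, format(score, trim = TRUE, scientific = FALSE),
                     strand)
  } else {
    lines <- sprintf("%s\t%d\t%d", df$chrom, df$start, df$end)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an open-chromatin (OCR) consensus peak table
#'
#' BED6+ with extra tab-separated columns `tp_unstim`, `tp_8h`, `tp_24h`
#' (0/1 accessibility per timepoint) and `n_reps` (replicate support);
#' when the extra columns are absent, peaks are marked accessible at every
#' timepoint with `n_reps = 2` (the consensus minimum).
#'
#' @param path peak file
#' @return OCR data.frame: peak_id, chrom, start, end, tp_* flags, n_reps
#' @export
read_ocr_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1)
  has_header <- grepl("^chrom\t", first)
  if (has_header) {
    df <- read_tsv_checked(path)
    out <- data.frame(peak_id = df$peak_id, chrom = df$chrom,
                      start = as.integer(df$start), end = as.integer(df$end),
                      stringsAsFactors = FALSE)
    for (tc in tp_cols())
      out[[tc]] <- if (tc %in% names(df)) as.logical(df[[tc]] > 0) else TRUE
    out$n_reps <- if ("n_reps" %in% names(df)) as.integer(df$n_reps) else 2L
  } else {
    bed <- read_bed(path)
    out <- data.frame(peak_id = ifelse(is.na(bed$name),
                                       paste0("peak_", seq_len(nrow(bed))),
                                       bed$name),
                      chrom = bed$chrom, start = bed$start, end = bed$end,
                      stringsAsFactors = FALSE)
    for (tc in tp_cols()) out[[tc]] <- TRUE
    out$n_reps <- 2L
  }
  validate_ocrs(out)
  out
}

#' Validate an OCR table
#'
#' Consensus OCR invariants: valid intervals, at least one timepoint flag
#' set, replicate support of at least 2.
#' @param ocrs OCR data.frame
#' @return `ocrs`, invisibly
#' @export
validate_ocrs <- function(ocrs) {
  validate_intervals(ocrs, "OCR")
  flags <- as.matrix(ocrs[, tp_cols(), drop = FALSE])
  if (nrow(ocrs) && any(rowSums(flags) == 0))
    stop("OCR with no accessible timepoint")
  if (nrow(ocrs) && any(ocrs$n_reps < 2))
    stop("consensus OCR with replicate support < 2")
  if (anyDuplicated(ocrs$peak_id)) stop("duplicate peak_id")
  invisible(ocrs)
}

#' Write an OCR table
#' @param ocrs OCR data.frame
#' @param path output path
#' @export
write_ocr_bed <- function(ocrs, path) {
  df <- ocrs
  for (tc in tp_cols()) df[[tc]] <- as.integer(df[[tc]])
  write.table(df[, c("chrom", "start", "end", "peak_id", tp_cols(), "n_reps")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  # prepend header for round-trip clarity
  lines <- readLines(path)
  writeLines(c(paste(c("chrom", "start", "end", "peak_id", tp_cols(), "n_reps"),
                     collapse = "\t"), lines), path)
  invisible(path)
}

#' Read gene models from a TSV gene table or a GTF
#'
#' The TSV dialect has a header `gene_id, symbol, chrom, strand, tss_csv,
#' biotype` with `tss_csv` a comma-separated list of 1-based TSS positions.
#' GTF input uses `transcript` records: the TSS is the record start for
#' `+`-strand transcripts and the record end for `-`-strand ones, converted
#' from 1-based closed GTF coordinates to the package's 0-based convention.
#'
#' @param path TSV or GTF file (`.gtf`/`.gtf.gz` detected by extension or
#'   by sniffing a 9-field tab layout)
#' @return gene table (see [gene_table()])
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 5)
  first <- first[!grepl("^#", first)]
  is_gtf <- grepl("\\.gtf(\\.gz)?$", path) ||
    (length(first) && length(strsplit(first[1], "\t")[[1]]) == 9)
  if (is_gtf) return(read_gtf_genes(path))
  df <- read_tsv_checked(path)
  need <- c("gene_id", "symbol", "chrom", "strand", "tss_csv", "biotype")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  tss <- lapply(strsplit(as.character(df$tss_csv), ","), function(x) {
    v <- suppressWarnings(as.integer(x))
    if (anyNA(v)) stop("non-integer TSS in tss_csv")
    v - 1L   # 1-based annotation input -> 0-based storage
  })
  gene_table(df$gene_id, df$symbol, df$chrom, df$strand, tss, df$biotype)
}

read_gtf_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9)) stop("malformed GTF: expected 9 fields")
  feature <- vapply(parts, `[[`, "", 3)
  keep <- feature == "transcript"
  if (!any(keep)) stop("GTF contains no transcript records")
  parts <- parts[keep]
  chrom <- vapply(parts, `[[`, "", 1)
  start1 <- as.integer(vapply(parts, `[[`, "", 4))   # 1-based inclusive
  end1 <- as.integer(vapply(parts, `[[`, "", 5))
  strand <- vapply(parts, `[[`, "", 7)
  if (!all(strand %in% c("+", "-"))) stop("unknown strand symbol in GTF")
  attrs <- vapply(parts, `[[`, "", 9)
  get_attr <- function(key) {
    m <- regmatches(attrs, regexpr(sprintf('%s "[^"]*"', key), attrs))
    out <- rep(NA_character_, length(attrs))
    hit <- grepl(sprintf('%s "', key), attrs)
    out[hit] <- sub(sprintf('%s "([^"]*)"', key), "\\1",
                    regmatches(attrs, regexpr(sprintf('%s "[^"]*"', key), attrs)))
    out
  }
  gene_id <- get_attr("gene_id")
  if (anyNA(gene_id)) stop("GTF transcript without gene_id attribute")
  symbol <- get_attr("gene_name"); symbol[is.na(symbol)] <- gene_id[is.na(symbol)]
  biotype <- get_attr("gene_biotype")
  bt2 <- get_attr("gene_type"); biotype[is.na(biotype)] <- bt2[is.na(biotype)]
  biotype[is.na(biotype)] <- "protein_coding"
  tss0 <- ifelse(strand == "+", start1 - 1L, end1 - 1L)  # to 0-based
  sp <- split(seq_along(gene_id), gene_id)
  ids <- names(sp)
  chrom_g <- vapply(sp, function(i) {
    u <- unique(chrom[i])
    if (length(u) > 1) stop(sprintf("gene %s on conflicting chromosomes",
                                    gene_id[i[1]]))
    u
  }, "")
  gene_table(ids,
             vapply(sp, function(i) symbol[i[1]], ""),
             chrom_g,
             vapply(sp, function(i) strand[i[1]], ""),
             lapply(sp, function(i) tss0[i]),
             vapply(sp, function(i) biotype[i[1]], ""))
}

#' Write a gene table in the package's TSV dialect
#'
#' TSS positions are written 1-based (`tss_csv`), mirroring annotation
#' conventions; [read_gene_table()] round-trips them back to 0-based.
#' @param genes gene table
#' @param path output path
#' @export
write_gene_table <- function(genes, path) {
  df <- data.frame(gene_id = genes$gene_id, symbol = genes$symbol,
                   chrom = genes$chrom, strand = genes$strand,
                   tss_csv = vapply(genes$tss,
                                    function(t) paste(t + 1L, collapse = ","), ""),
                   biotype = genes$biotype, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' Tab-separated with header `variant_id, chrom, pos, p_value, sentinel_id,
#' trait` and optional `beta`, `se`. Input positions are 1-based and stored
#' 0-based. p-values must lie in (0, 1]; duplicates of
#' (variant_id, sentinel_id, trait) are rejected.
#'
#' @param path summary-statistics TSV
#' @return data.frame of summary-stat records (0-based `pos`)
#' @export
read_summary_stats <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("variant_id", "chrom", "pos", "p_value", "sentinel_id", "trait")
  if (!all(need %in% names(df)))
    stop("summary stats must have columns: ", paste(need, collapse = ", "))
  df$pos <- as.integer(df$pos) - 1L
  df$p_value <- as.numeric(df$p_value)
  validate_summary_stats(df)
  df
}

#' Validate summary-statistic records
#' @param df summary-stat data.frame (0-based pos)
#' @return `df`, invisibly
#' @export
validate_summary_stats <- function(df) {
  if (any(is.na(df$p_value) | df$p_value <= 0 | df$p_value > 1))
    stop("p_value outside (0, 1]")
  if (any(is.na(df$sentinel_id) | !nzchar(df$sentinel_id)))
    stop("empty sentinel_id")
  key <- paste(df$variant_id, df$sentinel_id, df$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (variant_id, sentinel_id, trait) record")
  invisible(df)
}

#' Write summary statistics (positions back to 1-based)
#' @param df summary-stat data.frame with 0-based pos
#' @param path output path
#' @export
write_summary_stats <- function(df, path) {
  out <- df
  out$pos <- as.integer(out$pos) + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read chromatin loops from BEDPE
#'
#' Ten standard BEDPE columns (chrom1 start1 end1 chrom2 start2 end2 name
#' score strand1 strand2) followed by `resolution`, `timepoint` and
#' `qvalue`. Loop significance filtering is assumed done upstream (e.g.
#' Fit-Hi-C FDR thresholds); records are kept unless `max_q` is given.
#'
#' @param path BEDPE file
#' @param max_q optional significance cutoff; loops with `qvalue > max_q`
#'   are dropped
#' @return loop data.frame: loop_id, chrom, start1, end1, start2, end2,
#'   resolution, timepoint, qvalue
#' @export
read_loops_bedpe <- function(path, max_q = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(empty_loops())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 13))
    stop(sprintf("BEDPE parse error at line %d: expected 13 fields",
                 which(lengths(parts) < 13)[1]))
  f <- function(k) vapply(parts, `[[`, "", k)
  df <- data.frame(chrom1 = f(1), start1 = as.integer(f(2)), end1 = as.integer(f(3)),
                   chrom2 = f(4), start2 = as.integer(f(5)), end2 = as.integer(f(6)),
                   loop_id = f(7), resolution = as.integer(f(11)),
                   timepoint = f(12), qvalue = as.numeric(f(13)),
                   stringsAsFactors = FALSE)
  loops <- data.frame(loop_id = df$loop_id, chrom = df$chrom1,
                      start1 = df$start1, end1 = df$end1,
                      start2 = df$start2, end2 = df$end2,
                      resolution = df$resolution, timepoint = df$timepoint,
                      qvalue = df$qvalue, stringsAsFactors = FALSE)
  if (any(df$chrom1 != df$chrom2))
    stop("trans-chromosomal loop in BEDPE (intra-chromosomal loops only)")
  if (!is.null(max_q)) loops <- loops[loops$qvalue <= max_q, , drop = FALSE]
  canonicalize_loops(loops)
}

empty_loops <- function() {
  data.frame(loop_id = character(0), chrom = character(0),
             start1 = integer(0), end1 = integer(0),
             start2 = integer(0), end2 = integer(0),
             resolution = integer(0), timepoint = character(0),
             qvalue = numeric(0), stringsAsFactors = FALSE)
}

#' Write loops as BEDPE (13 columns)
#' @param loops loop data.frame
#' @param path output path
#' @export
write_loops_bedpe <- function(loops, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t.\t.\t.\t%d\t%s\t%g",
                   loops$chrom, loops$start1, loops$end1,
                   loops$chrom, loops$start2, loops$end2,
                   loops$loop_id, loops$resolution, loops$timepoint,
                   loops$qvalue)
  writeLines(lines, path)
  invisible(path)
}

#' Read a truth-set gene list
#'
#' Plain text, one gene symbol per line; an optional single header line
#' (`gene`, `symbol` or `gene_id`) is skipped. Symbols are upper-cased for
#' matching.
#'
#' @param path text file
#' @param name truth-set label (defaults to the file name)
#' @return list with `name` and `gene_ids` (unique, upper-case)
#' @export
read_truth_set <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- trimws(readLines(path))
  x <- x[nzchar(x)]
  if (length(x) && tolower(x[1]) %in% c("gene", "symbol", "gene_id")) x <- x[-1]
  if (!length(x)) stop("empty truth set")
  list(name = name, gene_ids = unique(toupper(x)))
}
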