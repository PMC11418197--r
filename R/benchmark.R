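# Benchmarking of effector-gene predictions: precision/recall against
# curated truth sets, pairwise concordance between prediction sets, a
# permutation enrichment test against genes within 1 Mb of each sentinel,
# and a one-sided two-proportion enrichment test.

norm_symbols <- function(x) unique(toupper(trimws(x)))

#' Precision and recall of a predicted gene set
#'
#' Precision is the fraction of predicted genes that are in the truth set;
#' recall is the fraction of truth-set genes that are predicted. Symbols
#' are matched after upper-casing. Both sets must be non-empty (precision
#' is undefined for an empty prediction).
#'
#' @param predicted character vector of predicted gene symbols
#' @param truth character vector of truth-set symbols, or the list returned
#'   by [read_truth_set()]
#' @return list: n_predicted, n_truth, overlap, precision, recall
#' @export
precision_recall <- function(predicted, truth) {
  if (is.list(truth) && !is.null(truth$gene_ids)) truth <- truth$gene_ids
  P <- norm_symbols(predicted); Tr <- norm_symbols(truth)
  if (!length(P)) stop("empty predicted set: precision undefined")
  if (!length(Tr)) stop("empty truth set")
  ov <- length(intersect(P, Tr))
  list(n_predicted = length(P), n_truth = length(Tr), overlap = ov,
       precision = ov / length(P), recall = ov / length(Tr))
}

#' Concordance between two gene sets
#'
#' The study's "percent overlap" leaves its denominator unstated, so all
#' normalizations are reported: overlap as a fraction of either set and the
#' Jaccard index.
#'
#' @param a,b character vectors of gene symbols (non-empty)
#' @return list: overlap, frac_of_a, frac_of_b, jaccard
#' @export
concordance <- function(a, b) {
  A <- norm_symbols(a); B <- norm_symbols(b)
  if (!length(A) || !length(B)) stop("empty gene set")
  ov <- length(intersect(A, B))
  list(overlap = ov, frac_of_a = ov / length(A), frac_of_b = ov / length(B),
       jaccard = ov / length(union(A, B)))
}

#' Permutation configuration for the 1 Mb enrichment null
#'
#' @param window bp around each sentinel defining the null gene universe
#'   (default 1,000,000: genes with at least one TSS within +/- 1 Mb)
#' @param iterations permutation count (default 10,000)
#' @param seed optional RNG seed (NULL: use the current RNG state)
#' @param sample_without_replacement if TRUE, each iteration draws a
#'   sentinel's replacement genes without replacement (default FALSE:
#'   per-pair independent uniform draws)
#' @return a `permutation_config` list
#' @export
permutation_config <- function(window = 1e6, iterations = 10000,
                               seed = NULL,
                               sample_without_replacement = FALSE) {
  stopifnot(window > 0, iterations >= 1)
  structure(list(window = window, iterations = as.integer(iterations),
                 seed = seed,
                 sample_without_replacement = sample_without_replacement),
            class = "permutation_config")
}

#' Permutation enrichment of observed sentinel-gene pairs
#'
#' Counts how many comparison pairs (e.g. co-localized eQTL sentinel-gene
#' assignments) are also present in the V2G pair set, then builds a null by
#' replacing each comparison pair's gene with one drawn uniformly from the
#' genes having a TSS within `window` of that sentinel, recounting over
#' `iterations` draws. The empirical p-value uses the add-one correction
#' `(1 + #\{null >= observed\}) / (1 + iterations)`, so it can never be 0;
#' fold is observed over the null mean. Sentinels with an empty window
#' universe are excluded with a warning.
#'
#' @param comparison data.frame (sentinel_id, gene_id): the external
#'   pairs being tested for overlap with the V2G predictions
#' @param v2g_pairs data.frame (sentinel_id, gene_id): the V2G pair set
#' @param genes gene table (TSS positions define the window universe)
#' @param sentinels data.frame (sentinel_id, chrom, pos): sentinel
#'   positions, 0-based
#' @param config [permutation_config()]
#' @return list: observed, null_draws, empirical_p, fold, n_pairs_used,
#'   excluded_sentinels
#' @export
permutation_enrichment <- function(comparison, v2g_pairs, genes, sentinels,
                                   config = permutation_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  v2g_key <- unique(paste(v2g_pairs$sentinel_id, toupper(v2g_pairs$gene_id),
                          sep = "\r"))
  sidx <- match(comparison$sentinel_id, sentinels$sentinel_id)
  if (anyNA(sidx)) stop("comparison pair with unknown sentinel")
  # per-sentinel gene universe: >=1 TSS within +/- window
  universes <- lapply(unique(comparison$sentinel_id), function(s) {
    i <- match(s, sentinels$sentinel_id)
    g <- genes[genes$chrom == sentinels$chrom[i], , drop = FALSE]
    if (!nrow(g)) return(character(0))
    d <- vapply(g$tss, function(t)
      min(abs(as.numeric(sentinels$pos[i]) - as.numeric(t))), 0)
    g$gene_id[d <= config$window]
  })
  names(universes) <- unique(comparison$sentinel_id)
  empty <- names(universes)[lengths(universes) == 0]
  if (length(empty)) {
    warning(sprintf("%d sentinel(s) with empty %g bp gene universe excluded",
                    length(empty), config$window))
    comparison <- comparison[!comparison$sentinel_id %in% empty, ,
                             drop = FALSE]
  }
  if (!nrow(comparison)) stop("no comparison pairs with usable sentinels")
  observed <- sum(paste(comparison$sentinel_id, toupper(comparison$gene_id),
                        sep = "\r") %in% v2g_key)
  iters <- config$iterations
  null_draws <- integer(iters)
  if (config$sample_without_replacement) {
    sp <- split(seq_len(nrow(comparison)), comparison$sentinel_id)
    for (it in seq_len(iters)) {
      tot <- 0L
      for (s in names(sp)) {
        u <- universes[[s]]
        k <- min(length(sp[[s]]), length(u))
        drawn <- u[sample.int(length(u), k)]
        tot <- tot + sum(paste(s, toupper(drawn), sep = "\r") %in% v2g_key)
      }
      null_draws[it] <- tot
    }
  } else {
    # per-pair independent draws, vectorized over iterations
    for (i in seq_len(nrow(comparison))) {
      u <- universes[[comparison$sentinel_id[i]]]
      hit <- paste(comparison$sentinel_id[i], toupper(u), sep = "\r") %in%
        v2g_key
      null_draws <- null_draws +
        hit[sample.int(length(u), iters, replace = TRUE)]
    }
  }
  empirical_p <- (1 + sum(null_draws >= observed)) / (1 + iters)
  list(observed = observed, null_draws = null_draws,
       empirical_p = empirical_p,
       fold = observed / mean(null_draws),
       n_pairs_used = nrow(comparison), excluded_sentinels = empty)
}

#' One-sided two-proportion enrichment test
#'
#' Tests whether the proportion of hits in the gene set exceeds the
#' background proportion, using the continuity-corrected two-sample
#' proportion test (R's `prop.test`, the tool the source analyses used),
#' one-sided "greater". The ratio is the plain proportion ratio (relative
#' enrichment); it is `NA` with a warning when the background proportion is
#' 0 (the p-value is still computed).
#'
#' @param hits_in_set,set_size hit count and size of the gene set
#' @param hits_in_background,background_size background counts
#' @return list: ratio, statistic (signed z), p
#' @export
proportion_enrichment <- function(hits_in_set, set_size,
                                  hits_in_background, background_size) {
  stopifnot(hits_in_set >= 0, hits_in_background >= 0,
            set_size > 0, background_size > 0,
            hits_in_set <= set_size, hits_in_background <= background_size)
  p1 <- hits_in_set / set_size
  p2 <- hits_in_background / background_size
  ratio <- if (p2 == 0) { warning("zero background proportion: ratio undefined")
                          NA_real_ } else p1 / p2
  pt <- suppressWarnings(
    prop.test(c(hits_in_set, hits_in_background),
              c(set_size, background_size),
              alternative = "greater", correct = TRUE))
  z <- sign(p1 - p2) * sqrt(unname(pt$statistic))
  list(ratio = ratio, statistic = z, p = pt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment for a family of p-values (wraps
#' `stats::p.adjust`), with input-range validation.
#'
#' @param p p-values in \[0, 1\]
#' @return adjusted p-values
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' @importFrom stats prop.test
NULL
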