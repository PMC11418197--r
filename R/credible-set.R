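# Fine-mapping by approximate Bayes factors: each association signal's
# p-values become z-scores, then Bayes factors, then normalized posterior
# probabilities; variants are added in decreasing posterior order until the
# cumulative posterior reaches the coverage target (default 95%).

#' Fine-mapping configuration
#'
#' @param prior_w prior variance W of the effect size under the alternative
#'   (Wakefield approximation); default 0.04, i.e. a prior SD of 0.2 on the
#'   log-odds/standardized-effect scale
#' @param trait_v sampling variance V used when standard errors are absent;
#'   default 1 (the z-score scale)
#' @param bf_mode `"wakefield"` (default) for the shrinkage ABF
#'   `sqrt(V/(V+W)) * exp(z^2 W / (2 (V+W)))`, or `"z2"` for the simpler
#'   `exp(z^2 / 2)` kernel
#' @param coverage cumulative posterior target in (0,1); default 0.95
#' @param p_floor p-values below this are floored before the normal-quantile
#'   transform (numeric stability for genome-wide hits); default 1e-300
#' @param renormalize_after_filter logical; if TRUE,
#'   [constrain_to_ocr()] renormalizes posteriors within the accessible set
#'   (default FALSE: the accessible set is a plain filter of the 95% set)
#' @return a `fine_map_config` list
#' @export
fine_map_config <- function(prior_w = 0.04, trait_v = 1,
                            bf_mode = c("wakefield", "z2"),
                            coverage = 0.95, p_floor = 1e-300,
                            renormalize_after_filter = FALSE) {
  bf_mode <- match.arg(bf_mode)
  stopifnot(prior_w > 0, trait_v > 0, coverage > 0, coverage < 1)
  structure(list(prior_w = prior_w, trait_v = trait_v, bf_mode = bf_mode,
                 coverage = coverage, p_floor = p_floor,
                 renormalize_after_filter = renormalize_after_filter),
            class = "fine_map_config")
}

#' Two-sided p-value to absolute z-score
#'
#' `z = Phi^{-1}(1 - p/2)`, the magnitude of the standard-normal deviate
#' whose two-sided tail probability is `p`. Monotone decreasing in `p`.
#'
#' @param p p-values in (0, 1]
#' @param p_floor lower floor applied before the quantile transform
#' @return non-negative z-scores
#' @export
p_to_z <- function(p, p_floor = 1e-300) {
  if (any(is.na(p) | p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  p <- pmax(p, p_floor)
  qnorm(p / 2, lower.tail = FALSE)
}

# log Bayes factor; computed in log space so that z2 mode cannot overflow
log_variant_bf <- function(z, config = fine_map_config()) {
  if (any(!is.finite(z))) stop("non-finite z")
  if (config$bf_mode == "wakefield") {
    v <- config$trait_v; w <- config$prior_w
    0.5 * log(v / (v + w)) + z^2 * w / (2 * (v + w))
  } else {
    z^2 / 2
  }
}

#' Approximate Bayes factor in favor of association
#'
#' Wakefield mode: `sqrt(V/(V+W)) * exp(z^2 W / (2(V+W)))`; z2 mode:
#' `exp(z^2/2)`. Strictly increasing in `|z|` in both modes. May overflow
#' to `Inf` for extreme z in z2 mode; posterior probabilities are always
#' computed in log space and remain finite.
#'
#' @param z non-negative z-scores
#' @param config [fine_map_config()]
#' @return Bayes factors
#' @export
variant_bf <- function(z, config = fine_map_config()) {
  exp(log_variant_bf(z, config))
}

#' Per-variant posterior probabilities within one signal
#'
#' `pp_i = BF_i / sum_j BF_j`, evaluated via a log-sum-exp so extreme
#' z-scores stay finite. Sums to 1 over the signal.
#'
#' @param p p-values of all variants of one association signal
#' @param config [fine_map_config()]
#' @return posterior probabilities summing to 1
#' @export
posterior_probabilities <- function(p, config = fine_map_config()) {
  if (!length(p)) stop("empty signal")
  z <- p_to_z(p, config$p_floor)
  lbf <- log_variant_bf(z, config)
  m <- max(lbf)
  w <- exp(lbf - m)
  s <- sum(w)
  if (!is.finite(s) || s <= 0) stop("all Bayes factors zero or non-finite")
  w / s
}

#' Build the 95% credible set for one association signal
#'
#' Variants are ordered from highest to lowest posterior probability and
#' added until the cumulative sum reaches the coverage target (inclusive
#' threshold, evaluated with a 1e-12 tolerance so exact-boundary sums such
#' as 19 x 0.05 = 0.95 are kept minimal). Ordering ties are broken by
#' ascending p-value, then ascending position, then variant_id.
#'
#' @param signal data.frame of summary-stat records for one sentinel
#'   (columns variant_id, chrom, pos, p_value, sentinel_id, trait)
#' @param config [fine_map_config()]
#' @return the signal with columns `z`, `bf`, `pp`, `cum_pp`,
#'   `in_credible_set` added, sorted in credible-set order
#' @export
build_credible_set <- function(signal, config = fine_map_config()) {
  stopifnot(nrow(signal) >= 1)
  if (length(unique(signal$sentinel_id)) != 1 ||
      length(unique(signal$trait)) != 1)
    stop("build_credible_set expects records of a single (sentinel, trait)")
  validate_summary_stats(signal)
  out <- signal
  out$z <- p_to_z(out$p_value, config$p_floor)
  out$bf <- variant_bf(out$z, config)
  out$pp <- posterior_probabilities(out$p_value, config)
  o <- order(-out$pp, out$p_value, out$pos, out$variant_id)
  out <- out[o, , drop = FALSE]
  out$cum_pp <- cumsum(out$pp)
  k <- which(out$cum_pp >= config$coverage - 1e-12)[1]
  if (is.na(k)) k <- nrow(out)   # numerical shortfall: keep everything
  out$in_credible_set <- seq_len(nrow(out)) <= k
  rownames(out) <- NULL
  out
}

#' Build credible sets for every (sentinel, trait) signal in a table
#'
#' @param stats full summary-stat table
#' @param config [fine_map_config()]
#' @return row-bound credible-set tables (see [build_credible_set()])
#' @export
build_credible_sets <- function(stats, config = fine_map_config()) {
  key <- paste(stats$sentinel_id, stats$trait, sep = "\r")
  parts <- lapply(split(seq_len(nrow(stats)), key), function(i)
    build_credible_set(stats[i, , drop = FALSE], config))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Constrain credible sets to open chromatin
#'
#' Keeps credible-set members whose 1-bp interval `[pos, pos+1)` overlaps at
#' least one OCR accessible at any of the requested timepoints. Posterior
#' probabilities are retained unrenormalized unless the configuration asks
#' otherwise: the accessible set is a filter of the 95% set, not a new
#' credible set. The report records per-sentinel sizes before and after and
#' their cross-sentinel means (the study's 14 -> 3 style shrinkage).
#'
#' @param cs credible-set table from [build_credible_sets()]
#' @param ocrs OCR table
#' @param timepoints timepoints at which accessibility counts
#'   (default all of [TIMEPOINTS])
#' @param config [fine_map_config()]
#' @return list with `accessible` (filtered table plus `ocr_id`) and
#'   `report` (per-sentinel sizes and means)
#' @export
constrain_to_ocr <- function(cs, ocrs, timepoints = TIMEPOINTS,
                             config = fine_map_config()) {
  stopifnot(all(timepoints %in% TIMEPOINTS))
  members <- cs[cs$in_credible_set, , drop = FALSE]
  keep_tp <- paste0("tp_", sub("^tp_", "", timepoints))
  acc_flag <- rowSums(as.matrix(ocrs[, keep_tp, drop = FALSE])) > 0
  open <- ocrs[acc_flag, , drop = FALSE]
  if (nrow(members) && nrow(open)) {
    hits <- intersect_intervals(variants_as_intervals(members), open, check_sorted = FALSE)
    first <- !duplicated(hits$a_idx)
    ocr_of <- rep(NA_character_, nrow(members))
    ocr_of[hits$a_idx[first]] <- open$peak_id[hits$b_idx[first]]
    sel <- !is.na(ocr_of)
  } else {
    ocr_of <- rep(NA_character_, nrow(members))
    sel <- logical(nrow(members))
  }
  accessible <- members[sel, , drop = FALSE]
  accessible$ocr_id <- ocr_of[sel]
  if (nrow(accessible) == 0)
    warning("no credible-set variant overlaps an accessible OCR")
  if (isTRUE(config$renormalize_after_filter) && nrow(accessible)) {
    sp <- split(seq_len(nrow(accessible)),
                paste(accessible$sentinel_id, accessible$trait, sep = "\r"))
    for (i in sp) accessible$pp[i] <- accessible$pp[i] / sum(accessible$pp[i])
  }
  key <- unique(members[, c("sentinel_id", "trait")])
  before <- table(paste(members$sentinel_id, members$trait, sep = "\r"))
  after <- table(paste(accessible$sentinel_id, accessible$trait, sep = "\r"))
  kk <- paste(key$sentinel_id, key$trait, sep = "\r")
  report <- data.frame(sentinel_id = key$sentinel_id, trait = key$trait,
                       n_before = as.integer(before[kk]),
                       n_after = ifelse(is.na(after[kk]), 0L,
                                        as.integer(after[kk])),
                       stringsAsFactors = FALSE)
  list(accessible = accessible,
       report = list(per_sentinel = report,
                     mean_before = mean(report$n_before),
                     mean_after = mean(report$n_after)))
}
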