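# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's overlap/merge machinery: plain double/triple loops and
# direct formula evaluation.

# O(n*m) interval intersection: every (i, j) with >=1 shared base
oracle_intersect <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i])
      out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) return(data.frame(a_idx = integer(0), b_idx = integer(0)))
  m <- do.call(rbind, out)
  data.frame(a_idx = m[, 1], b_idx = m[, 2])
}

# direct-formula credible set: sort by descending pp with the tie rules,
# take the minimal prefix reaching coverage
oracle_credible_members <- function(signal, prior_w = 0.04, trait_v = 1,
                                    coverage = 0.95) {
  z <- qnorm(pmax(signal$p_value, 1e-300) / 2, lower.tail = FALSE)
  bf <- sqrt(trait_v / (trait_v + prior_w)) *
    exp(z^2 * prior_w / (2 * (trait_v + prior_w)))
  pp <- bf / sum(bf)
  o <- order(-pp, signal$p_value, signal$pos, signal$variant_id)
  cum <- cumsum(pp[o])
  k <- which(cum >= coverage - 1e-12)[1]
  if (is.na(k)) k <- length(o)
  signal$variant_id[o[seq_len(k)]]
}

# greedy fine-to-coarse loop merge with paired both-anchor overlap, O(n^2)
oracle_merge <- function(loops) {
  o <- order(loops$resolution, loops$chrom, loops$start1, loops$start2,
             loops$loop_id)
  loops <- loops[o, , drop = FALSE]
  finest <- min(loops$resolution)
  kept <- loops[loops$resolution == finest, , drop = FALSE]
  for (i in which(loops$resolution != finest)) {
    cand <- loops[i, , drop = FALSE]
    absorbed <- FALSE
    for (j in seq_len(nrow(kept))) {
      if (kept$chrom[j] == cand$chrom &&
          kept$start1[j] < cand$end1 && cand$start1 < kept$end1[j] &&
          kept$start2[j] < cand$end2 && cand$start2 < kept$end2[j]) {
        absorbed <- TRUE; break
      }
    }
    if (!absorbed) kept <- rbind(kept, cand)
  }
  kept
}

# triple loop over (loop, promoter window, OCR): set of "ocr\rgene" keys
oracle_contacts <- function(loops, promoters, ocrs) {
  keys <- character(0)
  ov <- function(c1, s1, e1, c2, s2, e2) c1 == c2 && s1 < e2 && s2 < e1
  for (l in seq_len(nrow(loops))) for (p in seq_len(nrow(promoters))) {
    p1 <- ov(loops$chrom[l], loops$start1[l], loops$end1[l],
             promoters$chrom[p], promoters$start[p], promoters$end[p])
    p2 <- ov(loops$chrom[l], loops$start2[l], loops$end2[l],
             promoters$chrom[p], promoters$start[p], promoters$end[p])
    if (!p1 && !p2) next
    for (k in seq_len(nrow(ocrs))) {
      o1 <- ov(loops$chrom[l], loops$start1[l], loops$end1[l],
               ocrs$chrom[k], ocrs$start[k], ocrs$end[k])
      o2 <- ov(loops$chrom[l], loops$start2[l], loops$end2[l],
               ocrs$chrom[k], ocrs$start[k], ocrs$end[k])
      if ((p1 && o2) || (p2 && o1))
        keys <- c(keys, paste(ocrs$peak_id[k], promoters$gene_id[p],
                              sep = "\r"))
    }
  }
  sort(unique(keys))
}

# textbook continuity-corrected one-sided two-proportion z test
oracle_prop_test <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  d <- p1 - p2
  cc <- min(abs(d), 0.5 * (1 / n1 + 1 / n2))
  z <- (d - sign(d) * cc) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  pnorm(z, lower.tail = FALSE)
}

# Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m); out[o] <- adj
  out
}

# random loop fixture over 1/2/4 kb bins on one chromosome
random_loop_fixture <- function(n, chrom_length = 2e6) {
  res <- sample(c(1000L, 2000L, 4000L), n, replace = TRUE)
  a <- vapply(res, function(r) (sample.int(chrom_length %/% r - 60L, 1) - 1L) * r,
              0L)
  b <- a + vapply(res, function(r) sample(2:50, 1), 0L) * res
  data.frame(loop_id = sprintf("L%03d", seq_len(n)), chrom = "chr1",
             start1 = a, end1 = a + res, start2 = b, end2 = b + res,
             resolution = res, timepoint = "unstim",
             qvalue = 1e-7, stringsAsFactors = FALSE)
}

# random summary-stat signal for one sentinel
random_signal <- function(n, sentinel = "s1", trait = "T1D") {
  data.frame(variant_id = sprintf("%s_v%03d", sentinel, seq_len(n)),
             chrom = "chr1",
             pos = sample.int(1e6, n),
             p_value = 10^runif(n, -8, 0),
             sentinel_id = sentinel, trait = trait,
             stringsAsFactors = FALSE)
}

# randomized PIT: exactly U(0,1) when `observed` is exchangeable with the
# null draws (standard fix for discrete empirical p-values)
randomized_pit <- function(res) {
  n <- length(res$null_draws)
  (sum(res$null_draws > res$observed) +
     runif(1) * (sum(res$null_draws == res$observed) + 1)) / (n + 1)
}
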