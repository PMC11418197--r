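# Expression-trajectory clustering (k-means with an elbow criterion and
# per-gene correlation to the cluster centroid) and the immune
# expression-specificity score (whole blood + spleen over other tissues).

#' Cluster differential-gene expression trajectories
#'
#' Rows (genes) are z-scored across conditions, then k-means is run for
#' every k in `k_range` (plus k-1 and k+1 at the edges so the curvature is
#' defined everywhere) with `nstart` restarts, keeping the best inertia.
#' The number of clusters is chosen by the elbow criterion: the k in
#' `k_range` maximizing the second difference of the within-cluster sum of
#' squares. By default the curvature is computed on log(WCSS)
#' (`elbow_scale = "log"`), which locates the kink of the WCSS curve
#' rather than its overall convexity; `elbow_scale = "raw"` uses the plain
#' WCSS second difference. Ties break toward smaller k.
#'
#' @param mat numeric matrix, genes x conditions (rownames = gene ids)
#' @param k_range candidate cluster counts, inside \[2, 15\]
#' @param seed RNG seed for reproducible restarts
#' @param nstart k-means restarts per k (>= 10 recommended)
#' @param scale_rows z-score each row before clustering (default TRUE)
#' @param elbow_scale `"log"` (default) or `"raw"` WCSS curvature
#' @return list: k, assignment (named integer vector), centers, wcss
#'   (data.frame k/wcss), r_to_centroid (per-gene Pearson r to own
#'   centroid), scaled matrix
#' @export
cluster_trajectories <- function(mat, k_range = 2:10, seed = NULL,
                                 nstart = 10, scale_rows = TRUE,
                                 elbow_scale = c("log", "raw")) {
  elbow_scale <- match.arg(elbow_scale)
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > 15)
    stop("k_range must lie within [2, 15]")
  if (nrow(mat) <= max(k_range))
    stop("fewer genes than the largest candidate k")
  Z <- mat
  if (scale_rows) {
    sds <- apply(mat, 1, sd)
    if (any(sds == 0)) {
      warning(sum(sds == 0), " zero-variance gene(s): flat after scaling")
      sds[sds == 0] <- 1
    }
    Z <- (mat - rowMeans(mat)) / sds
  }
  n_distinct <- nrow(unique(Z))
  if (n_distinct == 1) {
    warning("all trajectories identical: single effective cluster")
    assignment <- rep(1L, nrow(Z)); names(assignment) <- rownames(Z)
    return(list(k = 1L, assignment = assignment,
                centers = matrix(colMeans(Z), 1), wcss = NULL,
                r_to_centroid = rep(1, nrow(Z)), scaled = Z))
  }
  if (n_distinct <= max(k_range)) {
    warning("few distinct trajectories: restricting k_range")
    k_range <- k_range[k_range < n_distinct]
    if (!length(k_range)) k_range <- 2L
  }
  if (!is.null(seed)) set.seed(seed)
  ks <- (min(k_range) - 1L):(max(k_range) + 1L)
  ks <- ks[ks >= 1 & ks < n_distinct]
  fits <- list(); wcss <- numeric(length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    if (k == 1) {
      wcss[i] <- sum(sweep(Z, 2, colMeans(Z))^2)
    } else {
      fits[[as.character(k)]] <- kmeans(Z, centers = k, nstart = nstart,
                                        iter.max = 100)
      wcss[i] <- fits[[as.character(k)]]$tot.withinss
    }
  }
  w <- if (elbow_scale == "log") log(pmax(wcss, .Machine$double.eps)) else wcss
  d2 <- rep(-Inf, length(ks))
  for (i in seq_along(ks))
    if (i > 1 && i < length(ks)) d2[i] <- w[i - 1] - 2 * w[i] + w[i + 1]
  cand <- which(ks %in% k_range & is.finite(d2))
  if (!length(cand)) cand <- which(ks %in% k_range)
  k_best <- ks[cand[which.max(d2[cand])]]   # which.max takes the first: ties -> smaller k
  fit <- fits[[as.character(k_best)]]
  r <- vapply(seq_len(nrow(Z)), function(i)
    suppressWarnings(cor(Z[i, ], fit$centers[fit$cluster[i], ])), 0)
  assignment <- fit$cluster
  names(assignment) <- rownames(Z)
  list(k = k_best, assignment = assignment, centers = fit$centers,
       wcss = data.frame(k = ks, wcss = wcss),
       r_to_centroid = r, scaled = Z)
}

#' Pearson correlation of a trajectory to a cluster centroid
#'
#' @param x gene trajectory
#' @param centroid centroid trajectory of the same length
#' @return Pearson product-moment correlation
#' @export
centroid_correlation <- function(x, centroid) {
  if (length(x) != length(centroid)) stop("unequal trajectory lengths")
  if (sd(x) == 0 || sd(centroid) == 0) stop("zero-variance vector")
  cor(x, centroid)
}

#' Immune expression-specificity score
#'
#' Per gene, the sum of median expression over the immune tissues (whole
#' blood and spleen by default, after GTEx v8 tissue labels) divided by the
#' sum over all remaining tissues. Scale-invariant; genes with zero
#' expression everywhere else are flagged `undefined` (score `NA`).
#'
#' @param medians data.frame: `gene_id` column plus one numeric column per
#'   tissue of median expression
#' @param immune_tissues tissue column names forming the numerator
#' @return data.frame gene_id, immune_sum, other_sum, score, undefined
#' @export
specificity_score <- function(medians,
                              immune_tissues = c("Whole Blood", "Spleen")) {
  if (!all(immune_tissues %in% names(medians)))
    stop("missing immune tissue column(s): ",
         paste(setdiff(immune_tissues, names(medians)), collapse = ", "))
  tissue_cols <- setdiff(names(medians), "gene_id")
  others <- setdiff(tissue_cols, immune_tissues)
  if (!length(others)) stop("no non-immune tissues present")
  vals <- as.matrix(medians[, tissue_cols, drop = FALSE])
  if (any(vals < 0)) stop("negative expression value")
  immune_sum <- rowSums(vals[, immune_tissues, drop = FALSE])
  other_sum <- rowSums(vals[, others, drop = FALSE])
  undefined <- other_sum == 0
  score <- ifelse(undefined, NA_real_, immune_sum / other_sum)
  data.frame(gene_id = medians$gene_id, immune_sum = immune_sum,
             other_sum = other_sum, score = score, undefined = undefined,
             stringsAsFactors = FALSE)
}

#' @importFrom stats sd
NULL
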