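#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions of the same spots,
#' chance-corrected so that independent partitions score near 0 and
#' identical partitions score 1. When both partitions are the trivial
#' single-cluster partition the index is defined as 1.
#'
#' @param labels_a,labels_b label vectors of equal length
#' @return scalar ARI (at most 1)
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stopf("partitions have different lengths (%d vs %d)",
          length(labels_a), length(labels_b))
  n <- length(labels_a)
  if (n < 2) stopf("need at least 2 items")
  tab <- table(labels_a, labels_b)
  a <- rowSums(tab); b <- colSums(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(a, 2)); sum_b <- sum(choose(b, 2))
  exp_term <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - exp_term
  if (denom == 0) return(1)  # both partitions trivial (or identical blocks)
  (sum_ij - exp_term) / denom
}

#' Normalized mutual information
#'
#' Mutual information between two partitions, normalized by the arithmetic
#' mean of their entropies; in `[0, 1]` with 1 for matching partitions.
#' Two single-cluster partitions (0/0) score 1 by convention.
#'
#' @inheritParams ari
#' @return scalar NMI in `[0, 1]`
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stopf("partitions have different lengths (%d vs %d)",
          length(labels_a), length(labels_b))
  n <- length(labels_a)
  tab <- table(labels_a, labels_b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  ha <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  if (ha + hb == 0) return(1)
  pij <- tab[tab > 0]
  outer_p <- outer(pa, pb)[tab > 0]
  mi <- sum(pij * log(pij / outer_p))
  mi / ((ha + hb) / 2)
}

#' Baseline spatial clustering
#'
#' A simple, fully in-package spatial clustering used to analyse simulated
#' datasets (and as the pluggable default): k-means on the concatenation of
#' the top principal components of log2-CPM expression with the min-max
#' scaled coordinates weighted by `smooth_weight`. `smooth_weight = 0`
#' reduces to expression-only clustering.
#'
#' @param ds a [spatial_dataset()]
#' @param K number of clusters (>= 2)
#' @param smooth_weight weight of the coordinate block
#' @param n_pcs number of principal components
#' @param seed RNG seed (k-means with 10 restarts)
#' @return factor of cluster labels, one per spot
#' @export
baseline_spatial_clustering <- function(ds, K, smooth_weight = 0.5,
                                        n_pcs = 10L, seed = 1L) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (K < 2) stopf("K must be >= 2")
  n <- length(ds$spot_ids)
  if (K > n) stopf("K (%d) exceeds the spot count (%d)", K, n)
  lc <- t(log2cpm(ds$counts))                 # spots x genes
  keep <- apply(lc, 2, sd) > 0
  pcs <- prcomp(scale(lc[, keep, drop = FALSE]))$x
  pcs <- pcs[, seq_len(min(n_pcs, ncol(pcs))), drop = FALSE]
  xy <- apply(ds$coords, 2, function(z) {
    r <- range(z); if (diff(r) > 0) (z - r[1]) / diff(r) else z * 0
  })
  feat <- cbind(pcs, smooth_weight * xy * sd(pcs[, 1]))
  km <- with_seed(seed, kmeans(feat, centers = K, nstart = 10, iter.max = 50))
  factor(km$cluster)
}

#' Deconvolution root mean square error
#'
#' Agreement between true and predicted per-spot cell-type proportion
#' matrices, with each cell type's squared error normalized by that type's
#' total true proportion `S_k` before averaging over types:
#' \deqn{RMSE = \sqrt{\frac{1}{K} \sum_k \frac{1}{S_k}
#'   \sum_i (P_{ik} - T_{ik})^2}}
#'
#' @param truth,pred spots x types matrices of matching shape
#' @return scalar RMSE (0 iff `pred == truth`)
#' @export
deconv_rmse <- function(truth, pred) {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  if (!identical(dim(truth), dim(pred)))
    stopf("shape mismatch: truth %s, pred %s",
          paste(dim(truth), collapse = "x"), paste(dim(pred), collapse = "x"))
  S <- colSums(truth)
  if (any(S <= 0)) {
    bad <- (colnames(truth) %||% seq_len(ncol(truth)))[S <= 0]
    stopf("zero total true proportion for type(s): %s",
          paste(bad, collapse = ", "))
  }
  K <- ncol(truth)
  sqrt(sum(colSums((pred - truth)^2) / S) / K)
}

#' Deconvolution Jensen-Shannon divergence
#'
#' Per cell type, the true and predicted proportion columns are normalized
#' over spots into distributions and compared by the Jensen-Shannon
#' divergence (symmetrized KL divergence to the midpoint, natural log, so
#' the maximum is `ln 2`); the result is averaged over types. Zero
#' probability cells contribute 0 through the `0 ln 0 = 0` convention.
#'
#' @inheritParams deconv_rmse
#' @return scalar mean JSD in `[0, ln 2]`
#' @export
deconv_jsd <- function(truth, pred) {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  if (!identical(dim(truth), dim(pred)))
    stopf("shape mismatch: truth %s, pred %s",
          paste(dim(truth), collapse = "x"), paste(dim(pred), collapse = "x"))
  if (any(colSums(truth) <= 0) || any(colSums(pred) <= 0))
    stopf("all-zero proportion column")
  kl <- function(p, q) {
    sel <- p > 0
    sum(p[sel] * log(p[sel] / q[sel]))
  }
  jsd_k <- vapply(seq_len(ncol(truth)), function(k) {
    qt <- truth[, k] / sum(truth[, k])
    qp <- pred[, k] / sum(pred[, k])
    mid <- (qt + qp) / 2
    kl(qt, mid) / 2 + kl(qp, mid) / 2
  }, numeric(1))
  mean(jsd_k)
}

#' Baseline cell-type deconvolution by non-negative least squares
#'
#' Regresses each spot's CPM profile on the per-type mean CPM profiles of a
#' single-cell reference under a non-negativity constraint and renormalizes
#' each spot's coefficients to proportions summing to 1. Genes are
#' intersected between the two datasets.
#'
#' @param ds a [spatial_dataset()]
#' @param ref a [single_cell_reference()]
#' @param min_shared_genes minimum size of the gene intersection
#' @return spots x types matrix of proportions (rows sum to 1)
#' @export
baseline_deconvolution <- function(ds, ref, min_shared_genes = 50L) {
  stopifnot(inherits(ds, "spatial_dataset"),
            inherits(ref, "single_cell_reference"))
  shared <- intersect(ds$gene_ids, ref$gene_ids)
  if (length(shared) < min_shared_genes)
    stopf("only %d shared genes (need >= %d)", length(shared), min_shared_genes)
  m <- as.matrix(ds$counts[match(shared, ds$gene_ids), , drop = FALSE])
  rc <- as.matrix(ref$counts[match(shared, ref$gene_ids), , drop = FALSE])
  # per-type mean CPM signatures
  types <- levels(ref$cell_types)
  cpm_ref <- sweep(rc, 2, pmax(colSums(rc), 1), "/") * 1e6
  sig <- vapply(types, function(t) {
    rowMeans(cpm_ref[, ref$cell_types == t, drop = FALSE])
  }, numeric(length(shared)))
  if (qr(sig)$rank < ncol(sig))
    warnf("rank-deficient signature matrix; proportions may be unstable")
  cpm_spot <- sweep(m, 2, pmax(colSums(m), 1), "/") * 1e6
  coefs <- apply(cpm_spot, 2, function(y) {
    b <- pracma::lsqnonneg(sig, y)$x
    if (sum(b) == 0) rep(1 / length(types), length(types)) else b / sum(b)
  })
  P <- if (is.matrix(coefs)) t(coefs) else matrix(coefs, ncol = 1)
  dimnames(P) <- list(ds$spot_ids, types)
  P
}

#' Precision and recall of spatially variable gene detection
#'
#' Treats the genes detected in the real dataset as truth and scores the
#' simulated dataset's detections: precision = TP / (TP + FP), recall =
#' TP / (TP + FN).
#'
#' @param real_svg,sim_svg character vectors of detected gene identifiers
#' @return named numeric vector `c(precision, recall)`
#' @export
svg_precision_recall <- function(real_svg, sim_svg) {
  tp <- length(intersect(real_svg, sim_svg))
  fp <- length(setdiff(sim_svg, real_svg))
  fn <- length(setdiff(real_svg, sim_svg))
  precision <- if (tp + fp == 0) {
    if (fn > 0) warnf("empty simulated detection set: precision set to 0")
    0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  c(precision = precision, recall = recall)
}

#' Baseline spatially variable gene detector
#'
#' Per-gene Moran's I on log2-CPM with permutation p-values (spot labels of
#' each gene's values permuted jointly across genes for efficiency),
#' Benjamini-Hochberg adjusted; genes with adjusted p below `fdr` are
#' returned.
#'
#' @param ds a [spatial_dataset()]
#' @param graph neighbor graph on `ds`
#' @param n_perm number of permutations (>= 50)
#' @param fdr adjusted-p threshold
#' @param seed RNG seed
#' @return character vector of detected gene identifiers; attribute
#'   `p_adjusted` carries the full adjusted p-value vector
#' @export
baseline_svg_detector <- function(ds, graph, n_perm = 200L, fdr = 0.05,
                                  seed = 1L) {
  stopifnot(inherits(ds, "spatial_dataset"), inherits(graph, "neighbor_graph"))
  if (n_perm < 50L) stopf("n_perm must be >= 50")
  lc <- log2cpm(ds$counts)
  obs <- morans_i_matrix(lc, graph)
  G <- nrow(lc); n <- ncol(lc)
  exceed <- rep(0L, G)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      perm <- sample.int(n)
      exceed <- exceed + (morans_i_matrix(lc[, perm, drop = FALSE], graph) >= obs)
    }
  })
  pvals <- (exceed + 1) / (n_perm + 1)
  padj <- p.adjust(pvals, method = "BH")
  out <- ds$gene_ids[padj < fdr]
  attr(out, "p_adjusted") <- setNames(padj, ds$gene_ids)
  out
}

#' Bivariate Moran's I matrix
#'
#' Spatial cross-correlation between genes X and Y on a neighbor graph:
#' \deqn{I_{XY} = \frac{N}{W} \frac{\sum_i \sum_j w_{ij}(x_i-\bar x)
#'   (y_j-\bar y)}{\sqrt{\sum_i (x_i-\bar x)^2}\sqrt{\sum_i (y_i-\bar y)^2}}}
#' computed on log2-CPM for all pairs of the requested genes. The diagonal
#' equals each gene's univariate Moran's I. Constant genes get zero rows
#' and columns with a warning.
#'
#' @param ds a [spatial_dataset()]
#' @param graph neighbor graph on `ds`
#' @param genes gene identifiers or indices (default: all; see
#'   [top_morans_genes()] for the usual subset)
#' @return genes x genes matrix of `I_XY`
#' @export
bivariate_morans_matrix <- function(ds, graph, genes = NULL) {
  stopifnot(inherits(ds, "spatial_dataset"))
  lc <- log2cpm(ds$counts)
  if (!is.null(genes)) {
    idx <- if (is.character(genes)) match(genes, ds$gene_ids) else genes
    if (anyNA(idx)) stopf("unknown gene(s)")
    lc <- lc[idx, , drop = FALSE]
  }
  if (nrow(lc) < 2) stopf("need at least 2 genes")
  n <- ncol(lc)
  W <- graph$adjacency
  if (nrow(W) != n) stopf("graph/dataset spot mismatch")
  z <- lc - rowMeans(lc)
  norms <- sqrt(rowSums(z^2))
  const <- norms == 0
  if (any(const)) warnf("%d constant gene(s): rows/columns set to 0", sum(const))
  norms[const] <- 1
  num <- as.matrix(z %*% W %*% t(z))     # (X, Y): sum_ij w_ij zx_i zy_j
  out <- (n / graph$total_weight) * num / outer(norms, norms)
  out[const, ] <- 0; out[, const] <- 0
  dimnames(out) <- list(rownames(lc), rownames(lc))
  out
}

#' Top genes by univariate Moran's I
#'
#' Default gene subset for the cross-correlation matrix (the full matrix is
#' quadratic in genes).
#'
#' @param ds a [spatial_dataset()]
#' @param graph neighbor graph
#' @param n how many genes
#' @return character vector of gene identifiers
#' @export
top_morans_genes <- function(ds, graph, n = 50L) {
  scores <- morans_i_matrix(log2cpm(ds$counts), graph)
  ds$gene_ids[order(-scores, ds$gene_ids)[seq_len(min(n, length(scores)))]]
}

#' Agreement between two spatial cross-correlation matrices
#'
#' Cosine similarity of the flattened matrices and the Mantel statistic
#' (Pearson correlation over corresponding entries after centring each
#' matrix by its own mean).
#'
#' @param real_m,sim_m matching-dimension matrices from
#'   [bivariate_morans_matrix()]
#' @return named numeric vector `c(cosine, mantel)`
#' @export
cross_corr_agreement <- function(real_m, sim_m) {
  if (!identical(dim(real_m), dim(sim_m))) stopf("shape mismatch")
  a <- as.numeric(real_m); b <- as.numeric(sim_m)
  cosine <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  ac <- a - mean(a); bc <- b - mean(b)
  mantel <- sum(ac * bc) / sqrt(sum(ac^2) * sum(bc^2))
  c(cosine = cosine, mantel = mantel)
}
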