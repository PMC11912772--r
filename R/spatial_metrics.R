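#' Moran's I spatial autocorrelation
#'
#' Global Moran's I of one per-spot variable over a neighbor graph:
#' \deqn{I = \frac{N}{W} \frac{\sum_{ij} w_{ij}(x_i-\bar x)(x_j-\bar x)}
#'   {\sum_i (x_i-\bar x)^2}}
#' with `W` the sum of all weights. Positive values indicate spatial
#' clustering of similar values, negative values dispersion. A constant
#' input is a 0/0 case and returns 0 with a warning.
#'
#' @param values numeric vector, one value per spot
#' @param graph a [build_neighbor_graph()] result
#' @return scalar Moran's I
#' @examples
#' g <- build_neighbor_graph(cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)), k = 2)
#' morans_i(c(1, -1, -1, 1), g)  # checkerboard: -1
#' @export
morans_i <- function(values, graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  W <- graph$adjacency
  n <- nrow(W)
  if (length(values) != n)
    stopf("values has length %d but graph has %d spots", length(values), n)
  z <- values - mean(values)
  den <- sum(z^2)
  if (den == 0) {
    warnf("constant input: Moran's I undefined, returning 0")
    return(0)
  }
  num <- sum(z * as.numeric(W %*% z))
  (n / graph$total_weight) * num / den
}

# Row-wise Moran's I for a features x spots matrix (constant rows -> 0).
morans_i_matrix <- function(x, graph) {
  W <- graph$adjacency
  n <- ncol(x)
  z <- x - rowMeans(x)
  num <- Matrix::rowSums((z %*% W) * z)
  den <- rowSums(z^2)
  out <- ifelse(den > 0, (n / graph$total_weight) * num / den, 0)
  as.numeric(out)
}

#' Spatial-domain transition matrix
#'
#' Row-stochastic K x K matrix over the spatial domains: entry (a, b) is the
#' fraction of ordered neighbor pairs starting in domain a that end in
#' domain b, i.e. the empirical transition probability of a random walk on
#' the neighbor graph restricted to one step. Domains whose spots have no
#' neighbors get a uniform row (with a warning).
#'
#' @param ds a [spatial_dataset()] with domain labels
#' @param graph neighbor graph on `ds`
#' @param domains optional label vector overriding `ds$domains`
#' @return K x K matrix with rows summing to 1
#' @export
transition_matrix <- function(ds, graph, domains = NULL) {
  labs <- domains %||% ds$domains
  if (is.null(labs)) stopf("dataset has no domain labels")
  labs <- factor(labs)
  K <- nlevels(labs)
  counts <- domain_edge_counts(labs, graph$adjacency)
  tm <- counts / pmax(rowSums(counts), 1)
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warnf("%d domain(s) have no neighbor pairs; uniform row substituted",
          sum(empty))
    tm[empty, ] <- 1 / K
  }
  dimnames(tm) <- list(levels(labs), levels(labs))
  tm
}

# Ordered inter-domain edge counts: entry (a,b) = # ordered neighbor pairs
# (i, j) with label(i) = a, label(j) = b.
domain_edge_counts <- function(labs, adj) {
  K <- nlevels(labs)
  M <- Matrix::sparseMatrix(i = seq_along(labs), j = as.integer(labs), x = 1,
                            dims = c(length(labs), K))
  as.matrix(Matrix::t(M) %*% adj %*% M)
}

#' Neighborhood enrichment matrix
#'
#' Z-scores of the observed inter-domain neighbor-pair counts against a
#' label-permutation null: `NEM_ij = (x_ij - mu_ij) / sigma_ij` where `x_ij`
#' is the ordered neighbor-pair count between domains i and j and `mu_ij`,
#' `sigma_ij` are its mean and standard deviation over `n_perm` random
#' permutations of the domain labels. Positive diagonal entries indicate
#' spatial segregation of domains. Cells with zero permutation variance are
#' reported as 0 with a warning.
#'
#' @inheritParams transition_matrix
#' @param n_perm number of label permutations (>= 100)
#' @param seed RNG seed for the permutations
#' @return K x K z-score matrix
#' @export
neighborhood_enrichment <- function(ds, graph, n_perm = 1000L, seed = 1L,
                                    domains = NULL) {
  labs <- domains %||% ds$domains
  if (is.null(labs)) stopf("dataset has no domain labels")
  labs <- factor(labs)
  if (n_perm < 100L) stopf("n_perm must be >= 100")
  if (any(table(labs) == 1L))
    warnf("domain(s) with a single spot: enrichment z-scores may be unstable")
  adj <- graph$adjacency
  obs <- domain_edge_counts(labs, adj)
  K <- nlevels(labs)
  acc <- matrix(0, K, K); acc2 <- matrix(0, K, K)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      x <- domain_edge_counts(sample(labs), adj)
      acc <- acc + x
      acc2 <- acc2 + x^2
    }
  })
  mu <- acc / n_perm
  sig <- sqrt(pmax(acc2 / n_perm - mu^2, 0))
  z <- matrix(0, K, K, dimnames = list(levels(labs), levels(labs)))
  ok <- sig > 0
  z[ok] <- (obs[ok] - mu[ok]) / sig[ok]
  if (any(!ok)) warnf("%d cell(s) with zero permutation variance set to 0",
                      sum(!ok))
  z
}

#' Per-domain graph centrality scores
#'
#' For each spatial domain `C_k`, three graph summaries on the spot neighbor
#' graph:
#' * `G1`, group degree centrality: the number of non-member spots adjacent
#'   to the domain, divided by `N - |C_k|`;
#' * `G2`, average clustering coefficient: mean over member spots of the
#'   local clustering coefficient `2 t_v / (d_v (d_v - 1))` (spots of degree
#'   < 2 contribute 0);
#' * `G3`, group closeness centrality: `|V - C_k|` divided by the summed
#'   shortest-path distances from each non-member spot to the domain.
#'   On a disconnected graph, unreachable spots are excluded with a warning.
#'
#' @inheritParams transition_matrix
#' @return K x 3 matrix with columns `G1`, `G2`, `G3`
#' @export
centrality_scores <- function(ds, graph, domains = NULL) {
  labs <- domains %||% ds$domains
  if (is.null(labs)) stopf("dataset has no domain labels")
  labs <- factor(labs)
  adj <- graph$adjacency
  n <- nrow(adj)
  K <- nlevels(labs)
  if (K == n) stopf("every spot is its own domain; centrality undefined")

  deg <- Matrix::rowSums(adj)
  # triangles per vertex: diag(A^3)/2
  A2 <- adj %*% adj
  tri <- Matrix::rowSums(A2 * adj) / 2
  local_cc <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0)

  out <- matrix(NA_real_, K, 3, dimnames = list(levels(labs),
                                                c("G1", "G2", "G3")))
  for (k in seq_len(K)) {
    members <- which(labs == levels(labs)[k])
    others <- setdiff(seq_len(n), members)
    # non-member spots adjacent to any member
    boundary <- others[Matrix::colSums(adj[members, others, drop = FALSE]) > 0]
    out[k, "G1"] <- length(boundary) / (n - length(members))
    out[k, "G2"] <- mean(local_cc[members])
    d <- bfs_dist_to_set(adj, members)[others]
    reach <- is.finite(d)
    if (!all(reach))
      warnf("domain %s: %d spot(s) unreachable, excluded from G3",
            levels(labs)[k], sum(!reach))
    out[k, "G3"] <- if (any(reach)) sum(reach) / sum(d[reach]) else 0
  }
  out
}

# Multi-source BFS: unweighted shortest-path distance from every vertex to
# the nearest vertex in `sources`.
bfs_dist_to_set <- function(adj, sources) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  d[sources] <- 0
  frontier <- sources
  lev <- 0
  while (length(frontier)) {
    lev <- lev + 1
    nxt <- which(Matrix::colSums(adj[frontier, , drop = FALSE]) > 0)
    nxt <- nxt[!is.finite(d[nxt])]
    d[nxt] <- lev
    frontier <- nxt
  }
  d
}

#' Nearest-neighbor expression correlation
#'
#' For every gene, the Pearson correlation between its value at each spot
#' and its value at that spot's single nearest neighbor (smallest Euclidean
#' distance; ties broken by lower spot index). Computed on log2-CPM.
#' Constant genes are skipped; their count is attached as attribute
#' `n_skipped`.
#'
#' @param ds a [spatial_dataset()]
#' @param graph unused placeholder for interface symmetry (nearest neighbor
#'   is defined by coordinates, not the graph); may be `NULL`
#' @return named numeric vector of per-gene correlations
#' @export
nn_correlation <- function(ds, graph = NULL) {
  stopifnot(inherits(ds, "spatial_dataset"))
  d <- as.matrix(dist(ds$coords))
  diag(d) <- Inf
  nn <- apply(d, 1L, which.min)  # which.min takes the first (lowest index) tie
  lc <- log2cpm(ds$counts)
  x <- lc
  y <- lc[, nn, drop = FALSE]
  keep <- apply(x, 1L, sd) > 0 & apply(y, 1L, sd) > 0
  out <- rep(NA_real_, nrow(lc))
  for (g in which(keep)) out[g] <- cor(x[g, ], y[g, ])
  res <- setNames(out[keep], ds$gene_ids[keep])
  attr(res, "n_skipped") <- sum(!keep)
  res
}

#' Cell-type spatial interaction
#'
#' For each unordered cell-type pair (a, b), the mean over ordered neighbor
#' spot pairs (i, j) of `p_ia * p_jb`, where `p` are the per-spot cell-type
#' proportions. High same-type values indicate spatial segregation of that
#' type; cross-type values rise when two types co-locate in adjacent spots.
#'
#' @inheritParams transition_matrix
#' @return named numeric vector over type pairs (`a:b`)
#' @export
celltype_interaction <- function(ds, graph) {
  if (is.null(ds$proportions)) stopf("dataset has no cell-type proportions")
  P <- ds$proportions
  adj <- graph$adjacency
  n_pairs <- sum(adj)
  # entry (a, b) = sum over ordered neighbor pairs of p_ia p_jb
  M <- as.matrix(Matrix::crossprod(P, adj %*% P)) / n_pairs
  types <- colnames(P) %||% paste0("type", seq_len(ncol(P)))
  idx <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  # symmetrize: unordered pair value averages the two ordered directions
  vals <- (M[idx] + M[cbind(idx[, 2], idx[, 1])]) / 2
  setNames(vals, paste(types[idx[, 1]], types[idx[, 2]], sep = ":"))
}

#' Proportion-weighted cross-type L statistic
#'
#' A Ripley-style second-order summary of cell-type co-location. For each
#' unordered type pair (a, b) and radius r, the weighted cross-K
#' \deqn{K_{ab}(r) = A \frac{\sum_{i \ne j} p_{ia} p_{jb} 1[d_{ij} \le r]}
#'   {W_a W_b}}
#' with `A` the bounding-box area of the coordinates and `W_a` the summed
#' proportion of type a, variance-stabilized to `L(r) = sqrt(K(r) / pi)`.
#' Under complete spatial randomness `L(r) - r` is near 0. No edge
#' correction is applied.
#'
#' @param ds a [spatial_dataset()] with proportions
#' @param radii positive ascending radii at which to evaluate L
#' @return numeric vector of length `n_pairs * n_radii`, named `a:b@r`
#' @export
l_statistic <- function(ds, radii) {
  if (is.null(ds$proportions)) stopf("dataset has no cell-type proportions")
  if (any(diff(radii) <= 0) || any(radii <= 0))
    stopf("radii must be positive and ascending")
  coords <- ds$coords
  dmax <- sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2))
  if (any(radii > dmax))
    warnf("radius exceeds the coordinate diameter (%.3g)", dmax)
  area <- prod(apply(coords, 2, function(z) diff(range(z))))
  P <- ds$proportions
  types <- colnames(P) %||% paste0("type", seq_len(ncol(P)))
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  Wt <- colSums(P)
  out <- c()
  pair_idx <- which(upper.tri(diag(ncol(P)), diag = TRUE), arr.ind = TRUE)
  for (r in radii) {
    ind <- (d <= r) * 1
    S <- crossprod(P, ind %*% P)  # (a,b): sum_{i != j} p_ia p_jb 1[dij <= r]
    K <- area * S / outer(Wt, Wt)
    L <- sqrt(pmax(as.matrix(K), 0) / pi)
    vals <- (L[pair_idx] + L[cbind(pair_idx[, 2], pair_idx[, 1])]) / 2
    out <- c(out, setNames(vals, paste0(types[pair_idx[, 1]], ":",
                                        types[pair_idx[, 2]], "@", r)))
  }
  out
}
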