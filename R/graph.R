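#' Build a spot neighbor graph from coordinates
#'
#' Constructs the symmetric spatial weight matrix `w_ij` used by every
#' spatial statistic (Moran's I, transition matrix, neighborhood enrichment,
#' centrality scores). Two constructions are offered:
#'
#' * `knn` (default): each spot is linked to its `k` nearest Euclidean
#'   neighbors and the relation is symmetrized by union, the common choice
#'   for hexagonal/gridded capture arrays (`k = 6` matches a hexagonal
#'   lattice). Distance ties are broken by the lower spot index, so the
#'   graph is deterministic.
#' * `delaunay`: edges of the Delaunay triangulation of the coordinates.
#'
#' @param coords spots x 2 numeric matrix
#' @param method `"knn"` or `"delaunay"`
#' @param k neighbor count for `method = "knn"`
#' @return an object of class `neighbor_graph`: list with `adjacency`
#'   (sparse symmetric 0/1 matrix, zero diagonal), `total_weight`
#'   (`W = sum w_ij`, ordered pairs), `k_param`, `method`.
#' @examples
#' g <- build_neighbor_graph(cbind(rep(1:3, 3), rep(1:3, each = 3)), k = 2)
#' g$total_weight
#' @export
build_neighbor_graph <- function(coords, method = c("knn", "delaunay"),
                                 k = 6L) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stopf("need at least 2 spots, got %d", n)

  if (method == "knn") {
    if (k >= n) stopf("k (%d) must be smaller than the spot count (%d)", k, n)
    d <- as.matrix(dist(coords))
    diag(d) <- Inf
    pairs <- matrix(0L, nrow = n * k, ncol = 2L)
    for (i in seq_len(n)) {
      # order() breaks distance ties by index, giving a deterministic graph
      nb <- order(d[i, ])[seq_len(k)]
      pairs[((i - 1L) * k + 1L):(i * k), ] <- cbind(i, nb)
    }
    adj <- Matrix::sparseMatrix(i = pairs[, 1], j = pairs[, 2], x = 1,
                                dims = c(n, n))
    adj <- ((adj + Matrix::t(adj)) > 0) * 1  # union symmetrization
  } else {
    if (anyDuplicated(coords)) stopf("duplicate coordinates not allowed for delaunay")
    edges <- delaunay_edges(coords)
    adj <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                                j = c(edges[, 2], edges[, 1]),
                                x = 1, dims = c(n, n))
    adj <- (adj > 0) * 1
  }
  adj <- as(adj, "CsparseMatrix")
  structure(list(adjacency = adj, total_weight = sum(adj),
                 k_param = if (method == "knn") as.integer(k) else NA_integer_,
                 method = method),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("neighbor_graph (%s): %d spots, W = %g\n",
              x$method, nrow(x$adjacency), x$total_weight))
  invisible(x)
}

# Bowyer-Watson incremental Delaunay triangulation; O(n^2), adequate for
# spot-array sizes. Returns a 2-column matrix of unique undirected edges.
delaunay_edges <- function(coords) {
  n <- nrow(coords)
  if (n == 2L) return(matrix(c(1L, 2L), 1L))
  # super-triangle enclosing all points
  cx <- mean(range(coords[, 1])); cy <- mean(range(coords[, 2]))
  r <- max(dist(rbind(c(cx, cy), coords))) * 10 + 1
  pts <- rbind(coords,
               c(cx - 2 * r, cy - r), c(cx + 2 * r, cy - r), c(cx, cy + 2 * r))
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  tris <- matrix(c(s1, s2, s3), ncol = 3L)

  circum <- function(tri) {
    p1 <- pts[tri[1], ]; p2 <- pts[tri[2], ]; p3 <- pts[tri[3], ]
    ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  cc <- matrix(circum(tris[1, ]), ncol = 3L)

  for (p in seq_len(n)) {
    px <- pts[p, 1]; py <- pts[p, 2]
    bad <- (px - cc[, 1])^2 + (py - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12)
    bad_tris <- tris[bad, , drop = FALSE]
    # boundary of the cavity: edges appearing exactly once among bad triangles
    ed <- rbind(bad_tris[, c(1, 2), drop = FALSE],
                bad_tris[, c(2, 3), drop = FALSE],
                bad_tris[, c(3, 1), drop = FALSE])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    boundary <- ed[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    tris <- tris[!bad, , drop = FALSE]
    cc <- cc[!bad, , drop = FALSE]
    if (nrow(boundary)) {
      new_tris <- cbind(boundary, p)
      tris <- rbind(tris, new_tris)
      cc <- rbind(cc, t(apply(new_tris, 1L, circum)))
    }
  }
  keep <- tris[, 1] <= n & tris[, 2] <= n & tris[, 3] <= n
  tris <- tris[keep, , drop = FALSE]
  if (!nrow(tris)) {
    # all points collinear: fall back to chain along the spread axis
    ax <- which.max(apply(coords, 2, function(z) diff(range(z))))
    o <- order(coords[, ax], seq_len(n))
    return(cbind(o[-n], o[-1]))
  }
  ed <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  unique(ed)
}
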