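test_that("Moran's I analytic cases: checkerboard -1, gradient positive", {
  coords <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  g <- build_neighbor_graph(coords, k = 2)  # rook adjacency on the 2x2 grid
  expect_equal(morans_i(c(1, -1, -1, 1), g), -1)

  side <- 6
  coords6 <- cbind(rep(1:side, side), rep(1:side, each = side))
  g6 <- build_neighbor_graph(coords6, k = 4)
  expect_gt(morans_i(coords6[, 1], g6), 0.5)
})

test_that("Moran's I equals the O(N^2) double-sum oracle on random fixtures", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(6:15, 1)
    coords <- matrix(runif(2 * n), n, 2)
    g <- build_neighbor_graph(coords, k = min(3, n - 1))
    x <- rnorm(n)
    expect_equal(morans_i(x, g), oracle_morans_i(x, as.matrix(g$adjacency)),
                 tolerance = 1e-12)
  }
  g2 <- chain_graph(4)
  expect_warning(res <- morans_i(rep(2, 4), g2), "constant")
  expect_equal(res, 0)
})

test_that("transition matrix matches hand enumeration and is row-stochastic", {
  ds <- chain_dataset(c("A", "A", "B", "B"))
  g <- chain_graph(4)
  tm <- transition_matrix(ds, g)
  # ordered neighbor pairs from A: (1,2),(2,1),(2,3) -> A->A 2/3, A->B 1/3
  expect_equal(tm["A", ], c(A = 2 / 3, B = 1 / 3))
  expect_equal(unname(rowSums(tm)), c(1, 1))

  single <- chain_dataset(c("A", "A", "A", "A"))
  expect_equal(unname(transition_matrix(single, g)), matrix(1, 1, 1))

  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(8:16, 1)
    coords <- matrix(runif(2 * n), n, 2)
    labs <- sample(c("a", "b", "c"), n, replace = TRUE)
    ds_r <- spatial_dataset(matrix(1, 2, n), coords, domains = labs)
    g_r <- build_neighbor_graph(coords, k = 3)
    tm_r <- suppressWarnings(transition_matrix(ds_r, g_r))
    expect_equal(unname(rowSums(tm_r)), rep(1, nrow(tm_r)), tolerance = 1e-9)
    if (length(unique(labs)) == 3)
      expect_equal(unname(tm_r),
                   unname(oracle_transition_matrix(labs,
                                                   as.matrix(g_r$adjacency))),
                   tolerance = 1e-12)
  }
})

test_that("neighborhood enrichment: segregated bands show diagonal dominance", {
  ds <- band_dataset(side = 10, n_domains = 2, seed = 21, n_genes = 30)
  g <- rook_graph(ds$coords)
  nem <- neighborhood_enrichment(ds, g, n_perm = 200, seed = 3)
  expect_true(all(diag(nem) > 0))
  expect_lt(nem[1, 2], 0)

  nem2 <- neighborhood_enrichment(ds, g, n_perm = 200, seed = 3)
  expect_identical(nem, nem2)
})

test_that("neighborhood enrichment is calibrated under random labels", {
  set.seed(22)
  n <- 100
  coords <- matrix(runif(2 * n), n, 2)
  labs <- sample(c("a", "b", "c"), n, replace = TRUE)
  ds <- spatial_dataset(matrix(1, 2, n), coords, domains = labs)
  g <- build_neighbor_graph(coords, k = 4)
  nem <- neighborhood_enrichment(ds, g, n_perm = 1000, seed = 4)
  expect_true(all(abs(nem) < 4))
})

test_that("centrality scores match hand enumeration and BFS oracle", {
  ds <- chain_dataset(c("A", "A", "B", "B"))
  g <- chain_graph(4)
  cs <- centrality_scores(ds, g)
  expect_equal(cs["A", "G1"], 0.5)  # one boundary spot (3) / (4 - 2)
  expect_equal(unname(cs[, "G2"]), c(0, 0))  # chains have no triangles
  # G3(A): distances from spots 3,4 to {1,2}: 1 and 2 -> 2/3
  expect_equal(cs["A", "G3"], 2 / 3)

  # triangle-free lattice -> G2 = 0 for all domains
  ds_l <- band_dataset(side = 6, n_domains = 2, seed = 23, n_genes = 20)
  g_l <- rook_graph(ds_l$coords)
  expect_equal(unname(centrality_scores(ds_l, g_l)[, "G2"]), c(0, 0))

  # BFS distances vs igraph on random graphs
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20
    coords <- matrix(runif(2 * n), n, 2)
    g_r <- build_neighbor_graph(coords, k = 3)
    labs <- factor(sample(c("a", "b"), n, replace = TRUE))
    ds_r <- spatial_dataset(matrix(1, 2, n), coords, domains = labs)
    cs_r <- centrality_scores(ds_r, g_r)
    ig <- igraph::graph_from_adjacency_matrix(as.matrix(g_r$adjacency),
                                              mode = "undirected")
    D <- igraph::distances(ig)
    for (k in 1:2) {
      members <- which(labs == levels(labs)[k])
      others <- setdiff(1:n, members)
      d <- apply(D[others, members, drop = FALSE], 1, min)
      reach <- is.finite(d)
      expect_equal(cs_r[k, "G3"], sum(reach) / sum(d[reach]))
      expect_equal(cs_r[k, "G1"],
                   oracle_group_degree(labs, as.matrix(g_r$adjacency), k))
    }
    # local clustering coefficient vs igraph
    cc_ig <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
    cc_ig[igraph::degree(ig) < 2] <- 0
    for (k in 1:2) {
      members <- which(labs == levels(labs)[k])
      expect_equal(cs_r[k, "G2"], mean(cc_ig[members]), tolerance = 1e-12)
    }
  }
})

test_that("relabeling domains permutes TM/NEM/CSM rows and columns", {
  ds <- band_dataset(side = 8, n_domains = 3, seed = 24, n_genes = 20)
  g <- rook_graph(ds$coords)
  relab <- factor(c(D1 = "Z", D2 = "Y", D3 = "X")[as.character(ds$domains)])
  tm1 <- transition_matrix(ds, g)
  tm2 <- transition_matrix(ds, g, domains = relab)
  expect_equal(unname(tm2[c("Z", "Y", "X"), c("Z", "Y", "X")]), unname(tm1))
  cs1 <- centrality_scores(ds, g)
  cs2 <- centrality_scores(ds, g, domains = relab)
  expect_equal(unname(cs2[c("Z", "Y", "X"), ]), unname(cs1))
})

test_that("nearest-neighbor correlation identities and oracle", {
  # each spot duplicates its nearest neighbor -> all correlations 1
  base <- matrix(rpois(40, 10) + 1, 10, 4)
  m <- base[, c(1, 1, 2, 2, 3, 3, 4, 4)]
  coords <- cbind(c(0, 0.1, 5, 5.1, 10, 10.1, 15, 15.1), 0)
  ds <- spatial_dataset(m, coords)
  v <- nn_correlation(ds)
  expect_true(all(abs(v - 1) < 1e-12))

  # direct oracle on a random fixture
  ds_r <- random_counts_dataset(25, n_genes = 8, n_spots = 10)
  v_r <- nn_correlation(ds_r)
  d <- as.matrix(dist(ds_r$coords)); diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  lc <- log2cpm(ds_r$counts)
  for (gname in names(v_r)) {
    gi <- match(gname, ds_r$gene_ids)
    expect_equal(v_r[[gname]], cor(lc[gi, ], lc[gi, nn]), tolerance = 1e-12)
  }
})

test_that("nn correlation is near zero for i.i.d. noise", {
  set.seed(26)
  n <- 1000
  m <- matrix(rpois(20 * n, 10), 20, n)
  ds <- spatial_dataset(m, coords = matrix(runif(2 * n), n, 2))
  v <- nn_correlation(ds)
  expect_lt(abs(mean(v)), 0.1)
})

test_that("cell-type interaction: identity, segregation sign, formula oracle", {
  # single type: proportions all 1 -> interaction 1
  ds1 <- chain_dataset(c("A", "A", "B", "B"))
  ds1$proportions <- matrix(1, 4, 1, dimnames = list(ds1$spot_ids, "t1"))
  g <- chain_graph(4)
  expect_equal(unname(celltype_interaction(ds1, g)), 1)

  # segregated bands: cross-type < same-type
  ds2 <- band_dataset(side = 8, n_domains = 2, seed = 27, n_genes = 20)
  near_pure <- ifelse(as.integer(ds2$domains) == 1, 0.95, 0.05)
  ds2$proportions <- cbind(t1 = near_pure, t2 = 1 - near_pure)
  g2 <- rook_graph(ds2$coords)
  ci <- celltype_interaction(ds2, g2)
  expect_lt(ci[["t1:t2"]], ci[["t1:t1"]])
  expect_lt(ci[["t1:t2"]], ci[["t2:t2"]])

  # brute-force neighbor-pair summation
  ds3 <- tiny_dataset(seed = 28, side = 4, n_cell_types = 3)
  g3 <- rook_graph(ds3$coords)
  ci3 <- celltype_interaction(ds3, g3)
  adj <- as.matrix(g3$adjacency)
  P <- ds3$proportions
  n_pairs <- sum(adj)
  for (a in 1:3) for (b in a:3) {
    s <- 0
    for (i in 1:nrow(P)) for (j in 1:nrow(P)) if (adj[i, j] > 0)
      s <- s + (P[i, a] * P[j, b] + P[i, b] * P[j, a]) / 2
    expect_equal(ci3[[paste0("type", a, ":type", b)]], s / n_pairs,
                 tolerance = 1e-12)
  }
})

test_that("L statistic: CSR null, co-location signal, output shape", {
  set.seed(29)
  n <- 1000
  coords <- matrix(runif(2 * n), n, 2)
  P <- matrix(0.5, n, 2, dimnames = list(NULL, c("t1", "t2")))
  ds <- spatial_dataset(matrix(1, 2, n), coords, proportions = P)
  radii <- c(0.05, 0.1, 0.15)
  L <- l_statistic(ds, radii)
  expect_length(L, 3 * 3)  # 3 type pairs x 3 radii
  csr_dev <- abs(L - rep(radii, each = 3)) / rep(radii, each = 3)
  expect_true(all(csr_dev < 0.15))

  # co-located pair: both types concentrated in one corner
  w <- as.numeric(coords[, 1] < 0.3 & coords[, 2] < 0.3)
  P2 <- cbind(t1 = 0.05 + 0.9 * w, t2 = 0.95 - 0.9 * w)
  ds2 <- spatial_dataset(matrix(1, 2, n), coords, proportions = P2)
  L2 <- l_statistic(ds2, radii = 0.1)
  expect_gt(L2[["t1:t1@0.1"]], 0.1)  # above the CSR value L(r) = r
})
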