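# Small builders shared across test files.

tiny_dataset <- function(seed = 1L, n_genes = 12L, side = 4L, n_domains = 2L,
                         n_cell_types = 3L) {
  cfg <- synthetic_config(n_spots_side = side, n_genes = n_genes,
                          n_domains = n_domains,
                          n_marker_genes_per_domain = 2L,
                          n_cell_types = n_cell_types, seed = seed)
  generate_fixture(cfg)
}

random_counts_dataset <- function(seed, n_genes = 8L, n_spots = 12L) {
  set.seed(seed)
  counts <- matrix(rpois(n_genes * n_spots, 5) + 1, n_genes, n_spots)
  spatial_dataset(counts, coords = cbind(runif(n_spots), runif(n_spots)))
}

band_dataset <- function(side = 20L, n_domains = 4L, seed = 1L,
                         n_genes = 150L) {
  cfg <- synthetic_config(n_spots_side = side, n_genes = n_genes,
                          n_domains = n_domains,
                          n_marker_genes_per_domain =
                            max(1L, min(10L, n_genes %/% (2L * n_domains))),
                          seed = seed)
  generate_fixture(cfg)
}

# exact rook adjacency (unit-distance 4-neighborhood) on an integer lattice;
# triangle-free by construction, unlike kNN which picks up diagonals at
# lattice boundaries
rook_graph <- function(coords) {
  d <- as.matrix(dist(coords))
  adj <- (abs(d - 1) < 1e-9) * 1
  structure(list(adjacency = methods::as(Matrix::Matrix(adj, sparse = TRUE),
                                         "CsparseMatrix"),
                 total_weight = sum(adj), k_param = NA_integer_,
                 method = "rook"),
            class = "neighbor_graph")
}

chain_dataset <- function(labels = c("A", "A", "B", "B")) {
  n <- length(labels)
  spatial_dataset(matrix(1:(2 * n), 2, n), coords = cbind(seq_len(n), 0),
                  domains = labels)
}

chain_graph <- function(n) build_neighbor_graph(cbind(seq_len(n), 0), k = 1)
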