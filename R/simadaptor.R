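#' Built-in negative-binomial reference simulator
#'
#' A self-contained count simulator used as the package's default plug-in:
#' per gene, a method-of-moments negative-binomial fit (mean m, variance v,
#' size `m^2 / (v - m)`; Poisson fallback when `v <= m`) and i.i.d.
#' resampling across spots. Genes are simulated independently -- no
#' gene-gene correlation structure is modelled.
#'
#' @param counts genes x spots count matrix
#' @param seed RNG seed
#' @return integer matrix of the same shape and dimnames
#' @export
builtin_nb_simulator <- function(counts, seed = 1L) {
  m <- as.matrix(counts)
  if (ncol(m) < 5) stopf("need at least 5 spots to fit, got %d", ncol(m))
  means <- rowMeans(m)
  vars <- apply(m, 1, var)
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  with_seed(seed, {
    for (g in seq_len(nrow(m))) {
      mu <- means[g]
      if (mu == 0) next  # all-zero gene stays all-zero
      v <- vars[g]
      out[g, ] <- if (v > mu) {
        rnbinom(ncol(m), size = mu^2 / (v - mu), mu = mu)
      } else {
        rpois(ncol(m), mu)
      }
    }
  })
  out
}

#' Identity simulator
#'
#' Returns its input unchanged; useful as a null plug-in for testing
#' adaptor plumbing.
#'
#' @inheritParams builtin_nb_simulator
#' @return the input matrix
#' @export
identity_simulator <- function(counts, seed = 1L) as.matrix(counts)

#' Cluster-then-simulate adaptor
#'
#' Turns any whole-matrix count simulator into a spatially structured one.
#' Spots are partitioned into spatial clusters (provided labels, the
#' dataset's domain labels, or labels derived by
#' [baseline_spatial_clustering()] with `K` clusters); each cluster's
#' gene x spot submatrix is passed to the simulator independently and the
#' simulated counts replace the originals. Coordinates (and labels, when
#' present) are carried over unchanged, so simulated spots inherit real
#' positions -- the mechanism by which domain-specific expression structure
#' survives simulation. `mode = "whole"` bypasses the split and hands the
#' full matrix to the simulator once.
#'
#' Per-cluster seeds are derived deterministically from the master seed and
#' the cluster *label*, so reordering clusters does not change the output.
#'
#' @param ds the reference [spatial_dataset()]
#' @param simulator function `(counts, seed) -> counts` of identical shape,
#'   e.g. [builtin_nb_simulator()]
#' @param labels optional partition of the spots; default `ds$domains`
#' @param K number of clusters when labels must be derived (required in
#'   that case; no silent default)
#' @param mode `"adaptor"` (per-cluster) or `"whole"`
#' @param seed master seed
#' @param min_cluster_size clusters smaller than this are passed through
#'   unsimulated with a warning
#' @return a `spatial_dataset` with simulated counts and the reference's
#'   coordinates, labels and proportions
#' @export
adapt_simulator <- function(ds, simulator = builtin_nb_simulator,
                            labels = NULL, K = NULL,
                            mode = c("adaptor", "whole"), seed = 1L,
                            min_cluster_size = 5L) {
  stopifnot(inherits(ds, "spatial_dataset"))
  mode <- match.arg(mode)
  counts <- as.matrix(ds$counts)

  if (mode == "whole") {
    sim_counts <- simulator(counts, seed = seed)
  } else {
    labs <- labels %||% ds$domains
    if (is.null(labs)) {
      if (is.null(K))
        stopf("no labels available: provide `labels` or `K` for clustering")
      labs <- baseline_spatial_clustering(ds, K = K, seed = seed)
    }
    labs <- factor(labs)
    if (length(labs) != ncol(counts))
      stopf("labels have length %d but there are %d spots",
            length(labs), ncol(counts))
    sim_counts <- counts
    for (lv in levels(labs)) {
      idx <- which(labs == lv)
      if (length(idx) < min_cluster_size) {
        warnf("cluster %s has %d spot(s) (< %d): passed through unsimulated",
              lv, length(idx), min_cluster_size)
        next
      }
      cl_seed <- (seed * 7919 + label_hash(lv)) %% .Machine$integer.max
      sim_counts[, idx] <- simulator(counts[, idx, drop = FALSE],
                                     seed = cl_seed)
    }
  }
  if (!identical(dim(sim_counts), dim(counts)))
    stopf("simulator returned shape %s, expected %s",
          paste(dim(sim_counts), collapse = "x"),
          paste(dim(counts), collapse = "x"))
  dimnames(sim_counts) <- dimnames(counts)
  spatial_dataset(sim_counts, coords = ds$coords, gene_ids = ds$gene_ids,
                  spot_ids = ds$spot_ids, domains = ds$domains,
                  proportions = ds$proportions)
}
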