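#' Log2 counts-per-million transform
#'
#' `log2(1e6 * Y_gk / N_k + pseudocount)` with `N_k` the library size of
#' spot `k`. The pseudocount (default 1) keeps zeros finite; the transform
#' is invariant to per-spot sequencing depth and strictly monotone in
#' counts.
#'
#' @param counts genes x spots matrix (dense or sparse)
#' @param pseudocount added inside the log
#' @return dense numeric matrix of the same shape
#' @export
log2cpm <- function(counts, pseudocount = 1) {
  m <- as.matrix(counts)
  N <- colSums(m)
  if (any(N <= 0)) {
    bad <- colnames(m)[N <= 0] %||% which(N <= 0)
    stopf("zero library size for spot(s): %s",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  log2(sweep(m, 2, N, "/") * 1e6 + pseudocount)
}

#' Quality-control filter for single-cell reference data
#'
#' Retains cells with between 200 and 2500 unique detected features
#' (inclusive) and a mitochondrial-count fraction of at most 5%. These are
#' the standard QC thresholds for droplet scRNA-seq.
#'
#' @param ref a [single_cell_reference()]
#' @param mito_gene_prefix prefix identifying mitochondrial genes
#'   (e.g. `"MT-"`, `"mt-"`)
#' @param min_features,max_features,max_mito_frac the three thresholds
#' @return the filtered `single_cell_reference`, with an attribute
#'   `removal_tally` counting cells failing each criterion
#' @export
qc_filter_cells <- function(ref, mito_gene_prefix = "MT-",
                            min_features = 200L, max_features = 2500L,
                            max_mito_frac = 0.05) {
  stopifnot(inherits(ref, "single_cell_reference"))
  m <- ref$counts
  n_feat <- Matrix::colSums(m > 0)
  is_mito <- startsWith(ref$gene_ids, mito_gene_prefix)
  tot <- Matrix::colSums(m)
  mito_frac <- ifelse(tot > 0, Matrix::colSums(m[is_mito, , drop = FALSE]) / tot, 0)

  too_few <- n_feat < min_features
  too_many <- n_feat > max_features
  too_mito <- mito_frac > max_mito_frac
  keep <- !(too_few | too_many | too_mito)
  if (!any(keep))
    stopf("no cells pass QC; review thresholds (min %d, max %d features, mito <= %g)",
          min_features, max_features, max_mito_frac)
  out <- single_cell_reference(m[, keep, drop = FALSE],
                               droplevels(ref$cell_types[keep]),
                               gene_ids = ref$gene_ids)
  attr(out, "removal_tally") <- c(low_features = sum(too_few),
                                  high_features = sum(too_many),
                                  high_mito = sum(too_mito))
  out
}

#' Select the top spatially variable genes
#'
#' When a dataset has more than `max_genes` genes, genes are ranked by
#' spatial variability -- univariate Moran's I of their log2-CPM profile on
#' the neighbor graph -- and the top `max_genes` are retained (original
#' relative order preserved; Moran ties broken by gene identifier). With
#' `max_genes` or fewer genes the dataset is returned unchanged, so the
#' operation is idempotent.
#'
#' @param ds a [spatial_dataset()]
#' @param graph a [build_neighbor_graph()] result on `ds`'s coordinates
#' @param max_genes retain at most this many genes (default 1000)
#' @return a `spatial_dataset` with at most `max_genes` genes
#' @export
select_genes <- function(ds, graph, max_genes = 1000L) {
  stopifnot(inherits(ds, "spatial_dataset"), inherits(graph, "neighbor_graph"))
  if (nrow(graph$adjacency) != length(ds$spot_ids))
    stopf("graph has %d spots but dataset has %d",
          nrow(graph$adjacency), length(ds$spot_ids))
  if (length(ds$gene_ids) <= max_genes) return(ds)
  lc <- log2cpm(ds$counts)
  scores <- morans_i_matrix(lc, graph)
  # descending Moran's I, ties by gene id; keep original gene order
  ord <- order(-scores, ds$gene_ids)[seq_len(max_genes)]
  subset_dataset(ds, genes = sort(ord))
}
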