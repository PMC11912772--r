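#' Construct a spatial transcriptomics dataset
#'
#' The central container of the package: a genes x spots UMI count matrix
#' together with 2D spot coordinates and, optionally, per-spot spatial-domain
#' labels and per-spot cell-type proportions. All metric and simulation
#' functions consume this class.
#'
#' @param counts non-negative integer matrix, genes in rows, spots in columns.
#'   Dense or `Matrix` sparse; stored sparsely.
#' @param coords numeric matrix or data frame with one row per spot and two
#'   columns (x, y). Arbitrary spatial units; never interpreted.
#' @param gene_ids,spot_ids character vectors; default to the dimnames of
#'   `counts`.
#' @param domains optional factor/character vector of spatial-domain labels,
#'   one per spot (the spatial clusters `C_k`).
#' @param proportions optional spots x cell-types matrix of estimated
#'   cell-type proportions; each row must sum to 1 (tolerance 1e-8).
#' @return An object of class `spatial_dataset` with elements `counts`
#'   (dgCMatrix), `coords`, `gene_ids`, `spot_ids`, `domains`, `proportions`.
#' @examples
#' ds <- spatial_dataset(matrix(1:6, 2, 3), coords = cbind(1:3, 0))
#' dim(ds$counts)
#' @export
spatial_dataset <- function(counts, coords, gene_ids = NULL, spot_ids = NULL,
                            domains = NULL, proportions = NULL) {
  counts <- coerce_sparse(counts)
  if (any(!is.finite(counts@x))) stopf("counts contain non-finite entries")
  if (any(counts@x < 0)) stopf("counts contain negative entries")
  n_genes <- nrow(counts)
  n_spots <- ncol(counts)

  gene_ids <- as.character(gene_ids %||% rownames(counts) %||%
                             paste0("gene", seq_len(n_genes)))
  spot_ids <- as.character(spot_ids %||% colnames(counts) %||%
                             paste0("spot", seq_len(n_spots)))
  if (length(gene_ids) != n_genes)
    stopf("gene_ids has length %d but counts has %d genes",
          length(gene_ids), n_genes)
  if (length(spot_ids) != n_spots)
    stopf("spot_ids has length %d but counts has %d spots",
          length(spot_ids), n_spots)
  if (anyDuplicated(spot_ids)) stopf("duplicate spot_ids")

  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2L)
    stopf("coords must be a numeric matrix with 2 columns")
  if (nrow(coords) != n_spots)
    stopf("coords has %d rows but counts has %d spots", nrow(coords), n_spots)
  dimnames(coords) <- list(spot_ids, c("x", "y"))

  if (!is.null(domains)) {
    if (length(domains) != n_spots)
      stopf("domains has length %d but there are %d spots",
            length(domains), n_spots)
    if (anyNA(domains)) stopf("domain labels must cover every spot (NA found)")
    domains <- factor(domains)
    names(domains) <- spot_ids
  }
  if (!is.null(proportions)) {
    proportions <- as.matrix(proportions)
    if (nrow(proportions) != n_spots)
      stopf("proportions has %d rows but there are %d spots",
            nrow(proportions), n_spots)
    rs <- rowSums(proportions)
    if (any(abs(rs - 1) > 1e-8))
      stopf("proportions rows must sum to 1 (max deviation %.3g)",
            max(abs(rs - 1)))
    if (any(proportions < 0)) stopf("proportions contain negative entries")
    rownames(proportions) <- spot_ids
  }

  dimnames(counts) <- list(gene_ids, spot_ids)
  structure(
    list(counts = counts, coords = coords, gene_ids = gene_ids,
         spot_ids = spot_ids, domains = domains, proportions = proportions),
    class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d genes x %d spots\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$domains))
    cat(sprintf("  domains: %d (%s)\n", nlevels(x$domains),
                paste(utils::head(levels(x$domains), 5), collapse = ", ")))
  if (!is.null(x$proportions))
    cat(sprintf("  cell-type proportions: %d types\n", ncol(x$proportions)))
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$counts)

#' Subset a spatial dataset by genes and/or spots
#'
#' @param ds a `spatial_dataset`
#' @param genes,spots index vectors (integer, logical or character)
#' @return a `spatial_dataset`
#' @export
subset_dataset <- function(ds, genes = NULL, spots = NULL) {
  stopifnot(inherits(ds, "spatial_dataset"))
  gi <- genes %||% seq_along(ds$gene_ids)
  si <- spots %||% seq_along(ds$spot_ids)
  spatial_dataset(ds$counts[gi, si, drop = FALSE],
                  coords = ds$coords[si, , drop = FALSE],
                  domains = if (!is.null(ds$domains)) droplevels(ds$domains[si]),
                  proportions = if (!is.null(ds$proportions))
                    ds$proportions[si, , drop = FALSE])
}

#' Construct a single-cell reference
#'
#' A genes x cells count matrix with per-cell type labels, used as ground
#' truth for cell-type deconvolution.
#'
#' @param counts genes x cells non-negative integer matrix
#' @param cell_types character/factor vector of cell-type labels, one per cell
#' @param gene_ids optional gene identifiers (default: rownames)
#' @return object of class `single_cell_reference`
#' @export
single_cell_reference <- function(counts, cell_types, gene_ids = NULL) {
  counts <- coerce_sparse(counts)
  if (any(counts@x < 0)) stopf("counts contain negative entries")
  if (length(cell_types) != ncol(counts))
    stopf("cell_types has length %d but counts has %d cells",
          length(cell_types), ncol(counts))
  if (anyNA(cell_types)) stopf("cell-type labels must cover all cells")
  gene_ids <- as.character(gene_ids %||% rownames(counts) %||%
                             paste0("gene", seq_len(nrow(counts))))
  rownames(counts) <- gene_ids
  structure(list(counts = counts, cell_types = factor(cell_types),
                 gene_ids = gene_ids),
            class = "single_cell_reference")
}

#' @export
print.single_cell_reference <- function(x, ...) {
  cat(sprintf("single_cell_reference: %d genes x %d cells, %d types\n",
              nrow(x$counts), ncol(x$counts), nlevels(x$cell_types)))
  invisible(x)
}

#' Read a spatial dataset from the standard file layout
#'
#' Reads a 10x-style triplet layout: Matrix Market counts plus features and
#' barcodes TSVs, a coordinates CSV (`spot_id,x,y`), and optional domains
#' (`spot_id,domain`) and proportions (`spot_id,<type>,...`) CSVs. Barcode
#' order defines spot order; coordinate rows are matched to barcodes by
#' `spot_id` and any mismatch in the spot sets is an error, never a silent
#' truncation.
#'
#' @param matrix_path path to the `.mtx` counts file (genes x spots; a
#'   spots x genes matrix is transposed using the barcode/feature counts)
#' @param features_path TSV of gene identifiers (first column used)
#' @param barcodes_path TSV of spot barcodes (first column used)
#' @param coords_path CSV with header `spot_id,x,y`
#' @param domains_path,proportions_path optional CSVs as described above
#' @return a [spatial_dataset()]
#' @export
read_spatial_dataset <- function(matrix_path, features_path, barcodes_path,
                                 coords_path, domains_path = NULL,
                                 proportions_path = NULL) {
  for (p in c(matrix_path, features_path, barcodes_path, coords_path,
              domains_path, proportions_path))
    if (!file.exists(p)) stopf("file not found: %s", p)

  m <- Matrix::readMM(matrix_path)
  genes <- read.delim(features_path, header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  barcodes <- read.delim(barcodes_path, header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
    # genes x spots, as stored
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(genes)) {
    m <- Matrix::t(m)
  } else {
    stopf("matrix is %d x %d but there are %d features and %d barcodes",
          nrow(m), ncol(m), length(genes), length(barcodes))
  }

  coords <- read.csv(coords_path, stringsAsFactors = FALSE)
  req <- c("spot_id", "x", "y")
  if (!all(req %in% names(coords)))
    stopf("coords CSV must have columns spot_id,x,y")
  missing_bc <- setdiff(barcodes, coords$spot_id)
  extra_bc <- setdiff(coords$spot_id, barcodes)
  if (length(missing_bc) || length(extra_bc))
    stopf(paste0("coords/barcodes mismatch: %d barcodes missing from coords",
                 ", %d coord rows absent from barcodes"),
          length(missing_bc), length(extra_bc))
  coords <- coords[match(barcodes, coords$spot_id), ]

  domains <- NULL
  if (!is.null(domains_path)) {
    dtab <- read.csv(domains_path, stringsAsFactors = FALSE)
    if (!all(c("spot_id", "domain") %in% names(dtab)))
      stopf("domains CSV must have columns spot_id,domain")
    idx <- match(barcodes, dtab$spot_id)
    if (anyNA(idx)) stopf("domains CSV does not cover every barcode")
    domains <- dtab$domain[idx]
  }
  proportions <- NULL
  if (!is.null(proportions_path)) {
    ptab <- read.csv(proportions_path, stringsAsFactors = FALSE,
                     check.names = FALSE)
    if (names(ptab)[1] != "spot_id")
      stopf("proportions CSV must start with a spot_id column")
    idx <- match(barcodes, ptab$spot_id)
    if (anyNA(idx)) stopf("proportions CSV does not cover every barcode")
    proportions <- as.matrix(ptab[idx, -1, drop = FALSE])
  }

  spatial_dataset(m, coords = as.matrix(coords[, c("x", "y")]),
                  gene_ids = genes, spot_ids = barcodes,
                  domains = domains, proportions = proportions)
}

#' Write a spatial dataset to the standard file layout
#'
#' Inverse of [read_spatial_dataset()]: writes `matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`, `coords.csv` and, when present, `domains.csv` and
#' `proportions.csv` into `dir`. Round-trips losslessly.
#'
#' @param ds a [spatial_dataset()]
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_spatial_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "spatial_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(ds$counts, file.path(dir, "matrix.mtx"))
  writeLines(ds$gene_ids, file.path(dir, "features.tsv"))
  writeLines(ds$spot_ids, file.path(dir, "barcodes.tsv"))
  write.csv(data.frame(spot_id = ds$spot_ids,
                       x = ds$coords[, 1], y = ds$coords[, 2]),
            file.path(dir, "coords.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(ds$domains))
    write.csv(data.frame(spot_id = ds$spot_ids,
                         domain = as.character(ds$domains)),
              file.path(dir, "domains.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(ds$proportions)) {
    ptab <- data.frame(spot_id = ds$spot_ids, ds$proportions,
                       check.names = FALSE)
    write.csv(ptab, file.path(dir, "proportions.csv"),
              row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
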