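#' Configuration for the synthetic spatial-data generator
#'
#' Describes a square lattice of spots partitioned into `n_domains`
#' contiguous vertical bands, with negative-binomial expression, planted
#' domain-marker genes, and Dirichlet per-spot cell-type proportions. These
#' fixtures provide the ground truth (domains, NB parameters, markers,
#' proportions) that every metric and the simulation adaptor are tested
#' against.
#'
#' @param n_spots_side lattice side length (total spots = side^2)
#' @param n_genes number of genes
#' @param n_domains number of spatial domains K (vertical bands)
#' @param nb_mean_range range for per-gene baseline NB means (uniform draw)
#' @param nb_dispersion NB size parameter r; variance is `mu + mu^2 / r`
#' @param domain_effect multiplicative fold-change applied to a domain's
#'   marker genes inside that domain
#' @param n_marker_genes_per_domain planted marker genes per domain
#' @param n_cell_types number of cell types for the proportion model
#' @param dirichlet_concentration list of length `n_domains`, one
#'   concentration vector (length `n_cell_types`) per domain; default gives
#'   each domain a distinct dominant type
#' @param seed RNG seed; all generators are bit-reproducible given the seed
#' @return object of class `synthetic_config`
#' @export
synthetic_config <- function(n_spots_side = 20L, n_genes = 150L,
                             n_domains = 3L, nb_mean_range = c(0.5, 20),
                             nb_dispersion = 2, domain_effect = 4,
                             n_marker_genes_per_domain = 10L,
                             n_cell_types = 4L,
                             dirichlet_concentration = NULL, seed = 1L) {
  if (n_domains > n_spots_side^2)
    stopf("n_domains (%d) exceeds spot count (%d)", n_domains, n_spots_side^2)
  if (nb_dispersion <= 0) stopf("nb_dispersion must be positive")
  if (domain_effect <= 0) stopf("domain_effect must be positive")
  if (is.null(dirichlet_concentration)) {
    dirichlet_concentration <- lapply(seq_len(n_domains), function(d) {
      conc <- rep(1, n_cell_types)
      conc[((d - 1L) %% n_cell_types) + 1L] <- 8
      conc
    })
  }
  if (length(dirichlet_concentration) != n_domains)
    stopf("need one Dirichlet concentration vector per domain")
  for (v in dirichlet_concentration)
    if (length(v) != n_cell_types)
      stopf("concentration length %d != n_cell_types %d", length(v), n_cell_types)
  structure(list(n_spots_side = as.integer(n_spots_side),
                 n_genes = as.integer(n_genes),
                 n_domains = as.integer(n_domains),
                 nb_mean_range = nb_mean_range,
                 nb_dispersion = nb_dispersion,
                 domain_effect = domain_effect,
                 n_marker_genes_per_domain = as.integer(n_marker_genes_per_domain),
                 n_cell_types = as.integer(n_cell_types),
                 dirichlet_concentration = dirichlet_concentration,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate the lattice skeleton: coordinates and domain bands
#'
#' Spots on an integer square lattice, assigned to K contiguous vertical
#' bands of (near-)equal width. Contiguous bands guarantee positive spatial
#' autocorrelation of the planted markers, the property every spatial
#' statistic relies on.
#'
#' @param cfg a [synthetic_config()]
#' @return list with `coords` (spots x 2), `domains` (factor), `spot_ids`
#' @export
generate_domain_lattice <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  s <- cfg$n_spots_side
  coords <- cbind(x = rep(seq_len(s), times = s),
                  y = rep(seq_len(s), each = s))
  # vertical bands: domain determined by x coordinate
  band <- ceiling(coords[, "x"] / s * cfg$n_domains)
  band <- pmin(pmax(band, 1L), cfg$n_domains)
  list(coords = coords,
       domains = factor(paste0("D", band)),
       spot_ids = sprintf("spot%04d", seq_len(s^2)))
}

#' Generate negative-binomial counts on a lattice skeleton
#'
#' Per gene g a baseline mean `mu_g ~ Uniform(nb_mean_range)`; each domain's
#' marker genes have mean `mu_g * domain_effect` inside that domain. Counts
#' are independent NB draws with variance `mu + mu^2 / dispersion`.
#'
#' @param skeleton result of [generate_domain_lattice()]
#' @param cfg a [synthetic_config()]
#' @return a [spatial_dataset()] with attributes `truth_params` (per-gene
#'   baseline means and dispersion) and `truth_markers` (data frame of
#'   planted marker genes and their domains)
#' @export
generate_counts_nb <- function(skeleton, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(skeleton$domains)) stopf("skeleton has no domains")
  G <- cfg$n_genes
  n <- nrow(skeleton$coords)
  K <- cfg$n_domains
  nm <- cfg$n_marker_genes_per_domain
  if (K * nm > G) stopf("too many marker genes for %d genes", G)

  with_seed(cfg$seed, {
    mu <- runif(G, cfg$nb_mean_range[1], cfg$nb_mean_range[2])
    gene_ids <- sprintf("g%04d", seq_len(G))
    # first K*nm genes are markers, nm per domain
    marker_gene <- seq_len(K * nm)
    marker_domain <- rep(levels(skeleton$domains)[seq_len(K)], each = nm)
    M <- matrix(mu, nrow = G, ncol = n)
    dom <- as.character(skeleton$domains)
    for (i in seq_along(marker_gene)) {
      in_dom <- dom == marker_domain[i]
      M[marker_gene[i], in_dom] <- mu[marker_gene[i]] * cfg$domain_effect
    }
    counts <- matrix(rnbinom(G * n, size = cfg$nb_dispersion, mu = as.vector(M)),
                     nrow = G, ncol = n)
    rownames(counts) <- gene_ids
    colnames(counts) <- skeleton$spot_ids
  })
  ds <- spatial_dataset(counts, coords = skeleton$coords,
                        gene_ids = gene_ids, spot_ids = skeleton$spot_ids,
                        domains = skeleton$domains)
  attr(ds, "truth_params") <- data.frame(gene = gene_ids, baseline_mean = mu,
                                         dispersion = cfg$nb_dispersion)
  attr(ds, "truth_markers") <- data.frame(gene = gene_ids[marker_gene],
                                          domain = marker_domain)
  ds
}

#' Generate per-spot cell-type proportions
#'
#' Each spot's proportion row is drawn from its domain's Dirichlet
#' distribution (gamma draws renormalized to sum exactly to 1).
#'
#' @inheritParams generate_counts_nb
#' @return spots x types matrix, rows summing to 1
#' @export
generate_celltype_proportions <- function(skeleton, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- nrow(skeleton$coords)
  Tn <- cfg$n_cell_types
  P <- matrix(NA_real_, n, Tn)
  with_seed(cfg$seed + 1L, {
    dom_idx <- as.integer(skeleton$domains)
    for (i in seq_len(n)) {
      conc <- cfg$dirichlet_concentration[[dom_idx[i]]]
      g <- rgamma(Tn, shape = conc, rate = 1)
      P[i, ] <- g / sum(g)
    }
  })
  dimnames(P) <- list(skeleton$spot_ids, paste0("type", seq_len(Tn)))
  P
}

#' Generate a paired single-cell reference
#'
#' Cells drawn per type with type-specific NB means consistent with the
#' spot-level expression model: marker genes of domain d are upweighted in
#' the cell type dominant in d, so deconvolution of fixture spots against
#' this reference is well-posed.
#'
#' @param cfg a [synthetic_config()]
#' @param cells_per_type cells simulated per type
#' @return a [single_cell_reference()] with attribute `truth_type_means`
#'   (genes x types matrix of NB means)
#' @export
generate_paired_reference <- function(cfg, cells_per_type = 200L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  G <- cfg$n_genes
  Tn <- cfg$n_cell_types
  with_seed(cfg$seed + 2L, {
    mu <- runif(G, cfg$nb_mean_range[1], cfg$nb_mean_range[2])
    type_means <- matrix(mu, G, Tn)
    nm <- cfg$n_marker_genes_per_domain
    # domain d markers upweighted in the type dominant in domain d
    for (d in seq_len(cfg$n_domains)) {
      ty <- ((d - 1L) %% Tn) + 1L
      idx <- ((d - 1L) * nm + 1L):(d * nm)
      type_means[idx, ty] <- mu[idx] * cfg$domain_effect
    }
    counts <- matrix(0L, G, Tn * cells_per_type)
    types <- rep(paste0("type", seq_len(Tn)), each = cells_per_type)
    for (t in seq_len(Tn)) {
      cols <- ((t - 1L) * cells_per_type + 1L):(t * cells_per_type)
      counts[, cols] <- rnbinom(G * cells_per_type, size = cfg$nb_dispersion,
                                mu = rep(type_means[, t], cells_per_type))
    }
    rownames(counts) <- sprintf("g%04d", seq_len(G))
    colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  })
  ref <- single_cell_reference(counts, types)
  dimnames(type_means) <- list(rownames(counts), paste0("type", seq_len(Tn)))
  attr(ref, "truth_type_means") <- type_means
  ref
}

#' Generate a complete synthetic fixture dataset
#'
#' Convenience wrapper chaining [generate_domain_lattice()],
#' [generate_counts_nb()] and [generate_celltype_proportions()].
#'
#' @param cfg a [synthetic_config()]
#' @return a [spatial_dataset()] with domains, proportions and truth
#'   attributes
#' @export
generate_fixture <- function(cfg = synthetic_config()) {
  skel <- generate_domain_lattice(cfg)
  ds <- generate_counts_nb(skel, cfg)
  ds$proportions <- generate_celltype_proportions(skel, cfg)
  ds
}
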