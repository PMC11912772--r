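#' Per-spot library size
#'
#' Total UMI counts per spot (column sums of the raw count matrix).
#'
#' @param ds a [spatial_dataset()]
#' @return named numeric vector, one value per spot
#' @export
library_size <- function(ds) {
  stopifnot(inherits(ds, "spatial_dataset"))
  setNames(Matrix::colSums(ds$counts), ds$spot_ids)
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Per-spot scaling factors comparing each library's composition to a
#' reference library. For test spot k and reference r, the per-gene
#' log-ratio is \eqn{M_g = \log_2(Y_{gk}/N_k) - \log_2(Y_{gr}/N_r)} and the
#' absolute intensity \eqn{A_g = \frac12[\log_2(Y_{gk}/N_k) +
#' \log_2(Y_{gr}/N_r)]}, over genes with positive counts in both libraries.
#' After trimming the most extreme `trim_M` fraction of M-values on each
#' side and the most extreme `trim_A` fraction of A-values,
#' \deqn{\log_2 TMM_k = \sum_{g \in G^*} w_g M_g / \sum_{g \in G^*} w_g}
#' with inverse-variance weights \eqn{w_g = 1/v_g}, where
#' \eqn{v_g = (N_k - Y_{gk})/(N_k Y_{gk}) + (N_r - Y_{gr})/(N_r Y_{gr})}
#' is the delta-method variance of \eqn{M_g}.
#' The reference spot is the one whose upper-quartile count fraction is
#' closest to the mean upper-quartile across spots.
#'
#' `as_printed = TRUE` switches the M-value to the ratio-of-logs form
#' \eqn{M_g = \log_2(Y_{gk}/N_k) / \log_2(Y_{gr}/N_r)} for auditing; the
#' default difference form is the canonical definition.
#'
#' @param ds a [spatial_dataset()]
#' @param ref_spot index of the reference spot, or `NULL` for the
#'   upper-quartile rule
#' @param trim_M,trim_A two-sided trim fractions on M and A
#' @param as_printed use the ratio-of-logs M-value variant
#' @return named numeric vector of TMM factors (reference spot has factor 1);
#'   attribute `ref_spot` records the reference index
#' @export
tmm_factor <- function(ds, ref_spot = NULL, trim_M = 0.30, trim_A = 0.05,
                       as_printed = FALSE) {
  stopifnot(inherits(ds, "spatial_dataset"))
  m <- as.matrix(ds$counts)
  N <- colSums(m)
  if (any(N <= 0)) stopf("zero library size for spot(s): %s",
                         paste(ds$spot_ids[N <= 0], collapse = ", "))
  if (is.null(ref_spot)) {
    uq <- apply(m, 2, function(col) quantile(col, 0.75)) / N
    ref_spot <- which.min(abs(uq - mean(uq)))
  }
  r <- m[, ref_spot]
  Nr <- N[ref_spot]
  out <- numeric(ncol(m))
  for (k in seq_len(ncol(m))) {
    if (k == ref_spot) { out[k] <- 1; next }
    y <- m[, k]
    keep <- y > 0 & r > 0
    if (!any(keep)) stopf("no genes shared with the reference for spot %s",
                          ds$spot_ids[k])
    fk <- y[keep] / N[k]; fr <- r[keep] / Nr
    M <- if (as_printed) log2(fk) / log2(fr) else log2(fk) - log2(fr)
    A <- (log2(fk) + log2(fr)) / 2
    v <- (N[k] - y[keep]) / (N[k] * y[keep]) + (Nr - r[keep]) / (Nr * r[keep])
    w <- 1 / v
    fin <- is.finite(M) & is.finite(A) & is.finite(w)
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    n <- length(M)
    if (n == 0) stopf("no genes survive trimming for spot %s", ds$spot_ids[k])
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    sel <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    if (!any(sel)) stopf("no genes survive trimming for spot %s", ds$spot_ids[k])
    if (max(abs(M[sel])) < 1e-10) { out[k] <- 1; next }
    out[k] <- 2^(sum(w[sel] * M[sel]) / sum(w[sel]))
  }
  res <- setNames(out, ds$spot_ids)
  attr(res, "ref_spot") <- ref_spot
  res
}

#' Effective library size
#'
#' Per-spot library size multiplied by its TMM normalization factor.
#'
#' @inheritParams tmm_factor
#' @param ... passed to [tmm_factor()]
#' @return named numeric vector per spot
#' @export
effective_library_size <- function(ds, ...) {
  ls <- library_size(ds)
  tmm <- tmm_factor(ds, ...)
  ls * as.numeric(tmm)
}

#' Scaled (z-scored) means and variances of the log2-CPM matrix
#'
#' Along the requested axis: per-spot (or per-gene) means and variances of
#' log2-CPM values, then z-score standardized across the axis population.
#' Two of the registry's metrics ("scaled mean", "scaled variance") at each
#' level are the standardized vectors returned here.
#'
#' @param ds a [spatial_dataset()]
#' @param axis `"spot"` (statistics per spot, across genes) or `"gene"`
#' @return list of class `moment_summary` with `means`, `variances`,
#'   `scaled_means`, `scaled_variances`
#' @export
scaled_moments <- function(ds, axis = c("spot", "gene")) {
  axis <- match.arg(axis)
  lc <- log2cpm(ds$counts)
  if (axis == "gene") lc <- t(lc)
  # now columns are the requested units
  mu <- colMeans(lc)
  v <- apply(lc, 2, var)
  zscore <- function(x) {
    s <- sd(x)
    if (s == 0) {
      warnf("constant %s-level vector: scaled values set to 0", axis)
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  }
  structure(list(axis = axis, means = mu, variances = v,
                 scaled_means = zscore(mu), scaled_variances = zscore(v)),
            class = "moment_summary")
}

#' Fraction of zero counts per spot or per gene
#'
#' @param ds a [spatial_dataset()]
#' @param axis `"spot"` or `"gene"`
#' @return numeric vector in `[0, 1]`
#' @export
fraction_zero <- function(ds, axis = c("spot", "gene")) {
  axis <- match.arg(axis)
  m <- ds$counts
  if (axis == "spot") {
    setNames(1 - Matrix::colSums(m > 0) / nrow(m), ds$spot_ids)
  } else {
    setNames(1 - Matrix::rowSums(m > 0) / ncol(m), ds$gene_ids)
  }
}

#' Paired relationship samples
#'
#' The three bivariate data-property samples: per spot, library size vs
#' fraction zero; per gene, raw-count mean vs variance; per gene, raw-count
#' mean vs fraction zero. Consumed by the bivariate kernel density
#' comparison.
#'
#' @param ds a [spatial_dataset()]
#' @param kind which relationship to compute
#' @return two-column matrix, one row per spot or gene
#' @export
relationship_sample <- function(ds, kind = c("libsize_vs_fraczero",
                                             "mean_vs_variance",
                                             "mean_vs_fraczero")) {
  kind <- match.arg(kind)
  m <- as.matrix(ds$counts)
  out <- switch(kind,
    libsize_vs_fraczero = cbind(libsize = library_size(ds),
                                fraczero = fraction_zero(ds, "spot")),
    mean_vs_variance = cbind(mean = rowMeans(m),
                             variance = apply(m, 1, var)),
    mean_vs_fraczero = cbind(mean = rowMeans(m),
                             fraczero = as.numeric(fraction_zero(ds, "gene"))))
  out
}

#' Pairwise Pearson correlation sample
#'
#' Pearson correlations on log2-CPM between pairs of spots (`axis =
#' "spot"`) or genes (`axis = "gene"`). All unordered pairs are used when
#' there are at most `max_pairs`; otherwise `max_pairs` pairs are sampled
#' uniformly without replacement (seeded). Constant units are skipped; the
#' skipped count is attached as attribute `n_skipped`.
#'
#' @param ds a [spatial_dataset()]
#' @param axis `"spot"` or `"gene"`
#' @param max_pairs maximum number of pairs
#' @param seed RNG seed for pair subsampling
#' @return numeric vector of correlations
#' @export
pairwise_correlation_sample <- function(ds, axis = c("spot", "gene"),
                                        max_pairs = 5000L, seed = 1L) {
  axis <- match.arg(axis)
  lc <- log2cpm(ds$counts)
  units <- if (axis == "spot") lc else t(lc)   # columns are units
  keep <- apply(units, 2, sd) > 0
  n_skipped <- sum(!keep)
  units <- units[, keep, drop = FALSE]
  m <- ncol(units)
  if (m < 2) stopf("fewer than 2 non-constant %ss", axis)
  npairs <- m * (m - 1) / 2
  if (npairs <= max_pairs) {
    idx <- which(upper.tri(diag(m)), arr.ind = TRUE)
  } else {
    lin <- with_seed(seed, sample(npairs, max_pairs))
    # map linear upper-triangle (column-major) index to (row, col)
    col <- ceiling((sqrt(8 * lin + 1) + 1) / 2)
    row <- lin - (col - 1) * (col - 2) / 2
    idx <- cbind(row, col)
  }
  vals <- vapply(seq_len(nrow(idx)), function(p) {
    cor(units[, idx[p, 1]], units[, idx[p, 2]])
  }, numeric(1))
  attr(vals, "n_skipped") <- n_skipped
  vals
}
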