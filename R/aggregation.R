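#' Rank-based overall score per method at one level
#'
#' Within each metric of the requested level, methods are ranked by raw KDE
#' z statistic in ascending order (1 = most similar to the real data; ties
#' get average ranks); each method's overall score at the level is the
#' unweighted mean of its ranks across the level's metrics. The ordering is
#' invariant to any strictly monotone transform of the statistics within a
#' metric.
#'
#' @param scores a [score_table()] data frame
#' @param level `"spot"`, `"gene"` or `"spatial"`
#' @return list with `ranks` (methods x metrics matrix) and `overall`
#'   (named vector of mean ranks)
#' @export
overall_rank_score <- function(scores, level = c("spot", "gene", "spatial")) {
  level <- match.arg(level)
  sub <- scores[scores$level == level & scores$status == "ok", , drop = FALSE]
  if (!nrow(sub)) stopf("no scores at level %s", level)
  metrics <- unique(sub$metric)
  methods <- unique(sub$method)
  ranks <- matrix(NA_real_, length(methods), length(metrics),
                  dimnames = list(methods, metrics))
  for (met in metrics) {
    s <- sub[sub$metric == met, ]
    missing <- setdiff(methods, s$method)
    if (length(missing))
      warnf("metric %s missing for method(s) %s; excluded from its ranking",
            met, paste(missing, collapse = ", "))
    ranks[s$method, met] <- rank(s$raw_z, ties.method = "average")
  }
  overall <- rowMeans(ranks, na.rm = TRUE)
  list(ranks = ranks, overall = overall)
}

#' Per-dataset consistency summary
#'
#' Mean raw KDE z statistic over each level's metrics for every
#' (method, dataset) combination -- the per-dataset summaries behind
#' box/forest-style consistency displays.
#'
#' @param scores a [score_table()] (possibly row-bound over datasets)
#' @return data frame with columns `method`, `dataset`, `level`, `mean_z`,
#'   `n_metrics`
#' @export
dataset_consistency <- function(scores) {
  sub <- scores[scores$status == "ok", , drop = FALSE]
  if (!nrow(sub)) stopf("no usable scores")
  agg <- aggregate(raw_z ~ method + dataset + level, data = sub, FUN = mean)
  cnt <- aggregate(raw_z ~ method + dataset + level, data = sub, FUN = length)
  names(agg)[4] <- "mean_z"
  agg$n_metrics <- cnt$raw_z
  agg
}

#' Concordance index
#'
#' Over all pairs (i, j) with distinct true outcomes, the fraction whose
#' predicted ordering matches the true ordering; predicted ties receive
#' half credit. 1 means perfect agreement, 0 perfect reversal.
#'
#' @param true_scores,predicted_scores equal-length numeric vectors
#' @return scalar C-index in `[0, 1]`
#' @export
concordance_index <- function(true_scores, predicted_scores) {
  if (length(true_scores) != length(predicted_scores))
    stopf("length mismatch")
  n <- length(true_scores)
  if (n < 2) stopf("need at least 2 items")
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (true_scores[i] == true_scores[j]) next
      den <- den + 1
      d_true <- true_scores[i] < true_scores[j]
      if (predicted_scores[i] == predicted_scores[j]) {
        num <- num + 0.5
      } else if ((predicted_scores[i] < predicted_scores[j]) == d_true) {
        num <- num + 1
      }
    }
  }
  if (den == 0) stopf("all true values tied: C-index undefined")
  num / den
}

#' Per-metric model-effect regression
#'
#' Ordinary least squares of the KDE statistic on simulation-method
#' indicator variables (reference level = first method alphabetically),
#' fitted per metric: quantifies how switching methods shifts the score.
#'
#' @param scores a [score_table()]
#' @param metric one registry metric name
#' @return data frame of coefficients with `estimate`, `std_error`,
#'   `p_value` per term
#' @export
model_effect_regression <- function(scores, metric) {
  sub <- scores[scores$metric == metric & scores$status == "ok", ,
                drop = FALSE]
  if (length(unique(sub$method)) < 2)
    stopf("need scores from >= 2 methods for metric %s", metric)
  sub$method <- factor(sub$method, levels = sort(unique(sub$method)))
  fit <- lm(raw_z ~ method, data = sub)
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
             p_value = sm[, 4], row.names = NULL)
}

#' Evaluation-grid skeleton
#'
#' One ledger row per (method, dataset, metric) combination, each with a
#' status field; the full benchmark design has cardinality equal to the
#' product of the three lists.
#'
#' @param methods,datasets character vectors of identifiers
#' @param metrics character vector (default: the registry's 35 metrics)
#' @return data frame with columns `method`, `dataset`, `metric`, `status`
#' @examples
#' nrow(evaluation_grid(paste0("m", 1:13), paste0("d", 1:10)))  # 4550
#' @export
evaluation_grid <- function(methods, datasets, metrics = NULL) {
  metrics <- metrics %||% metric_registry()$metric
  if (!length(methods) || !length(datasets) || !length(metrics))
    stopf("methods, datasets and metrics must be non-empty")
  if (anyDuplicated(methods) || anyDuplicated(datasets) ||
      anyDuplicated(metrics))
    stopf("duplicate identifiers")
  g <- expand.grid(metric = metrics, dataset = datasets, method = methods,
                   stringsAsFactors = FALSE)[, c(3, 2, 1)]
  g$status <- "pending"
  rownames(g) <- NULL
  g
}

#' Downsampling grid for scalability studies
#'
#' For each (spot count, gene count) combination, a seeded uniform
#' subsample of the dataset preserving coordinates. The defaults --
#' spots (200, 500, 1000, 3000, 5000) x genes (200, 500, 1000) -- give 15
#' datasets. Nested sizes under the same seed are containment-consistent:
#' the subsample of size s is the first s elements of one fixed
#' permutation, so a smaller subsample is always contained in a larger one.
#'
#' @param ds a [spatial_dataset()]
#' @param spot_counts,gene_counts sizes to draw (each must not exceed the
#'   dataset's size)
#' @param seed RNG seed
#' @return named list of `spatial_dataset`s (`spots<S>_genes<G>`)
#' @export
downsampling_grid <- function(ds, spot_counts = c(200, 500, 1000, 3000, 5000),
                              gene_counts = c(200, 500, 1000), seed = 1L) {
  stopifnot(inherits(ds, "spatial_dataset"))
  n <- length(ds$spot_ids); G <- length(ds$gene_ids)
  if (any(spot_counts > n)) stopf("spot count request exceeds %d spots", n)
  if (any(gene_counts > G)) stopf("gene count request exceeds %d genes", G)
  perm <- with_seed(seed, list(spots = sample.int(n), genes = sample.int(G)))
  out <- list()
  for (s in spot_counts) {
    for (g in gene_counts) {
      si <- sort(perm$spots[seq_len(s)])
      gi <- sort(perm$genes[seq_len(g)])
      out[[sprintf("spots%d_genes%d", s, g)]] <- subset_dataset(ds, gi, si)
    }
  }
  out
}
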