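test_that("library size equals the summation oracle and is gene-order invariant", {
  m <- matrix(1, 3, 4)
  ds <- spatial_dataset(m, coords = cbind(1:4, 0))
  expect_equal(unname(library_size(ds)), rep(3, 4))

  ds2 <- random_counts_dataset(20)
  ls <- unname(library_size(ds2))
  loop <- sapply(seq_len(ncol(ds2$counts)), function(k) {
    s <- 0
    for (g in seq_len(nrow(ds2$counts))) s <- s + as.matrix(ds2$counts)[g, k]
    s
  })
  expect_equal(ls, loop)

  perm <- sample(nrow(ds2$counts))
  ds_p <- subset_dataset(ds2, genes = perm)
  expect_equal(unname(library_size(ds_p)), ls)
})

test_that("TMM is 1 for spots identical or depth-scaled to the reference", {
  base <- matrix(rpois(80, 20) + 1, 20, 4)
  base[, 2] <- base[, 1]          # identical to potential reference
  base[, 3] <- base[, 1] * 3     # depth-scaled copy
  ds <- spatial_dataset(base, coords = cbind(1:4, 0))
  tmm <- tmm_factor(ds, ref_spot = 1)
  expect_equal(unname(tmm[1:3]), c(1, 1, 1), tolerance = 1e-12)
})

test_that("TMM reduces to 1 under random depth scalings of the reference", {
  set.seed(31)
  for (rep in 1:5) {
    y <- rpois(30, 50) + 1
    sc <- sample(2:7, 3)
    m <- unname(cbind(y, y * sc[1], y * sc[2], y * sc[3]))
    ds <- spatial_dataset(m, coords = cbind(1:4, 0))
    expect_equal(as.numeric(tmm_factor(ds, ref_spot = 1)), rep(1, 4),
                 tolerance = 1e-12)
  }
})

test_that("TMM matches the explicit sort-trim-weight oracle", {
  set.seed(32)
  for (rep in 1:6) {
    m <- matrix(rpois(20 * 5, 30) + rpois(20 * 5, 5) * 10, 20, 5)
    ds <- spatial_dataset(m, coords = cbind(1:5, 0))
    tmm <- tmm_factor(ds, ref_spot = 2)
    N <- colSums(m)
    for (k in c(1, 3, 4, 5)) {
      expect_equal(unname(tmm[k]), oracle_tmm(m[, k], m[, 2], N[k], N[2]),
                   tolerance = 1e-12)
    }
  }
})

test_that("TMM agrees with edgeR up to its geometric-mean rescaling", {
  set.seed(33)
  m <- matrix(rnbinom(50 * 6, mu = 60, size = 3) + 1, 50, 6)
  ds <- spatial_dataset(m, coords = cbind(1:6, 0))
  mine <- as.numeric(tmm_factor(ds, ref_spot = 1))
  theirs <- edgeR::calcNormFactors(m, method = "TMM", refColumn = 1,
                                   logratioTrim = 0.30, sumTrim = 0.05,
                                   doWeighting = TRUE)
  # edgeR rescales factors to geometric mean 1; compare ratios to spot 1
  expect_equal(mine / mine[1], theirs / theirs[1], tolerance = 1e-6)
})

test_that("effective library size composes library size and TMM", {
  ds <- random_counts_dataset(40, n_genes = 20, n_spots = 6)
  eff <- effective_library_size(ds, ref_spot = 1)
  expect_equal(unname(eff),
               unname(library_size(ds)) *
                 as.numeric(tmm_factor(ds, ref_spot = 1)))

  base <- matrix(5, 10, 4)
  ds_eq <- spatial_dataset(base, coords = cbind(1:4, 0))
  expect_equal(unname(effective_library_size(ds_eq)),
               unname(library_size(ds_eq)))
})

test_that("scaled moments are z-scores and match the two-pass oracle", {
  ds <- random_counts_dataset(50, n_genes = 5, n_spots = 6)
  for (axis in c("spot", "gene")) {
    sm <- scaled_moments(ds, axis)
    expect_equal(mean(sm$scaled_means), 0, tolerance = 1e-9)
    expect_equal(sd(sm$scaled_means), 1, tolerance = 1e-9)
    expect_equal(mean(sm$scaled_variances), 0, tolerance = 1e-9)
    expect_equal(sd(sm$scaled_variances), 1, tolerance = 1e-9)
  }
  lc <- log2cpm(ds$counts)
  sm <- scaled_moments(ds, "spot")
  mu <- apply(lc, 2, mean)
  expect_equal(unname(sm$scaled_means), unname((mu - mean(mu)) / sd(mu)))

  # two identical spots: z-scores of a constant pair are 0 (with warning)
  m <- matrix(rpois(10, 6) + 1, 5, 2)
  m[, 2] <- m[, 1]
  # both the mean and the variance vectors are constant: two warnings
  expect_warning(expect_warning(sm2 <- scaled_moments(
    spatial_dataset(m, coords = cbind(1:2, 0)), "spot"), "constant"),
    "constant")
  expect_equal(unname(sm2$scaled_means), c(0, 0))
})

test_that("fraction zero counts zeros exactly", {
  m <- matrix(c(0, 1, 2, 0, 0, 3), 2, 3)
  ds <- spatial_dataset(m, coords = cbind(1:3, 0))
  expect_equal(unname(fraction_zero(ds, "spot")), c(0.5, 0.5, 0.5))
  expect_equal(unname(fraction_zero(ds, "gene")), c(2 / 3, 1 / 3))
  dense <- spatial_dataset(matrix(1, 2, 3), coords = cbind(1:3, 0))
  expect_true(all(fraction_zero(dense, "gene") == 0))
})

test_that("relationship samples zip their component metrics", {
  ds <- random_counts_dataset(60)
  rel <- relationship_sample(ds, "libsize_vs_fraczero")
  expect_identical(nrow(rel), ncol(ds$counts))
  expect_equal(unname(rel[, 1]), unname(library_size(ds)))
  expect_equal(unname(rel[, 2]), unname(fraction_zero(ds, "spot")))

  rel2 <- relationship_sample(ds, "mean_vs_fraczero")
  expect_equal(unname(rel2[, 2]), unname(fraction_zero(ds, "gene")))
})

test_that("mean-variance pairs track the identity line for Poisson data", {
  set.seed(61)
  m <- matrix(rpois(200 * 5000, 8), 200, 5000)
  ds <- spatial_dataset(m, coords = cbind(seq_len(5000), 0))
  rel <- relationship_sample(ds, "mean_vs_variance")
  rel_dev <- abs(rel[, 2] - rel[, 1]) / rel[, 1]
  expect_lt(median(rel_dev), 0.2)
})

test_that("pairwise correlations match the direct double-sum formula", {
  ds <- random_counts_dataset(70, n_genes = 10, n_spots = 8)
  vals <- pairwise_correlation_sample(ds, "gene", max_pairs = 100)
  expect_length(vals, choose(10, 2))
  lc <- log2cpm(ds$counts)
  k <- 0
  for (j in 2:10) for (i in 1:(j - 1)) {
    k <- k + 1
    A <- lc[i, ]; B <- lc[j, ]
    r <- sum((A - mean(A)) * (B - mean(B))) /
      (sqrt(sum((A - mean(A))^2)) * sqrt(sum((B - mean(B))^2)))
    expect_equal(vals[k], r, tolerance = 1e-12)
  }
})

test_that("correlation identities: duplicated spots give correlation 1", {
  m <- matrix(rpois(12, 9) + 1, 6, 2)
  m[, 2] <- m[, 1]
  ds <- spatial_dataset(m, coords = cbind(1:2, 0))
  expect_equal(as.numeric(pairwise_correlation_sample(ds, "spot")), 1)
  expect_true(all(abs(pairwise_correlation_sample(
    random_counts_dataset(81), "gene")) <= 1))
})

test_that("correlation subsampling is seeded and unbiased on small fixtures", {
  ds <- random_counts_dataset(80, n_genes = 30, n_spots = 10)
  s1 <- pairwise_correlation_sample(ds, "gene", max_pairs = 50, seed = 5)
  s2 <- pairwise_correlation_sample(ds, "gene", max_pairs = 50, seed = 5)
  expect_identical(s1, s2)
  full <- pairwise_correlation_sample(ds, "gene", max_pairs = 1e6)
  sub_means <- sapply(1:30, function(s)
    mean(pairwise_correlation_sample(ds, "gene", max_pairs = 100, seed = s)))
  mc_se <- sd(sub_means)
  expect_lt(abs(mean(sub_means) - mean(full)), 4 * mc_se + 1e-3)
})

test_that("property metrics are permutation-equivariant", {
  ds <- random_counts_dataset(90, n_genes = 15, n_spots = 12)
  set.seed(91)
  sp <- sample(12)
  ds_p <- subset_dataset(ds, spots = sp)
  expect_equal(unname(library_size(ds_p)), unname(library_size(ds))[sp])
  expect_equal(unname(fraction_zero(ds_p, "spot")),
               unname(fraction_zero(ds, "spot"))[sp])
  gp <- sample(15)
  ds_g <- subset_dataset(ds, genes = gp)
  expect_equal(unname(fraction_zero(ds_g, "gene")),
               unname(fraction_zero(ds, "gene"))[gp])
})
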