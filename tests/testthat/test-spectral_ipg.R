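# Cis masking, doubly stochastic scaling, eigendecomposition by modulus,
# k-means on rescaled eigenvectors, and cluster consolidation.

test_that("cis masking resamples cis pixels from their donor rows/columns", {
  m <- rand_sym_cm(20, weights = FALSE)
  bt <- bin_table(c(a = 10 * 25000, b = 10 * 25000), 25000)
  m <- contact_matrix(bt, m$values)
  mm <- mask_cis(m, seed = 3)
  code <- ipgtools:::chrom_code(bt)
  trans <- outer(code, code, "!=")
  expect_identical(mm$values[trans], m$values[trans])
  expect_equal(mm$values, t(mm$values))
  # every masked value is a member of its donor trans multiset
  for (i in 1:20) for (j in i:20) {
    if (code[i] != code[j]) next
    don <- c(m$values[i, trans[i, ]], m$values[trans[, j], j])
    expect_true(mm$values[i, j] %in% don)
  }
})

test_that("masking a constant-trans matrix fills cis with that constant", {
  bt <- bin_table(c(a = 5 * 5e4, b = 5 * 5e4), 5e4)
  v <- matrix(7, 10, 10)
  diag(v) <- 7
  m <- contact_matrix(bt, v)
  expect_true(all(mask_cis(m, seed = 1)$values == 7))
})

test_that("masking requires at least two chromosomes", {
  m <- rand_sym_cm(10)
  expect_error(mask_cis(m), ">=2 chromosomes")
})

test_that("stochastic scaling produces unit marginals on valid bins", {
  u <- uniform_cm(12)
  s <- stochastic_scale(u)
  expect_true(all(abs(s$values - 1 / 12) < 1e-9))

  m <- rand_sym_cm(30, seed = 6, weights = FALSE)
  m$values <- m$values + 1  # strictly positive
  m$bins$valid[c(3, 17)] <- FALSE
  s2 <- stochastic_scale(m)
  marg <- rowSums(s2$values[-c(3, 17), -c(3, 17)])
  expect_true(all(abs(marg - 1) < 1e-4))
  expect_true(all(s2$values[3, ] == 0))
})

test_that("eigendecomposition matches a dense solver and orders by modulus", {
  set.seed(8)
  n <- 30
  v <- matrix(rnorm(n * n), n, n)
  v <- (v + t(v)) / 2 + diag(n) * 0.1
  bt <- bin_table(c(e = n * 5e4), 5e4)
  m <- contact_matrix(bt, v, weights = rep(1, n), balanced = TRUE)
  spec <- eigendecompose(m, n_eigs = 6)
  oracle <- eigen(v, symmetric = TRUE)
  ord <- order(abs(oracle$values), decreasing = TRUE)
  expect_equal(spec$values, oracle$values[ord][1:6], tolerance = 1e-8)
  expect_true(all(diff(abs(spec$values)) <= 1e-12))
  for (k in 1:6) {
    dot <- abs(sum(spec$vectors[, k] * oracle$vectors[, ord[k]]))
    expect_equal(dot, 1, tolerance = 1e-8)
  }
  expect_error(eigendecompose(m, n_eigs = n), "smaller than")
})

test_that("two-block trans structure yields a two-valued leading vector", {
  bt <- bin_table(c(a = 10 * 5e4, b = 10 * 5e4), 5e4)
  blk <- ifelse(outer(rep(1:2, each = 10), rep(1:2, each = 10), "=="), 2, 0.5)
  m <- stochastic_scale(contact_matrix(bt, blk))
  spec <- eigendecompose(m, n_eigs = 2)
  e1 <- round(spec$vectors[, 1], 10)
  expect_equal(length(unique(e1)), 2)
  expect_lt(max(e1) * min(e1), 0)  # opposite signs per block
})

test_that("the trivial constant eigenvector is dropped before numbering", {
  u <- stochastic_scale(uniform_cm(15, n_chrom = 2))
  spec <- eigendecompose(u, n_eigs = 3)
  cv <- apply(spec$vectors, 2, function(x) stats::sd(x) / abs(mean(x)))
  expect_true(all(cv > 1e-3 | is.na(cv)))
  expect_true(all(abs(spec$values) < 0.999))
})

test_that("k-means on planted blobs recovers them exactly", {
  set.seed(2)
  centers <- matrix(c(0, 0, 5, 0, 0, 5), 3, 2, byrow = TRUE)
  lab <- rep(1:3, each = 60)
  X <- centers[lab, ] + matrix(rnorm(360, sd = 0.2), 180, 2)
  bt <- bin_table(c(k = 180 * 5e4), 5e4)
  spec <- structure(list(values = c(1, 0.5),
                         vectors = X, bins = bt, orientation_ref = NULL),
                    class = "eigenspectrum")
  cl <- cluster_bins(spec, k = 3, rescale = "none", seed = 4)
  expect_equal(ari(cl$cluster, lab), 1)
  expect_gt(cl$silhouette, 0.8)
  # determinism under a fixed seed
  cl2 <- cluster_bins(spec, k = 3, rescale = "none", seed = 4)
  expect_identical(cl$cluster, cl2$cluster)
})

test_that("silhouette is missing for a single cluster", {
  bt <- bin_table(c(k = 40 * 5e4), 5e4)
  spec <- structure(list(values = c(1), vectors = matrix(rnorm(40), 40, 1),
                         bins = bt, orientation_ref = NULL),
                    class = "eigenspectrum")
  cl <- cluster_bins(spec, k = 1)
  expect_true(is.na(cl$silhouette))
})

test_that("consolidation merges identical profiles and honors user maps", {
  bt <- bin_table(c(c = 80 * 5e4), 5e4)
  cl <- structure(list(k = 4, cluster = rep(1:4, each = 20),
                       ipg = factor(rep(paste0("IPG", 1:4), each = 20)),
                       cluster_to_ipg = stats::setNames(paste0("IPG", 1:4), 1:4),
                       silhouette = 0.5, bins = bt),
                  class = "ipg_assignment")
  prof <- c(rep(1, 20), rep(1, 20), rep(5, 20), rep(9, 20))
  tracks <- list(x = signal_track(bt, prof),
                 y = signal_track(bt, rev(prof)),
                 z = signal_track(bt, rep(c(0, 0, 3, -2), each = 20)))
  out <- consolidate_clusters(cl, tracks, merge_threshold = 0.9)
  expect_equal(out$cluster_to_ipg[["1"]], out$cluster_to_ipg[["2"]])
  expect_false(out$cluster_to_ipg[["3"]] == out$cluster_to_ipg[["4"]])
  # threshold 1 merges nothing
  none <- consolidate_clusters(cl, tracks, merge_threshold = 1)
  expect_equal(length(unique(none$cluster_to_ipg)), 4)
  # explicit map overrides; duplicated cluster ids are an error
  man <- consolidate_clusters(cl, cluster_map = c("1" = "X", "2" = "X"))
  expect_equal(unname(man$cluster_to_ipg[c("1", "2")]), c("X", "X"))
  expect_error(consolidate_clusters(cl,
    cluster_map = stats::setNames(c("X", "Y"), c("1", "1"))), "twice")
})

test_that("rank-m reconstruction error decreases monotonically", {
  sim <- default_sim()
  m <- default_balanced()
  bv <- balanced_values(m); bv[is.na(bv)] <- 0
  mb <- contact_matrix(m$bins, bv, weights = m$weights, balanced = TRUE)
  sto <- stochastic_scale(mask_cis(mb, seed = 2))
  idx <- which(sto$bins$valid)
  sub <- sto$values[idx, idx]
  e <- eigen(sub, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)
  errs <- vapply(1:6, function(m_) {
    keep <- ord[1:m_]
    approx <- e$vectors[, keep] %*% (e$values[keep] * t(e$vectors[, keep]))
    norm(sub - approx, "F")
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("clustering is insensitive to the masking seed", {
  sim <- default_sim()
  m <- default_balanced()
  r1 <- ipg_pipeline(m, sim$tracks, mask_seed = 1, cluster_seed = 5)
  r2 <- ipg_pipeline(m, sim$tracks, mask_seed = 2, cluster_seed = 5)
  ok <- !is.na(r1$ipg) & !is.na(r2$ipg)
  expect_gt(ari(r1$ipg[ok], r2$ipg[ok]), 0.95)
})

test_that("positional cluster pairs consolidate back to planted states", {
  sim <- default_sim()
  m <- default_balanced()
  res <- ipg_pipeline(m, sim$tracks, mask_seed = 101, cluster_seed = 102)
  expect_gt(res$k, length(unique(res$cluster_to_ipg)))
  ok <- !is.na(res$ipg)
  expect_gt(ari(res$ipg[ok], sim$truth$state[ok]), 0.9)
})
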