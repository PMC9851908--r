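# Spectral decomposition of trans contact frequencies: cis masking by
# resampling, iterative proportional fitting to a doubly stochastic matrix,
# eigendecomposition ordered by eigenvalue modulus, k-means on rescaled
# eigenvectors, and consolidation of clusters into interaction profile
# groups guided by functional tracks.

#' Mask cis pixels by resampling trans pixels
#'
#' Every cis pixel (i, j) in the upper triangle is replaced by a value drawn
#' uniformly from the trans pixels of row i or column j (one fair coin flip
#' per pixel); the lower triangle is mirrored so symmetry is preserved.
#' Trans pixels are untouched. Only valid bins donate.
#'
#' @param m A [contact_matrix()] with at least two chromosomes.
#' @param seed RNG seed for the resampling.
#' @return A [contact_matrix()] with masked cis values.
#' @export
mask_cis <- function(m, seed = 1L) {
  bins <- m$bins
  if (length(unique(bins$chrom[bins$valid])) < 2)
    stop("cis masking requires >=2 chromosomes")
  v <- m$values
  n <- nrow(v)
  code <- chrom_code(bins)
  valid <- bins$valid
  with_seed(seed, {
    # donor pool per bin: trans values against valid bins
    donors <- lapply(seq_len(n), function(i)
      v[i, code != code[i] & valid])
    ut <- which(upper.tri(v, diag = TRUE) & outer(code, code, "==") &
                  outer(valid, valid, "&"), arr.ind = TRUE)
    if (nrow(ut)) {
      use_row <- stats::runif(nrow(ut)) < 0.5
      pick <- numeric(nrow(ut))
      for (k in seq_len(nrow(ut))) {
        pool <- donors[[if (use_row[k]) ut[k, 1] else ut[k, 2]]]
        pick[k] <- pool[sample.int(length(pool), 1)]
      }
      v[ut] <- pick
      v[ut[, c(2, 1), drop = FALSE]] <- pick
    }
    contact_matrix(bins, v, weights = m$weights, balanced = m$balanced)
  })
}

#' Rescale a symmetric matrix to be doubly stochastic
#'
#' Iterative proportional fitting so every valid row and column sums to 1
#' within tolerance; invalid bins are excluded from the marginals.
#'
#' @param m A (cis-masked) [contact_matrix()].
#' @param tol Relative marginal variance at convergence.
#' @param max_iter Maximum iterations.
#' @return A [contact_matrix()] whose values are the rescaled matrix
#'   (`balanced = TRUE`); invalid rows/columns are zero.
#' @export
stochastic_scale <- function(m, tol = 1e-10, max_iter = 1000) {
  valid <- m$bins$valid
  b <- sinkhorn(m$values, valid, tol, max_iter, target = 1)
  b0 <- ifelse(is.na(b), 0, b)
  v <- m$values * outer(b0, b0)
  contact_matrix(m$bins, v, weights = b, balanced = TRUE)
}

#' Leading eigenpairs of the processed trans matrix
#'
#' Eigenpairs of the valid-bin submatrix are ordered by descending
#' eigenvalue modulus (not algebraic sign). The trivial constant
#' eigenvector of the doubly stochastic matrix (coefficient of variation
#' < 1e-3) is detected and dropped before numbering E1..Em. Each
#' eigenvector's sign is fixed so its correlation with `orientation_track`
#' is non-negative; without a reference (or with zero correlation) the
#' first nonzero entry is made positive.
#'
#' @param m A doubly stochastic [contact_matrix()] from [stochastic_scale()].
#' @param n_eigs Number of leading components to keep (default 9, E1-E9).
#' @param orientation_track Optional [signal_track()] used for sign fixing.
#' @return An `eigenspectrum`: `values` (eigenvalues), `vectors` (bins x m,
#'   `NA` on invalid bins), `bins`, `orientation_ref`.
#' @export
eigendecompose <- function(m, n_eigs = 9, orientation_track = NULL) {
  valid <- m$bins$valid
  idx <- which(valid)
  if (n_eigs >= length(idx))
    stop("n_eigs must be smaller than the number of valid bins")
  sub <- m$values[idx, idx, drop = FALSE]
  eig <- eigen(sub, symmetric = TRUE)
  ord <- order(abs(eig$values), decreasing = TRUE)
  lam <- eig$values[ord]
  vec <- eig$vectors[, ord, drop = FALSE]
  # drop the trivial constant eigenvector (leading for a stochastic matrix)
  keep <- seq_len(ncol(vec))
  cv <- apply(vec, 2, function(x) stats::sd(x) / max(abs(mean(x)), 1e-300))
  triv <- which(cv < 1e-3)
  if (length(triv)) keep <- setdiff(keep, triv[1])
  keep <- keep[seq_len(n_eigs)]
  lam <- lam[keep]
  vec <- vec[, keep, drop = FALSE]
  ref <- if (!is.null(orientation_track)) orientation_track$value[idx]
  for (j in seq_len(ncol(vec))) {
    s <- 0
    if (!is.null(ref)) {
      cc <- suppressWarnings(stats::cor(vec[, j], ref,
                                        use = "complete.obs"))
      if (is.finite(cc) && cc != 0) s <- sign(cc)
    }
    if (s == 0) {
      nz <- which(vec[, j] != 0)[1]
      s <- sign(vec[nz, j])
    }
    vec[, j] <- vec[, j] * s
  }
  vectors <- matrix(NA_real_, nrow(m$bins), length(keep),
                    dimnames = list(NULL, paste0("E", seq_along(keep))))
  vectors[idx, ] <- vec
  structure(list(values = lam, vectors = vectors, bins = m$bins,
                 orientation_ref = if (!is.null(orientation_track))
                   orientation_track$name),
            class = "eigenspectrum")
}

#' @export
print.eigenspectrum <- function(x, ...) {
  cat(sprintf("eigenspectrum: %d components over %d bins\n",
              length(x$values), nrow(x$bins)))
  cat("  |eigenvalues|:", paste(sprintf("%.4f", abs(x$values)), collapse = " "),
      "\n")
  invisible(x)
}

# representation used for clustering: rescaled eigenvector columns
eig_embedding <- function(spec, rescale = c("eigenvalue", "unit-variance", "none")) {
  rescale <- match.arg(rescale)
  X <- spec$vectors
  ok <- stats::complete.cases(X)
  Xo <- X[ok, , drop = FALSE]
  Xo <- switch(rescale,
    eigenvalue = sweep(Xo, 2, abs(spec$values), "*"),
    `unit-variance` = scale(Xo, center = FALSE,
                            scale = apply(Xo, 2, stats::sd)),
    none = Xo)
  list(X = Xo, ok = ok)
}

#' Cluster bins on rescaled eigenvectors
#'
#' k-means on the rows of the rescaled, concatenated eigenvectors; the
#' default rescaling multiplies each unit-norm eigenvector by its
#' eigenvalue modulus so components are weighted by the structure they
#' capture. The mean silhouette width is computed on the same
#' representation.
#'
#' @param spec An [eigendecompose()] result.
#' @param k Number of clusters (default 8).
#' @param rescale One of `"eigenvalue"`, `"unit-variance"`, `"none"`.
#' @param seed RNG seed.
#' @param n_init Number of k-means restarts; the best inertia wins.
#' @return An `ipg_assignment`: per-bin `cluster` (integer, `NA` on invalid
#'   bins), `ipg` (factor, initially one group per cluster),
#'   `cluster_to_ipg` map, `silhouette`, `bins`.
#' @export
cluster_bins <- function(spec, k = 8, rescale = "eigenvalue", seed = 1L,
                         n_init = 30) {
  emb <- eig_embedding(spec, rescale)
  X <- emb$X
  if (nrow(unique(X)) < k) stop("fewer distinct rows than clusters")
  km <- with_seed(seed, stats::kmeans(X, centers = k, nstart = n_init,
                                      iter.max = 100))
  sil <- NA_real_
  if (k > 1) {
    si <- cluster::silhouette(km$cluster, stats::dist(X))
    sil <- mean(si[, "sil_width"])
  }
  cl <- rep(NA_integer_, nrow(spec$vectors))
  cl[emb$ok] <- km$cluster
  cluster_to_ipg <- stats::setNames(paste0("IPG", seq_len(k)), seq_len(k))
  structure(list(k = k, cluster = cl,
                 ipg = factor(cluster_to_ipg[as.character(cl)],
                              levels = unique(cluster_to_ipg)),
                 cluster_to_ipg = cluster_to_ipg,
                 silhouette = sil, bins = spec$bins, rescale = rescale),
            class = "ipg_assignment")
}

#' @export
print.ipg_assignment <- function(x, ...) {
  cat(sprintf("ipg_assignment: k = %d clusters -> %d groups, silhouette %.3f\n",
              x$k, length(unique(stats::na.omit(x$cluster_to_ipg))),
              x$silhouette))
  print(table(x$ipg, useNA = "ifany"))
  invisible(x)
}

#' Silhouette over a grid of k
#'
#' @param spec An [eigendecompose()] result.
#' @param k_grid Candidate cluster counts (default 4:12).
#' @inheritParams cluster_bins
#' @return Data frame with columns `k` and `silhouette`.
#' @export
silhouette_scan <- function(spec, k_grid = 4:12, rescale = "eigenvalue",
                            seed = 1L, n_init = 10) {
  data.frame(k = k_grid,
             silhouette = vapply(k_grid, function(k)
               cluster_bins(spec, k, rescale, seed, n_init)$silhouette,
               numeric(1)))
}

#' Consolidate clusters into interaction profile groups
#'
#' Per-cluster mean functional profiles (one entry per track) are
#' standardized track-wise across clusters; clusters whose profile vectors
#' correlate above `merge_threshold` are merged (connected components of
#' the correlation graph). An explicit `cluster_map` overrides the
#' automatic merge.
#'
#' @param assign An [cluster_bins()] result.
#' @param tracks Named list of [signal_track()] objects on the same bins.
#' @param merge_threshold Pearson correlation above which clusters merge
#'   (1.0 merges nothing); within-state cluster pairs correlate near 1 so
#'   the default cut is high.
#' @param cluster_map Optional named character vector mapping cluster id to
#'   group name; each cluster must be mapped at most once.
#' @return The assignment with `ipg` and `cluster_to_ipg` replaced and a
#'   `merge_report` attached.
#' @export
consolidate_clusters <- function(assign, tracks = NULL, merge_threshold = 0.98,
                                 cluster_map = NULL) {
  k <- assign$k
  if (!is.null(cluster_map)) {
    ids <- names(cluster_map)
    if (anyDuplicated(ids)) stop("cluster mapped twice in cluster_map")
    map <- stats::setNames(paste0("IPG", seq_len(k)), seq_len(k))
    map[ids] <- cluster_map
    groups <- map
    report <- data.frame(cluster = names(map), ipg = unname(map))
  } else {
    if (is.null(tracks) || !length(tracks))
      stop("tracks are required for automatic consolidation")
    prof <- sapply(tracks, function(tr)
      tapply(tr$value, assign$cluster, mean, na.rm = TRUE))
    prof <- prof[as.character(seq_len(k)), , drop = FALSE]
    prof_z <- scale(prof)  # standardize each track across clusters
    prof_z[, apply(prof, 2, stats::sd) == 0] <- 0
    cmat <- suppressWarnings(stats::cor(t(prof_z)))
    cmat[is.na(cmat)] <- 0
    adj <- cmat > merge_threshold
    diag(adj) <- TRUE
    # connected components by label propagation
    comp <- seq_len(k)
    repeat {
      new <- vapply(seq_len(k), function(i) min(comp[adj[i, ]]), numeric(1))
      if (all(new == comp)) break
      comp <- new
    }
    comp <- match(comp, sort(unique(comp)))
    groups <- stats::setNames(paste0("IPG", comp), seq_len(k))
    report <- data.frame(cluster = seq_len(k), ipg = unname(groups),
                         profile_component = comp)
  }
  ipg_levels <- unique(unname(groups))
  out <- assign
  out$cluster_to_ipg <- groups
  out$ipg <- factor(groups[as.character(assign$cluster)], levels = ipg_levels)
  out$merge_report <- report
  out
}

#' Full spectral IPG pipeline
#'
#' mask cis -> doubly stochastic scaling -> eigendecomposition ->
#' k-means -> consolidation.
#'
#' @param m A balanced-or-raw [contact_matrix()] (bin-filtered).
#' @param tracks Named list of functional [signal_track()]s used for sign
#'   orientation (first track) and consolidation.
#' @param n_eigs,k,rescale,n_init,merge_threshold Stage parameters.
#' @param mask_seed,cluster_seed Stage seeds.
#' @return Consolidated `ipg_assignment` with the `eigenspectrum` attached
#'   as `$spectrum`.
#' @export
ipg_pipeline <- function(m, tracks, n_eigs = 9, k = 8, rescale = "eigenvalue",
                         n_init = 30, merge_threshold = 0.98,
                         mask_seed = 1L, cluster_seed = 1L) {
  if (!m$balanced && !is.null(m$weights)) {
    bv <- balanced_values(m)
    bv[is.na(bv)] <- 0
    m <- contact_matrix(m$bins, bv, weights = m$weights, balanced = TRUE)
  }
  masked <- mask_cis(m, seed = mask_seed)
  sto <- stochastic_scale(masked)
  spec <- eigendecompose(sto, n_eigs = n_eigs, orientation_track = tracks[[1]])
  cl <- cluster_bins(spec, k = k, rescale = rescale, seed = cluster_seed,
                     n_init = n_init)
  out <- consolidate_clusters(cl, tracks, merge_threshold = merge_threshold)
  out$spectrum <- spec
  out
}
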