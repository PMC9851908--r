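# Distance-decay (P(s)) curves, log-log derivatives, saddle plots and
# pairwise group observed/expected summaries.

# geometric separation strata with ratio 2^(1/8); stratum index for a
# separation of d bins (d >= 1)
STRATUM_RATIO <- 2^(1 / 8)

stratum_index <- function(d_bins) {
  pmax(0L, floor(log(d_bins) / log(STRATUM_RATIO))) + 1L
}

stratum_table <- function(max_index, bin_size) {
  k <- seq_len(max_index)
  lo <- STRATUM_RATIO^(k - 1)
  hi <- STRATUM_RATIO^k
  data.frame(stratum = k,
             s_lo = lo * bin_size, s_hi = hi * bin_size,
             s_mid = sqrt(lo * hi) * bin_size)
}

# upper-triangle cis pixel pooling into strata; returns per-stratum sums
pool_strata <- function(v, take, d_bins) {
  st <- stratum_index(d_bins)
  ok <- take & !is.na(v)
  data.frame(stratum = sort(unique(st[ok])),
             sum = as.numeric(tapply(v[ok], st[ok], sum)),
             n = as.numeric(tapply(v[ok], st[ok], length)))
}

#' Per-chromosome expected contact frequency versus distance
#'
#' Mean balanced contact frequency over valid cis pixels, pooled into
#' geometrically increasing separation strata (ratio 2^(1/8)). The main
#' diagonal (s = 0) is excluded.
#'
#' @param m A balanced [contact_matrix()].
#' @return A `contact_decay` data frame with columns `chrom`, `stratum`,
#'   `s_lo`, `s_hi`, `s_mid` (bp), `P`, `n_pixels`.
#' @export
expected_cis <- function(m) {
  bins <- m$bins
  bs <- bin_size_of(bins)
  bv <- balanced_values(m)
  out <- list()
  for (ch in attr(bins, "chrom_order")) {
    sel <- which(bins$chrom == ch)
    if (sum(bins$valid[sel]) < 2) {
      warning("chromosome ", ch, " has fewer than 2 valid bins; skipped")
      next
    }
    sub <- bv[sel, sel, drop = FALSE]
    nc <- length(sel)
    ut <- which(upper.tri(sub), arr.ind = TRUE)
    d <- ut[, 2] - ut[, 1]
    ps <- pool_strata(sub[ut], rep(TRUE, nrow(ut)), d)
    if (!nrow(ps)) next
    st <- stratum_table(max(ps$stratum), bs)
    df <- merge(st[st$stratum %in% ps$stratum, ], ps, by = "stratum")
    out[[ch]] <- data.frame(chrom = ch, df[, c("stratum", "s_lo", "s_hi", "s_mid")],
                            P = df$sum / df$n, n_pixels = df$n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, bin_size = bs, class = c("contact_decay", "data.frame"))
}

# domain membership of each bin: index into `domains` covering the bin
# midpoint, NA when uncovered
bin_domain <- function(bins, domains) {
  mid <- bin_mid(bins)
  gmid <- as_granges(bins$chrom, floor(mid), floor(mid) + 1)
  gd <- as_granges(domains$chrom, domains$start, domains$end)
  ov <- GenomicRanges::findOverlaps(gmid, gd, select = "first")
  as.integer(ov)
}

#' P(s) restricted to labeled domains
#'
#' For each group label, pixels are included iff both bins lie within the
#' same domain carrying that label. Curves are pooled over chromosomes and
#' normalized to unity at the stratum containing `normalization_s`.
#'
#' @param m A balanced [contact_matrix()] (10-kb or finer resolution in
#'   real use).
#' @param domains Labeled [interval_set()] of group domains.
#' @param normalization_s Separation (bp) at which P is set to 1
#'   (default 10 kb).
#' @return A `contact_decay` data frame with a `group` column.
#' @export
ps_by_group <- function(m, domains, normalization_s = 10000) {
  bins <- m$bins
  bs <- bin_size_of(bins)
  bv <- balanced_values(m)
  dom_of <- bin_domain(bins, domains)
  n <- nrow(bins)
  ut <- which(upper.tri(bv), arr.ind = TRUE)
  same_chrom <- bins$chrom[ut[, 1]] == bins$chrom[ut[, 2]]
  same_dom <- !is.na(dom_of[ut[, 1]]) & dom_of[ut[, 1]] == dom_of[ut[, 2]]
  keep <- same_chrom & same_dom
  ut <- ut[keep, , drop = FALSE]
  dom <- dom_of[ut[, 1]]
  grp <- domains$label[dom]
  d <- ut[, 2] - ut[, 1]
  v <- bv[ut]
  out <- list()
  for (g in unique(domains$label)) {
    gi <- which(grp == g)
    if (!length(gi) || all(is.na(v[gi]))) {
      warning("group ", g, " has no qualifying pixels")
      next
    }
    ps <- pool_strata(v[gi], rep(TRUE, length(gi)), d[gi])
    st <- stratum_table(max(ps$stratum), bs)
    df <- merge(st[st$stratum %in% ps$stratum, ], ps, by = "stratum")
    P <- df$sum / df$n
    norm_idx <- which(df$stratum == stratum_index(max(normalization_s / bs, 1)))
    if (!length(norm_idx)) norm_idx <- 1L
    out[[g]] <- data.frame(group = g,
                           df[, c("stratum", "s_lo", "s_hi", "s_mid")],
                           P = P / P[norm_idx], n_pixels = df$n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, bin_size = bs, normalization_s = normalization_s,
            class = c("contact_decay", "data.frame"))
}

#' Log-log derivative of a P(s) curve
#'
#' Centered finite differences of log P against log s, optionally smoothed
#' with a moving average over `smooth_window` strata. Strata with
#' nonpositive P are skipped.
#'
#' @param decay One curve of a `contact_decay` (single chromosome/group).
#' @param smooth_window Moving-average width in strata (1 = no smoothing).
#' @return Data frame with `s_mid` and `slope`.
#' @export
ps_derivative <- function(decay, smooth_window = 1) {
  decay <- decay[!is.na(decay$P) & decay$P > 0, , drop = FALSE]
  if (nrow(decay) < 3) stop("need at least 3 strata with positive P")
  lx <- log(decay$s_mid)
  ly <- log(decay$P)
  nst <- length(lx)
  slope <- rep(NA_real_, nst)
  slope[2:(nst - 1)] <- (ly[3:nst] - ly[1:(nst - 2)]) /
    (lx[3:nst] - lx[1:(nst - 2)])
  slope[1] <- (ly[2] - ly[1]) / (lx[2] - lx[1])
  slope[nst] <- (ly[nst] - ly[nst - 1]) / (lx[nst] - lx[nst - 1])
  if (smooth_window > 1) {
    w <- smooth_window
    sm <- stats::filter(slope, rep(1 / w, w), sides = 2)
    slope <- ifelse(is.na(sm), slope, as.numeric(sm))
  }
  data.frame(s_mid = decay$s_mid, slope = slope)
}

# observed/expected matrix; NA outside the requested scope, on invalid
# bins and on the main diagonal. Cis expected is the per-chromosome
# stratum mean; trans expected the per-chromosome-pair mean.
oe_matrix <- function(m, scope = c("cis", "trans")) {
  scope <- match.arg(scope)
  bins <- m$bins
  bv <- balanced_values(m)
  code <- chrom_code(bins)
  n <- nrow(bins)
  E <- matrix(NA_real_, n, n)
  if (scope == "cis") {
    dec <- expected_cis(m)
    for (ch in unique(dec$chrom)) {
      sel <- which(bins$chrom == ch)
      sub_d <- abs(outer(sel, sel, "-"))
      expc <- rep(NA_real_, max(dec$stratum[dec$chrom == ch]))
      dc <- dec[dec$chrom == ch, ]
      expc[dc$stratum] <- dc$P
      ei <- matrix(NA_real_, length(sel), length(sel))
      off <- sub_d > 0
      ei[off] <- expc[stratum_index(sub_d[off])]
      E[sel, sel] <- ei
    }
  } else {
    chroms <- attr(bins, "chrom_order")
    for (a in seq_along(chroms)) for (b in seq_along(chroms)) {
      if (a == b) next
      ia <- which(code == a); ib <- which(code == b)
      blk <- bv[ia, ib, drop = FALSE]
      mu <- mean(blk, na.rm = TRUE)
      if (is.finite(mu) && mu > 0) E[ia, ib] <- mu
    }
  }
  bv / E
}

# mean of a symmetric pixel-level matrix over groups of bins
group_pair_means <- function(oe, groups) {
  lev <- levels(groups)
  gi <- as.integer(groups)
  full <- matrix(0, length(groups), length(lev))
  ok <- !is.na(gi)
  full[cbind(which(ok), gi[ok])] <- 1
  M <- !is.na(oe)
  O <- ifelse(M, oe, 0)
  sums <- t(full) %*% O %*% full
  counts <- t(full) %*% M %*% full
  res <- sums / counts
  res[counts == 0] <- NA_real_
  dimnames(res) <- list(lev, lev)
  list(means = res, counts = counts,
       global = sum(O) / sum(M))
}

#' Saddle plot: observed/expected by track percentile
#'
#' Valid bins are ranked by `track` (stable ties by bin index) and split
#' into `n_quantiles` equal-count groups; the mean observed/expected
#' contact frequency is computed for every group pair and divided by the
#' global mean over all included pixels.
#'
#' @param m A balanced [contact_matrix()].
#' @param track Ranking [signal_track()].
#' @param n_quantiles Number of percentile groups (default 50).
#' @param scope `"cis"` or `"trans"`.
#' @param order `"ascending"` or `"descending"` layout of the quantiles.
#' @param trim Fraction of extreme bins to drop at each end (default 0).
#' @return A `saddle_summary` list: `matrix`, `counts`, `edges`, `scope`.
#' @export
saddle <- function(m, track, n_quantiles = 50, scope = c("cis", "trans"),
                   order = c("ascending", "descending"), trim = 0) {
  scope <- match.arg(scope)
  order <- match.arg(order)
  usable <- m$bins$valid & !is.na(track$value)
  if (n_quantiles > sum(usable)) stop("more quantiles than valid bins")
  oe <- oe_matrix(m, scope)
  val <- track$value
  r <- rank(val[usable], ties.method = "first")
  nq <- n_quantiles
  qg <- ceiling(r / (length(r) / nq))
  if (trim > 0) {
    lo <- stats::quantile(val[usable], trim)
    hi <- stats::quantile(val[usable], 1 - trim)
    qg[val[usable] < lo | val[usable] > hi] <- NA
  }
  groups <- rep(NA_integer_, nrow(m$bins))
  groups[usable] <- qg
  gp <- group_pair_means(oe, factor(groups, levels = seq_len(nq)))
  mat <- gp$means / gp$global
  edges <- stats::quantile(val[usable], probs = seq(0, 1, length.out = nq + 1))
  if (order == "descending") {
    mat <- mat[rev(seq_len(nq)), rev(seq_len(nq))]
    gp$counts <- gp$counts[rev(seq_len(nq)), rev(seq_len(nq))]
    edges <- rev(edges)
  }
  structure(list(matrix = mat, counts = gp$counts, edges = edges,
                 n_quantiles = nq, scope = scope, order = order),
            class = "saddle_summary")
}

#' @export
print.saddle_summary <- function(x, ...) {
  cat(sprintf("saddle_summary: %d x %d quantiles, scope %s (%s)\n",
              x$n_quantiles, x$n_quantiles, x$scope, x$order))
  invisible(x)
}

#' Pairwise mean observed/expected between groups
#'
#' @param m A balanced [contact_matrix()].
#' @param labels An `ipg_assignment` (or any factor of per-bin labels).
#' @param scope `"cis"` or `"trans"`.
#' @return A `group x group` symmetric matrix of mean observed/expected,
#'   with the global mean normalized out.
#' @export
ipg_pairwise_oe <- function(m, labels, scope = c("cis", "trans")) {
  scope <- match.arg(scope)
  lab <- if (inherits(labels, "ipg_assignment")) labels$ipg else labels
  lab <- factor(lab)
  oe <- oe_matrix(m, scope)
  lab[!m$bins$valid] <- NA
  gp <- group_pair_means(oe, lab)
  gp$means / gp$global
}
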