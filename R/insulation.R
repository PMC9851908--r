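# Diamond insulation scores, prominence-based insulating-locus calls,
# per-group boundary statistics, and observed/expected pileups at oriented
# CTCF sites.

#' Diamond insulation score
#'
#' For each bin b the mean balanced contact frequency is taken over the
#' off-diagonal diamond spanning `window` upstream by `window` downstream
#' (pixels (i, j) with b-w < i <= b < j <= b+w, w = window in bins), then
#' log2-transformed after division by the chromosome-wide mean diamond
#' value. Scores are missing within `window` of chromosome edges and where
#' the diamond contains no valid pixel.
#'
#' @param m A balanced [contact_matrix()] at a resolution of at most
#'   `window`/2.
#' @param window Sliding window in bp (default 100 kb).
#' @return An `insulation_profile`: `bins`, `score`, `window`.
#' @export
insulation_score <- function(m, window = 100000) {
  bins <- m$bins
  bs <- bin_size_of(bins)
  w <- as.integer(round(window / bs))
  if (w < 2) stop("window must span at least 2 bins")
  bv <- balanced_values(m)
  n <- nrow(bins)
  raw <- rep(NA_real_, n)
  code <- chrom_code(bins)
  for (ch in unique(code)) {
    sel <- which(code == ch)
    nc <- length(sel)
    sub <- bv[sel, sel, drop = FALSE]
    for (b in seq_len(nc)) {
      if (b - w + 1 < 1 || b + w > nc) next
      dia <- sub[(b - w + 1):b, (b + 1):(b + w), drop = FALSE]
      if (all(is.na(dia))) next
      raw[sel[b]] <- mean(dia, na.rm = TRUE)
    }
    chm <- mean(raw[sel], na.rm = TRUE)
    raw[sel] <- log2(raw[sel] / chm)
  }
  structure(list(bins = bins, score = raw, window = window),
            class = "insulation_profile")
}

#' @export
print.insulation_profile <- function(x, ...) {
  cat(sprintf("insulation_profile: window %s bp, %d scored bins\n",
              format(x$window, big.mark = ","), sum(!is.na(x$score))))
  invisible(x)
}

# topographic prominence of local maxima of y (edge plateaus count as
# maxima); returns data.frame(pos, prominence)
peak_prominence <- function(y) {
  n <- length(y)
  ok <- which(!is.na(y))
  if (length(ok) < 3) return(data.frame(pos = integer(), prominence = numeric()))
  yy <- y[ok]
  m <- length(yy)
  is_peak <- vapply(seq_len(m), function(i) {
    l <- if (i > 1) yy[i - 1] else -Inf
    r <- if (i < m) yy[i + 1] else -Inf
    yy[i] > l && yy[i] >= r   # left-leaning plateau rule
  }, logical(1))
  peaks <- which(is_peak)
  prom <- vapply(peaks, function(p) {
    # walk left until a strictly higher value or the edge
    lbase <- yy[p]
    i <- p - 1
    while (i >= 1 && yy[i] <= yy[p]) { lbase <- min(lbase, yy[i]); i <- i - 1 }
    if (i < 1) lbase <- min(yy[seq_len(p)])
    rbase <- yy[p]
    i <- p + 1
    while (i <= m && yy[i] <= yy[p]) { rbase <- min(rbase, yy[i]); i <- i + 1 }
    if (i > m) rbase <- min(yy[p:m])
    yy[p] - max(lbase, rbase)
  }, numeric(1))
  data.frame(pos = ok[peaks], prominence = prom)
}

#' Call insulating loci by peak prominence
#'
#' Local minima of the insulation score are found per chromosome; the
#' topographic prominence of each minimum (computed on the negated score,
#' edges treated as maxima) must reach `min_prominence`.
#'
#' @param profile An [insulation_score()] result.
#' @param min_prominence Minimum prominence (the two stringency tiers used
#'   in practice are 0.01 and 0.1).
#' @return An [interval_set()] of minima bins with prominence in `score`.
#' @export
call_insulating_loci <- function(profile, min_prominence = 0.01) {
  bins <- profile$bins
  code <- chrom_code(bins)
  out <- list()
  for (ch in unique(code)) {
    sel <- which(code == ch)
    pp <- peak_prominence(-profile$score[sel])
    pp <- pp[pp$prominence >= min_prominence, , drop = FALSE]
    if (!nrow(pp)) next
    idx <- sel[pp$pos]
    out[[length(out) + 1]] <- data.frame(chrom = bins$chrom[idx],
                                         start = bins$start[idx],
                                         end = bins$end[idx],
                                         score = pp$prominence)
  }
  if (!length(out)) return(empty_interval_set(attr(bins, "chrom_order")))
  df <- do.call(rbind, out)
  interval_set(df$chrom, df$start, df$end, label = "boundary",
               score = df$score, chrom_order = attr(bins, "chrom_order"))
}

#' Boundary density and prominence per group
#'
#' @param loci Insulating loci from [call_insulating_loci()].
#' @param labels An `ipg_assignment` (or factor of per-bin labels) on bins
#'   compatible with the loci coordinates.
#' @return List with `density` (loci per Mb of group territory, NA for
#'   groups without territory) and `prominences` (list of score vectors).
#' @export
boundary_stats_by_group <- function(loci, labels) {
  bins <- labels$bins
  lab <- if (inherits(labels, "ipg_assignment")) labels$ipg else labels
  lab <- factor(lab)
  territory_mb <- tapply(bins$end - bins$start, lab, sum) / 1e6
  lev <- levels(lab)
  counts <- stats::setNames(rep(0, length(lev)), lev)
  proms <- stats::setNames(vector("list", length(lev)), lev)
  if (nrow(loci)) {
    gl <- as_granges(loci$chrom, loci$start, loci$end)
    gb <- bins_granges(bins)
    hit <- GenomicRanges::findOverlaps(gl, gb, select = "first")
    lab_of <- lab[hit]
    for (g in lev) {
      sel <- which(!is.na(lab_of) & lab_of == g)
      counts[g] <- length(sel)
      proms[[g]] <- loci$score[sel]
    }
  }
  dens <- counts / as.numeric(territory_mb[lev])
  dens[is.na(territory_mb[lev]) | territory_mb[lev] == 0] <- NA
  list(density = dens, counts = counts, territory_mb = territory_mb,
       prominences = proms)
}

# group-specific distance expected: stratum means restricted to pixels with
# both bins inside the group's domains
group_expected <- function(m, group_bins) {
  bins <- m$bins
  bs <- bin_size_of(bins)
  bv <- balanced_values(m)
  ut <- which(upper.tri(bv), arr.ind = TRUE)
  keep <- group_bins[ut[, 1]] & group_bins[ut[, 2]] &
    bins$chrom[ut[, 1]] == bins$chrom[ut[, 2]]
  ut <- ut[keep, , drop = FALSE]
  d <- ut[, 2] - ut[, 1]
  ps <- pool_strata(bv[ut], rep(TRUE, nrow(ut)), d)
  expc <- rep(NA_real_, if (nrow(ps)) max(ps$stratum) else 0)
  expc[ps$stratum] <- ps$sum / ps$n
  expc
}

#' Observed/expected pileup at oriented sites
#'
#' Snippets centered on the diagonal at each site midpoint are divided by a
#' group-specific distance expected (computed from pixels within the
#' group's own territory) and averaged per group. Minus-strand snippets are
#' mirrored so all sites share the motif orientation. Sites within `flank`
#' of a chromosome edge (or on an invalid center bin) are skipped and
#' counted.
#'
#' @param m A balanced [contact_matrix()].
#' @param sites Data frame with `chrom`, `pos` (bp midpoint), `strand`.
#' @param flank Flank on each side in bp (multiple of the bin size).
#' @param group_labels Optional `ipg_assignment`/factor; sites are grouped
#'   by the label of their center bin. Without labels a single pileup is
#'   returned under group `"all"`.
#' @return List per group: `map` (mean O/E matrix), `n_sites`, `n_skipped`.
#' @export
pileup_at_sites <- function(m, sites, flank = 300000, group_labels = NULL) {
  bins <- m$bins
  bs <- bin_size_of(bins)
  f <- as.integer(round(flank / bs))
  if (f < 1) stop("flank must cover at least one bin")
  bv <- balanced_values(m)
  code <- chrom_code(bins)
  lab <- if (is.null(group_labels)) factor(rep("all", nrow(bins)))
         else if (inherits(group_labels, "ipg_assignment")) group_labels$ipg
         else factor(group_labels)
  # site -> center bin index
  gs <- as_granges(sites$chrom, floor(sites$pos), floor(sites$pos) + 1)
  cb <- GenomicRanges::findOverlaps(gs, bins_granges(bins), select = "first")
  lev <- levels(lab)
  acc <- lapply(lev, function(g) matrix(0, 2 * f + 1, 2 * f + 1))
  cnt <- lapply(lev, function(g) matrix(0, 2 * f + 1, 2 * f + 1))
  names(acc) <- names(cnt) <- lev
  n_sites <- stats::setNames(rep(0L, length(lev)), lev)
  skipped <- 0L
  expc <- lapply(lev, function(g) group_expected(m, !is.na(lab) & lab == g &
                                                   bins$valid))
  names(expc) <- lev
  dmat <- abs(outer(-f:f, -f:f, "-"))
  for (s in seq_len(nrow(sites))) {
    b <- cb[s]
    if (is.na(b) || is.na(lab[b])) { skipped <- skipped + 1L; next }
    g <- as.character(lab[b])
    sel <- (b - f):(b + f)
    if (min(sel) < 1 || max(sel) > nrow(bins) ||
        length(unique(code[sel])) > 1 || !bins$valid[b]) {
      skipped <- skipped + 1L; next
    }
    snip <- bv[sel, sel, drop = FALSE]
    e <- expc[[g]]
    E <- matrix(NA_real_, 2 * f + 1, 2 * f + 1)
    off <- dmat > 0 & stratum_index(pmax(dmat, 1)) <= length(e)
    E[off] <- e[stratum_index(dmat[off])]
    oe <- snip / E
    if (identical(sites$strand[s], "-"))
      oe <- oe[rev(seq_len(nrow(oe))), rev(seq_len(ncol(oe)))]
    ok <- !is.na(oe)
    a <- acc[[g]]; a[ok] <- a[ok] + oe[ok]; acc[[g]] <- a
    k <- cnt[[g]]; k[ok] <- k[ok] + 1; cnt[[g]] <- k
    n_sites[g] <- n_sites[g] + 1L
  }
  out <- lapply(lev, function(g) {
    mp <- acc[[g]] / cnt[[g]]
    mp[cnt[[g]] == 0] <- NA_real_
    list(map = mp, n_sites = n_sites[[g]])
  })
  names(out) <- lev
  structure(list(groups = out, flank = flank, n_skipped = skipped),
            class = "pileup")
}
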