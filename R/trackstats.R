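# Track-vs-label descriptive statistics: rescaled domain stackups and
# metaplots, percentile-grouped signal summaries, and threshold-ROC
# evaluation of tracks as classifiers for group labels.

# overlap-weighted resampling of a numeric vector (bin values of one
# domain) onto `nb` equal output bins; preserves the mean exactly
resample_mean <- function(x, nb) {
  n <- length(x)
  edges <- seq(0, n, length.out = nb + 1)
  out <- numeric(nb)
  for (k in seq_len(nb)) {
    lo <- edges[k]; hi <- edges[k + 1]
    i0 <- floor(lo) + 1
    i1 <- ceiling(hi)
    w <- pmin(hi, i0:i1) - pmax(lo, (i0:i1) - 1)
    xv <- x[i0:i1]
    ok <- !is.na(xv) & w > 0
    if (!any(ok)) out[k] <- NA_real_
    else out[k] <- sum(xv[ok] * w[ok]) / sum(w[ok])
  }
  out
}

#' Rescaled stacked heatmap of domains
#'
#' Each domain's intradomain signal is resampled to `rescale_bins` columns
#' by overlap-weighted averaging; flanking regions of `flank` bp are
#' appended at native bin resolution. Rows are sorted by `sort_key`.
#'
#' @param track A [signal_track()].
#' @param domains An [interval_set()] of domains (each at least one bin).
#' @param rescale_bins Number of intradomain columns (default 25).
#' @param flank Flank on each side in bp (default 500 kb).
#' @param sort_key `"size"`, `"none"`, or a [signal_track()] whose
#'   intradomain mean orders the rows.
#' @return A `stackup`: `values` (rows = domains), `rescale_bins`,
#'   `flank_bins`, `order` (domain row order used).
#' @export
stackup <- function(track, domains, rescale_bins = 25, flank = 500000,
                    sort_key = "size") {
  bins <- track$bins
  bs <- bin_size_of(bins)
  fb <- as.integer(round(flank / bs))
  code <- chrom_code(bins)
  gb <- bins_granges(bins)
  gd <- as_granges(domains$chrom, domains$start, domains$end)
  rows <- matrix(NA_real_, nrow(domains), rescale_bins + 2 * fb)
  key <- numeric(nrow(domains))
  for (r in seq_len(nrow(domains))) {
    hits <- S4Vectors::subjectHits(
      GenomicRanges::findOverlaps(gd[r], gb))
    if (!length(hits)) { key[r] <- NA; next }
    hits <- hits[code[hits] == code[hits[1]]]
    inner <- track$value[hits]
    body <- resample_mean(inner, rescale_bins)
    lf <- (min(hits) - fb):(min(hits) - 1)
    rf <- (max(hits) + 1):(max(hits) + fb)
    grab <- function(ix) {
      v <- rep(NA_real_, length(ix))
      ok <- ix >= 1 & ix <= nrow(bins)
      ok[ok] <- code[ix[ok]] == code[hits[1]]
      v[ok] <- track$value[ix[ok]]
      v
    }
    rows[r, ] <- c(if (fb > 0) grab(lf), body, if (fb > 0) grab(rf))
    key[r] <- if (identical(sort_key, "size")) domains$end[r] - domains$start[r]
      else if (inherits(sort_key, "signal_track")) mean(sort_key$value[hits], na.rm = TRUE)
      else r
  }
  ord <- if (identical(sort_key, "none")) seq_len(nrow(domains))
         else order(key, decreasing = TRUE)
  structure(list(values = rows[ord, , drop = FALSE], rescale_bins = rescale_bins,
                 flank_bins = fb, order = ord, domains = domains),
            class = "stackup")
}

#' Column means and standard deviations of a stackup
#'
#' @param stack A [stackup()].
#' @return Data frame with `column`, `mean`, `sd` (missing ignored;
#'   all-missing columns are `NA`).
#' @export
metaplot <- function(stack) {
  v <- stack$values
  if (nrow(v) < 1) stop("empty stackup")
  data.frame(column = seq_len(ncol(v)),
             mean = apply(v, 2, function(x)
               if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)),
             sd = apply(v, 2, function(x)
               if (all(is.na(x))) NA_real_ else stats::sd(x, na.rm = TRUE)))
}

#' Percentile-grouped signal summaries
#'
#' Bins are ranked by `track_to_rank` (stable ties by bin index) and split
#' into `n_percentiles` groups whose sizes differ by at most one; the mean
#' and standard deviation of each target track are reported per group.
#'
#' @param track_to_rank Ranking [signal_track()].
#' @param tracks Named list of target [signal_track()]s on the same bins.
#' @param n_percentiles Number of groups (default 100).
#' @return Data frame with `percentile`, `track`, `mean`, `sd`, `n`.
#' @export
percentile_histogram <- function(track_to_rank, tracks, n_percentiles = 100) {
  ok <- !is.na(track_to_rank$value)
  if (n_percentiles > sum(ok)) stop("more percentiles than valid bins")
  r <- rank(track_to_rank$value[ok], ties.method = "first")
  grp <- ceiling(r * n_percentiles / length(r))
  out <- list()
  for (nm in names(tracks)) {
    tv <- tracks[[nm]]$value[ok]
    mu <- tapply(tv, grp, mean, na.rm = TRUE)
    sdv <- tapply(tv, grp, stats::sd, na.rm = TRUE)
    nn <- tapply(tv, grp, length)
    out[[nm]] <- data.frame(percentile = as.integer(names(mu)), track = nm,
                            mean = as.numeric(mu), sd = as.numeric(sdv),
                            n = as.integer(nn))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' ROC curve and AUC of a track as a classifier for a group label
#'
#' Every unique track value is a threshold; AUC is the trapezoid area,
#' equal to P(score+ > score-) + 0.5 P(tie) under rank tie handling.
#'
#' @param track Scoring [signal_track()].
#' @param labels An `ipg_assignment` (or factor of per-bin labels).
#' @param target_ipg Label treated as the positive class.
#' @return List with `curve` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_for_label <- function(track, labels, target_ipg) {
  lab <- if (inherits(labels, "ipg_assignment")) labels$ipg else factor(labels)
  ok <- !is.na(track$value) & !is.na(lab)
  y <- lab[ok] == target_ipg
  x <- track$value[ok]
  if (!any(y) || all(y)) stop("labels contain a single class")
  np <- sum(y)
  nn <- sum(!y)
  thr <- sort(unique(x), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(x >= t & y), 0)
  fp <- vapply(thr, function(t) sum(x >= t & !y), 0)
  curve <- data.frame(threshold = c(Inf, thr),
                      fpr = c(0, fp / nn), tpr = c(0, tp / np))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}
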