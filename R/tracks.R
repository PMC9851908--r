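#' Per-bin quantitative signal track
#'
#' Missing data are explicit `NA` values and are propagated, never imputed
#' as zero.
#'
#' @param bins A [bin_table()].
#' @param value Numeric vector, one value per bin (`NA` allowed).
#' @param name Optional track name.
#' @export
signal_track <- function(bins, value, name = NULL) {
  stopifnot(inherits(bins, "bin_table"), length(value) == nrow(bins))
  structure(list(bins = bins, value = as.numeric(value), name = name),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track%s: %d bins, %d missing, mean %.4g\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              length(x$value), sum(is.na(x$value)),
              mean(x$value, na.rm = TRUE)))
  invisible(x)
}

#' Sorted genomic interval set (0-based, half-open)
#'
#' @param chrom,start,end Interval coordinates.
#' @param label Optional character labels (BED name column).
#' @param score Optional numeric scores.
#' @param chrom_order Optional fixed chromosome ordering; defaults to order
#'   of first appearance.
#' @export
interval_set <- function(chrom, start, end, label = NA_character_,
                         score = NA_real_, chrom_order = NULL) {
  if (any(end < start)) stop("negative-length interval")
  if (length(chrom) == 0) {
    label <- character(0)
    score <- numeric(0)
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   label = label, score = score, stringsAsFactors = FALSE)
  if (is.null(chrom_order)) chrom_order <- unique(df$chrom)
  df <- df[order(match(df$chrom, chrom_order), df$start, df$end), ]
  rownames(df) <- NULL
  structure(df, chrom_order = chrom_order,
            class = c("interval_set", "data.frame"))
}

empty_interval_set <- function(chrom_order = character()) {
  interval_set(character(), numeric(), numeric(), chrom_order = chrom_order)
}

iv_width <- function(iv) iv$end - iv$start

# ---- GRanges conversion (0-based half-open <-> 1-based closed) ----

as_granges <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
}

bins_granges <- function(bins) as_granges(bins$chrom, bins$start, bins$end)

#' Aggregate scored intervals into genomic bins
#'
#' @param intervals An [interval_set()] with numeric `score`.
#' @param bins A [bin_table()].
#' @param stat Aggregation statistic: `"mean"` (overlap-weighted mean of
#'   scores), `"sum"` (total mass, apportioning each interval's score by the
#'   fraction of its length in the bin), or `"fraction"` (unweighted mean of
#'   scores over overlapping records, e.g. methylated CpGs / total CpGs).
#' @return A [signal_track()]; bins with no overlapping data are `NA`.
#' @export
aggregate_track <- function(intervals, bins, stat = c("mean", "sum", "fraction")) {
  stat <- match.arg(stat)
  stopifnot(inherits(bins, "bin_table"))
  lens <- attr(bins, "chrom_lengths")
  known <- intervals$chrom %in% names(lens)
  if (!all(known)) stop("interval on unknown chromosome")
  if (any(intervals$end > lens[intervals$chrom]))
    stop("interval extends past chromosome end")
  value <- rep(NA_real_, nrow(bins))
  if (nrow(intervals) == 0) return(signal_track(bins, value))
  giv <- as_granges(intervals$chrom, intervals$start, intervals$end)
  gb <- bins_granges(bins)
  ov <- GenomicRanges::findOverlaps(giv, gb)
  if (length(ov) == 0) return(signal_track(bins, value))
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  w_ov <- GenomicRanges::width(GenomicRanges::pintersect(giv[qi], gb[si]))
  sc <- intervals$score[qi]
  agg <- switch(stat,
    mean = {
      num <- tapply(sc * w_ov, si, sum)
      den <- tapply(w_ov, si, sum)
      num / den
    },
    sum = {
      frac <- w_ov / pmax(iv_width(intervals)[qi], 1)
      tapply(sc * frac, si, sum)
    },
    fraction = {
      num <- tapply(sc, si, sum)
      den <- tapply(rep(1, length(si)), si, sum)
      num / den
    })
  value[as.integer(names(agg))] <- as.numeric(agg)
  signal_track(bins, value)
}

# ---- bedGraph / BED IO via rtracklayer ----

#' Write a signal track as bedGraph
#'
#' Bins with missing values are omitted from the file.
#' @param track A [signal_track()].
#' @param path Output file path.
#' @export
write_bedgraph <- function(track, path) {
  keep <- !is.na(track$value)
  b <- track$bins[keep, , drop = FALSE]
  gr <- as_granges(b$chrom, b$start, b$end)
  GenomicRanges::mcols(gr)$score <- track$value[keep]
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' Read a bedGraph file onto a bin table
#'
#' Records are overlap-weighted mean-aggregated onto `bins` so the file need
#' not be at bin resolution.
#' @param path bedGraph file.
#' @param bins Target [bin_table()].
#' @export
read_bedgraph <- function(path, bins) {
  gr <- rtracklayer::import.bedGraph(path)
  iv <- interval_set(as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
                     score = GenomicRanges::mcols(gr)$score,
                     chrom_order = attr(bins, "chrom_order"))
  aggregate_track(iv, bins, stat = "mean")
}

#' Write an interval set as BED
#'
#' Labels go to the BED name column, scores to the score column.
#' @param iv An [interval_set()].
#' @param path Output file path.
#' @export
write_bed <- function(iv, path) {
  gr <- as_granges(iv$chrom, iv$start, iv$end)
  nm <- ifelse(is.na(iv$label), ".", iv$label)
  GenomicRanges::mcols(gr)$name <- nm
  GenomicRanges::mcols(gr)$score <- ifelse(is.na(iv$score), 0, iv$score)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read a BED file as an interval set
#'
#' @param path BED file (>= 3 columns; name and score kept when present).
#' @param chrom_order Optional fixed chromosome ordering.
#' @export
read_bed <- function(path, chrom_order = NULL) {
  gr <- rtracklayer::import.bed(path)
  mc <- GenomicRanges::mcols(gr)
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
               label = if ("name" %in% names(mc)) as.character(mc$name) else NA_character_,
               score = if ("score" %in% names(mc)) as.numeric(mc$score) else NA_real_,
               chrom_order = chrom_order)
}
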