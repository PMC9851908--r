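#' Binned genome coordinate table
#'
#' A `bin_table` tiles each chromosome with fixed-size bins (0-based,
#' half-open coordinates). The last bin of a chromosome may be shorter.
#' Chromosome order is fixed at construction and is never re-sorted.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in base
#'   pairs; names give the chromosome order.
#' @param bin_size Bin width in base pairs.
#' @param centromeres Optional named numeric vector of centromere positions
#'   (bp) per chromosome.
#' @return A data frame of class `bin_table` with columns `chrom`, `start`,
#'   `end`, `valid` and attributes `bin_size`, `chrom_order`, `chrom_lengths`,
#'   `centromeres`.
#' @export
bin_table <- function(chrom_lengths, bin_size, centromeres = NULL) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            bin_size >= 1)
  chroms <- names(chrom_lengths)
  if (anyDuplicated(chroms) > 0) stop("duplicated chromosome names")
  if (!is.null(centromeres)) {
    bad <- setdiff(names(centromeres), chroms)
    if (length(bad)) stop("centromere for unknown chromosome: ", bad[1])
    if (any(centromeres < 0 | centromeres > chrom_lengths[names(centromeres)]))
      stop("centromere outside chromosome")
  }
  rows <- lapply(chroms, function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$valid <- TRUE
  rownames(df) <- NULL
  structure(df,
            bin_size = bin_size,
            chrom_order = chroms,
            chrom_lengths = chrom_lengths,
            centromeres = centromeres,
            class = c("bin_table", "data.frame"))
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("bin_table: %d bins, %d chromosomes, bin size %s bp, %d valid\n",
              nrow(x), length(attr(x, "chrom_order")),
              format(attr(x, "bin_size"), big.mark = ","), sum(x$valid)))
  invisible(x)
}

n_bins <- function(bins) nrow(bins)

bin_size_of <- function(bins) attr(bins, "bin_size")

# integer chromosome code in the fixed chromosome order
chrom_code <- function(bins) {
  match(bins$chrom, attr(bins, "chrom_order"))
}

bin_mid <- function(bins) (bins$start + bins$end) / 2

#' Distance from the centromere for every bin
#'
#' @param bins A [bin_table()] whose chromosomes carry centromere positions.
#' @return Numeric vector of |bin midpoint - centromere| in base pairs
#'   (NA for chromosomes without an annotated centromere).
#' @export
centromere_distance <- function(bins) {
  cen <- attr(bins, "centromeres")
  if (is.null(cen)) return(rep(NA_real_, nrow(bins)))
  abs(bin_mid(bins) - unname(cen[bins$chrom]))
}

# logical matrix: TRUE where both bins are on the same chromosome
cis_mask <- function(bins) {
  code <- chrom_code(bins)
  outer(code, code, "==")
}

same_bins <- function(a, b) {
  nrow(a) == nrow(b) && all(a$chrom == b$chrom) && all(a$start == b$start) &&
    all(a$end == b$end)
}

check_tiling <- function(df, bin_size) {
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (is.unsorted(sub$start, strictly = TRUE) ||
        any(sub$end[-nrow(sub)] != sub$start[-1]) ||
        any(sub$end - sub$start <= 0) ||
        any((sub$end - sub$start)[-nrow(sub)] != bin_size))
      stop("non-tiling bin table")
  }
  invisible(TRUE)
}
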