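#' Symmetric binned contact matrix
#'
#' Holds raw or balanced genome-wide contact frequencies together with the
#' bin table, per-bin balancing weights and a balanced flag. Invalid bins
#' have missing weights; their pixels are excluded from every downstream
#' computation rather than treated as zero.
#'
#' @param bins A [bin_table()].
#' @param values Symmetric non-negative numeric matrix, one row/column per bin.
#' @param weights Optional per-bin balancing weights (`NA` on invalid bins).
#' @param balanced Logical; `TRUE` when `values` already incorporate weights.
#' @export
contact_matrix <- function(bins, values, weights = NULL, balanced = FALSE) {
  stopifnot(inherits(bins, "bin_table"), is.matrix(values),
            nrow(values) == nrow(bins), ncol(values) == nrow(bins))
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("contact matrix must be symmetric")
  if (!is.null(weights)) stopifnot(length(weights) == nrow(bins))
  structure(list(bins = bins, values = unname(values), weights = weights,
                 balanced = balanced),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d bins (%d valid), %s, %d nonzero pixels\n",
              nrow(x$bins), sum(x$bins$valid),
              if (x$balanced) "balanced" else "raw",
              sum(x$values[upper.tri(x$values, diag = TRUE)] > 0)))
  invisible(x)
}

#' Balanced contact values
#'
#' Applies the stored iterative-correction weights: `b[i] * b[j] * raw[i, j]`.
#' Pixels touching invalid bins are `NA`.
#' @param m A [contact_matrix()] with weights (or already balanced values).
#' @return Numeric matrix.
#' @export
balanced_values <- function(m) {
  v <- m$values
  if (!m$balanced) {
    if (is.null(m$weights)) stop("matrix has no balancing weights")
    v <- v * outer(m$weights, m$weights)
  }
  bad <- !m$bins$valid | (if (is.null(m$weights)) FALSE else is.na(m$weights))
  v[bad, ] <- NA_real_
  v[, bad] <- NA_real_
  v
}

# ---- plain-text COO IO ----
#
# Dialect: <path> is a TSV with header bin1_id<TAB>bin2_id<TAB>count holding
# the upper triangle (bin1_id <= bin2_id, 0-based ids); a sidecar
# <path>.bins.tsv holds the bin table (chrom, start, end, valid, weight) with
# "#bin_size=", "#chrom_lengths=" and optional "#centromeres=" header lines.

#' Write a contact matrix in the plain-text COO dialect
#'
#' @param m A [contact_matrix()].
#' @param path Pixel file path; the bin table goes to `<path>.bins.tsv`.
#' @export
write_contact_matrix <- function(m, path) {
  ut <- which(upper.tri(m$values, diag = TRUE) & m$values != 0, arr.ind = TRUE)
  px <- data.frame(bin1_id = ut[, 1] - 1L, bin2_id = ut[, 2] - 1L,
                   count = m$values[ut])
  px <- px[order(px$bin1_id, px$bin2_id), ]
  utils::write.table(px, path, sep = "\t", quote = FALSE, row.names = FALSE)
  b <- m$bins
  side <- paste0(path, ".bins.tsv")
  con <- file(side, "w")
  writeLines(sprintf("#bin_size=%d", as.integer(bin_size_of(b))), con)
  lens <- attr(b, "chrom_lengths")
  writeLines(paste0("#chrom_lengths=",
                    paste(names(lens), as.integer(lens), sep = ":", collapse = ",")), con)
  cen <- attr(b, "centromeres")
  if (!is.null(cen))
    writeLines(paste0("#centromeres=",
                      paste(names(cen), as.integer(cen), sep = ":", collapse = ",")), con)
  bd <- data.frame(chrom = b$chrom, start = b$start, end = b$end,
                   valid = as.integer(b$valid),
                   weight = if (is.null(m$weights)) NA_real_ else m$weights)
  utils::write.table(bd, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

parse_kv <- function(line, key) {
  body <- sub(paste0("^#", key, "="), "", line)
  parts <- strsplit(strsplit(body, ",")[[1]], ":")
  stats::setNames(as.numeric(vapply(parts, `[`, "", 2)),
                  vapply(parts, `[`, "", 1))
}

#' Read a contact matrix from the plain-text COO dialect
#'
#' @param path Pixel file written by [write_contact_matrix()] (a sidecar
#'   `<path>.bins.tsv` must exist).
#' @param resolution Bin size in bp; required when the sidecar does not
#'   declare one.
#' @param symmetrize If `TRUE`, lower-triangle pixels are mirrored; otherwise
#'   their presence is an error.
#' @export
read_contact_matrix <- function(path, resolution = NULL, symmetrize = FALSE) {
  side <- paste0(path, ".bins.tsv")
  if (!file.exists(side)) stop("missing sidecar bin table: ", side)
  hdr <- readLines(side, n = 5)
  hdr <- hdr[startsWith(hdr, "#")]
  bs_line <- grep("^#bin_size=", hdr, value = TRUE)
  if (length(bs_line)) {
    bin_size <- as.numeric(sub("^#bin_size=", "", bs_line[1]))
  } else if (!is.null(resolution)) {
    bin_size <- resolution
  } else stop("resolution unavailable")
  if (!is.null(resolution) && length(bs_line) && resolution != bin_size)
    stop("requested resolution does not match file bin size")
  len_line <- grep("^#chrom_lengths=", hdr, value = TRUE)
  cen_line <- grep("^#centromeres=", hdr, value = TRUE)
  bd <- utils::read.table(side, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  lens <- if (length(len_line)) parse_kv(len_line[1], "chrom_lengths") else
    tapply(bd$end, bd$chrom, max)[unique(bd$chrom)]
  check_tiling(bd, bin_size)
  bins <- bin_table(lens, bin_size,
                    centromeres = if (length(cen_line)) parse_kv(cen_line[1], "centromeres"))
  if (nrow(bins) != nrow(bd) || !all(bins$chrom == bd$chrom) ||
      !all(bins$start == bd$start))
    stop("non-tiling bin table")
  bins$valid <- as.logical(bd$valid)
  px <- utils::read.table(path, header = TRUE, sep = "\t")
  n <- nrow(bins)
  if (any(px$bin1_id < 0 | px$bin2_id >= n)) stop("pixel bin id out of range")
  low <- px$bin1_id > px$bin2_id
  if (any(low) && !symmetrize)
    stop("asymmetric COO input (lower-triangle pixels); set symmetrize=TRUE")
  v <- matrix(0, n, n)
  v[cbind(px$bin1_id + 1L, px$bin2_id + 1L)] <- px$count
  v <- pmax(v, t(v))  # mirror upper triangle
  w <- bd$weight
  has_w <- !all(is.na(w))
  contact_matrix(bins, v, weights = if (has_w) w, balanced = FALSE)
}

# ---- bin-level filtering ----

#' Mark low-coverage bins invalid
#'
#' A bin is invalidated when its total raw coverage falls more than
#' `mad_threshold` median absolute deviations below the median coverage of
#' currently valid bins, or when it has fewer than `min_nnz` nonzero pixels.
#' Values are untouched; only the validity mask changes.
#'
#' @param m A raw [contact_matrix()].
#' @param mad_threshold MADs below the median at which to cut (default 5).
#' @param min_nnz Minimum nonzero pixels per bin (default 2).
#' @export
filter_bins <- function(m, mad_threshold = 5, min_nnz = 2) {
  v <- m$values
  valid <- m$bins$valid
  cov <- colSums(v)
  nnz <- colSums(v != 0)
  med <- stats::median(cov[valid])
  madv <- stats::mad(cov[valid])
  bad <- cov < med - mad_threshold * madv | nnz < min_nnz
  new_valid <- valid & !bad
  if (!any(new_valid)) stop("empty matrix after filtering")
  bins <- m$bins
  bins$valid <- new_valid
  contact_matrix(bins, v, weights = m$weights, balanced = m$balanced)
}

# symmetric Sinkhorn/IPF: returns per-bin factors b (NA on invalid) such that
# the matrix b_i b_j v_ij has all valid-bin marginals equal to `target`
sinkhorn <- function(v, valid, tol, max_iter, target = 1) {
  idx <- which(valid)
  sub <- v[idx, idx, drop = FALSE]
  if (any(rowSums(sub) == 0))
    stop("valid bin with zero coverage; filter bins first")
  b <- rep(1, length(idx))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- as.numeric((sub %*% b) * b)
    rel_var <- stats::var(s) / mean(s)^2
    if (!is.na(rel_var) && rel_var < tol) { converged <- TRUE; break }
    b <- b / sqrt(s / mean(s))
  }
  if (!converged) {
    s <- as.numeric((sub %*% b) * b)
    rel_var <- stats::var(s) / mean(s)^2
    if (is.na(rel_var) || rel_var >= tol)
      stop(sprintf("iterative correction did not converge in %d iterations (relative marginal variance %.3g)",
                   max_iter, rel_var))
  }
  # exact scale so marginals equal `target`
  s <- as.numeric((sub %*% b) * b)
  b <- b * sqrt(target / mean(s))
  out <- rep(NA_real_, length(valid))
  out[idx] <- b
  out
}

#' Iterative-correction (ICE) balancing
#'
#' Computes per-bin multiplicative weights so that the marginal sums of the
#' weighted matrix are equal over valid bins, removing multiplicative
#' per-bin biases. Convergence is declared when the relative variance of the
#' valid-bin marginals drops below `tol`.
#'
#' @param m A bin-filtered [contact_matrix()].
#' @param tol Relative marginal variance at convergence (default 1e-5).
#' @param max_iter Maximum iterations (default 300).
#' @return The matrix with `weights` filled in (missing on invalid bins) and
#'   raw values untouched; use [balanced_values()] to materialize.
#' @export
iterative_correction <- function(m, tol = 1e-5, max_iter = 300) {
  stopifnot(tol > 0)
  w <- sinkhorn(m$values, m$bins$valid, tol, max_iter)
  contact_matrix(m$bins, m$values, weights = w, balanced = FALSE)
}
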