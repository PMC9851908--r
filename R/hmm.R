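# Two-state hidden Markov segmentation of signal tracks: a Bernoulli HMM
# for broad-mark (H3K9me3-like) domains on binarized tracks and a Gaussian
# HMM for replication-timing domains, plus differential-RT region calling.

#' Binarize a track by z-scored log signal
#'
#' The track is log-transformed with a pseudocount, z-scored over
#' non-missing bins, and thresholded. Missing stays missing.
#'
#' @param track A [signal_track()] (non-negative where the log applies).
#' @param threshold z-score cutoff (default 1).
#' @param pseudocount Added before the log (default 1).
#' @return A binary [signal_track()] (0/1/NA).
#' @export
binarize_track <- function(track, threshold = 1, pseudocount = 1) {
  x <- track$value
  if (all(is.na(x))) stop("all-missing track")
  lx <- log(x + pseudocount)
  if (any(is.nan(lx) | is.infinite(lx), na.rm = TRUE))
    stop("log transform undefined; increase pseudocount")
  s <- stats::sd(lx, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("degenerate track (zero variance)")
  z <- (lx - mean(lx, na.rm = TRUE)) / s
  signal_track(track$bins, ifelse(is.na(z), NA_real_, as.numeric(z >= threshold)),
               name = track$name)
}

# split a per-bin vector into maximal runs of non-missing values within
# chromosomes; returns list of (idx = bin indices, obs = values)
obs_sequences <- function(bins, value) {
  code <- chrom_code(bins)
  brk <- c(TRUE, diff(code) != 0)       # new chromosome starts a sequence
  miss <- is.na(value)
  seq_id <- cumsum(brk | c(FALSE, miss[-length(miss)] != miss[-1]) | miss)
  out <- list()
  for (g in unique(seq_id[!miss])) {
    idx <- which(seq_id == g & !miss)
    out[[length(out) + 1]] <- list(idx = idx, obs = value[idx])
  }
  out
}

emission_density <- function(obs, family, par) {
  if (family == "bernoulli") {
    cbind(ifelse(obs > 0.5, par$p[1], 1 - par$p[1]),
          ifelse(obs > 0.5, par$p[2], 1 - par$p[2]))
  } else {
    cbind(stats::dnorm(obs, par$mean[1], par$sd[1]),
          stats::dnorm(obs, par$mean[2], par$sd[2]))
  }
}

init_params <- function(obs_all, family, jitter_sd, restart) {
  if (family == "bernoulli") {
    hi <- mean(obs_all) # quantile split around overall rate
    p <- c(min(0.45, max(0.02, hi / 2)), max(0.55, min(0.98, 0.5 + hi / 2)))
    if (restart > 1)
      p <- pmin(0.99, pmax(0.01, p + stats::rnorm(2, 0, jitter_sd)))
    list(p = sort(p))
  } else {
    km <- stats::kmeans(obs_all, centers = 2, nstart = 3)
    mu <- sort(km$centers[, 1])
    sdv <- rep(max(stats::sd(obs_all) / 2, 1e-3), 2)
    if (restart > 1) mu <- mu + stats::rnorm(2, 0, jitter_sd * stats::sd(obs_all))
    list(mean = mu, sd = sdv)
  }
}

#' Fit a two-state HMM by Baum-Welch
#'
#' Maximum-likelihood EM fit of a 2-state hidden Markov model with
#' Bernoulli or Gaussian emissions over one or more observation sequences
#' (e.g. per chromosome). Initialization is a quantile split (Bernoulli) or
#' k-means (Gaussian) with seeded jittered restarts; the best likelihood
#' wins. States are ordered post hoc so state 1 has the higher emission
#' mean / success probability (the "domain" state).
#'
#' @param observations Numeric vector or list of numeric vectors.
#' @param family `"bernoulli"` or `"gaussian"`.
#' @param seed RNG seed for initialization.
#' @param max_iter Maximum EM iterations.
#' @param tol Absolute log-likelihood improvement at convergence.
#' @param n_restarts Number of seeded restarts.
#' @return An `ipg_hmm`: `family`, `init`, `transition` (2x2, row
#'   stochastic), `emission` (`p` or `mean`/`sd`, state 1 = high),
#'   `loglik`, `loglik_trace`, `converged`.
#' @export
fit_hmm <- function(observations, family = c("bernoulli", "gaussian"),
                    seed = 1L, max_iter = 200, tol = 1e-6, n_restarts = 5) {
  family <- match.arg(family)
  seqs <- if (is.list(observations)) observations else list(observations)
  seqs <- lapply(seqs, function(x) x[!is.na(x)])
  seqs <- seqs[lengths(seqs) > 0]
  obs_all <- unlist(seqs)
  if (length(unique(obs_all)) < 2) stop("need >= 2 distinct observed values")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      par <- init_params(obs_all, family, jitter_sd = 0.1, restart = r)
      init <- c(0.5, 0.5)
      trans <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
      ll_trace <- numeric(0)
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        g_sum <- matrix(0, 1, 2)
        g1_sum <- c(0, 0)
        xi_sum <- matrix(0, 2, 2)
        wsum <- c(0, 0)
        wx <- c(0, 0)
        wx2 <- c(0, 0)
        ll <- 0
        for (sq in seqs) {
          dens <- emission_density(sq, family, par)
          fb <- hmm_forward_backward(dens, init, trans)
          ll <- ll + fb$loglik
          g <- fb$gamma
          g1_sum <- g1_sum + g[1, ]
          xi_sum <- xi_sum + fb$xi
          wsum <- wsum + colSums(g)
          wx <- wx + colSums(g * sq)
          wx2 <- wx2 + colSums(g * sq^2)
        }
        ll_trace <- c(ll_trace, ll)
        # M step
        init <- g1_sum / sum(g1_sum)
        trans <- xi_sum / rowSums(xi_sum)
        if (family == "bernoulli") {
          par$p <- pmin(1 - 1e-8, pmax(1e-8, wx / wsum))
        } else {
          par$mean <- wx / wsum
          par$sd <- pmax(sqrt(wx2 / wsum - par$mean^2), 1e-4)
        }
        if (it > 1 && abs(ll_trace[it] - ll_trace[it - 1]) < tol) {
          converged <- TRUE
          break
        }
      }
      cand <- list(par = par, init = init, trans = trans,
                   loglik = ll_trace[length(ll_trace)],
                   loglik_trace = ll_trace, converged = converged)
      if (is.null(best) || cand$loglik > best$loglik) best <- cand
    }
  })
  if (!best$converged)
    warning("EM did not converge within max_iter; returning best model")
  # state 1 = higher emission
  hi_first <- if (family == "bernoulli") order(-best$par$p) else
    order(-best$par$mean)
  perm <- hi_first
  emission <- if (family == "bernoulli") list(p = best$par$p[perm]) else
    list(mean = best$par$mean[perm], sd = best$par$sd[perm])
  structure(list(family = family,
                 init = best$init[perm],
                 transition = best$trans[perm, perm, drop = FALSE],
                 emission = emission,
                 loglik = best$loglik,
                 loglik_trace = best$loglik_trace,
                 converged = best$converged),
            class = "ipg_hmm")
}

#' @export
print.ipg_hmm <- function(x, ...) {
  cat(sprintf("2-state %s HMM, logLik %.2f (%sconverged)\n", x$family,
              x$loglik, if (x$converged) "" else "not "))
  if (x$family == "bernoulli")
    cat(sprintf("  p(high) = %.3f, p(low) = %.3f\n",
                x$emission$p[1], x$emission$p[2]))
  else
    cat(sprintf("  mean(high) = %.3f (sd %.3f), mean(low) = %.3f (sd %.3f)\n",
                x$emission$mean[1], x$emission$sd[1], x$emission$mean[2],
                x$emission$sd[2]))
  cat(sprintf("  stay probabilities: %.4f / %.4f\n",
              x$transition[1, 1], x$transition[2, 2]))
  invisible(x)
}

# Viterbi state path for a model and observation vector (no NAs)
viterbi_path <- function(model, obs) {
  par <- if (model$family == "bernoulli") list(p = model$emission$p) else
    list(mean = model$emission$mean, sd = model$emission$sd)
  dens <- emission_density(obs, model$family, par)
  hmm_viterbi(dens, model$init, model$transition)
}

#' Call domains from the Viterbi parse
#'
#' Runs the Viterbi algorithm per observation sequence (missing bins break
#' sequences), takes maximal runs of the high-emission state as domains,
#' and merges runs separated by at most `min_gap` low-state bins.
#'
#' @param model A fitted [fit_hmm()] model.
#' @param track A [signal_track()] of observations.
#' @param min_gap Gap (bins) up to which neighboring domains merge
#'   (default 1).
#' @return An [interval_set()] of domains (label `"domain"`).
#' @export
viterbi_domains <- function(model, track, min_gap = 1) {
  bins <- track$bins
  state <- rep(NA_integer_, nrow(bins))
  for (sq in obs_sequences(bins, track$value))
    state[sq$idx] <- viterbi_path(model, sq$obs)
  hi <- !is.na(state) & state == 1L
  out <- list()
  code <- chrom_code(bins)
  for (ch in unique(code)) {
    sel <- which(code == ch)
    h <- hi[sel]
    r <- rle(h)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    if (!nrow(runs)) next
    # merge runs separated by <= min_gap bins
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) for (k in 2:nrow(runs)) {
      gap <- runs$start[k] - merged$end[nrow(merged)] - 1
      if (gap <= min_gap) merged$end[nrow(merged)] <- runs$end[k]
      else merged <- rbind(merged, runs[k, ])
    }
    out[[length(out) + 1]] <- data.frame(
      chrom = bins$chrom[sel[1]],
      start = bins$start[sel[merged$start]],
      end = bins$end[sel[merged$end]])
  }
  if (!length(out)) return(empty_interval_set(attr(bins, "chrom_order")))
  df <- do.call(rbind, out)
  interval_set(df$chrom, df$start, df$end, label = "domain",
               chrom_order = attr(bins, "chrom_order"))
}

#' Replication-timing track from early/late counts
#'
#' Counts are library-normalized to equal totals; the per-bin log2
#' early/late ratio is z-scored over finite bins. Bins with a zero count in
#' either fraction are missing.
#'
#' @param early,late [signal_track()]s of non-negative counts on the same
#'   bins.
#' @param normalize Scale each fraction to unit total before the ratio
#'   (library-size normalization; default `TRUE`).
#' @return An `rt_track`: `bins`, `early`, `late`, `ratio` (log2 E/L), `z`.
#' @export
rt_process <- function(early, late, normalize = TRUE) {
  if (!same_bins(early$bins, late$bins)) stop("mismatched bin tables")
  e <- early$value
  l <- late$value
  te <- sum(e, na.rm = TRUE)
  tl <- sum(l, na.rm = TRUE)
  if (te == 0 || tl == 0) stop("zero total count in a fraction")
  en <- if (normalize) e / te else e
  ln <- if (normalize) l / tl else l
  ratio <- log2(en / ln)
  ratio[!is.finite(ratio)] <- NA_real_
  s <- stats::sd(ratio, na.rm = TRUE)
  degenerate <- !is.finite(s) || s == 0
  if (degenerate) {
    warning("degenerate replication-timing ratio (zero variance); z set to 0")
    z <- ifelse(is.na(ratio), NA_real_, 0)
  } else {
    z <- (ratio - mean(ratio, na.rm = TRUE)) / s
  }
  structure(list(bins = early$bins, early = e, late = l, ratio = ratio,
                 z = z, degenerate = degenerate),
            class = "rt_track")
}

#' Differentially timed regions between two RT tracks
#'
#' Bins where |z_b - z_a| reaches `cutoff` are flagged (label `"hastened"`
#' when replication becomes earlier in `b`, `"delayed"` otherwise) and
#' flagged bins of the same label separated by at most `merge_distance` are
#' merged into regions.
#'
#' @param a,b `rt_track`s on the same bins.
#' @param cutoff z-score difference cutoff (default 0.75).
#' @param merge_distance Merge gap in bp (default 250 kb).
#' @return An [interval_set()] of regions with the mean z difference as
#'   score.
#' @export
differential_rt <- function(a, b, cutoff = 0.75, merge_distance = 250000) {
  if (!same_bins(a$bins, b$bins)) stop("mismatched bin tables")
  bins <- a$bins
  dz <- b$z - a$z
  flag <- !is.na(dz) & abs(dz) >= cutoff
  lab <- ifelse(dz > 0, "hastened", "delayed")
  out <- list()
  for (lv in c("hastened", "delayed")) {
    idx <- which(flag & lab == lv)
    if (!length(idx)) next
    code <- chrom_code(bins)
    cur <- NULL
    for (i in idx) {
      if (!is.null(cur) && code[i] == cur$code &&
          bins$start[i] - cur$end <= merge_distance) {
        cur$end <- bins$end[i]
        cur$dz <- c(cur$dz, dz[i])
      } else {
        if (!is.null(cur)) out[[length(out) + 1]] <- cur
        cur <- list(chrom = bins$chrom[i], code = code[i],
                    start = bins$start[i], end = bins$end[i], dz = dz[i],
                    label = lv)
      }
    }
    if (!is.null(cur)) out[[length(out) + 1]] <- cur
  }
  if (!length(out)) return(empty_interval_set(attr(bins, "chrom_order")))
  interval_set(vapply(out, `[[`, "", "chrom"),
               vapply(out, `[[`, 0, "start"),
               vapply(out, `[[`, 0, "end"),
               label = vapply(out, `[[`, "", "label"),
               score = vapply(out, function(x) mean(x$dz), 0),
               chrom_order = attr(bins, "chrom_order"))
}
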