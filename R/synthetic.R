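# Synthetic multi-chromosome Hi-C generator with planted interaction
# profile groups, a centromere-distance positional gradient, a power-law
# distance decay with an extrusion shoulder, and per-state Gaussian signal
# tracks. Gives every pipeline stage a ground truth at desk scale.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Synthetic genome layout
#'
#' @param chromosomes Data frame with columns `name`, `n_bins`,
#'   `centromere_bin` (1-based bin index). The default is three chromosomes
#'   of 550/500/450 bins so that trans decomposition has multiple
#'   chromosome pairs.
#' @param bin_size Bin width in bp (default 50 kb).
#' @export
genome_spec <- function(chromosomes = NULL, bin_size = 50000) {
  if (is.null(chromosomes))
    chromosomes <- data.frame(name = c("chrA", "chrB", "chrC"),
                              n_bins = c(550, 500, 450),
                              centromere_bin = c(220, 200, 180),
                              stringsAsFactors = FALSE)
  stopifnot(all(chromosomes$n_bins >= 20),
            all(chromosomes$centromere_bin >= 1),
            all(chromosomes$centromere_bin <= chromosomes$n_bins))
  structure(list(chromosomes = chromosomes, bin_size = bin_size),
            class = "genome_spec")
}

spec_bins <- function(spec) {
  lens <- stats::setNames(spec$chromosomes$n_bins * spec$bin_size,
                          spec$chromosomes$name)
  cen <- stats::setNames((spec$chromosomes$centromere_bin - 0.5) * spec$bin_size,
                         spec$chromosomes$name)
  bin_table(lens, spec$bin_size, centromeres = cen)
}

#' Planted chromatin-state model
#'
#' Defaults encode five states in the spirit of A1/A2/B0/B1/B4: two active
#' states with mutual affinity, a neutral silent state with a near-uniform
#' contact-preference row, facultative heterochromatin, and a strongly
#' self-affine constitutive heterochromatin state whose homotypic affinity
#' is the largest entry of the matrix.
#'
#' @param states State names.
#' @param affinity Symmetric state-by-state contact preference matrix.
#' @param positional_strength Weight of the centromere-distance similarity
#'   term (0 disables it).
#' @param pos_scale Length scale of the positional term, in bins.
#' @param decay_exponent Cis power-law exponent (P(s) ~ s^-decay_exponent).
#' @param shoulder_size Per-state extrusion-shoulder scale in bins.
#' @param shoulder_amp Per-state shoulder amplitude (0 removes the shoulder).
#' @param trans_level Trans decay constant relative to d(1 bin) = 1.
#' @param domain_length_mean Mean planted domain length in bins.
#' @param track_means,track_sds State-by-track Gaussian emission parameters.
#' @param ctcf_prob Probability of planting an oriented CTCF site at a
#'   domain boundary not flanked by the last (B4-like) state.
#' @param seed Default RNG seed for the generators.
#' @export
state_model <- function(states = c("A1", "A2", "B0", "B1", "B4"),
                        affinity = NULL,
                        positional_strength = 0.4,
                        pos_scale = 150,
                        decay_exponent = 1,
                        shoulder_size = NULL,
                        shoulder_amp = NULL,
                        trans_level = 0.02,
                        domain_length_mean = 10,
                        track_means = NULL,
                        track_sds = NULL,
                        ctcf_prob = 0.7,
                        seed = 1L) {
  k <- length(states)
  if (is.null(affinity)) {
    stopifnot(k == 5)
    affinity <- matrix(c(
      2.81, 3.11, 0.71, 1.78, 0.88,
      3.11, 0.82, 0.88, 0.60, 0.51,
      0.71, 0.88, 1.58, 0.83, 0.91,
      1.78, 0.60, 0.83, 2.99, 1.19,
      0.88, 0.51, 0.91, 1.19, 3.59), 5, 5, byrow = TRUE)
  }
  dimnames(affinity) <- list(states, states)
  stopifnot(isSymmetric(unname(affinity)), all(affinity > 0))
  if (is.null(shoulder_size)) shoulder_size <- rep(8, k)
  if (is.null(shoulder_amp)) shoulder_amp <- rep(1, k)
  if (is.null(track_means)) {
    stopifnot(k == 5)
    track_means <- matrix(c(
      # H3K9me3, H3K27me3, H2AZ,  RT
      0.2, 0.2, 0.3,  1.8,   # A1-like: early, speckle-proximal
      0.3, 1.0, 0.9,  0.6,   # A2-like: weakly active
      0.5, 0.5, 2.0, -0.5,   # B0-like: H2A.Z-rich neutral silent
      0.6, 2.2, 0.8, -0.8,   # B1-like: H3K27me3 facultative
      2.5, 0.5, 0.3, -1.5),  # B4-like: H3K9me3 constitutive, very late
      nrow = 5, byrow = TRUE,
      dimnames = list(states, c("H3K9me3", "H3K27me3", "H2AZ", "RT")))
  }
  if (is.null(track_sds))
    track_sds <- matrix(0.3, k, ncol(track_means),
                        dimnames = dimnames(track_means))
  structure(list(states = states, n_states = k, affinity = affinity,
                 positional_strength = positional_strength,
                 pos_scale = pos_scale, decay_exponent = decay_exponent,
                 shoulder_size = shoulder_size, shoulder_amp = shoulder_amp,
                 trans_level = trans_level,
                 domain_length_mean = domain_length_mean,
                 track_means = track_means, track_sds = track_sds,
                 ctcf_prob = ctcf_prob, seed = seed),
            class = "state_model")
}

#' Paint planted state labels along the genome
#'
#' Domains are painted per chromosome as a Markov chain of geometric run
#' lengths (mean `domain_length_mean`); successive domains never repeat a
#' state. Replication-timing class is 1 (early) for the first two states
#' and 0 (late) otherwise. CTCF sites are planted at domain boundaries that
#' do not touch the last (B4-like) state, with random orientation and
#' fold-change scores 1 + Exp(mean 2).
#'
#' @param spec A [genome_spec()].
#' @param model A [state_model()].
#' @param seed RNG seed (defaults to `model$seed`).
#' @return A `ground_truth` list: `bins`, per-bin `state` (factor),
#'   `domain_id`, `rt_class`, `domains` interval set, `ctcf_sites` data frame.
#' @export
generate_labels <- function(spec, model, seed = model$seed) {
  bins <- spec_bins(spec)
  k <- model$n_states
  p_end <- 1 / model$domain_length_mean
  with_seed(seed, {
    state <- integer(0)
    domain_id <- integer(0)
    did <- 0L
    for (ci in seq_len(nrow(spec$chromosomes))) {
      n <- spec$chromosomes$n_bins[ci]
      pos <- 0L
      prev <- 0L
      while (pos < n) {
        s <- if (k == 1) 1L else {
          cand <- setdiff(seq_len(k), prev)
          cand[sample.int(length(cand), 1)]
        }
        # a single-state model paints each chromosome as one domain
        len <- if (k == 1) n - pos
               else min(1L + stats::rgeom(1, p_end), n - pos)
        did <- did + 1L
        state <- c(state, rep(s, len))
        domain_id <- c(domain_id, rep(did, len))
        pos <- pos + len
        prev <- s
      }
    }
    state_f <- factor(model$states[state], levels = model$states)
    rt_class <- as.integer(state <= min(2, k))
    # domain interval set in bp
    first <- !duplicated(domain_id)
    last <- !duplicated(domain_id, fromLast = TRUE)
    domains <- interval_set(bins$chrom[first], bins$start[first],
                            bins$end[last],
                            label = as.character(state_f[first]),
                            chrom_order = attr(bins, "chrom_order"))
    # CTCF sites at internal boundaries away from the B4-like state
    b4 <- model$states[k]
    ctcf <- data.frame(chrom = character(), pos = numeric(),
                       strand = character(), fc = numeric(),
                       stringsAsFactors = FALSE)
    bnd <- which(domain_id[-1] != domain_id[-length(domain_id)] &
                   bins$chrom[-1] == bins$chrom[-nrow(bins)])
    for (b in bnd) {
      if (state_f[b] == b4 || state_f[b + 1] == b4) next
      if (stats::runif(1) > model$ctcf_prob) next
      ctcf <- rbind(ctcf, data.frame(
        chrom = bins$chrom[b], pos = bins$end[b],
        strand = sample(c("+", "-"), 1), fc = 1 + stats::rexp(1, 1 / 2),
        stringsAsFactors = FALSE))
    }
    structure(list(bins = bins, state = state_f, domain_id = domain_id,
                   rt_class = rt_class, domains = domains, ctcf_sites = ctcf),
              class = "ground_truth")
  })
}

# per-pixel expected intensity (upper triangle semantics, full matrix built)
lambda_matrix <- function(truth, spec, model) {
  bins <- truth$bins
  n <- nrow(bins)
  si <- as.integer(truth$state)
  aff <- model$affinity[cbind(rep(si, n), rep(si, each = n))]
  dim(aff) <- c(n, n)
  cpos <- centromere_distance(bins) / spec$bin_size  # in bins
  g <- exp(-model$positional_strength *
             abs(outer(cpos, cpos, "-")) / model$pos_scale)
  code <- chrom_code(bins)
  cis <- outer(code, code, "==")
  gi <- seq_len(n)
  # separation in bins within a chromosome
  s <- abs(outer(gi, gi, "-"))
  s[s == 0] <- 1
  d <- matrix(model$trans_level, n, n)
  dcis <- s^(-model$decay_exponent)
  same_dom <- outer(truth$domain_id, truth$domain_id, "==")
  amp <- model$shoulder_amp[si]
  sh <- model$shoulder_size[si]
  shoulder <- matrix(1, n, n)
  sd_idx <- which(same_dom & cis)
  if (length(sd_idx)) {
    row <- ((sd_idx - 1) %% n) + 1
    shoulder[sd_idx] <- 1 + amp[row] * exp(-s[sd_idx] / sh[row])
  }
  d[cis] <- (dcis * shoulder)[cis]
  aff * g * d
}

#' Draw a synthetic contact matrix from planted structure
#'
#' Expected pixel intensity is the product of the state-pair affinity, the
#' centromere-distance similarity term and a distance decay (power law with
#' an exponential extrusion shoulder inside domains in cis; constant in
#' trans), scaled to the requested total depth. Counts are Poisson.
#'
#' @param truth Output of [generate_labels()].
#' @param spec A [genome_spec()].
#' @param model A [state_model()].
#' @param depth Expected total pair count (0 gives an all-zero matrix).
#' @param seed RNG seed.
#' @return A raw [contact_matrix()].
#' @export
generate_contacts <- function(truth, spec, model, depth = 1e7,
                              seed = model$seed) {
  stopifnot(depth >= 0)
  bins <- truth$bins
  n <- nrow(bins)
  if (depth == 0)
    return(contact_matrix(bins, matrix(0, n, n)))
  lam <- lambda_matrix(truth, spec, model)
  ut <- upper.tri(lam, diag = TRUE)
  lam_ut <- lam[ut]
  lam_ut <- lam_ut * depth / sum(lam_ut)
  cis <- cis_mask(bins)
  mean_trans <- mean(lam_ut[!cis[ut]])
  if (is.finite(mean_trans) && mean_trans < 0.01)
    warning("expected trans pixel intensity below 0.01; trans structure will be noisy")
  with_seed(seed, {
    v <- matrix(0, n, n)
    v[ut] <- stats::rpois(length(lam_ut), lam_ut)
    v <- pmax(v, t(v))
    contact_matrix(bins, v)
  })
}

#' Draw per-state Gaussian signal tracks
#'
#' One track per column of `model$track_means`; each bin's value is drawn
#' from the Gaussian of its planted state. The RT-like track is bimodal by
#' construction of the state means (positive early, negative late).
#'
#' @param truth Output of [generate_labels()].
#' @param model A [state_model()].
#' @param seed RNG seed.
#' @return Named list of [signal_track()] objects.
#' @export
generate_tracks <- function(truth, model, seed = model$seed) {
  si <- as.integer(truth$state)
  nm <- colnames(model$track_means)
  with_seed(seed, {
    out <- lapply(seq_along(nm), function(j) {
      signal_track(truth$bins,
                   stats::rnorm(length(si), model$track_means[si, j],
                                model$track_sds[si, j]),
                   name = nm[j])
    })
    names(out) <- nm
    out
  })
}

#' One-call synthetic dataset
#'
#' @inheritParams generate_contacts
#' @return List with `truth`, `matrix` (raw contacts) and `tracks`.
#' @export
simulate_ipg_genome <- function(spec = genome_spec(), model = state_model(),
                                depth = 1e7, seed = model$seed) {
  truth <- generate_labels(spec, model, seed = seed)
  m <- generate_contacts(truth, spec, model, depth = depth, seed = seed + 1L)
  tracks <- generate_tracks(truth, model, seed = seed + 2L)
  list(truth = truth, matrix = m, tracks = tracks)
}
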