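# Shared fixtures, all generated in code.

# uniform single- or multi-chromosome contact matrix with unit weights
uniform_cm <- function(n, n_chrom = 1, bin_size = 50000, value = 1) {
  lens <- stats::setNames(rep(n * bin_size, n_chrom),
                          paste0("chr", seq_len(n_chrom)))
  bt <- bin_table(lens, bin_size)
  contact_matrix(bt, matrix(value, n * n_chrom, n * n_chrom),
                 weights = rep(1, n * n_chrom), balanced = TRUE)
}

rand_sym_cm <- function(n, bin_size = 25000, lambda = 20, seed = 1,
                        weights = TRUE) {
  set.seed(seed)
  v <- matrix(stats::rpois(n * n, lambda), n, n)
  v <- v + t(v)
  bt <- bin_table(c(chrR = n * bin_size), bin_size)
  contact_matrix(bt, v * 1.0, weights = if (weights) rep(1, n), balanced = FALSE)
}

# exactly balanced two-state genome with alternating 10-bin domains on two
# chromosomes; affinity [[2, 0.5], [0.5, 2]]
two_state_sim <- function(depth = 1e6, seed = 5, n_bins = 300,
                          positional_strength = 0) {
  gs <- genome_spec(data.frame(name = c("c1", "c2"),
                               n_bins = c(n_bins, n_bins),
                               centromere_bin = c(n_bins %/% 2, n_bins %/% 2)))
  bins <- ipgtools:::spec_bins(gs)
  st <- rep(rep(c(1L, 2L), each = 10), length.out = 2 * n_bins)
  tm <- matrix(c(1, 0, 0, 1, 0, 0, 1, -1), 2, 4,
               dimnames = list(c("A", "B"), c("H3K9me3", "H3K27me3", "H2AZ", "RT")))
  model <- state_model(states = c("A", "B"),
                       affinity = matrix(c(2, 0.5, 0.5, 2), 2, 2),
                       positional_strength = positional_strength,
                       track_means = tm, track_sds = matrix(0.3, 2, 4))
  new_chrom <- c(1, diff(match(bins$chrom, unique(bins$chrom)))) != 0
  truth <- list(bins = bins,
                state = factor(c("A", "B")[st], levels = c("A", "B")),
                domain_id = cumsum(c(1L, diff(st) != 0) | new_chrom),
                rt_class = as.integer(st == 1))
  m <- generate_contacts(truth, gs, model, depth = depth, seed = seed)
  list(truth = truth, matrix = m, model = model, spec = gs,
       indicator = signal_track(bins, as.numeric(truth$state == "A")))
}

# memoised default five-state simulation shared across test files
.fixture_cache <- new.env(parent = emptyenv())
default_sim <- function(seed = 7) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_ipg_genome(seed = seed)
  .fixture_cache[[key]]
}

default_balanced <- function(seed = 7) {
  key <- paste0("bal", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- iterative_correction(filter_bins(default_sim(seed)$matrix))
  .fixture_cache[[key]]
}

# adjusted Rand index (independent implementation for recovery checks)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

expect_same_values <- function(x, y, tol = 1e-12) {
  expect_true(max(abs(x - y), na.rm = TRUE) <= tol)
}
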