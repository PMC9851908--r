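# One-dimensional loop-extrusion-factor (LEF) dynamics with CTCF capture
# and release, and a simplified contact-map synthesis for insulation
# readout. One monomer corresponds to 1 kb of chromatin.

#' Loop-extrusion lattice
#'
#' @param n_monomers Lattice size (1 monomer = 1 kb).
#' @param ctcf Optional data frame with `pos` (0-based monomer), `strand`
#'   (`"+"` blocks right-moving downstream legs, `"-"` blocks left-moving
#'   upstream legs) and `fc` (ChIP fold change > 1). Capture probability is
#'   min((fc - 1) / fc_med, 1) with fc_med the median fold change over the
#'   site list; an explicit `p_capture` column overrides it.
#' @param blocked_regions Optional data frame with `start`, `end` (0-based,
#'   half-open monomer intervals) impermeable to LEF legs.
#' @export
lef_lattice <- function(n_monomers, ctcf = NULL, blocked_regions = NULL) {
  stopifnot(n_monomers >= 10)
  if (!is.null(ctcf) && nrow(ctcf)) {
    stopifnot(all(ctcf$pos >= 0 & ctcf$pos < n_monomers),
              all(ctcf$strand %in% c("+", "-")), all(ctcf$fc > 0))
    if (is.null(ctcf$p_capture)) {
      fc_med <- stats::median(ctcf$fc)
      ctcf$p_capture <- pmin(pmax((ctcf$fc - 1) / fc_med, 0), 1)
    }
    stopifnot(all(ctcf$p_capture >= 0 & ctcf$p_capture <= 1))
  }
  blocked <- rep(FALSE, n_monomers)
  if (!is.null(blocked_regions) && nrow(blocked_regions))
    for (r in seq_len(nrow(blocked_regions)))
      blocked[(blocked_regions$start[r] + 1):blocked_regions$end[r]] <- TRUE
  structure(list(n_monomers = n_monomers, ctcf = ctcf, blocked = blocked),
            class = "lef_lattice")
}

#' Loop-extrusion simulation parameters
#'
#' Defaults: each free leg steps outward with probability 1/2 per step,
#' captured legs are released with probability 0.006 per step, each LEF is
#' unloaded (and immediately reloaded, keeping density constant) with
#' probability 1/100 per step, and LEFs are separated by an average of 600
#' monomers. `md_steps_per_1d` is kept as metadata only (each 1D step
#' corresponds to 400 molecular-dynamics steps in the 3D layer, which is
#' not simulated here).
#'
#' @param step_prob,release_prob,unload_prob Per-step probabilities.
#' @param mean_separation Average monomers per LEF.
#' @param n_steps Number of 1D steps.
#' @param sample_every Sampling stride in steps.
#' @param orientation `"convergent"` (oriented blocking) or `"agnostic"`.
#' @param md_steps_per_1d Metadata only.
#' @export
lef_params <- function(step_prob = 0.5, release_prob = 0.006,
                       unload_prob = 0.01, mean_separation = 600,
                       n_steps = 10000, sample_every = 10,
                       orientation = c("convergent", "agnostic"),
                       md_steps_per_1d = 400) {
  orientation <- match.arg(orientation)
  stopifnot(step_prob >= 0, step_prob <= 1, release_prob >= 0,
            release_prob <= 1, unload_prob >= 0, unload_prob <= 1)
  structure(list(step_prob = step_prob, release_prob = release_prob,
                 unload_prob = unload_prob, mean_separation = mean_separation,
                 n_steps = n_steps, sample_every = sample_every,
                 orientation = orientation, md_steps_per_1d = md_steps_per_1d),
            class = "lef_params")
}

#' Run the 1D loop-extrusion simulation
#'
#' N = floor(n_monomers / mean_separation) LEFs are loaded at uniformly
#' random unoccupied adjacent monomer pairs and stepped symmetrically with
#' occupancy exclusion, CTCF capture/release and constant-density
#' unload/reload. Deterministic under `seed`.
#'
#' @param lattice A [lef_lattice()].
#' @param params A [lef_params()].
#' @param seed RNG seed.
#' @param track_interval Optional c(lo, hi) monomer interval (0-based,
#'   half-open) for traversal bookkeeping of legs loaded outside it.
#' @return A `lef_trajectory`: `i`, `j` (samples x LEFs matrices of leg
#'   positions), `captured_i`, `captured_j`, `dwells` (release-terminated
#'   capture durations in steps), traversal counters, `lattice`, `params`.
#' @export
lef_simulate <- function(lattice, params = lef_params(), seed = 1L,
                         track_interval = NULL) {
  n_lefs <- max(1L, as.integer(floor(lattice$n_monomers / params$mean_separation)))
  ct <- lattice$ctcf
  tl <- if (is.null(track_interval)) -1L else as.integer(track_interval[1])
  th <- if (is.null(track_interval)) -1L else as.integer(track_interval[2])
  res <- with_seed(seed, lef_simulate_cpp(
    as.integer(lattice$n_monomers), n_lefs,
    as.integer(params$n_steps), as.integer(params$sample_every),
    params$step_prob, params$release_prob, params$unload_prob,
    if (is.null(ct)) integer() else as.integer(ct$pos),
    if (is.null(ct)) integer() else ifelse(ct$strand == "+", 1L, -1L),
    if (is.null(ct)) numeric() else ct$p_capture,
    lattice$blocked, params$orientation == "agnostic", tl, th))
  structure(c(res, list(n_lefs = n_lefs, lattice = lattice, params = params,
                        seed = seed)),
            class = "lef_trajectory")
}

#' @export
print.lef_trajectory <- function(x, ...) {
  cat(sprintf("lef_trajectory: %d LEFs on %d monomers, %d samples, mean loop %.1f\n",
              x$n_lefs, x$lattice$n_monomers, nrow(x$i),
              mean(x$j - x$i)))
  invisible(x)
}

#' Mean loop size over a trajectory
#'
#' @param traj A [lef_simulate()] trajectory.
#' @param burn_in Fraction of initial samples discarded (default 0.2).
#' @export
mean_loop_size <- function(traj, burn_in = 0.2) {
  keep <- seq_len(nrow(traj$i)) > burn_in * nrow(traj$i)
  mean(traj$j[keep, ] - traj$i[keep, ])
}

#' Mean captured-leg dwell time
#'
#' Exposure estimator robust to unload censoring: total time spent captured
#' (completed plus censored episodes) divided by the number of release
#' events. For the geometric release process this estimates 1/release_prob.
#'
#' @param traj A [lef_simulate()] trajectory.
#' @export
mean_dwell_time <- function(traj) {
  if (!length(traj$dwells)) return(NA_real_)
  (sum(traj$dwells) + sum(traj$censored_dwells)) / length(traj$dwells)
}

#' Synthesize a contact map from a LEF trajectory
#'
#' Loop-base contacts (one count per LEF per sampled state at its (i, j)
#' pair) are added on top of a smooth power-law background (exponent 1,
#' total mass `background_weight` times the loop mass), then binned to
#' `resolution` monomers. The result is a single-chromosome
#' [contact_matrix()] flagged as balanced, ready for insulation analysis.
#'
#' @param traj A [lef_simulate()] trajectory with >= 100 sampled states.
#' @param resolution Bin width in monomers.
#' @param background_weight Background-to-loop mass ratio (default 1).
#' @export
contact_map_from_trajectory <- function(traj, resolution = 10,
                                        background_weight = 1) {
  if (nrow(traj$i) < 100) stop("need >= 100 sampled states")
  n <- traj$lattice$n_monomers
  nb <- ceiling(n / resolution)
  v <- matrix(0, nb, nb)
  bi <- pmin(floor(as.vector(traj$i) / resolution) + 1L, nb)
  bj <- pmin(floor(as.vector(traj$j) / resolution) + 1L, nb)
  for (k in seq_along(bi)) {
    v[bi[k], bj[k]] <- v[bi[k], bj[k]] + 1
    if (bi[k] != bj[k]) v[bj[k], bi[k]] <- v[bj[k], bi[k]] + 1
  }
  loop_mass <- sum(v[upper.tri(v, diag = TRUE)])
  d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  bg <- 1 / pmax(d, 1)
  bg <- bg * background_weight * loop_mass / sum(bg[upper.tri(bg, diag = TRUE)])
  v <- v + bg
  bins <- bin_table(stats::setNames(n * 1000, "sim"), resolution * 1000)
  contact_matrix(bins, v[seq_len(nrow(bins)), seq_len(nrow(bins))],
                 weights = rep(1, nrow(bins)), balanced = TRUE)
}

#' Heterochromatin barrier traversal assay
#'
#' Runs the simulator on two lattice variants sharing flanking convergent
#' CTCF clusters around a heterochromatin-like interval: `open` (legs may
#' enter the interval) and `blocked` (the interval is impermeable).
#' Reports the fraction of legs loaded outside the interval that fully
#' cross it, and a peripheral-edge contact enrichment proxy (fraction of
#' sampled loop bases with exactly one base inside the interval).
#'
#' @param n_monomers Lattice size.
#' @param interval c(lo, hi) monomer interval (0-based, half-open).
#' @param params A [lef_params()].
#' @param seed RNG seed.
#' @param n_ctcf_flank CTCF sites in each flanking cluster (default 3).
#' @return List with per-variant traversal fractions, edge enrichment and
#'   trajectories.
#' @export
barrier_traversal_assay <- function(n_monomers, interval,
                                    params = lef_params(), seed = 1L,
                                    n_ctcf_flank = 3) {
  lo <- interval[1]; hi <- interval[2]
  stopifnot(lo > 0, hi > lo, hi < n_monomers)
  gap <- 20
  left <- data.frame(pos = lo - gap * seq_len(n_ctcf_flank), strand = "+",
                     fc = 3)
  right <- data.frame(pos = hi + gap * seq_len(n_ctcf_flank), strand = "-",
                      fc = 3)
  ctcf <- rbind(left, right)
  ctcf <- ctcf[ctcf$pos >= 0 & ctcf$pos < n_monomers, ]
  run <- function(block) {
    lat <- lef_lattice(n_monomers, ctcf = ctcf,
                       blocked_regions = if (block)
                         data.frame(start = lo, end = hi))
    traj <- lef_simulate(lat, params, seed = seed,
                         track_interval = c(lo, hi))
    inside_i <- traj$i >= lo & traj$i < hi
    inside_j <- traj$j >= lo & traj$j < hi
    spanning <- sum(xor(inside_i, inside_j))
    list(traj = traj,
         traversal = if (traj$n_candidate_legs > 0)
           traj$n_crossed_legs / traj$n_candidate_legs else 0,
         edge_contact_fraction = mean(xor(inside_i, inside_j)),
         edge_contact_count = spanning)
  }
  open <- run(FALSE)
  blocked <- run(TRUE)
  list(open = open[-1], blocked = blocked[-1],
       open_traj = open$traj, blocked_traj = blocked$traj,
       edge_enrichment_ratio = (open$edge_contact_count + 1) /
         (blocked$edge_contact_count + 1))
}
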