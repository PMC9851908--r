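# One-dimensional loop-extrusion dynamics: occupancy exclusion, CTCF
# capture/release, density conservation, loop-size scaling, contact-map
# synthesis and the heterochromatin traversal assay.

test_that("occupancy exclusion and LEF count hold over a trajectory", {
  traj <- lef_simulate(lef_lattice(12000),
                       lef_params(n_steps = 3000, sample_every = 10), seed = 1)
  expect_equal(traj$n_lefs, 12000 %/% 600)
  expect_equal(traj$occupancy_violations, 0)
  expect_true(all(traj$i < traj$j))
  # no two legs on one monomer in any sampled state
  for (s in seq(1, nrow(traj$i), by = 29)) {
    pos <- c(traj$i[s, ], traj$j[s, ])
    expect_equal(anyDuplicated(pos), 0)
  }
})

test_that("degenerate step and unload probabilities behave analytically", {
  lat <- lef_lattice(10000)
  frozen <- lef_simulate(lat, lef_params(step_prob = 0, n_steps = 500,
                                         sample_every = 10), seed = 2)
  expect_true(all(frozen$j - frozen$i == 1))
  churn <- lef_simulate(lat, lef_params(unload_prob = 1, n_steps = 300,
                                        sample_every = 5), seed = 3)
  expect_true(all(churn$j - churn$i == 1))
})

test_that("convergent CTCFs with certain capture absorb both legs", {
  # one LEF on a small lattice flanked by p_capture = 1 sites, no release
  ct <- data.frame(pos = c(200, 800), strand = c("-", "+"), fc = c(100, 100),
                   p_capture = c(1, 1))
  lat <- lef_lattice(1000, ctcf = ct)
  expect_equal(lat$ctcf$p_capture, c(1, 1))
  traj <- lef_simulate(lat, lef_params(mean_separation = 1000,
                                       release_prob = 0, unload_prob = 0,
                                       n_steps = 6000, sample_every = 100),
                       seed = 4)
  last <- nrow(traj$i)
  expect_equal(traj$i[last, 1], 200)
  expect_equal(traj$j[last, 1], 800)
  expect_true(traj$captured_i[last, 1])
  expect_true(traj$captured_j[last, 1])
})

test_that("captured dwell times follow the geometric release process", {
  pos <- seq(50, 39950, by = 50)
  ct <- data.frame(pos = pos, strand = rep(c("+", "-"), length.out = length(pos)),
                   fc = 3)
  lat <- lef_lattice(40000, ctcf = ct)
  traj <- lef_simulate(lat, lef_params(n_steps = 20000, sample_every = 500),
                       seed = 5)
  expect_gt(length(traj$dwells), 1000)
  est <- mean_dwell_time(traj)
  expect_lt(abs(est * 0.006 - 1), 0.08)
  # empirical dwell distribution is heavy consistent with geometric:
  # sd close to mean for completed episodes
  expect_lt(abs(stats::sd(traj$dwells) / mean(traj$dwells) - 1), 0.15)
})

test_that("steady-state loop size scales as growth rate over unload rate", {
  lat <- lef_lattice(60000)
  cases <- list(c(step = 0.5, unload = 0.01, expect = 100),
                c(step = 0.25, unload = 0.01, expect = 50),
                c(step = 0.5, unload = 0.02, expect = 50))
  for (cs in cases) {
    traj <- lef_simulate(lat, lef_params(step_prob = cs[["step"]],
                                         unload_prob = cs[["unload"]],
                                         mean_separation = 4000,
                                         n_steps = 30000, sample_every = 50),
                         seed = 6)
    expect_lt(abs(mean_loop_size(traj) / cs[["expect"]] - 1), 0.15)
  }
})

test_that("denser CTCF barriers shorten extruded loops monotonically", {
  sizes <- vapply(c(0, 400, 1200), function(nct) {
    ct <- if (nct > 0)
      data.frame(pos = round(seq(100, 29900, length.out = nct)),
                 strand = rep(c("+", "-"), length.out = nct), fc = 10)
    lat <- lef_lattice(30000, ctcf = ct)
    traj <- lef_simulate(lat, lef_params(mean_separation = 1500,
                                         release_prob = 0.002,
                                         n_steps = 10000, sample_every = 50),
                         seed = 7)
    mean_loop_size(traj)
  }, numeric(1))
  expect_true(all(diff(sizes) < 0))
})

test_that("contact maps show planted loops over the background", {
  # a single permanently captured loop enriches its base pixel
  ct <- data.frame(pos = c(300, 700), strand = c("-", "+"), fc = c(100, 100),
                   p_capture = c(1, 1))
  lat <- lef_lattice(1000, ctcf = ct)
  traj <- lef_simulate(lat, lef_params(mean_separation = 1000,
                                       release_prob = 0, unload_prob = 0,
                                       n_steps = 12000, sample_every = 100),
                       seed = 8)
  cm <- contact_map_from_trajectory(traj, resolution = 10)
  bi <- 300 %/% 10 + 1; bj <- 700 %/% 10 + 1
  d <- bj - bi
  same_sep <- cm$values[cbind(seq_len(nrow(cm$values) - d),
                              seq_len(nrow(cm$values) - d) + d)]
  expect_gt(cm$values[bi, bj], 10 * stats::median(same_sep))
  expect_error(contact_map_from_trajectory(
    lef_simulate(lat, lef_params(mean_separation = 1000, n_steps = 50,
                                 sample_every = 10), seed = 1)), ">= 100")
})

test_that("convergent sites create a corner dot and insulating loci", {
  ct <- data.frame(pos = c(14750, 15250), strand = c("-", "+"), fc = c(9, 9))
  lat <- lef_lattice(30000, ctcf = ct)
  traj <- lef_simulate(lat, lef_params(n_steps = 40000, sample_every = 50,
                                       unload_prob = 0.003,
                                       release_prob = 0.0005), seed = 3)
  cm <- contact_map_from_trajectory(traj, resolution = 50)
  bv <- balanced_values(cm)
  ci <- 14750 %/% 50 + 1; cj <- 15250 %/% 50 + 1
  d <- cj - ci
  ref <- bv[cbind(seq(ci - 60, ci + 60), seq(ci - 60, ci + 60) + d)]
  expect_gt(bv[ci, cj] / stats::median(ref, na.rm = TRUE), 3)
  prof <- insulation_score(cm, window = 5e5)
  loci <- call_insulating_loci(prof, 0.01)
  bins_of <- loci$start / 5e4 + 1
  expect_true(any(abs(bins_of - ci) <= 2))
  expect_true(any(abs(bins_of - cj) <= 2))
})

test_that("blocked heterochromatin is never traversed; open is", {
  bta <- barrier_traversal_assay(30000, c(14900, 15100),
                                 lef_params(unload_prob = 0.002,
                                            n_steps = 20000,
                                            sample_every = 50), seed = 8)
  expect_identical(bta$blocked$traversal, 0)
  expect_gt(bta$open$traversal, 0)
  expect_gt(bta$edge_enrichment_ratio, 1)
  # hard constraint: no sampled leg inside the blocked interval
  tb <- bta$blocked_traj
  expect_false(any(tb$i >= 14900 & tb$i < 15100))
  expect_false(any(tb$j >= 14900 & tb$j < 15100))
})

test_that("trajectories are reproducible under a fixed seed", {
  lat <- lef_lattice(10000)
  a <- lef_simulate(lat, lef_params(n_steps = 1000, sample_every = 10), seed = 9)
  b <- lef_simulate(lat, lef_params(n_steps = 1000, sample_every = 10), seed = 9)
  expect_identical(a$i, b$i)
  expect_identical(a$j, b$j)
  c <- lef_simulate(lat, lef_params(n_steps = 1000, sample_every = 10), seed = 10)
  expect_false(identical(a$i, c$i))
})
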