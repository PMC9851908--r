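# Two-state Bernoulli/Gaussian HMM segmentation, replication-timing
# processing and differential-RT region calling.

sim_bern_hmm <- function(n, p0, p1, stay, seed) {
  set.seed(seed)
  s <- integer(n); s[1] <- stats::rbinom(1, 1, 0.5)
  for (t in 2:n) s[t] <- if (stats::runif(1) < stay) s[t - 1] else 1 - s[t - 1]
  list(states = s, obs = stats::rbinom(n, 1, ifelse(s == 1, p1, p0)))
}

sim_gauss_hmm <- function(n, mu, sd, stay, seed) {
  set.seed(seed)
  s <- integer(n); s[1] <- stats::rbinom(1, 1, 0.5)
  for (t in 2:n) s[t] <- if (stats::runif(1) < stay) s[t - 1] else 1 - s[t - 1]
  list(states = s, obs = stats::rnorm(n, mu[s + 1], sd))
}

test_that("binarization thresholds the z-scored log signal", {
  bt <- bin_table(c(h = 200 * 25000), 25000)
  expect_error(binarize_track(signal_track(bt, rep(3, 200))), "degenerate")
  expect_error(binarize_track(signal_track(bt, rep(NA_real_, 200))),
               "all-missing")
  set.seed(1)
  hi <- sample(c(TRUE, FALSE), 200, TRUE, prob = c(0.3, 0.7))
  x <- ifelse(hi, exp(3 + rnorm(200, 0, 0.1)), exp(0 + rnorm(200, 0, 0.1)))
  x[5] <- NA
  b <- binarize_track(signal_track(bt, x), threshold = 1)
  expect_true(is.na(b$value[5]))
  expect_equal(b$value[-5], as.numeric(hi)[-5])
})

test_that("Baum-Welch recovers Bernoulli parameters from one long sequence", {
  d <- sim_bern_hmm(10000, 0.05, 0.9, 0.98, seed = 1)
  fit <- fit_hmm(d$obs, "bernoulli", seed = 2)
  expect_lt(abs(fit$emission$p[1] - 0.9), 0.05)
  expect_lt(abs(fit$emission$p[2] - 0.05), 0.05)
  expect_lt(abs(fit$transition[1, 1] - 0.98), 0.01)
  expect_lt(abs(fit$transition[2, 2] - 0.98), 0.01)
  # EM monotonicity
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
})

test_that("Baum-Welch recovers Gaussian parameters", {
  d <- sim_gauss_hmm(10000, c(-1, 1), 0.3, 0.98, seed = 3)
  fit <- fit_hmm(d$obs, "gaussian", seed = 4)
  expect_lt(abs(fit$emission$mean[1] - 1), 0.1)
  expect_lt(abs(fit$emission$mean[2] + 1), 0.1)
  expect_lt(abs(fit$emission$sd[1] - 0.3), 0.05)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_error(fit_hmm(rep(1, 50), "bernoulli"), "distinct")
})

test_that("Viterbi equals exhaustive path enumeration up to length 12", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    fam <- sample(c("bernoulli", "gaussian"), 1)
    trans <- matrix(stats::runif(4), 2); trans <- trans / rowSums(trans)
    init <- stats::runif(2); init <- init / sum(init)
    emission <- if (fam == "bernoulli") list(p = sort(stats::runif(2),
                                                      decreasing = TRUE))
                else list(mean = sort(stats::rnorm(2), decreasing = TRUE),
                          sd = stats::runif(2, 0.2, 1))
    model <- structure(list(family = fam, init = init, transition = trans,
                            emission = emission), class = "ipg_hmm")
    obs <- if (fam == "bernoulli") stats::rbinom(n, 1, 0.5) else stats::rnorm(n)
    vp <- ipgtools:::viterbi_path(model, obs)
    dens <- ipgtools:::emission_density(obs, fam,
      if (fam == "bernoulli") list(p = emission$p) else emission)
    best <- NULL; bestlp <- -Inf
    for (mask in 0:(2^n - 1)) {
      path <- as.integer(intToBits(mask))[1:n] + 1L
      lp <- log(init[path[1]]) + log(dens[1, path[1]])
      if (n > 1) for (t in 2:n)
        lp <- lp + log(trans[path[t - 1], path[t]]) + log(dens[t, path[t]])
      if (lp > bestlp) { bestlp <- lp; best <- path }
    }
    expect_equal(vp, best)
  }
})

test_that("Viterbi domain calls recover planted domains and merge gaps", {
  bt <- bin_table(c(v = 60 * 25000), 25000)
  model <- structure(list(family = "bernoulli", init = c(0.5, 0.5),
                          transition = matrix(c(0.95, 0.05, 0.05, 0.95), 2),
                          emission = list(p = c(0.95, 0.05))),
                     class = "ipg_hmm")
  obs <- rep(0, 60); obs[11:30] <- 1; obs[20] <- 0  # one-bin hole
  dom <- viterbi_domains(model, signal_track(bt, obs), min_gap = 1)
  expect_equal(nrow(dom), 1)
  expect_equal(dom$start, 10 * 25000)
  expect_equal(dom$end, 30 * 25000)
  # all-ones observation gives one domain per chromosome
  bt2 <- bin_table(c(x = 20 * 25000, y = 20 * 25000), 25000)
  dom2 <- viterbi_domains(model, signal_track(bt2, rep(1, 40)))
  expect_equal(nrow(dom2), 2)
  # appending missing bins at chromosome ends does not change calls
  obs_na <- c(obs, rep(NA, 10))
  bt3 <- bin_table(c(v = 70 * 25000), 25000)
  dom3 <- viterbi_domains(model, signal_track(bt3, obs_na), min_gap = 1)
  expect_equal(dom3$start, dom$start)
  expect_equal(dom3$end, dom$end)
})

test_that("planted domains are recovered with high base-pair overlap", {
  set.seed(6)
  n <- 2000
  bt <- bin_table(c(d = n * 25000), 25000)
  s <- integer(n); s[1] <- 0
  for (t in 2:n) s[t] <- if (stats::runif(1) < 0.985) s[t - 1] else 1 - s[t - 1]
  obs <- stats::rbinom(n, 1, ifelse(s == 1, 0.9, 0.05))
  fit <- fit_hmm(obs, "bernoulli", seed = 7)
  dom <- viterbi_domains(fit, signal_track(bt, as.numeric(obs)), min_gap = 1)
  called <- rep(FALSE, n)
  for (r in seq_len(nrow(dom)))
    called[(dom$start[r] / 25000 + 1):(dom$end[r] / 25000)] <- TRUE
  jac <- sum(called & s == 1) / sum(called | s == 1)
  expect_gt(jac, 0.9)
})

test_that("replication timing ratios and z-scores follow their definitions", {
  bt <- bin_table(c(r = 100 * 5e4), 5e4)
  set.seed(8)
  e <- stats::rpois(100, 60); l <- stats::rpois(100, 60)
  e[3] <- 0; l[3] <- 0
  rt <- rt_process(signal_track(bt, e), signal_track(bt, l))
  expect_true(is.na(rt$ratio[3]))
  expect_equal(mean(rt$z, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(stats::sd(rt$z, na.rm = TRUE), 1, tolerance = 1e-12)
  # hand-computed ratio
  en <- e / sum(e); ln <- l / sum(l)
  expect_equal(rt$ratio[-3], log2(en / ln)[-3])
  # doubling early gives ratio one without library normalization
  lp <- l + 1
  expect_warning(
    rt2 <- rt_process(signal_track(bt, 2 * lp), signal_track(bt, lp),
                      normalize = FALSE),
    "degenerate")
  expect_true(all(abs(rt2$ratio - 1) < 1e-12))
  expect_true(rt2$degenerate)
  expect_error(rt_process(signal_track(bt, rep(0, 100)), signal_track(bt, l)),
               "zero total")
})

test_that("differential RT flags, labels and merges regions", {
  bt <- bin_table(c(r = 100 * 5e4), 5e4)
  set.seed(9)
  base <- rnorm(100)
  rt_a <- list(bins = bt, z = (base - mean(base)) / sd(base))
  expect_equal(nrow(differential_rt(rt_a, rt_a)), 0)
  # three flagged bins separated by 200 kb and 300 kb -> two regions
  z2 <- rt_a$z
  flag <- c(10, 15, 22)  # gaps of 4 bins (200 kb) and 6 bins (300 kb)
  z2[flag] <- z2[flag] + 2
  rt_b <- list(bins = bt, z = z2)
  dr <- differential_rt(rt_a, rt_b, cutoff = 0.75, merge_distance = 250000)
  expect_equal(nrow(dr), 2)
  expect_true(all(dr$label == "hastened"))
  expect_equal(dr$start[1], 9 * 5e4)
  expect_equal(dr$end[1], 15 * 5e4)
  # antisymmetry up to label swap
  dr2 <- differential_rt(rt_b, rt_a, cutoff = 0.75, merge_distance = 250000)
  expect_equal(dr2$start, dr$start)
  expect_true(all(dr2$label == "delayed"))
  bt2 <- bin_table(c(r = 99 * 5e4), 5e4)
  expect_error(differential_rt(rt_a, list(bins = bt2, z = z2[-1])),
               "mismatched")
})
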