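poisson_spikes <- function(n_neurons, rate, duration, seed = 1) {
  set.seed(seed)
  n <- rpois(1, n_neurons * rate * duration / 1000)
  as_spike_data(tibble::tibble(time = sort(runif(n, 0, duration)),
                               neuron = sample(n_neurons, n, TRUE)),
                n_neurons = n_neurons, duration = duration)
}

regular_spikes <- function(n_neurons, period, duration) {
  tt <- seq(period, duration - 1e-9, by = period)
  as_spike_data(tibble::tibble(
    time = rep(tt, n_neurons),
    neuron = rep(seq_len(n_neurons), each = length(tt))),
    n_neurons = n_neurons, duration = duration)
}

test_that("Fano factor: Poisson near one, clock-like near zero", {
  ps <- poisson_spikes(50, 20, 20000)
  expect_equal(fano_factor(ps, window = 100), 1, tolerance = 0.05)
  rs <- regular_spikes(20, 10, 5000)
  expect_lt(fano_factor(rs, window = 100), 0.05)
  expect_error(fano_factor(ps, window = 5000), "windows")
  # thinning a Poisson process keeps FF at one
  thin <- ps[runif(nrow(ps)) < 0.3, ]
  expect_equal(suppressWarnings(fano_factor(thin, window = 100)), 1,
               tolerance = 0.07)
})

test_that("ISI CV: Poisson near one, clock-like zero", {
  ps <- poisson_spikes(50, 20, 20000)
  expect_equal(cv_isi(ps), 1, tolerance = 0.05)
  rs <- regular_spikes(20, 10, 5000)
  expect_equal(cv_isi(rs), 0)
  thin <- ps[runif(nrow(ps)) < 0.3, ]
  expect_equal(cv_isi(thin), 1, tolerance = 0.07)
})

test_that("oscillation index: power scaling, mean invariance, band options", {
  set.seed(9)
  x <- rnorm(8192, sd = 10)
  # halving the amplitude drops the band power fourfold
  expect_equal(oscillation_index(x) - oscillation_index(x / 2), log10(4),
               tolerance = 1e-10)
  # invariant to the series mean
  expect_equal(oscillation_index(x + 137), oscillation_index(x))
  # band readings: the literal band is a subset of the default band
  expect_lt(oscillation_index(x, band = "literal"), oscillation_index(x))
  # a pure in-band oscillation is captured almost entirely
  tt <- seq_len(4096)
  y <- 100 + 30 * sin(2 * pi * 60 * tt / 1000)
  expect_equal(10^oscillation_index(y), 30^2 / 2 / 2, tolerance = 0.01)
  expect_error(oscillation_index(x[1:4]), "too short")
})

test_that("pulse packets: degenerate jitter, moments, centre protocol", {
  st0 <- generate_pulse_packets(centers = c(300), targets = 1:10,
                                sigma_pp = 0, seed = 1)
  expect_true(all(st0$times == 300))
  st <- generate_pulse_packets(centers = 500, targets = 1:10, n_pp = 10000,
                               sigma_pp = 10, seed = 2)
  expect_equal(sd(st$times - 500), 10, tolerance = 0.02)
  expect_equal(mean(st$times - 500), 0, tolerance = 0.3)
  # protocol centres 200k + 200: the last of ten packets sits at 2200 ms
  st10 <- generate_pulse_packets(targets = 1:100, seed = 3)
  expect_equal(st10$packets$t_c, 200 * (1:10) + 200)
  expect_equal(max(st10$packets$t_c), 2200)
})

test_that("common input: spacing and identical delivery times", {
  st <- generate_common_input(onsets = c(400), targets = 1:100)
  expect_equal(diff(st$times)[1], 0.1)
  expect_equal(length(st$times), 500)
  # one shared time vector delivered to every target by construction
  expect_identical(st$targets, 1:100)
  st10 <- generate_common_input(targets = 1:5)
  expect_equal(st10$windows$onset, 200 * (1:10) + 200)
})

test_that("AUC: endpoints, pair-counting oracle, monotone invariance", {
  expect_equal(roc_auc(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(roc_auc(c(1, 2, 3), c(5, 6, 7)), 0)
  x <- c(1, 2, 3, 4)
  expect_equal(roc_auc(x, x), 0.5)
  set.seed(10)
  for (k in 1:20) {
    pos <- sample(0:8, 12, replace = TRUE) # integer-valued: forces ties
    neg <- sample(0:8, 9, replace = TRUE)
    expect_equal(roc_auc(pos, neg), auc_pair_count(pos, neg))
    # invariance under a monotone transform of the measurement scale
    expect_equal(roc_auc(exp(pos / 3), exp(neg / 3)), roc_auc(pos, neg))
  }
})

test_that("packet-response AUC separates planted responses from baseline", {
  rate <- tibble::tibble(time = seq(2.5, 3000, by = 5),
                         rate = 20)
  centers <- c(500, 1000, 1500, 2000, 2500)
  rate$rate[rate$time %in% (centers + 7.5)] <- 60 # bins holding t_k + 10
  expect_equal(packet_response_auc(rate, centers, response_lag = 10,
                                   baseline_lag = 100), 1)
  flat <- tibble::tibble(time = seq(2.5, 3000, by = 5), rate = 20)
  expect_equal(packet_response_auc(flat, centers), 0.5)
})

test_that("SPIKE-distance axioms: identity, symmetry, range", {
  tr <- list(c(10, 25, 30), c(10, 25, 30), c(10, 25, 30))
  expect_equal(spike_distance(tr, c(0, 40)), 0)
  a <- sort(runif(20, 0, 200))
  b <- sort(runif(25, 0, 200))
  c3 <- sort(runif(15, 0, 200))
  d1 <- spike_distance(list(a, b, c3), c(0, 200))
  d2 <- spike_distance(list(c3, a, b), c(0, 200))
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_gt(d1, 0)
  expect_lt(d1, 1)
})

test_that("SPIKE profile matches the naive reference implementation", {
  set.seed(11)
  for (k in 1:12) {
    u <- sort(c(0, runif(sample(2:12, 1), 0, 100), 100))
    v <- sort(c(0, runif(sample(2:12, 1), 0, 100), 100))
    at <- runif(40, 1, 99)
    at <- at[!at %in% c(u, v)]
    mine <- dfcnet:::.spike_profile_pair(u, v, at)
    ref <- vapply(at, function(t) spike_profile_naive(u, v, t), numeric(1))
    expect_equal(mine, ref, tolerance = 1e-12)
  }
  # two 2-spike trains with known offsets, pointwise against the oracle
  u <- c(0, 40, 60, 100)
  v <- c(0, 45, 70, 100)
  at <- c(10, 42, 50, 65, 80, 95)
  expect_equal(dfcnet:::.spike_profile_pair(u, v, at),
               vapply(at, function(t) spike_profile_naive(u, v, t),
                      numeric(1)),
               tolerance = 1e-12)
})

test_that("windowed SPIKE-distance equals its per-window evaluation", {
  set.seed(12)
  sp <- poisson_spikes(12, 15, 1200)
  d <- spike_distance_windows(sp, onsets = c(300, 600), window = 50,
                              baseline_offset = 100)
  for (i in 1:2) {
    t0 <- c(300, 600)[i]
    expect_equal(d$D_ST[i], spike_distance(sp, c(t0, t0 + 50)),
                 tolerance = 1e-12)
    expect_equal(d$D_BL[i], spike_distance(sp, c(t0 + 100, t0 + 150)),
                 tolerance = 1e-12)
  }
})
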