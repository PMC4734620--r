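test_that("alpha kernel has unit peak at tau_s, zero onset, integral e*tau_s", {
  for (tau_s in c(0.5, 1, 3)) {
    expect_equal(alpha_psc(tau_s, tau_s), 1)
    expect_equal(alpha_psc(0, tau_s), 0)
    expect_equal(alpha_psc(-1, tau_s), 0)
    q <- integrate(alpha_psc, 0, Inf, tau_s = tau_s, rel.tol = 1e-10)$value
    expect_equal(q, exp(1) * tau_s, tolerance = 1e-6)
  }
})

test_that("connectivity: complete graph, expected in-degree, determinism", {
  g1 <- build_connectivity(3, epsilon = 1, seed = 1)
  expect_true(all(g1$in_degree == 2))
  expect_true(all(g1$out_degree == 2))

  g <- build_connectivity(2000, epsilon = 0.1, seed = 2)
  # mean in-degree within 3 binomial sd of epsilon * (n - 1)
  exp_c <- 0.1 * 1999
  sd_c <- sqrt(1999 * 0.1 * 0.9 / 2000)
  expect_lt(abs(g$mean_in_degree - exp_c), 3 * sd_c)

  g2a <- build_connectivity(50, epsilon = 0.1, seed = 7)
  g2b <- build_connectivity(50, epsilon = 0.1, seed = 7)
  expect_identical(g2a$idx, g2b$idx)
  expect_error(build_connectivity(10, epsilon = 0), "epsilon")
  expect_error(build_connectivity(10, epsilon = 1.2), "epsilon")
})

test_that("subthreshold drift without noise or coupling produces no spikes", {
  net <- network_spec(
    populations = list(I = list(n = 20, neuron = neuron_params(),
                                drive = external_drive(mu = 10, sigma = 0))),
    projections = list(), epsilon = 0.5, seed = 1)
  sim <- simulate_network(net, duration = 500)
  expect_identical(nrow(sim$spikes), 0L)
})

test_that("noiseless suprathreshold neuron fires at the deterministic rate", {
  np <- neuron_params()
  net <- network_spec(
    populations = list(I = list(n = 1, neuron = np,
                                drive = external_drive(mu = 22, sigma = 0))),
    projections = list(), epsilon = 1, seed = 1)
  sim <- simulate_network(net, duration = 4000)
  r_sim <- unname(mean_rates(sim))
  expect_equal(r_sim, lif_deterministic_rate(22, np), tolerance = 0.01)
  # refractory gap respected
  isi <- diff(sim$spikes$time)
  expect_true(all(isi >= np$t_ref))
})

test_that("identical spec and seed give identical spikes", {
  net <- ii_network(n = 300, J_total = 150, seed = 42)
  s1 <- simulate_network(net, duration = 400)
  s2 <- simulate_network(net, duration = 400)
  expect_identical(s1$spikes$time, s2$spikes$time)
  expect_identical(s1$spikes$neuron, s2$spikes$neuron)
})

test_that("every spike delivers exactly out-degree postsynaptic currents", {
  net <- ii_network(n = 400, J_total = 150, seed = 9)
  sim <- simulate_network(net, duration = 600)
  expect_identical(sim$diagnostics$delivered_pscs,
                   sim$diagnostics$expected_pscs)
  expect_gt(sim$diagnostics$delivered_pscs, 0)
})

test_that("delays that are not grid multiples are rejected, not rounded", {
  net <- ii_network(n = 50, J_total = 10, delay = 5.05, seed = 1)
  expect_error(simulate_network(net, duration = 100), "multiple of dt")
  ctrl <- controller_spec("direct", K = 10, d_c = 6.53)
  net2 <- ii_network(n = 50, J_total = 10, seed = 1)
  expect_error(simulate_network(net2, ctrl, duration = 100),
               "multiple of dt")
})

test_that("population rate normalises counts to spikes/s per neuron", {
  set.seed(1)
  # 1000 neurons, one spike each, uniform over 1 s: 1 sp/s at full binning
  s <- as_spike_data(tibble::tibble(time = runif(1000, 0, 1000),
                                    neuron = 1:1000),
                     n_neurons = 1000, duration = 1000)
  r <- population_rate(s, bin = 1000)
  expect_equal(r$rate, 1)
  # homogeneous Poisson at 10 sp/s
  n_spk <- rpois(1, 1000 * 10 * 10)
  s2 <- as_spike_data(tibble::tibble(time = runif(n_spk, 0, 10000),
                                     neuron = sample(1000, n_spk, TRUE)),
                      n_neurons = 1000, duration = 10000)
  r2 <- population_rate(s2, bin = 10)
  expect_equal(mean(r2$rate), 10, tolerance = 0.05)
  # conservation: sum(count) equals the number of spikes
  expect_identical(sum(r2$count), n_spk)
  # empty data warns and returns zeros
  s0 <- as_spike_data(tibble::tibble(time = numeric(), neuron = integer()),
                      n_neurons = 10, duration = 100)
  expect_warning(r0 <- population_rate(s0, bin = 10), "empty")
  expect_true(all(r0$rate == 0))
})

test_that("asynchronous regime sanity: near-Poisson statistics well below J_cr", {
  net <- ii_network(n = 1000, J_total = 30, seed = 11)
  sim <- simulate_network(rate_compensate(net)$network, duration = 3000)
  expect_gt(fano_factor(sim, t_range = c(200, 3000)), 0.8)
  expect_lt(fano_factor(sim, t_range = c(200, 3000)), 1.2)
  cv <- cv_isi(sim, t_range = c(200, 3000))
  expect_gt(cv, 0.8)
  expect_lt(cv, 1.2)
})

test_that("supercritical network oscillates at the mean-field frequency", {
  # Hopf consistency: simulated spectral peak vs Im(lambda)/2pi of the
  # unstable mean-field eigenvalue, within 20 percent
  net <- ii_network(n = 2000, J_total = 200, seed = 12)
  sim <- simulate_network(rate_compensate(net)$network, duration = 3000)
  rt <- population_rate(sim, bin = 1)
  rt <- rt[rt$time > 300, ]
  x <- rt$count - mean(rt$count)
  p <- Mod(fft(x))^2
  f <- (seq_along(x) - 1) * 1000 / length(x)
  inb <- f > 5 & f < 200
  f_sim <- f[inb][which.max(p[inb])]
  sp <- find_spectrum(mf_config("II", op = operating_point(14, 6), J = 200))
  f_theory <- max(sp$roots$im[sp$roots$re > 0]) / (2 * pi)
  expect_gt(sp$rightmost, 0)
  expect_lt(abs(f_sim - f_theory) / f_theory, 0.2)
})

test_that("simulated linear response matches R(i omega) at a probe frequency", {
  # common sinusoidal drive replayed through the injection channel on an
  # uncoupled ensemble; coherent demodulation of the population rate
  f_hz <- 40
  eps <- 1
  dur <- 8000
  tt <- seq(0, dur - 1)  # 1 ms update grid
  trace <- eps * sin(2 * pi * f_hz * tt / 1000)
  net <- ii_network(n = 2000, J_total = 0, seed = 13)
  ctrl <- controller_spec("noise", trace = trace, onset = 0)
  sim <- simulate_network(net, ctrl, duration = dur)
  rt <- population_rate(sim, bin = 1)
  x <- rt$rate[rt$time > 500]
  t_ms <- rt$time[rt$time > 500]
  # amplitude of the rate modulation at the probe frequency; the injected
  # current is held on the 1 ms grid at the *start* of each bin while the
  # rate bin is centred, handled by projecting on the analytic signal
  z <- 2 * sum(x * exp(-2i * pi * f_hz * t_ms / 1000)) / length(x)
  amp_sim <- Mod(z)
  amp_theory <- eps * Mod(neuron_response(2i * pi * f_hz,
                                          operating_point(14, 6)))
  expect_lt(abs(amp_sim - amp_theory) / amp_theory, 0.1)
})
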