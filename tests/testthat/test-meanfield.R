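op_def <- operating_point(14, 6)

test_that("stationary rate: refractory bound, monotonicity, sigma = 0 form", {
  np <- neuron_params()
  # mu -> infinity approaches 1/t_ref
  expect_equal(stationary_rate(5000, 6, np) * np$t_ref / 1000, 1,
               tolerance = 0.05)
  # monotone increasing in mu at fixed sigma
  mus <- seq(6, 24, by = 2)
  rs <- vapply(mus, stationary_rate, numeric(1), sigma = 6, neuron = np)
  expect_true(all(diff(rs) > 0))
  # deterministic closed form at sigma = 0
  expect_equal(stationary_rate(30, 0, np), lif_deterministic_rate(30, np))
  expect_identical(stationary_rate(10, 0, np), 0)
})

test_that("stationary rate matches a long single-neuron simulation", {
  net <- network_spec(
    populations = list(I = list(n = 200, neuron = neuron_params(),
                                drive = external_drive(14, 6))),
    projections = list(), epsilon = 0.5, seed = 3)
  sim <- simulate_network(net, duration = 10000)
  expect_equal(unname(mean_rates(sim)), stationary_rate(14, 6),
               tolerance = 0.03)
})

test_that("zero-frequency neuron response equals the f-I slope", {
  r_small <- neuron_response(0.05 + 0i, op_def)
  expect_equal(Re(r_small), op_def$G_s, tolerance = 1e-3)
  expect_lt(abs(Im(r_small)), 1e-3 * op_def$G_s)
})

test_that("neuron response is conjugate-symmetric and matches the",
{
  # high-precision reference values (independent arbitrary-precision
  # evaluation of the same hypergeometric formulas, 40 digits)
  ref <- list(
    list(lam = 100 + 300i, val = 3.189296315173989 - 1.901018848505982i),
    list(lam = 0 + 50i,    val = 6.633000865948791 - 1.493502163196486i),
    list(lam = -200 + 800i, val = 1.391664868842471 - 1.911015999845721i),
    list(lam = 30 + 1200i, val = 1.304925523367415 - 1.364580745334655i))
  for (r in ref) {
    expect_equal(neuron_response(r$lam, op_def), r$val, tolerance = 1e-12)
    expect_equal(neuron_response(Conj(r$lam), op_def),
                 Conj(neuron_response(r$lam, op_def)), tolerance = 1e-14)
  }
  u <- dfcnet:::lif_u(op_def$y_t, 0.9 + 2.1i)
  expect_equal(u$u, -1.36537977875955792 + 17.0850917350202168i,
               tolerance = 1e-13)
})

test_that("synaptic transfer matches its closed form and quadrature", {
  # printed values at landmark frequencies
  expect_equal(synaptic_response(0, tau_s = 1), exp(1) * 1e-3 + 0i)
  expect_equal(Mod(synaptic_response(1i * 1000, tau_s = 1)),
               exp(1) * 1e-3 / 2)
  # numerical Laplace transform of the alpha kernel at random lambda
  set.seed(4)
  for (k in 1:20) {
    lam <- complex(real = runif(1, -300, 300), imaginary = runif(1, 0, 1200))
    num <- laplace_transform(function(t) alpha_psc(t * 1000, 1), lam,
                             upper = 0.05)
    expect_equal(synaptic_response(lam, tau_s = 1), num, tolerance = 1e-8)
  }
  # phase with the delay factor: omega d + 2 atan(omega tau_r)
  w <- 2 * pi * 60
  ph <- -Arg(synaptic_response(1i * w, tau_s = 1, delay = 5))
  expect_equal(ph, w * 5e-3 + 2 * atan(w * 1e-3), tolerance = 1e-10)
})

test_that("box-kernel transfer: static value, quadrature, effective delay", {
  kern <- control_kernel("box", a = 0, b = 1)
  expect_equal(control_response(0 + 0i, kern), 1e-3 + 0i)
  set.seed(5)
  for (k in 1:10) {
    lam <- complex(real = runif(1, -200, 200), imaginary = runif(1, 0, 1200))
    num <- laplace_transform(function(t) as.numeric(t >= 0 & t < 1e-3),
                             lam, upper = 2e-3)
    expect_equal(control_response(lam, kern), num, tolerance = 1e-10)
  }
  # phase at omega for b = 1, d_c = 6.5 equals omega * 7 ms
  w <- 2 * pi * 45
  ph <- -Arg(control_response(1i * w, kern, d_c = 6.5))
  expect_equal(ph, w * 7e-3, tolerance = 1e-6)
})

test_that("controller-off characteristic equation reduces to the open loop", {
  cfg_open <- mf_config("II", op = op_def, J = 200)
  cfg_k0 <- mf_config("II", op = op_def, J = 200,
                      controller = controller_spec("direct", K = 0,
                                                   d_c = 6.5))
  set.seed(6)
  lam <- complex(real = runif(50, -800, 150),
                 imaginary = runif(50, 0, 1200))
  expect_equal(characteristic_residual(lam, cfg_k0),
               characteristic_residual(lam, cfg_open), tolerance = 1e-14)
})

test_that("matched direct control cancels a coupling increment exactly", {
  # K = delta J, m = s (alpha kernel), d_c = d: the (J + dJ) system under
  # control has the same characteristic residual as the J system without
  dj <- 85
  cfg_ref <- mf_config("II", op = op_def, J = 200)
  cfg_ctl <- mf_config("II", op = op_def, J = 200 + dj,
                       controller = controller_spec(
                         "direct", K = dj, d_c = 5,
                         kernel = control_kernel("alpha", tau = 1)))
  set.seed(7)
  lam <- complex(real = runif(100, -900, 180),
                 imaginary = runif(100, -1200, 1200))
  expect_equal(characteristic_residual(lam, cfg_ctl),
               characteristic_residual(lam, cfg_ref), tolerance = 1e-10)
})

test_that("degenerate differential configuration is rejected", {
  expect_error(controller_spec("differential", K = 10, d_c1 = 3, d_c2 = 3),
               "identically zero")
})

test_that("spectrum: supercritical pair, residuals, conjugate closure", {
  cfg <- mf_config("II", op = op_def, J = 200)
  sp <- find_spectrum(cfg)
  expect_gt(sp$rightmost, 0)
  expect_true(all(sp$roots$residual < 1e-8))
  # roots closed under conjugation
  for (i in seq_len(nrow(sp$roots))) {
    j <- which(abs(sp$roots$re - sp$roots$re[i]) < 1e-6 &
                 abs(sp$roots$im + sp$roots$im[i]) < 1e-6)
    expect_true(length(j) >= 1)
  }
  # residual oracle: re-evaluate F at every reported root
  res <- Mod(characteristic_residual(complex(real = sp$roots$re,
                                             imaginary = sp$roots$im),
                                     cfg))
  expect_true(all(res < 1e-8))
  # uncoupled network: no eigenvalues from the coupling term at all
  expect_error(find_spectrum(mf_config("II", op = op_def, J = 0)),
               "no roots")
})

test_that("critical coupling marks the marginal root of the spectrum", {
  cc <- critical_coupling(op_def)
  expect_gt(cc$J_cr, 0)
  sp <- find_spectrum(mf_config("II", op = op_def, J = cc$J_cr))
  expect_lt(abs(sp$rightmost), 1e-6)
  i <- which.max(sp$roots$re)
  expect_equal(abs(sp$roots$im[i]), cc$omega_cr, tolerance = 1e-6)
})

test_that("static gain dominates stability along a constant-rate path", {
  # along constant rate, raising mu and lowering sigma raises G_s and must
  # lower the critical coupling (the network destabilises more easily)
  np <- neuron_params()
  r_target <- stationary_rate(14, 6, np)
  sig2 <- 4.5
  mu2 <- uniroot(function(m) stationary_rate(m, sig2, np) - r_target,
                 c(0, 25))$root
  op2 <- operating_point(mu2, sig2, np)
  expect_gt(op2$G_s, op_def$G_s)
  expect_lt(critical_coupling(op2)$J_cr, critical_coupling(op_def)$J_cr)
})

test_that("kernel-matching mismatch is the printed effective-delay difference", {
  expect_equal(kernel_matching_delta(5, 1, 6.5, 1), 0)
  expect_equal(kernel_matching_delta(5, 1, 5, 4 * 1), 0)
  # linear in each argument
  base <- kernel_matching_delta(5, 1, 6.5, 1)
  expect_equal(kernel_matching_delta(5 + 2, 1, 6.5, 1), base + 2)
  expect_equal(kernel_matching_delta(5, 1 + 0.5, 6.5, 1), base + 1)
  expect_equal(kernel_matching_delta(5, 1, 6.5 + 3, 1), base - 3)
  expect_equal(kernel_matching_delta(5, 1, 6.5, 1 + 2), base - 1)
})

test_that("landscape K = 0 column equals the uncontrolled rightmost eigenvalue", {
  cfg <- mf_config("II", op = op_def, J = 200,
                   controller = controller_spec("direct", K = 0, d_c = 6.5))
  ls <- stability_landscape(cfg, K = c(0, 150), d_c = c(2, 6.5, 12))
  open_rm <- find_spectrum(mf_config("II", op = op_def, J = 200))$rightmost
  k0 <- ls$re_max[ls$K == 0]
  expect_equal(k0, rep(open_rm, 3), tolerance = 1e-6)
  # spot agreement of a controlled cell with a direct spectrum computation
  cfg1 <- cfg
  cfg1$controller$K <- 150
  cfg1$controller$d_c <- 6.5
  expect_equal(ls$re_max[ls$K == 150 & ls$d_c == 6.5],
               find_spectrum(cfg1)$rightmost, tolerance = 1e-6)
})

test_that("mean-field stability sign predicts the simulated state", {
  # 3 x 3 (K, d_c) probe of the direct-control landscape at reduced size:
  # the sign of the rightmost eigenvalue should predict oscillatory vs
  # asynchronous simulation outcomes in at least 7 of 9 cells
  ks <- c(50, 300, 459)
  dcs <- c(1, 6.5, 20)
  net <- ii_network(n = 2000, J_total = 200, seed = 21)
  agree <- 0
  for (K in ks) {
    for (dc in dcs) {
      ctrl <- controller_spec("direct", K = K, d_c = dc, onset = 0)
      cfg <- mf_config("II", op = op_def, J = 200, controller = ctrl)
      pred_stable <- find_spectrum(cfg)$rightmost < 0
      sim <- simulate_network(rate_compensate(net, ctrl)$network, ctrl,
                              duration = 1500)
      pt <- oscillation_index(population_rate(sim, bin = 1)[-(1:300), ])
      sim_stable <- pt < 2  # AI-level band power at N = 2000
      agree <- agree + (pred_stable == sim_stable)
    }
  }
  expect_gte(agree, 7)
})
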