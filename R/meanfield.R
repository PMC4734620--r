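#' Stationary firing rate of the white-noise-driven LIF neuron
#'
#' Mean first-passage-time (Siegert) rate with absolute refractory period,
#' for the diffusion approximation of the input `mu + sigma sqrt(tau_m)
#' eta(t)`:
#' `1/r0 = t_ref + tau_m sqrt(pi) * Int_{y_r}^{y_t} e^{u^2} (1 + erf(u)) du`
#' with normalised threshold and reset arguments
#' `y_t = (v_theta - v_rest - mu)/sigma`, `y_r = (v_reset - v_rest -
#' mu)/sigma`. For `sigma = 0` the deterministic closed form
#' `1/(t_ref + tau_m log((mu' - v_reset')/(mu' - v_theta')))` is used
#' (primes relative to rest), returning 0 below threshold.
#'
#' @param mu Mean input (mV).
#' @param sigma Noise amplitude (mV).
#' @param neuron [neuron_params()].
#' @return Stationary rate in spikes/s.
#' @examples
#' stationary_rate(14, 6)        # fluctuation-driven, ~28 sp/s
#' stationary_rate(30, 0)        # deterministic suprathreshold
#' @export
stationary_rate <- function(mu, sigma, neuron = neuron_params()) {
  tau_s_ <- neuron$tau_m / 1000
  tref_s <- neuron$t_ref / 1000
  mu_eff <- neuron$v_rest + mu
  if (sigma == 0) {
    if (mu_eff <= neuron$v_theta) {
      return(0)
    }
    isi <- tref_s + tau_s_ * log((mu_eff - neuron$v_reset) /
                                 (mu_eff - neuron$v_theta))
    return(1 / isi)
  }
  y_t <- (neuron$v_theta - mu_eff) / sigma
  y_r <- (neuron$v_reset - mu_eff) / sigma
  i <- integrate(.siegert_f, y_r, y_t, rel.tol = 1e-12,
                 abs.tol = 0)$value
  1 / (tref_s + tau_s_ * sqrt(pi) * i)
}

# e^{u^2}(1 + erf u), written via the scaled complementary error function
# so large negative arguments neither overflow nor cancel (erfcx itself
# loses floating-point range beyond |u| ~ 2e4; clamp to its asymptote)
.siegert_f <- function(u) {
  out <- numeric(length(u))
  neg <- u <= 0
  # erfcx(x) = e^{x^2} erfc(x) loses floating-point range near x ~ 26;
  # switch to its asymptotic series beyond that
  big <- u < -25
  x <- abs(u[big])
  out[big] <- (1 - 0.5 / x^2 + 0.75 / x^4) / (x * sqrt(pi))
  nb <- neg & !big
  out[nb] <- pracma::erfcx(-u[nb])
  out[!neg] <- 2 * exp(u[!neg]^2) - pracma::erfcx(u[!neg])
  out
}

#' Static gain of the f-I curve
#'
#' Slope `G_s = d r0 / d mu` of the stationary rate with respect to the mean
#' input, evaluated analytically from the Siegert formula. This is the
#' zero-frequency limit of the neuron response function.
#'
#' @inheritParams stationary_rate
#' @return Gain in (spikes/s)/mV.
#' @export
static_gain <- function(mu, sigma, neuron = neuron_params()) {
  stopifnot(sigma > 0)
  r0 <- stationary_rate(mu, sigma, neuron)
  mu_eff <- neuron$v_rest + mu
  y_t <- (neuron$v_theta - mu_eff) / sigma
  y_r <- (neuron$v_reset - mu_eff) / sigma
  r0^2 * (neuron$tau_m / 1000) * sqrt(pi) *
    (.siegert_f(y_t) - .siegert_f(y_r)) / sigma
}

#' Operating point of a population
#'
#' Bundles the drive statistics with the derived stationary rate, static
#' gain and the normalised threshold/reset arguments used by the linear
#' response theory.
#'
#' @inheritParams stationary_rate
#' @return An object of class `op_point` with fields `mu`, `sigma`, `r0`
#'   (spikes/s), `G_s`, `y_t`, `y_r` and the neuron parameters.
#' @export
operating_point <- function(mu, sigma, neuron = neuron_params()) {
  stopifnot(sigma > 0)
  mu_eff <- neuron$v_rest + mu
  structure(list(mu = mu, sigma = sigma, neuron = neuron,
                 r0 = stationary_rate(mu, sigma, neuron),
                 G_s = static_gain(mu, sigma, neuron),
                 y_t = (neuron$v_theta - mu_eff) / sigma,
                 y_r = (neuron$v_reset - mu_eff) / sigma),
            class = "op_point")
}

#' @export
print.op_point <- function(x, ...) {
  cat(sprintf(
    "<op_point> mu = %g mV, sigma = %g mV: r0 = %.3f sp/s, G_s = %.4f (sp/s)/mV\n",
    x$mu, x$sigma, x$r0, x$G_s))
  invisible(x)
}

#' Linear response function of the noisy LIF neuron
#'
#' Transfer from a small modulation of the mean input current (mV) to the
#' modulation of the instantaneous firing rate (spikes/s), at complex
#' frequency `lambda` (1/s):
#' `R(lambda) = (1 - r0 t_ref) (r0/sigma) / (1 + lambda tau_m) *
#'   (U'(y_t) - U'(y_r)) / (U(y_t) - U(y_r))`
#' with `U` the confluent-hypergeometric solution of the perturbed
#' Fokker-Planck operator (see [lif_u]) and the prefactor `(1 - r0 t_ref)`
#' accounting for the refractory (non-responding) fraction. The
#' zero-frequency limit equals the static gain `G_s`; for `|lambda tau_m| <
#' 1e-7` that limit is returned directly to avoid cancellation.
#'
#' @param lambda Complex frequency(ies), 1/s; `lambda = 1i * omega` for
#'   steady-state oscillatory response at `omega` rad/s.
#' @param op An [operating_point()].
#' @return Complex response, same length as `lambda`, in (spikes/s)/mV.
#' @examples
#' op <- operating_point(14, 6)
#' Mod(neuron_response(2i * pi * 60, op))
#' @export
neuron_response <- function(lambda, op) {
  stopifnot(inherits(op, "op_point"))
  tau_m <- op$neuron$tau_m / 1000
  tref <- op$neuron$t_ref / 1000
  l_tau <- lambda * tau_m
  out <- rep(NA_complex_, length(lambda))
  tiny <- Mod(l_tau) < 1e-7
  out[tiny] <- op$G_s + 0i
  if (any(!tiny)) {
    lt <- l_tau[!tiny]
    ut <- lif_u(op$y_t, lt)
    ur <- lif_u(op$y_r, lt)
    out[!tiny] <- (1 - op$r0 * tref) * (op$r0 / op$sigma) / (1 + lt) *
      (ut$du - ur$du) / (ut$u - ur$u)
  }
  out
}

#' Synaptic transfer function of the alpha kernel
#'
#' Laplace transform of `s(t) = (t/tau_s) e^{1 - t/tau_s}`:
#' `S(lambda) = e tau_s / (1 + lambda tau_s)^2`, in seconds (so `S(0) = e
#' tau_s`). The transmission-delay factor `e^{-lambda d}` is included only
#' when `delay > 0`; at `lambda = i omega` the phase lag is then
#' `omega d + 2 atan(omega tau_s)`.
#'
#' @param lambda Complex frequency(ies), 1/s.
#' @param tau_s Synaptic time constant (ms).
#' @param delay Transmission delay (ms), default 0 (kept separate).
#' @return Complex transfer, units of seconds.
#' @export
synaptic_response <- function(lambda, tau_s = 1, delay = 0) {
  lambda <- as.complex(lambda)
  ts <- tau_s / 1000
  out <- exp(1) * ts / (1 + lambda * ts)^2
  if (delay != 0) out <- out * exp(-lambda * delay / 1000)
  out
}

#' Control-kernel transfer function
#'
#' For the box kernel `m(t) = H(t - a) - H(t - b)`:
#' `M(lambda) = (e^{-a lambda} - e^{-b lambda})/lambda * e^{-lambda d_c}`
#' in seconds, with `M(0) = b - a`. At `lambda = i omega` and `a = 0` the
#' phase lag is `omega (d_c + b/2)`, i.e. the kernel contributes an
#' effective delay of half its width.
#'
#' @param lambda Complex frequency(ies), 1/s.
#' @param kernel A [control_kernel()].
#' @param d_c Control delay (ms), default 0 (kept separate).
#' @return Complex transfer, units of seconds.
#' @export
control_response <- function(lambda, kernel = control_kernel(), d_c = 0) {
  lambda <- as.complex(lambda)
  if (kernel$shape == "alpha") {
    out <- synaptic_response(lambda, kernel$tau)
  } else {
    a <- kernel$a / 1000
    b <- kernel$b / 1000
    out <- rep(NA_complex_, length(lambda))
    small <- Mod(lambda * b) < 1e-8
    out[small] <- (b - a) + 0i
    ls <- lambda[!small]
    out[!small] <- (exp(-a * ls) - exp(-b * ls)) / ls
  }
  if (d_c != 0) out <- out * exp(-lambda * d_c / 1000)
  out
}

#' Mean-field configuration for stability analysis
#'
#' Assembles the ingredients of the characteristic equation: topology,
#' operating point(s), couplings, synaptic kernel and (optionally) a
#' controller. Topologies:
#'
#' * `"II"` - purely inhibitory network, total coupling `J`; the controller
#'   records and stimulates the same population.
#' * `"EI_recI_stimE"` - E-I loop (couplings `J_EI`, `J_IE`), controller
#'   records I and stimulates E (the control term subtracts from the
#'   `I -> E` branch).
#' * `"EI_recE_stimE"` - E-I loop, controller records and stimulates E (a
#'   control self-loop on E in parallel with the full `E -> I -> E` loop).
#'
#' @param topology One of the strings above.
#' @param op Operating point for `"II"`.
#' @param op_e,op_i Operating points of E and I for the E-I topologies.
#' @param J Total coupling, mV (II).
#' @param J_EI,J_IE Total couplings, mV (E-I).
#' @param tau_s Synaptic time constant (ms).
#' @param d Transmission delay (ms).
#' @param controller A [controller_spec()] or `NULL` for the open loop.
#' @return An object of class `mf_config`.
#' @examples
#' cfg <- mf_config("II", op = operating_point(14, 6), J = 200,
#'                  controller = controller_spec("direct", K = 150,
#'                                               d_c = 6.5))
#' @export
mf_config <- function(topology = c("II", "EI_recI_stimE", "EI_recE_stimE"),
                      op = NULL, op_e = NULL, op_i = NULL, J = NULL,
                      J_EI = NULL, J_IE = NULL, tau_s = 1, d = 5,
                      controller = NULL) {
  topology <- match.arg(topology)
  if (topology == "II") {
    stopifnot(inherits(op, "op_point"), is.numeric(J))
  } else {
    stopifnot(inherits(op_e, "op_point"), inherits(op_i, "op_point"),
              is.numeric(J_EI), is.numeric(J_IE))
  }
  if (!is.null(controller)) {
    stopifnot(inherits(controller, "controller_spec"))
    if (controller$mode == "noise") {
      abort("the open-loop noise comparator has no characteristic equation")
    }
  }
  structure(list(topology = topology, op = op, op_e = op_e, op_i = op_i,
                 J = J, J_EI = J_EI, J_IE = J_IE, tau_s = tau_s, d = d,
                 controller = controller),
            class = "mf_config")
}

# control loop factor (complex vector over lambda): the term that enters the
# bracket alongside the synaptic coupling. Positive sign = suppressive.
.control_term <- function(lambda, ctrl) {
  if (is.null(ctrl)) {
    return(rep(0 + 0i, length(lambda)))
  }
  m <- control_response(lambda, ctrl$kernel)
  switch(ctrl$mode,
    direct = ctrl$K * m * exp(-lambda * ctrl$d_c / 1000),
    differential = ctrl$K * m * (exp(-lambda * ctrl$d_c1 / 1000) -
                                 exp(-lambda * ctrl$d_c2 / 1000)),
    enhance = -ctrl$K * m * exp(-lambda * ctrl$d_c / 1000),
    abort(sprintf("unsupported controller mode '%s'", ctrl$mode)))
}

#' Characteristic residual of the closed-loop network
#'
#' Returns `F(lambda)` whose roots are the eigenvalues of the linearised
#' population dynamics. With the inhibitory sign written explicitly (the
#' "+1" side of the self-consistency condition), the implemented forms are
#'
#' * II open loop:     `F = 1 + J R S e^{-ld}`
#' * II direct:        `F = 1 + J R S e^{-ld} - K R M e^{-l d_c}`
#' * II differential:  `F = 1 + J R S e^{-ld} - K R M (e^{-l d_c1} - e^{-l d_c2})`
#' * II enhance:       `F = 1 + J R S e^{-ld} + K R M e^{-l d_c}`
#' * E-I (record I, stimulate E):
#'   `F = 1 + (J_EI S e^{-ld} -/+ K M e^{-l d_c}) R_E J_IE R_I S e^{-ld}`
#' * E-I (record E, stimulate E):
#'   `F = 1 + J_EI J_IE R_E R_I S^2 e^{-2ld} -/+ K R_E M e^{-l d_c}`
#'
#' so that with `K = delta J`, `m = s` and `d_c = d` direct control cancels
#' a coupling increment `delta J` identically.
#'
#' @param lambda Complex frequency(ies), 1/s.
#' @param config An [mf_config()].
#' @param r_cache Optional list of precomputed neuron responses at `lambda`
#'   (`r` for II, `r_e`/`r_i` for E-I) to avoid re-evaluating the
#'   hypergeometric functions on a fixed grid.
#' @return Complex residuals, same length as `lambda`.
#' @export
characteristic_residual <- function(lambda, config, r_cache = NULL) {
  stopifnot(inherits(config, "mf_config"))
  s <- synaptic_response(lambda, config$tau_s)
  ed <- exp(-lambda * config$d / 1000)
  ctrl <- .control_term(lambda, config$controller)
  if (config$topology == "II") {
    r <- r_cache$r %||% neuron_response(lambda, config$op)
    1 + config$J * r * s * ed - ctrl * r
  } else {
    r_e <- r_cache$r_e %||% neuron_response(lambda, config$op_e)
    r_i <- r_cache$r_i %||% neuron_response(lambda, config$op_i)
    if (config$topology == "EI_recI_stimE") {
      1 + (config$J_EI * s * ed - ctrl) * r_e * config$J_IE * r_i * s * ed
    } else {
      1 + config$J_EI * config$J_IE * r_e * r_i * (s * ed)^2 - ctrl * r_e
    }
  }
}

# neuron-response cache for a fixed lambda set
.r_cache_for <- function(lambda, config) {
  if (config$topology == "II") {
    list(r = neuron_response(lambda, config$op))
  } else {
    r_e <- neuron_response(lambda, config$op_e)
    same <- identical(config$op_e, config$op_i)
    list(r_e = r_e,
         r_i = if (same) r_e else neuron_response(lambda, config$op_i))
  }
}

# damped complex Newton iteration on F; derivative by central difference.
# A root is accepted as soon as |F| drops below `tol` (F is O(1)-scaled for
# the characteristic equations here); failure to decrease |F| before that
# point means the seed's basin holds no root and it is dropped.
.newton_root <- function(lambda0, f, tol = 1e-11, max_iter = 60L) {
  lam <- lambda0
  fl <- f(lam)
  for (it in seq_len(max_iter)) {
    if (is.finite(Mod(fl)) && Mod(fl) < tol) {
      return(list(lambda = lam, residual = Mod(fl)))
    }
    h <- 1e-6 * max(1, Mod(lam))
    df <- (f(lam + h) - f(lam - h)) / (2 * h)
    if (!is.finite(Mod(df)) || Mod(df) == 0) {
      return(NULL)
    }
    step <- fl / df
    ok <- FALSE
    for (damp in 0:8) {
      cand <- lam - step / 2^damp
      fc <- f(cand)
      if (is.finite(Mod(fc)) && Mod(fc) < Mod(fl)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      return(NULL)
    }
    lam <- cand
    fl <- fc
  }
  if (is.finite(Mod(fl)) && Mod(fl) < tol) {
    list(lambda = lam, residual = Mod(fl))
  } else {
    NULL
  }
}

# indices of strict local minima of a matrix (8-neighbourhood), borders
# included
.local_minima <- function(a) {
  nr <- nrow(a)
  nc <- ncol(a)
  pad <- matrix(Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- a
  ok <- matrix(TRUE, nr, nc)
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ok <- ok & (a <= pad[2:(nr + 1) + di, 2:(nc + 1) + dj])
    }
  }
  which(ok, arr.ind = TRUE)
}

#' Eigenvalue spectrum of the characteristic equation
#'
#' Locates roots of `F(lambda) = 0` inside a rectangular search region of
#' the complex plane by dense grid seeding (local minima of `|F|`) followed
#' by damped complex Newton polishing, then deduplicates and closes the set
#' under complex conjugation (the search runs on `Im(lambda) >= 0` only;
#' roots come in conjugate pairs because the underlying impulse responses
#' are real).
#'
#' @param config An [mf_config()].
#' @param re_range,im_range Search region (1/s); `im_range[1]` must be >= 0.
#' @param n_re,n_im Grid resolution for seeding.
#' @param tol Residual tolerance `|F| < tol` for accepted roots.
#' @return An object of class `dfc_spectrum`: a list with `roots` (tibble
#'   with `re`, `im`, `residual`), `rightmost` (max real part) and the
#'   config.
#' @examples
#' cfg <- mf_config("II", op = operating_point(14, 6), J = 200)
#' sp <- find_spectrum(cfg)
#' sp$rightmost > 0   # supercritical: unstable conjugate pair
#' @export
find_spectrum <- function(config, re_range = c(-1000, 200),
                          im_range = c(0, 2 * pi * 200), n_re = 49,
                          n_im = 141, tol = 1e-9) {
  stopifnot(im_range[1] >= 0, re_range[1] < re_range[2])
  xs <- seq(re_range[1], re_range[2], length.out = n_re)
  ys <- seq(im_range[1], im_range[2], length.out = n_im)
  lam_grid <- outer(ys * 1i, xs, `+`)  # n_im x n_re
  lam_vec <- as.vector(lam_grid)
  cache <- .r_cache_for(lam_vec, config)
  fg <- matrix(Mod(characteristic_residual(lam_vec, config, cache)),
               n_im, n_re)
  seeds <- .local_minima(fg)
  f <- function(l) characteristic_residual(l, config)
  roots <- list()
  for (k in seq_len(nrow(seeds))) {
    lam0 <- lam_grid[seeds[k, 1], seeds[k, 2]]
    r <- .newton_root(lam0, f, tol = min(tol, 1e-10))
    if (is.null(r)) next
    lam <- r$lambda
    if (Im(lam) < -1) next  # conjugate image of an in-region root
    if (Re(lam) < re_range[1] - 1 || Re(lam) > re_range[2] + 1 ||
        Im(lam) > im_range[2] + 1) {
      next
    }
    if (Im(lam) < 0) lam <- Conj(lam)
    dup <- any(vapply(roots, function(x) Mod(x - lam) <
                        1e-5 * max(1, Mod(lam)), logical(1)))
    if (!dup) roots[[length(roots) + 1]] <- lam
  }
  if (!length(roots)) {
    abort("no roots of the characteristic equation found in the search region")
  }
  lam <- unlist(roots)
  res <- Mod(f(lam))
  keep <- res < tol
  lam <- lam[keep]
  res <- res[keep]
  # conjugate closure
  cc <- Im(lam) > 1e-9
  lam <- c(lam, Conj(lam[cc]))
  res <- c(res, res[cc])
  ord <- order(-Re(lam), Im(lam))
  out <- list(roots = tibble(re = Re(lam)[ord], im = Im(lam)[ord],
                             residual = res[ord]),
              rightmost = max(Re(lam)), config = config)
  class(out) <- "dfc_spectrum"
  out
}

#' @export
print.dfc_spectrum <- function(x, ...) {
  cat("<dfc_spectrum>", nrow(x$roots), "roots, rightmost Re(lambda) =",
      signif(x$rightmost, 6), "1/s\n")
  print(head(x$roots, 8))
  invisible(x)
}

#' Critical coupling of the inhibitory network
#'
#' Scans the imaginary axis for marginal-stability frequencies (where the
#' loop phase of `R(i omega) S(i omega) e^{-i omega d}` crosses an odd
#' multiple of pi) and evaluates the candidate coupling `J_i = 1 / |R S|`
#' at each; the critical coupling is the minimum and `omega_cr` its
#' frequency. Crossings are refined by root finding on the imaginary part
#' of the loop transfer.
#'
#' @param op An [operating_point()].
#' @param tau_s Synaptic time constant (ms).
#' @param d Transmission delay (ms).
#' @param omega_max Upper edge of the scanned band (rad/s).
#' @return A list with `J_cr` (mV), `omega_cr` (rad/s), `f_cr` (Hz) and a
#'   tibble `candidates` of all phase crossings.
#' @examples
#' critical_coupling(operating_point(14, 6))$J_cr  # ~112 mV
#' @export
critical_coupling <- function(op, tau_s = 1, d = 5, omega_max = 3000) {
  loop <- function(w) {
    neuron_response(1i * w, op) * synaptic_response(1i * w, tau_s) *
      exp(-1i * w * d / 1000)
  }
  om <- seq(1, omega_max, length.out = 1200)
  p <- loop(om)
  ph <- Arg(p)
  dph <- diff(ph)
  phu <- ph + 2 * pi * cumsum(c(0, (dph < -pi) - (dph > pi)))
  cand <- list()
  for (k in 0:5) {
    tgt <- -(2 * k + 1) * pi
    idx <- which(diff(sign(phu - tgt)) != 0)
    for (i in idx) {
      w <- uniroot(function(w) Im(loop(w)), lower = om[i],
                   upper = om[i + 1], tol = 1e-10)$root
      pw <- loop(w)
      if (Re(pw) >= 0) next  # wrong branch (phase multiple of 2 pi)
      cand[[length(cand) + 1]] <- c(omega = w, J = 1 / Mod(pw))
    }
  }
  if (!length(cand)) {
    abort("no marginal-stability phase crossing in the scanned band")
  }
  tab <- do.call(rbind, cand)
  tab <- tibble(omega = tab[, "omega"], f_Hz = tab[, "omega"] / (2 * pi),
                J = tab[, "J"])
  i0 <- which.min(tab$J)
  list(J_cr = tab$J[i0], omega_cr = tab$omega[i0], f_cr = tab$f_Hz[i0],
       candidates = tab)
}

#' Stability landscape over control gain and delay
#'
#' Computes the real part of the rightmost eigenvalue of the closed-loop
#' characteristic equation on a `(K, d_c)` grid. The grid seeding of the
#' root search shares one evaluation of the neuron response across all
#' cells; the rightmost few candidate minima per cell are Newton-polished.
#' For differential control the `d_c` axis varies `d_c1` while `d_c2` is
#' held at the value in `controller`.
#'
#' @param config An [mf_config()] whose `controller` supplies mode, kernel
#'   and (for differential) `d_c2`; its `K`/`d_c` are overridden by the
#'   grid.
#' @param K Numeric vector of gains (mV).
#' @param d_c Numeric vector of control delays (ms).
#' @param re_range,im_range,n_re,n_im Root-search region and seeding grid,
#'   as in [find_spectrum()].
#' @return A `dfc_landscape`: tibble with columns `K`, `d_c`, `d_eff`
#'   (control delay plus half kernel width, ms), `re_max` (1/s), `im_at_max`
#'   (rad/s) and attribute `config`.
#' @export
stability_landscape <- function(config, K = seq(0, 300, by = 10),
                                d_c = seq(0, 30, by = 1),
                                re_range = c(-1000, 200),
                                im_range = c(0, 2 * pi * 200),
                                n_re = 49, n_im = 141) {
  stopifnot(inherits(config, "mf_config"),
            !is.null(config$controller))
  xs <- seq(re_range[1], re_range[2], length.out = n_re)
  ys <- seq(im_range[1], im_range[2], length.out = n_im)
  lam_grid <- outer(ys * 1i, xs, `+`)
  lam_vec <- as.vector(lam_grid)
  cache <- .r_cache_for(lam_vec, config)
  kern <- config$controller$kernel
  d_eff_half <- if (kern$shape == "alpha") 2 * kern$tau else
    (kern$a + kern$b) / 2
  cells <- tidyr::expand_grid(d_c = d_c, K = K)
  out <- purrr::pmap(cells, function(d_c, K) {
    cfg <- config
    cfg$controller$K <- K
    if (cfg$controller$mode == "differential") {
      cfg$controller$d_c1 <- d_c
      if (isTRUE(all.equal(d_c, cfg$controller$d_c2))) {
        # degenerate cell: control term vanishes identically
        cfg$controller <- NULL
      }
    } else {
      cfg$controller$d_c <- d_c
    }
    fg <- matrix(Mod(characteristic_residual(lam_vec, cfg, cache)),
                 n_im, n_re)
    seeds <- .local_minima(fg)
    seed_lam <- lam_grid[cbind(seeds[, 1], seeds[, 2])]
    seed_lam <- seed_lam[order(-Re(seed_lam))]
    f <- function(l) characteristic_residual(l, cfg)
    best <- NULL
    for (lam0 in seed_lam) {
      # skip seeds that cannot beat the current best: a polished root can
      # move at most a couple of grid cells from its seed
      if (!is.null(best) && Re(lam0) < Re(best) - 3 * diff(xs[1:2])) break
      r <- .newton_root(lam0, f, tol = 1e-9)
      if (is.null(r)) next
      if (Re(r$lambda) > re_range[2] + 1) next
      if (is.null(best) || Re(r$lambda) > Re(best)) best <- r$lambda
    }
    if (is.null(best)) {
      tibble(K = K, d_c = d_c, re_max = NA_real_, im_at_max = NA_real_)
    } else {
      tibble(K = K, d_c = d_c, re_max = Re(best),
             im_at_max = abs(Im(best)))
    }
  })
  res <- dplyr::bind_rows(out)
  res$d_eff <- res$d_c + d_eff_half
  res <- res[, c("K", "d_c", "d_eff", "re_max", "im_at_max")]
  class(res) <- c("dfc_landscape", class(res))
  attr(res, "config") <- config
  res
}

#' Stable control domains of a landscape
#'
#' Groups the stable cells (`re_max < 0`) of a [stability_landscape()] into
#' contiguous runs along the delay axis and summarises each domain by its
#' delay range, its area (number of stable cells, the robustness measure:
#' a larger domain tolerates larger parameter errors) and its most stable
#' cell. Domains are returned ordered by decreasing area, so the first row
#' is the principal control domain.
#'
#' @param landscape A `dfc_landscape`.
#' @return Tibble with one row per domain: `d_c_min`, `d_c_max`, `area`
#'   (stable cell count), `d_eff_mid` (effective delay of the domain
#'   centre), `d_eff_opt` (effective delay of the most stable cell),
#'   `K_opt`, `re_max_min`.
#' @export
landscape_domains <- function(landscape) {
  by_dc <- landscape |>
    dplyr::group_by(.data$d_c) |>
    dplyr::summarise(best = min(.data$re_max, na.rm = TRUE),
                     n_stable = sum(.data$re_max < 0, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(.data$d_c)
  stable <- by_dc$best < 0
  if (!any(stable)) {
    return(tibble(d_c_min = numeric(), d_c_max = numeric(),
                  area = integer(), d_eff_mid = numeric(),
                  d_eff_opt = numeric(), K_opt = numeric(),
                  re_max_min = numeric()))
  }
  run <- cumsum(c(TRUE, diff(stable) != 0))
  ids <- unique(run[stable])
  out <- purrr::map_dfr(ids, function(id) {
    dcs <- by_dc$d_c[run == id & stable]
    cells <- landscape[landscape$d_c %in% dcs & !is.na(landscape$re_max), ]
    i <- which.min(cells$re_max)
    half <- cells$d_eff[i] - cells$d_c[i]
    tibble(d_c_min = min(dcs), d_c_max = max(dcs),
           area = sum(by_dc$n_stable[by_dc$d_c %in% dcs]),
           d_eff_mid = (min(dcs) + max(dcs)) / 2 + half,
           d_eff_opt = cells$d_eff[i], K_opt = cells$K[i],
           re_max_min = cells$re_max[i])
  })
  dplyr::arrange(out, dplyr::desc(.data$area))
}

#' Optimal gain and stability margin at a fixed control delay
#'
#' Minimises the rightmost eigenvalue real part over the control gain `K`
#' at a fixed delay (coarse scan plus golden-section refinement). The
#' minimised value is the stability margin `B_cr` of the closed loop: more
#' negative means more robust control.
#'
#' @param config An [mf_config()] with a controller (its `K` is overridden;
#'   for differential control the fixed delay is `d_c1`).
#' @param K_range Gain interval searched (mV).
#' @param n_scan Number of coarse scan points.
#' @param ... Passed to the internal rightmost-eigenvalue evaluation
#'   ([find_spectrum()] region arguments).
#' @return List with `K_opt` (mV), `B_cr` (1/s) and the scan tibble.
#' @export
optimal_gain <- function(config, K_range = c(0, 300), n_scan = 31, ...) {
  rightmost_at <- function(K) {
    cfg <- config
    cfg$controller$K <- K
    find_spectrum(cfg, ...)$rightmost
  }
  ks <- seq(K_range[1], K_range[2], length.out = n_scan)
  scan <- vapply(ks, rightmost_at, numeric(1))
  i <- which.min(scan)
  lo <- ks[max(1, i - 1)]
  hi <- ks[min(length(ks), i + 1)]
  opt <- optimize(rightmost_at, c(lo, hi), tol = 0.25)
  if (opt$objective < scan[i]) {
    k_opt <- opt$minimum
    b_cr <- opt$objective
  } else {
    k_opt <- ks[i]
    b_cr <- scan[i]
  }
  list(K_opt = k_opt, B_cr = b_cr, scan = tibble(K = ks, re_max = scan))
}

#' Effective-delay mismatch between synaptic and control kernels
#'
#' `Delta_d = (d + 2 tau_r) - (d_c + b/2)` in ms: the difference between
#' the effective delay of the synaptic alpha kernel (transmission delay
#' plus twice its rise time, from the small-omega expansion of its phase)
#' and of the box control kernel (control delay plus half the box width).
#' Control is predicted to be most stable where the mismatch vanishes,
#' under the approximation `atan(omega tau_r) ~ omega tau_r`.
#'
#' @param d Synaptic transmission delay (ms).
#' @param tau_r Synaptic rise time constant (ms).
#' @param d_c Control delay (ms).
#' @param b Box kernel width (ms).
#' @return Mismatch in ms.
#' @examples
#' kernel_matching_delta(5, 1, 6.5, 1)  # 0: the matched configuration
#' @export
kernel_matching_delta <- function(d, tau_r, d_c, b) {
  stopifnot(all(d >= 0), all(tau_r >= 0), all(d_c >= 0), all(b >= 0))
  (d + 2 * tau_r) - (d_c + b / 2)
}
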