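# Closed-loop signal generation in R. These functions reproduce, on a
# recorded rate history, exactly the control current that the compiled
# simulator computes online; they are the reference for tests and for
# open-loop replay.

# sum of rate * dt over the window (t - delay - b, t - delay - a],
# in spikes per neuron (rate column in sp/s, bin widths in ms)
.kernel_window_sum <- function(rate_history, kernel, delay, t) {
  stopifnot(all(c("time", "rate") %in% names(rate_history)))
  tt <- rate_history$time
  if (length(tt) < 2) abort("rate history too short")
  w <- tt[2] - tt[1]
  lo <- t - delay - kernel$b
  hi <- t - delay - kernel$a
  if (lo < tt[1] - w / 2 - 1e-9 || hi > tt[length(tt)] + w / 2 + 1e-9) {
    abort(sprintf(
      "insufficient rate history: need coverage of (%g, %g] ms, have (%g, %g] ms",
      lo, hi, tt[1] - w / 2, tt[length(tt)] + w / 2))
  }
  inw <- tt > lo + 1e-9 & tt <= hi + 1e-9
  sum(rate_history$rate[inw]) * (w / 1000)
}

#' Direct delayed-feedback control signal
#'
#' `I_C(t) = K (m * v)(t - d_c)` evaluated on a recorded population-rate
#' history (regularly binned, `rate` in spikes/s per neuron). The box
#' kernel is unnormalised, so the static contribution is
#' `K * v0 * (b - a)` with the kernel support in seconds. The sign is the
#' suppressive convention: the current is depolarising when the delayed
#' rate is high, counteracting the net inhibitory recurrent feedback.
#'
#' @param rate_history Tibble with `time` (ms, regular bins) and `rate`
#'   (spikes/s per neuron), e.g. from [population_rate()].
#' @param spec A [controller_spec()] with mode `"direct"` (or
#'   `"enhance"`, for [enhance_signal()]).
#' @param t Evaluation time(s), ms.
#' @return Control current (mV), one value per `t`.
#' @examples
#' h <- tibble::tibble(time = seq(0.5, 100, 1), rate = 20)
#' cs <- controller_spec("direct", K = 100, d_c = 6.5)
#' direct_signal(h, cs, t = 50)  # K * v0 * b = 100 * 20 * 1e-3
#' @export
direct_signal <- function(rate_history, spec, t) {
  stopifnot(inherits(spec, "controller_spec"))
  vapply(t, function(tt) {
    spec$K * .kernel_window_sum(rate_history, spec$kernel, spec$d_c, tt)
  }, numeric(1))
}

#' Differential delayed-feedback control signal
#'
#' `I_C(t) = K (m * (v(. - d_c1) - v(. - d_c2)))(t)`. For a stationary
#' rate the long-run time average of this signal vanishes, so differential
#' control injects no net current and requires no rate compensation.
#'
#' @inheritParams direct_signal
#' @param spec A [controller_spec()] with mode `"differential"`.
#' @export
differential_signal <- function(rate_history, spec, t) {
  stopifnot(inherits(spec, "controller_spec"),
            spec$mode == "differential")
  vapply(t, function(tt) {
    spec$K *
      (.kernel_window_sum(rate_history, spec$kernel, spec$d_c1, tt) -
       .kernel_window_sum(rate_history, spec$kernel, spec$d_c2, tt))
  }, numeric(1))
}

#' Enhancing (oscillation-inducing) control signal
#'
#' Same magnitude as [direct_signal()] with the opposite sign, so the
#' feedback adds to the recurrent coupling and pushes an asynchronous
#' network across the Hopf bifurcation into synchronous-irregular
#' oscillations.
#'
#' @inheritParams direct_signal
#' @export
enhance_signal <- function(rate_history, spec, t) {
  -direct_signal(rate_history, spec, t)
}

#' Open-loop Gaussian comparator matched to a control trace
#'
#' Generates an i.i.d. Gaussian current trace with exactly the sample mean
#' and variance of a reference (closed-loop) control trace, on the same
#' update grid. Used as the open-loop "same power" stimulation control
#' condition: injected as a common current it does not suppress
#' synchronous-irregular oscillations.
#'
#' @param reference Tibble with `time` and `I_C` (a `dfc_sim$control`).
#' @param seed Integer seed.
#' @return Tibble with `time` and `I_C`.
#' @export
matched_noise_signal <- function(reference, seed = 1L) {
  stopifnot(all(c("time", "I_C") %in% names(reference)),
            nrow(reference) >= 2)
  m <- mean(reference$I_C)
  s <- sd(reference$I_C)
  z <- local({
    set.seed(seed)
    rnorm(nrow(reference))
  })
  z <- (z - mean(z)) / sd(z)
  tibble(time = reference$time, I_C = m + s * z)
}

#' Rate compensation of the external drive
#'
#' Adjusts the mean and noise amplitude of each population's external
#' drive so that the network with recurrence (and, if supplied, with a
#' controller) operates at the same effective point `(mu, sigma)` - and
#' hence the same mean-field stationary rate - as the uncoupled reference.
#' The recurrent contributions are removed analytically:
#' mean `sign * J * r0_src * e * tau_s`, variance
#' `J^2 / C * r0_src * e^2 tau_s / 4`, and the static control contribution
#' `+/- K * r0_rec * (b - a)` (zero for differential control, whose mean
#' vanishes).
#'
#' @param network A [network_spec()] whose drives state the *target*
#'   operating point of each population.
#' @param controller Optional [controller_spec()].
#' @param target_rate Optional target rate (spikes/s); if given, the target
#'   mean input of every population is first adjusted (at fixed sigma) to
#'   meet it.
#' @param verify If `TRUE`, run a short simulation and error if any
#'   realised rate deviates from its target by more than `tol`.
#' @param iterate Number of simulation-based refinement passes: after the
#'   analytic compensation, each pass simulates briefly and corrects the
#'   mean drives by the rate error divided by the static gain. Useful for
#'   the two-population loop, where the uniform mean-field estimate can
#'   miss when the uncontrolled state is synchronous.
#' @param tol Relative rate tolerance for `verify`.
#' @param duration,seed Refinement/verification run length (ms) and seed.
#' @return A list with `network` (compensated copy), `drives` (tibble of
#'   original and compensated `mu`, `sigma` and target rates) and, when
#'   verified, `achieved` rates.
#' @examples
#' net <- ii_network(n = 2000, J_total = 200)
#' rate_compensate(net)$drives
#' @export
rate_compensate <- function(network, controller = NULL, target_rate = NULL,
                            verify = FALSE, iterate = 0, tol = 0.05,
                            duration = 2000, seed = NULL) {
  stopifnot(inherits(network, "network_spec"))
  pops <- network$populations
  pop_names <- names(pops)
  target <- purrr::map(pops, function(p) {
    mu <- p$drive$mu
    sigma <- p$drive$sigma
    if (!is.null(target_rate)) {
      mu <- uniroot(function(m) {
        stationary_rate(m, sigma, p$neuron) - target_rate
      }, lower = p$neuron$v_reset - 20 * sigma,
        upper = p$neuron$v_theta + 20 * sigma, tol = 1e-9)$root
    }
    list(mu = mu, sigma = sigma,
         r0 = stationary_rate(mu, sigma, p$neuron))
  })
  names(target) <- pop_names

  comp <- network
  rows <- list()
  for (nm in pop_names) {
    mu_rec <- 0
    var_rec <- 0
    for (pr in network$projections) {
      if (pr$tgt != nm) next
      syn <- pr$synapse
      r_src <- target[[pr$src]]$r0
      c_in <- network$epsilon * pops[[pr$src]]$n
      ts <- syn$tau_s / 1000
      mu_rec <- mu_rec + syn$sign * syn$J_total * r_src * exp(1) * ts
      var_rec <- var_rec + syn$J_total^2 / c_in * r_src * exp(2) * ts / 4
    }
    mu_ctrl <- 0
    if (!is.null(controller) && controller$mode != "differential") {
      stim <- controller$stimulate %||% pop_names[1]
      if (stim == nm) {
        if (controller$mode == "noise") {
          mu_ctrl <- mean(controller$trace)
        } else {
          rec <- controller$record %||% pop_names[length(pop_names)]
          r_rec <- target[[rec]]$r0
          supp <- (controller$kernel$b - controller$kernel$a) / 1000
          sgn <- if (controller$mode == "enhance") -1 else 1
          mu_ctrl <- sgn * controller$K * r_rec * supp
        }
      }
    }
    sig2 <- target[[nm]]$sigma^2 - var_rec
    if (sig2 <= 0) {
      abort(sprintf(
        paste0("population '%s': recurrent input variance (%.2f mV^2) ",
               "exceeds the target variance (%.2f mV^2); ",
               "no compensated drive exists"),
        nm, var_rec, target[[nm]]$sigma^2))
    }
    mu_ext <- target[[nm]]$mu - mu_rec - mu_ctrl
    comp$populations[[nm]]$drive <- external_drive(mu_ext, sqrt(sig2))
    rows[[nm]] <- tibble(pop = nm, mu_target = target[[nm]]$mu,
                         sigma_target = target[[nm]]$sigma,
                         r0_target = target[[nm]]$r0, mu_ext = mu_ext,
                         sigma_ext = sqrt(sig2))
  }
  out <- list(network = comp, drives = dplyr::bind_rows(rows))
  for (it in seq_len(iterate)) {
    sim <- simulate_network(comp, controller, duration = duration,
                            seed = (seed %||% network$seed) + 7000 + it)
    achieved <- mean_rates(sim)
    for (nm in pop_names) {
      gain <- static_gain(target[[nm]]$mu, target[[nm]]$sigma,
                          pops[[nm]]$neuron)
      dmu <- (target[[nm]]$r0 - achieved[[nm]]) / gain
      dmu <- max(min(dmu, 3), -3)  # damp large corrections
      dr <- comp$populations[[nm]]$drive
      comp$populations[[nm]]$drive <- external_drive(dr$mu + dmu, dr$sigma)
      out$drives$mu_ext[out$drives$pop == nm] <- dr$mu + dmu
    }
    out$network <- comp
  }
  if (verify) {
    sim <- simulate_network(comp, controller, duration = duration,
                            seed = seed %||% network$seed)
    achieved <- mean_rates(sim)
    out$achieved <- achieved
    relerr <- abs(achieved - out$drives$r0_target) / out$drives$r0_target
    if (any(relerr > tol)) {
      abort(sprintf(
        "rate compensation missed the target: achieved %s vs target %s sp/s",
        paste(signif(achieved, 4), collapse = "/"),
        paste(signif(out$drives$r0_target, 4), collapse = "/")))
    }
  }
  out
}

#' Adaptive online tuning of the control gain
#'
#' Heuristic gain tuning for the case where the network coupling is not
#' known: with the control delay fixed (e.g. inferred from the oscillation
#' period), the gain `K` descends the log band power of the population
#' rate by finite-difference sign steps (each objective evaluation is a
#' short rate-compensated simulation; the step magnitude decreases as
#' `a0 / iter^0.6`, the direction is the sign of the two-sided
#' finite-difference gradient). Sign steps make the descent robust to the
#' flat, noisy objective far from the stable domain. This is a documented
#' heuristic, not a prescribed algorithm.
#'
#' @param network A [network_spec()].
#' @param controller Template [controller_spec()]; its `K` is the starting
#'   point and is overridden during tuning.
#' @param K_init,K_max Starting gain and upper bound (mV).
#' @param n_iter Number of iterations.
#' @param segment Simulation length per objective evaluation (ms).
#' @param a0 Initial step size (mV per unit log-power gradient).
#' @param c_fd Finite-difference probe half-width (mV).
#' @param seed Integer seed (fresh noise per iteration, common random
#'   numbers within each two-sided probe).
#' @return A list with `K_opt`, `converged` (logical: step size decayed
#'   and the last iterates agree within 10 percent) and `trace` (tibble
#'   with `iter`, `K`, `objective`).
#' @export
adaptive_tune_gain <- function(network, controller, K_init = 50,
                               K_max = 600, n_iter = 20, segment = 500,
                               a0 = 80, c_fd = 15, seed = 1L) {
  stopifnot(inherits(network, "network_spec"),
            inherits(controller, "controller_spec"))
  objective <- function(K, it) {
    ctrl <- controller
    ctrl$K <- K
    ctrl$onset <- 0
    rc <- rate_compensate(network, ctrl)
    sim <- simulate_network(rc$network, ctrl, duration = segment,
                            seed = seed * 1000 + it)
    oscillation_index(population_rate(sim, bin = 1))
  }
  k <- K_init
  rows <- list()
  for (it in seq_len(n_iter)) {
    g <- objective(min(k + c_fd, K_max), it) -
      objective(max(k - c_fd, 0), it)
    step <- a0 / it^0.6
    k_new <- min(max(k - step * sign(g), 0), K_max)
    rows[[it]] <- tibble(iter = it, K = k_new,
                         objective = objective(k_new, it))
    k <- k_new
  }
  trace <- dplyr::bind_rows(rows)
  last <- tail(trace$K, 5)
  converged <- diff(range(last)) <= 0.1 * max(mean(last), 1)
  list(K_opt = mean(last), converged = converged, trace = trace)
}
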