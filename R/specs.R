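#' Neuron parameters for the leaky integrate-and-fire model
#'
#' All potentials are in mV relative to an absolute scale with the resting
#' potential `v_rest`; all currents in the package are expressed in mV, i.e.
#' the membrane resistance is absorbed into the current (`R_m I` convention).
#'
#' The defaults place the operating point `mu = 14`, `sigma = 6` mV in the
#' fluctuation-driven regime: the threshold sits one noise standard
#' deviation above the mean input and the reset lies high (close to the
#' mean input), so firing is Poisson-like (ISI CV and Fano factor near 1)
#' at a stationary rate of about 24 spikes/s. The critical recurrent
#' coupling of the standard inhibitory network is then about 112 mV, with
#' synchronous-irregular oscillations near 56 Hz.
#'
#' @param tau_m Membrane time constant (ms).
#' @param v_rest Resting potential (mV).
#' @param v_theta Spike threshold (mV).
#' @param v_reset Post-spike reset potential (mV).
#' @param t_ref Absolute refractory period (ms).
#' @return An object of class `neuron_params` (a validated named list).
#' @examples
#' neuron_params()
#' @export
neuron_params <- function(tau_m = 10, v_rest = 0, v_theta = 20,
                          v_reset = 14, t_ref = 0.5) {
  stopifnot(tau_m > 0, t_ref >= 0)
  if (v_reset >= v_theta) {
    abort("`v_reset` must be below `v_theta`.")
  }
  structure(list(tau_m = tau_m, v_rest = v_rest, v_theta = v_theta,
                 v_reset = v_reset, t_ref = t_ref),
            class = "neuron_params")
}

#' Synapse parameters (alpha-function postsynaptic currents)
#'
#' `J_total` is the total recurrent coupling of the projection in mV; each
#' realised connection carries weight `J_total / C` exactly, where
#' `C = epsilon * N_src` is the expected in-degree. `sign` is +1 for
#' excitatory and -1 for inhibitory projections.
#'
#' @param J_total Total coupling (mV, magnitude).
#' @param tau_s Synaptic (alpha-kernel rise) time constant (ms).
#' @param delay Transmission delay (ms); must be a positive multiple of the
#'   integration step.
#' @param sign +1 (excitatory) or -1 (inhibitory).
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(J_total, tau_s = 1, delay = 5, sign = -1) {
  stopifnot(J_total >= 0, tau_s > 0, delay >= 0, sign %in% c(-1, 1))
  structure(list(J_total = J_total, tau_s = tau_s, delay = delay,
                 sign = sign),
            class = "synapse_params")
}

#' External drive: mean plus Gaussian white noise
#'
#' Each neuron receives an independent white-noise current
#' `mu + sigma * sqrt(tau_m) * eta(t)` with `<eta> = 0` and delta
#' autocorrelation, so `sigma` parameterises the input fluctuation on the
#' mV scale (the stationary free membrane standard deviation is
#' `sigma / sqrt(2)`).
#'
#' @param mu Mean input (mV).
#' @param sigma Noise amplitude (mV), non-negative.
#' @return An object of class `external_drive`.
#' @export
external_drive <- function(mu = 14, sigma = 6) {
  stopifnot(sigma >= 0)
  structure(list(mu = mu, sigma = sigma), class = "external_drive")
}

#' Specification of a sparse random spiking network
#'
#' Populations are named (conventionally `"I"`, or `"E"` and `"I"`);
#' projections connect ordered pairs of populations with Erdos-Renyi
#' connectivity of probability `epsilon`. For the two-population network the
#' standard configuration keeps only the `E -> I` and `I -> E` projections
#' (the oscillation-generating loop) and omits within-population recurrence.
#'
#' @param populations Named list; each element a list with fields `n`
#'   (size), `neuron` ([neuron_params()]) and `drive` ([external_drive()]).
#' @param projections List of lists with fields `src`, `tgt` (population
#'   names) and `synapse` ([synapse_params()]).
#' @param epsilon Connection probability in (0, 1].
#' @param seed Integer seed controlling connectivity and noise streams.
#' @return An object of class `network_spec`.
#' @examples
#' net <- ii_network(n = 1000, J_total = 200)
#' net$populations$I$n
#' @export
network_spec <- function(populations, projections, epsilon = 0.1,
                         seed = 1L) {
  if (!(epsilon > 0 && epsilon <= 1)) {
    abort("`epsilon` must lie in (0, 1].")
  }
  stopifnot(length(populations) >= 1, !is.null(names(populations)))
  for (p in populations) {
    stopifnot(p$n >= 1, inherits(p$neuron, "neuron_params"),
              inherits(p$drive, "external_drive"))
  }
  for (pr in projections) {
    if (!pr$src %in% names(populations) ||
        !pr$tgt %in% names(populations)) {
      abort("projection references an unknown population")
    }
    stopifnot(inherits(pr$synapse, "synapse_params"))
  }
  structure(list(populations = populations, projections = projections,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "network_spec")
}

#' Standard purely inhibitory network
#'
#' Convenience constructor for the single-population inhibitory network:
#' `n` neurons, connection probability `epsilon`, total inhibitory coupling
#' `J_total` (per-connection weight `J_total / (epsilon * n)`), alpha
#' synapses and a common transmission delay.
#'
#' @inheritParams network_spec
#' @param n Number of neurons.
#' @param J_total Total recurrent coupling (mV); `J_total = 200` with the
#'   default neuron parameters is supercritical (synchronous-irregular),
#'   values below ~112 are asynchronous-irregular.
#' @param mu,sigma External drive parameters (mV).
#' @param neuron Neuron parameters.
#' @param tau_s,delay Synapse kernel time constant and transmission delay
#'   (ms).
#' @return A [network_spec()].
#' @export
ii_network <- function(n = 10000, J_total = 200, epsilon = 0.1, mu = 14,
                       sigma = 6, neuron = neuron_params(), tau_s = 1,
                       delay = 5, seed = 1L) {
  network_spec(
    populations = list(I = list(n = n, neuron = neuron,
                                drive = external_drive(mu, sigma))),
    projections = list(list(src = "I", tgt = "I",
                            synapse = synapse_params(J_total, tau_s, delay,
                                                     sign = -1))),
    epsilon = epsilon, seed = seed)
}

#' Standard excitatory-inhibitory loop network
#'
#' Two populations coupled only through the oscillation-generating
#' `E -> I -> E` loop (within-population recurrence omitted). `J_EI` is the
#' total inhibitory coupling from I onto E, `J_IE` the total excitatory
#' coupling from E onto I.
#'
#' @inheritParams ii_network
#' @param n_e,n_i Population sizes.
#' @param J_EI,J_IE Total couplings (mV, magnitudes).
#' @return A [network_spec()].
#' @export
ei_network <- function(n_e = 8000, n_i = 2000, J_EI = 300, J_IE = 300,
                       epsilon = 0.1, mu = 14, sigma = 6,
                       neuron = neuron_params(), tau_s = 1, delay = 5,
                       seed = 1L) {
  network_spec(
    populations = list(
      E = list(n = n_e, neuron = neuron,
               drive = external_drive(mu, sigma)),
      I = list(n = n_i, neuron = neuron,
               drive = external_drive(mu, sigma))),
    projections = list(
      list(src = "I", tgt = "E",
           synapse = synapse_params(J_EI, tau_s, delay, sign = -1)),
      list(src = "E", tgt = "I",
           synapse = synapse_params(J_IE, tau_s, delay, sign = +1))),
    epsilon = epsilon, seed = seed)
}

#' Control kernel
#'
#' The box kernel is `m(t) = H(t - a) - H(t - b)` (unnormalised, so its
#' zero-frequency transfer equals the width `b - a`; effective delay
#' contribution `(a + b)/2`). The alpha shape reuses the synaptic kernel
#' `(t/tau) e^{1 - t/tau}` and exists for mean-field analyses in which the
#' control kernel is matched to the synapse (`m = s`); the simulator itself
#' supports the box shape only.
#'
#' @param shape Kernel shape; `"box"` or `"alpha"`.
#' @param a Onset (ms), `0 <= a < b` (box only).
#' @param b Offset (ms) (box only).
#' @param tau Time constant (ms) of the alpha shape.
#' @return An object of class `control_kernel`.
#' @export
control_kernel <- function(shape = c("box", "alpha"), a = 0, b = 1,
                           tau = 1) {
  shape <- match.arg(shape)
  if (shape == "box") stopifnot(a >= 0, b > a)
  if (shape == "alpha") stopifnot(tau > 0)
  structure(list(shape = shape, a = a, b = b, tau = tau),
            class = "control_kernel")
}

#' Delayed feedback controller specification
#'
#' The controller observes the instantaneous population rate `v(t)` of the
#' recorded population and injects an identical current into every neuron of
#' the stimulated population, held constant within each update step:
#'
#' * direct (suppression): `I_C(t) = +K (m * v)(t - d_c)`
#' * differential: `I_C(t) = K (m * (v(. - d_c1) - v(. - d_c2)))(t)`
#' * enhance: `I_C(t) = -K (m * v)(t - d_c)` (adds to the recurrent
#'   coupling, inducing oscillations)
#' * noise: replays a pre-computed common current trace (open-loop
#'   comparator; see [matched_noise_signal()])
#'
#' Signs follow the convention that direct control counteracts, and
#' enhancement reinforces, the net inhibitory feedback of the network. With
#' `m` equal to the synaptic kernel, `d_c = d` and `K` equal to a coupling
#' increment `delta J`, direct control cancels that increment exactly.
#'
#' @param mode One of `"direct"`, `"differential"`, `"enhance"`, `"noise"`.
#' @param K Control gain (mV), non-negative.
#' @param d_c Control delay (ms) for direct/enhance.
#' @param d_c1,d_c2 The two delays (ms) for differential control.
#' @param kernel A [control_kernel()].
#' @param record,stimulate Names of the observed and stimulated populations.
#' @param update Update step of the control current (ms).
#' @param onset Time (ms) at which the controller switches on.
#' @param trace Numeric vector of common current values (mV), one per
#'   update step after onset; only for `mode = "noise"`.
#' @return An object of class `controller_spec`.
#' @examples
#' controller_spec("direct", K = 150, d_c = 6.5)
#' @export
controller_spec <- function(mode = c("direct", "differential", "enhance",
                                     "noise"),
                            K = 0, d_c = 6.5, d_c1 = NULL, d_c2 = 1,
                            kernel = control_kernel(), record = NULL,
                            stimulate = NULL, update = 1, onset = 0,
                            trace = NULL) {
  mode <- match.arg(mode)
  stopifnot(K >= 0, update > 0, onset >= 0)
  if (mode == "differential") {
    d_c1 <- d_c1 %||% d_c
    if (isTRUE(all.equal(d_c1, d_c2))) {
      abort("differential control requires `d_c1 != d_c2` (the signal is identically zero otherwise)")
    }
    stopifnot(d_c1 >= 0, d_c2 >= 0)
  } else {
    stopifnot(d_c >= 0)
  }
  if (mode == "noise" && is.null(trace)) {
    abort("`mode = \"noise\"` requires a `trace` of current values")
  }
  structure(list(mode = mode, K = K, d_c = d_c, d_c1 = d_c1, d_c2 = d_c2,
                 kernel = kernel, record = record, stimulate = stimulate,
                 update = update, onset = onset, trace = trace),
            class = "controller_spec")
}

# delay (ms) -> integration steps; rejects non-multiples rather than
# silently rounding
.steps <- function(x, dt, what = "delay") {
  s <- x / dt
  if (abs(s - round(s)) > 1e-9) {
    abort(sprintf("%s = %g ms is not a multiple of dt = %g ms", what, x, dt))
  }
  as.integer(round(s))
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec>", length(x$populations), "population(s),",
      length(x$projections), "projection(s), epsilon =", x$epsilon, "\n")
  for (nm in names(x$populations)) {
    p <- x$populations[[nm]]
    cat(sprintf("  %s: n = %d, mu = %g mV, sigma = %g mV\n", nm, p$n,
                p$drive$mu, p$drive$sigma))
  }
  for (pr in x$projections) {
    cat(sprintf("  %s -> %s: J = %g mV (%s), tau_s = %g ms, d = %g ms\n",
                pr$src, pr$tgt, pr$synapse$J_total,
                if (pr$synapse$sign > 0) "exc" else "inh",
                pr$synapse$tau_s, pr$synapse$delay))
  }
  invisible(x)
}

#' @export
print.controller_spec <- function(x, ...) {
  cat("<controller_spec>", x$mode, "K =", x$K, "mV")
  if (x$mode == "differential") {
    cat(", d_c1 =", x$d_c1, "ms, d_c2 =", x$d_c2, "ms")
  } else if (x$mode != "noise") {
    cat(", d_c =", x$d_c, "ms")
  }
  cat(", kernel box [", x$kernel$a, ",", x$kernel$b, "] ms, onset =",
      x$onset, "ms\n")
  invisible(x)
}
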