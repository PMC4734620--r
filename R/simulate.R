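#' Alpha-function postsynaptic current kernel
#'
#' `s(t) = (t / tau_s) e^{1 - t/tau_s}` for `t >= 0` and 0 otherwise;
#' normalised to peak value 1 at `t = tau_s`, with time integral
#' `e * tau_s`.
#'
#' @param t Time(s) since the presynaptic spike (ms).
#' @param tau_s Synaptic time constant (ms).
#' @return Kernel values (dimensionless).
#' @examples
#' alpha_psc(1, tau_s = 1)  # peak = 1
#' @export
alpha_psc <- function(t, tau_s = 1) {
  stopifnot(tau_s > 0)
  ifelse(t >= 0, (t / tau_s) * exp(1 - t / tau_s), 0)
}

#' Random connectivity of a projection
#'
#' Draws the Erdos-Renyi adjacency of one projection: every ordered pair
#' `(j -> i)` with `i != j` (self-connections excluded within a population)
#' is connected independently with probability `epsilon`. Reproducible for
#' a fixed seed; the same generator is used internally by
#' [simulate_network()].
#'
#' @param n_src,n_tgt Source and target population sizes.
#' @param epsilon Connection probability in (0, 1].
#' @param same_pop Are source and target the same population (excludes
#'   self-loops)?
#' @param seed Integer seed.
#' @return A list with `ptr` (0-based CSR row pointer over sources), `idx`
#'   (0-based target indices), `out_degree`, `in_degree` and
#'   `mean_in_degree`.
#' @examples
#' g <- build_connectivity(50, 50, epsilon = 0.1, seed = 1)
#' g$mean_in_degree
#' @export
build_connectivity <- function(n_src, n_tgt = n_src, epsilon = 0.1,
                               same_pop = TRUE, seed = 1L) {
  if (!(epsilon > 0 && epsilon <= 1)) {
    abort("`epsilon` must lie in (0, 1].")
  }
  g <- .build_connectivity_cpp(n_src, n_tgt, 0L, same_pop, epsilon,
                               as.double(seed))
  ind <- tabulate(g$idx + 1L, nbins = n_tgt)
  list(ptr = g$ptr, idx = g$idx, out_degree = diff(g$ptr),
       in_degree = ind, mean_in_degree = mean(ind))
}

# internal: per-stream seeds derived from the master seed with fixed
# offsets, so e.g. attaching a controller never perturbs the noise stream
.stream_seed <- function(seed, stream, index = 0L) {
  base <- c(connectivity = 1e6, noise = 2e6, stimulus = 3e6,
            controller = 4e6)
  as.double(seed) * 16 + base[[stream]] + as.double(index)
}

#' Simulate a spiking network, optionally under closed-loop control
#'
#' Integrates the network of leaky integrate-and-fire neurons defined by
#' `network` for `duration` ms at step `dt`, with alpha-function recurrent
#' synapses, per-neuron Gaussian white-noise drive and, if `controller` is
#' given, a common control current injected identically into every neuron
#' of the stimulated population (updated every `controller$update` ms from
#' the delayed population rate of the recorded population).
#'
#' The membrane follows an exact exponential update between grid points and
#' the alpha kernels are propagated exactly as a pair of linear states, so
#' `dt` only controls spike-grid alignment. All delays must be multiples of
#' `dt` (rejected otherwise, never rounded).
#'
#' @param network A [network_spec()].
#' @param controller A [controller_spec()] or `NULL`.
#' @param duration Simulated time (ms).
#' @param dt Integration step (ms); the controller update step must be a
#'   multiple of it.
#' @param stimuli Optional list of stimulus descriptors as produced by
#'   [generate_pulse_packets()] or [generate_common_input()]: each a list
#'   with `times` (ms), `targets` (1-based neuron ids), `weight` (mV) and
#'   `tau_s` (ms).
#' @param record_vm Integer vector of neuron ids (1-based, global across
#'   populations) whose membrane potential is recorded every `dt`.
#' @param seed Optional integer overriding `network$seed`.
#' @return An object of class `dfc_sim`: a list with
#' * `spikes`: [spike_data] tibble (`time` ms, `neuron` id, `pop` label),
#' * `counts`: tibble of per-step population spike counts,
#' * `control`: tibble of the injected control current (one row per update),
#' * `vm`: tibble of recorded membrane traces (long format),
#' * `diagnostics`: delivered vs expected postsynaptic currents, realized
#'    rates per population, and the specs used.
#' @examples
#' net <- ii_network(n = 400, J_total = 0, mu = 14, sigma = 6, seed = 2)
#' sim <- simulate_network(net, duration = 500)
#' mean_rates(sim)
#' @export
simulate_network <- function(network, controller = NULL, duration,
                             dt = .dt_default, stimuli = list(),
                             record_vm = integer(0), seed = NULL) {
  stopifnot(inherits(network, "network_spec"), duration > 0, dt > 0)
  seed <- seed %||% network$seed
  pops <- network$populations
  pop_names <- names(pops)
  n_by_pop <- vapply(pops, function(p) as.integer(p$n), integer(1))
  pop_start <- c(0L, cumsum(n_by_pop))
  n_steps <- .steps(duration, dt, "duration")

  pop_list <- purrr::imap(pops, function(p, nm) {
    list(n = as.integer(p$n), tau_m = p$neuron$tau_m,
         v_rest = p$neuron$v_rest, v_theta = p$neuron$v_theta,
         v_reset = p$neuron$v_reset,
         t_ref_steps = .steps(p$neuron$t_ref, dt, "t_ref"),
         mu = p$drive$mu, sigma = p$drive$sigma,
         v_init_sd = p$drive$sigma / sqrt(2))
  })
  names(pop_list) <- NULL

  proj_list <- purrr::imap(network$projections, function(pr, k) {
    sp <- match(pr$src, pop_names) - 1L
    tp <- match(pr$tgt, pop_names) - 1L
    cexp <- network$epsilon * n_by_pop[[pr$src]]
    ds <- .steps(pr$synapse$delay, dt, "synaptic delay")
    if (ds < 1) abort("synaptic delays must be at least one step `dt`")
    list(src = sp, tgt = tp,
         weight = pr$synapse$sign * pr$synapse$J_total / cexp,
         tau_s = pr$synapse$tau_s, delay_steps = ds, p = network$epsilon,
         seed = .stream_seed(seed, "connectivity", k))
  })

  stim_list <- purrr::map(stimuli, function(st) {
    list(steps = as.integer(round(st$times / dt)),
         targets = as.integer(st$targets) - 1L,
         weight = st$weight, tau_s = st$tau_s %||% 1)
  })

  ctrl_list <- list(mode = 0L)
  if (!is.null(controller)) {
    stopifnot(inherits(controller, "controller_spec"))
    record <- controller$record %||% pop_names[length(pop_names)]
    stimulate <- controller$stimulate %||% pop_names[1]
    if (!record %in% pop_names || !stimulate %in% pop_names) {
      abort("controller record/stimulate population not in the network")
    }
    upd <- .steps(controller$update, dt, "controller update step")
    mode_code <- match(controller$mode,
                       c("direct", "differential", "enhance", "noise"))
    ctrl_list <- list(
      mode = mode_code, K = controller$K,
      dc_steps = if (controller$mode == "differential") {
        .steps(controller$d_c1, dt, "d_c1")
      } else .steps(controller$d_c, dt, "d_c"),
      dc2_steps = if (controller$mode == "differential") {
        .steps(controller$d_c2, dt, "d_c2")
      } else 0L,
      a_steps = .steps(controller$kernel$a, dt, "kernel onset"),
      b_steps = .steps(controller$kernel$b, dt, "kernel width"),
      update_steps = upd,
      onset_step = .steps(controller$onset, dt, "controller onset"),
      record_pop = match(record, pop_names) - 1L,
      stim_pop = match(stimulate, pop_names) - 1L,
      trace = controller$trace %||% numeric(0))
  }

  res <- .sim_lif_cpp(pop_list, proj_list, stim_list, ctrl_list,
                      n_steps, dt, .stream_seed(seed, "noise"),
                      as.integer(record_vm) - 1L, 1L)

  pop_of <- rep(pop_names, n_by_pop)
  spikes <- tibble(time = res$spike_time, neuron = res$spike_id + 1L,
                   pop = pop_of[res$spike_id + 1L])
  spikes <- as_spike_data(spikes, n_neurons = sum(n_by_pop),
                          duration = duration,
                          pop_sizes = setNames(n_by_pop, pop_names))
  counts <- as_tibble(stats::setNames(
    as.data.frame(res$pop_counts), pop_names))
  counts$time <- (seq_len(n_steps)) * dt
  counts <- counts[, c("time", pop_names)]
  control <- tibble(time = res$control_time, I_C = res$control_value)
  vm <- NULL
  if (length(record_vm)) {
    vm <- as.data.frame(res$vm)
    names(vm) <- paste0("n", record_vm)
    vm <- tibble::add_column(as_tibble(vm), time = res$vm_time,
                             .before = 1)
  }
  rates <- vapply(pop_names, function(nm) {
    sum(spikes$pop == nm) / n_by_pop[[nm]] / (duration / 1000)
  }, numeric(1))
  out <- list(spikes = spikes, counts = counts, control = control, vm = vm,
              diagnostics = list(
                delivered_pscs = res$delivered_pscs,
                expected_pscs = res$expected_pscs,
                rates = rates, network = network,
                controller = controller, dt = dt, seed = seed,
                duration = duration))
  class(out) <- "dfc_sim"
  out
}

#' @export
print.dfc_sim <- function(x, ...) {
  d <- x$diagnostics
  cat("<dfc_sim>", nrow(x$spikes), "spikes /", d$duration, "ms\n")
  cat("  rates:",
      paste(sprintf("%s = %.2f sp/s", names(d$rates), d$rates),
            collapse = ", "), "\n")
  if (!is.null(d$controller)) cat("  controller:", d$controller$mode,
                                  "K =", d$controller$K, "mV\n")
  invisible(x)
}

#' Mean firing rate per population
#'
#' @param sim A `dfc_sim`.
#' @return Named numeric vector of per-neuron mean rates (spikes/s).
#' @export
mean_rates <- function(sim) {
  stopifnot(inherits(sim, "dfc_sim"))
  sim$diagnostics$rates
}

#' Spike data container
#'
#' A tibble of spike events (`time` in ms, `neuron` id, optional `pop`
#' label) carrying the population size and recording duration as
#' attributes, so that rate and count statistics can be normalised without
#' re-supplying them.
#'
#' @param x A data frame with columns `time` and `neuron`.
#' @param n_neurons Total number of neurons (including silent ones).
#' @param duration Recording duration (ms).
#' @param pop_sizes Optional named vector of per-population sizes.
#' @return A `spike_data` tibble.
#' @export
as_spike_data <- function(x, n_neurons, duration, pop_sizes = NULL) {
  stopifnot(all(c("time", "neuron") %in% names(x)), n_neurons >= 1,
            duration > 0)
  x <- as_tibble(x)
  if (nrow(x) && (min(x$time) < 0 || max(x$time) > duration)) {
    abort("spike times must lie within [0, duration]")
  }
  structure(x, n_neurons = as.integer(n_neurons), duration = duration,
            pop_sizes = pop_sizes,
            class = c("spike_data", class(x)))
}

# keep attributes across dplyr-style subsetting
#' @export
`[.spike_data` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("time", "neuron") %in% names(out))) {
    attr(out, "n_neurons") <- attr(x, "n_neurons")
    attr(out, "duration") <- attr(x, "duration")
    attr(out, "pop_sizes") <- attr(x, "pop_sizes")
    class(out) <- unique(c("spike_data", class(out)))
  }
  out
}

#' Instantaneous population rate
#'
#' Bins spikes into non-overlapping windows and converts counts to the
#' per-neuron population rate in spikes/s: `rate = count / (N * bin)`.
#'
#' @param spikes A [as_spike_data()] tibble (or a `dfc_sim`, whose spikes
#'   are used).
#' @param bin Bin width (ms).
#' @param pop Optional population label to restrict to (its size is then
#'   used for normalisation).
#' @return Tibble with `time` (bin centre, ms), `count` and `rate`
#'   (spikes/s per neuron).
#' @examples
#' s <- as_spike_data(data.frame(time = runif(1000, 0, 1000),
#'                               neuron = sample(100, 1000, TRUE)),
#'                    n_neurons = 100, duration = 1000)
#' mean(population_rate(s, bin = 10)$rate)  # ~10 sp/s
#' @export
population_rate <- function(spikes, bin = 1, pop = NULL) {
  if (inherits(spikes, "dfc_sim")) spikes <- spikes$spikes
  stopifnot(inherits(spikes, "spike_data"), bin > 0)
  duration <- attr(spikes, "duration")
  n <- attr(spikes, "n_neurons")
  if (!is.null(pop)) {
    sizes <- attr(spikes, "pop_sizes")
    stopifnot(!is.null(sizes), pop %in% names(sizes))
    spikes <- spikes[spikes$pop == pop, ]
    n <- sizes[[pop]]
  }
  edges <- seq(0, duration, by = bin)
  if (edges[length(edges)] < duration) edges <- c(edges, duration)
  if (!nrow(spikes)) {
    warn("empty spike data: returning an all-zero rate")
    counts <- rep(0L, length(edges) - 1)
  } else {
    counts <- as.integer(
      table(cut(spikes$time, edges, include.lowest = TRUE,
                labels = FALSE)) [as.character(seq_len(length(edges) - 1))])
    counts[is.na(counts)] <- 0L
  }
  widths <- diff(edges)
  tibble(time = utils::head(edges, -1) + widths / 2, count = counts,
         rate = counts / (n * widths / 1000))
}
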