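#' Write spikes to a plain-text file
#'
#' Two whitespace-separated columns `time_ms neuron_id`, times fixed to
#' three decimal places, preceded by `#` header comment lines carrying the
#' population size and duration so that the file round-trips losslessly
#' through [read_spikes()].
#'
#' @param spikes A [as_spike_data()] tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_data"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# dfcnet spike data",
               sprintf("# n_neurons %d", attr(spikes, "n_neurons")),
               sprintf("# duration_ms %.3f", attr(spikes, "duration")),
               "# time_ms neuron_id"), con)
  if (nrow(spikes)) {
    writeLines(sprintf("%.3f %d", spikes$time, spikes$neuron), con)
  }
  invisible(path)
}

#' Read spikes from a plain-text file
#'
#' Counterpart of [write_spikes()]. Malformed lines and neuron ids outside
#' `[1, n_neurons]` are rejected with the offending line number.
#'
#' @param path File path.
#' @return A [as_spike_data()] tibble.
#' @export
read_spikes <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- lines[hdr]
  get_meta <- function(key) {
    m <- meta[grepl(paste0("^# ", key, " "), meta)]
    if (!length(m)) abort(sprintf("missing '# %s' header in %s", key, path))
    as.numeric(sub(paste0("^# ", key, " "), "", m[1]))
  }
  n <- as.integer(get_meta("n_neurons"))
  duration <- get_meta("duration_ms")
  body_idx <- which(!hdr)
  if (!length(body_idx)) {
    return(as_spike_data(tibble(time = numeric(), neuron = integer()),
                         n_neurons = n, duration = duration))
  }
  parts <- strsplit(trimws(lines[body_idx]), "\\s+")
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    abort(sprintf("malformed spike line %d in %s: '%s'",
                  body_idx[bad[1]], path, lines[body_idx[bad[1]]]))
  }
  m <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE))
  if (anyNA(m)) {
    bad <- body_idx[which(rowSums(is.na(m)) > 0)[1]]
    abort(sprintf("malformed spike line %d in %s", bad, path))
  }
  ids <- as.integer(m[, 2])
  out_of_range <- which(ids < 1 | ids > n)
  if (length(out_of_range)) {
    abort(sprintf("neuron id %d out of [1, %d] at line %d of %s",
                  ids[out_of_range[1]], n, body_idx[out_of_range[1]], path))
  }
  as_spike_data(tibble(time = m[, 1], neuron = ids), n_neurons = n,
                duration = duration)
}

# ---- flat-section configuration files ------------------------------------

.config_defaults <- function() {
  list(network = list(n = 10000, epsilon = 0.1, seed = 1),
       neurons = list(tau_m = 10, v_rest = 0, v_theta = 20, v_reset = 14,
                      t_ref = 0.5),
       synapses = list(J_total = 200, tau_s = 1, delay = 5),
       drive = list(mu = 14, sigma = 6),
       controller = list(mode = "none", K_mV = 0, d_c_ms = 6.5,
                         d_c1_ms = 6.5, d_c2_ms = 1, kernel_width_ms = 1,
                         update_ms = 1, onset_ms = 0))
}

#' Read a network/controller configuration file
#'
#' Flat-section `key = value` format (INI style) describing the standard
#' inhibitory network and an optional controller:
#' sections `[network]` (`n`, `epsilon`, `seed`), `[neurons]`, `[synapses]`,
#' `[drive]` and `[controller]` (`mode`, `K_mV`, `d_c_ms`, `d_c1_ms`,
#' `d_c2_ms`, `kernel_width_ms`, `update_ms`, `onset_ms`). Unknown sections
#' or keys are rejected, listing every offending key; missing keys take the
#' defaults (an empty file yields the all-default specification, with a
#' warning). Delays are validated as multiples of the integration step.
#'
#' @param path Configuration file path.
#' @param dt Integration step used for grid-multiple validation (ms).
#' @return A list with `network` ([network_spec()]), `controller`
#'   ([controller_spec()] or `NULL`) and `values` (the merged settings with
#'   a `source` marker `"default"` or `"user"` per key).
#' @export
read_config <- function(path, dt = .dt_default) {
  defaults <- .config_defaults()
  lines <- readLines(path)
  lines <- trimws(sub("[#;].*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warn("empty configuration: using all defaults")
  }
  section <- NA_character_
  user <- list()
  errors <- character()
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (grepl("^\\[.+\\]$", l)) {
      section <- sub("^\\[(.+)\\]$", "\\1", l)
      if (!section %in% names(defaults)) {
        errors <- c(errors, sprintf("unknown section [%s]", section))
        section <- NA_character_
      }
      next
    }
    if (!grepl("=", l)) {
      errors <- c(errors, sprintf("line %d is not 'key = value': '%s'", i, l))
      next
    }
    if (is.na(section)) next
    key <- trimws(sub("=.*$", "", l))
    val <- trimws(sub("^[^=]*=", "", l))
    if (!key %in% names(defaults[[section]])) {
      errors <- c(errors, sprintf("unknown key '%s' in [%s]", key, section))
      next
    }
    user[[section]][[key]] <-
      if (key == "mode") val else as.numeric(val)
  }
  if (length(errors)) {
    abort(paste(c("invalid configuration:", errors), collapse = "\n  "))
  }
  merged <- defaults
  src <- lapply(defaults, function(s) {
    setNames(rep("default", length(s)), names(s))
  })
  for (s in names(user)) {
    for (k in names(user[[s]])) {
      merged[[s]][[k]] <- user[[s]][[k]]
      src[[s]][[k]] <- "user"
    }
  }
  .steps(merged$synapses$delay, dt, "synapses.delay")
  net <- ii_network(n = merged$network$n, J_total = merged$synapses$J_total,
                    epsilon = merged$network$epsilon,
                    mu = merged$drive$mu, sigma = merged$drive$sigma,
                    neuron = do.call(neuron_params, merged$neurons),
                    tau_s = merged$synapses$tau_s,
                    delay = merged$synapses$delay,
                    seed = merged$network$seed)
  ctrl <- NULL
  mc <- merged$controller
  if (mc$mode != "none") {
    if (!mc$mode %in% c("direct", "differential", "enhance")) {
      abort(sprintf("unknown controller mode '%s'", mc$mode))
    }
    for (k in c("d_c_ms", "d_c1_ms", "d_c2_ms", "kernel_width_ms",
                "onset_ms")) {
      .steps(mc[[k]], dt, paste0("controller.", k))
    }
    ctrl <- controller_spec(mc$mode, K = mc$K_mV, d_c = mc$d_c_ms,
                            d_c1 = mc$d_c1_ms, d_c2 = mc$d_c2_ms,
                            kernel = control_kernel("box", 0,
                                                    mc$kernel_width_ms),
                            update = mc$update_ms, onset = mc$onset_ms)
  }
  list(network = net, controller = ctrl,
       values = purrr::imap_dfr(merged, function(s, sec) {
         tibble(section = sec, key = names(s),
                value = as.character(unlist(s)),
                source = unname(src[[sec]][names(s)]))
       }))
}

#' Write a configuration file
#'
#' Serialises the standard inhibitory network plus optional controller in
#' the format of [read_config()]; `read_config(write_config(...))`
#' round-trips the specification.
#'
#' @param network A [network_spec()] with a single population.
#' @param controller A [controller_spec()] or `NULL`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(network, controller = NULL, path) {
  stopifnot(inherits(network, "network_spec"),
            length(network$populations) == 1)
  p <- network$populations[[1]]
  syn <- network$projections[[1]]$synapse
  lines <- c(
    "[network]",
    sprintf("n = %d", p$n),
    sprintf("epsilon = %g", network$epsilon),
    sprintf("seed = %d", network$seed),
    "[neurons]",
    sprintf("tau_m = %g", p$neuron$tau_m),
    sprintf("v_rest = %g", p$neuron$v_rest),
    sprintf("v_theta = %g", p$neuron$v_theta),
    sprintf("v_reset = %g", p$neuron$v_reset),
    sprintf("t_ref = %g", p$neuron$t_ref),
    "[synapses]",
    sprintf("J_total = %g", syn$J_total),
    sprintf("tau_s = %g", syn$tau_s),
    sprintf("delay = %g", syn$delay),
    "[drive]",
    sprintf("mu = %g", p$drive$mu),
    sprintf("sigma = %g", p$drive$sigma))
  if (!is.null(controller)) {
    lines <- c(lines, "[controller]",
               sprintf("mode = %s", controller$mode),
               sprintf("K_mV = %g", controller$K),
               sprintf("d_c_ms = %g", controller$d_c %||% 6.5),
               sprintf("d_c1_ms = %g", controller$d_c1 %||% 6.5),
               sprintf("d_c2_ms = %g", controller$d_c2 %||% 1),
               sprintf("kernel_width_ms = %g", controller$kernel$b),
               sprintf("update_ms = %g", controller$update),
               sprintf("onset_ms = %g", controller$onset))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- experiment presets --------------------------------------------------

# Gains for the controlled presets come from the analytic stability
# landscape of the standard network (J = 200 mV, box kernel b = 1 ms,
# d_c = 6.5 ms): the direct/differential optima over K at the main domain.
.preset_K_direct <- 459
.preset_K_differential <- 348

#' Available experiment presets
#'
#' Each preset binds a network, controller and analysis protocol that runs
#' end-to-end from the specification alone (no external data):
#'
#' * `ii_ai`: inhibitory network at healthy subcritical coupling
#'   (J = 50 mV, about 45 percent of critical), rate-compensated.
#' * `ii_si`: supercritical inhibitory network (J = 200 mV), oscillatory.
#' * `ii_dfc`: the `ii_si` network under direct DFC (K from the analytic
#'   optimum, d_c = 6.5 ms, onset 200 ms).
#' * `ii_dfc_differential`: differential DFC (d_c1 = 6.5, d_c2 = 1 ms).
#' * `ii_noise_matched`: open-loop common Gaussian input with moments
#'   matched to the `ii_dfc` control signal.
#' * `ii_noise_strong`: strong independent noise (sigma = 14 mV),
#'   rate-matched.
#' * `ei_si`, `ei_dfc`: two-population E-I loop (record I, stimulate E),
#'   oscillating in the beta band, without and with direct DFC (onset
#'   250 ms).
#' * `ei_enhance`: subcritical E-I network driven into oscillation by
#'   enhancing feedback (onset 250 ms).
#' * `ii_recovery_*` (`ai`, `dfc`, `noise`): the N = 1000 stimulus-
#'   processing conditions used for pulse-packet AUC and SPIKE-distance
#'   analyses.
#' * `ii_adaptive`: adaptive gain tuning on a reduced network.
#'
#' @return Character vector of preset names.
#' @export
preset_names <- function() {
  c("ii_ai", "ii_si", "ii_dfc", "ii_dfc_differential",
    "ii_noise_matched", "ii_noise_strong", "ei_si", "ei_dfc",
    "ei_enhance", "ii_recovery_ai", "ii_recovery_dfc",
    "ii_recovery_noise", "ii_adaptive")
}

# solve the drive mean giving the target rate at a prescribed sigma
.mu_for_rate <- function(rate, sigma, neuron) {
  uniroot(function(m) stationary_rate(m, sigma, neuron) - rate,
          lower = neuron$v_reset - 20 * sigma,
          upper = neuron$v_theta + 20 * sigma, tol = 1e-9)$root
}

#' Build the network, controller and stimuli of a preset
#'
#' @param name A preset name from [preset_names()].
#' @param n Size of the (first) population; E-I presets use `0.8 n`
#'   excitatory and `0.2 n` inhibitory neurons. Recovery presets are fixed
#'   at N = 1000 by protocol.
#' @param duration Simulated time (ms).
#' @param seed Integer seed.
#' @return List with `network` (already rate-compensated), `controller`,
#'   `stimuli`, `duration`, `analysis_start` (ms) and bookkeeping fields.
#' @export
build_preset <- function(name, n = 10000, duration = 4000, seed = 1L) {
  name <- match.arg(name, preset_names())
  np <- neuron_params()
  r0 <- stationary_rate(14, 6, np)
  out <- list(name = name, duration = duration, stimuli = list(),
              controller = NULL, analysis_start = 200, seed = seed)
  comp <- function(net, ctrl = NULL, ...) {
    rate_compensate(net, ctrl, ...)$network
  }
  if (name %in% c("ii_ai", "ii_si", "ii_dfc", "ii_dfc_differential",
                  "ii_noise_matched", "ii_noise_strong")) {
    J <- if (name == "ii_ai") 50 else 200
    net <- ii_network(n = n, J_total = J, seed = seed)
    if (name == "ii_dfc") {
      out$controller <- controller_spec("direct", K = .preset_K_direct,
                                        d_c = 6.5, onset = 200)
    } else if (name == "ii_dfc_differential") {
      out$controller <- controller_spec("differential",
                                        K = .preset_K_differential,
                                        d_c1 = 6.5, d_c2 = 1, onset = 200)
    } else if (name == "ii_noise_matched") {
      # reference DFC run provides the moment-matched common noise trace
      ref <- build_preset("ii_dfc", n = n, duration = duration,
                          seed = seed)
      sim <- simulate_network(ref$network, ref$controller,
                              duration = duration, seed = seed)
      tr <- matched_noise_signal(sim$control, seed = seed + 1)
      out$controller <- controller_spec("noise", onset = 200,
                                        trace = tr$I_C)
    } else if (name == "ii_noise_strong") {
      mu14 <- .mu_for_rate(r0, 14, np)
      net <- ii_network(n = n, J_total = 200, mu = mu14, sigma = 14,
                        seed = seed)
    }
    out$network <- comp(net, out$controller)
    out$analysis_start <- if (is.null(out$controller)) 200 else 500
  } else if (name %in% c("ei_si", "ei_dfc", "ei_enhance")) {
    n_e <- round(0.8 * n)
    n_i <- n - n_e
    J <- if (name == "ei_enhance") 50 else 100
    net <- ei_network(n_e = n_e, n_i = n_i, J_EI = J, J_IE = J,
                      seed = seed)
    if (name == "ei_dfc") {
      out$controller <- controller_spec("direct", K = 250, d_c = 6.5,
                                        record = "I", stimulate = "E",
                                        onset = 250)
    } else if (name == "ei_enhance") {
      out$controller <- controller_spec("enhance", K = 150, d_c = 5,
                                        record = "I", stimulate = "E",
                                        onset = 250)
    }
    out$network <- rate_compensate(net, out$controller, iterate = 2,
                                   duration = 1000)$network
    out$analysis_start <- if (is.null(out$controller)) 250 else 500
  } else if (name %in% c("ii_recovery_ai", "ii_recovery_dfc",
                         "ii_recovery_noise")) {
    n <- 1000  # protocol size
    duration <- max(duration, 2400)
    out$duration <- duration
    targets <- 1:100
    J <- if (name == "ii_recovery_ai") 50 else 200
    if (name == "ii_recovery_dfc") {
      out$controller <- controller_spec("direct", K = .preset_K_direct,
                                        d_c = 6.5, onset = 0)
    }
    if (name == "ii_recovery_noise") {
      mu14 <- .mu_for_rate(r0, 14, np)
      net <- ii_network(n = n, J_total = J, mu = mu14, sigma = 14,
                        seed = seed)
    } else {
      net <- ii_network(n = n, J_total = J, seed = seed)
    }
    out$network <- comp(net, out$controller)
    out$stimuli <- list(
      packets = generate_pulse_packets(centers = 200 * (1:10) + 200,
                                       targets = targets, seed = seed + 2),
      common = NULL)
    out$targets <- targets
    out$analysis_start <- 200
  } else if (name == "ii_adaptive") {
    out$network <- comp(ii_network(n = n, J_total = 200, seed = seed))
    out$controller <- controller_spec("direct", K = 0, d_c = 6.5,
                                      onset = 0)
  }
  out
}

#' Run an experiment preset end to end
#'
#' Builds the preset, simulates it, computes the standard metric report
#' and writes all outputs (spikes, population rate, control trace, metrics
#' and a run manifest) as plain text / JSON into `out_dir`.
#'
#' @param name Preset name, see [preset_names()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed overriding the preset default.
#' @param n,duration Network size and simulated time (ms).
#' @return The manifest (list), invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_preset <- function(name, out_dir, seed = 1L, n = 10000,
                       duration = 4000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  pre <- build_preset(name, n = n, duration = duration, seed = seed)
  stimuli <- purrr::compact(pre$stimuli)
  sim <- simulate_network(pre$network, pre$controller,
                          duration = pre$duration, stimuli = stimuli,
                          seed = seed)
  rate <- population_rate(sim, bin = 1)
  span <- pre$duration - pre$analysis_start
  metrics <- metric_report(sim, window = min(100, floor(span / 12)),
                           t_range = c(pre$analysis_start, pre$duration))
  write_spikes(sim$spikes, file.path(out_dir, "spikes.txt"))
  utils::write.table(rate, file.path(out_dir, "rate.txt"),
                     row.names = FALSE, quote = FALSE)
  if (nrow(sim$control)) {
    utils::write.table(sim$control, file.path(out_dir, "control.txt"),
                       row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(as.list(metrics),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    preset = name, seed = seed, n = n, duration = pre$duration,
    package_version = as.character(utils::packageVersion("dfcnet")),
    outputs = c("spikes.txt", "rate.txt", "metrics.json"),
    wall_clock_s = as.numeric(difftime(Sys.time(), t_start,
                                       units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
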