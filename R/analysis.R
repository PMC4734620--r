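#' Fano factor of spike counts
#'
#' Variance-to-mean ratio of per-neuron spike counts in non-overlapping
#' windows, averaged over neurons. A homogeneous Poisson process has
#' `FF = 1`; a perfectly regular train approaches 0.
#'
#' @param spikes A [as_spike_data()] tibble (or a `dfc_sim`).
#' @param window Counting-window length (ms).
#' @param t_range Optional `c(start, end)` (ms) restricting the analysis,
#'   e.g. to the post-onset segment of a controlled run.
#' @return Mean Fano factor across neurons with at least one spike.
#' @examples
#' s <- as_spike_data(data.frame(time = sort(runif(2000, 0, 2000)),
#'                               neuron = sample(20, 2000, TRUE)),
#'                    n_neurons = 20, duration = 2000)
#' fano_factor(s, window = 100)  # ~1 for Poisson trains
#' @export
fano_factor <- function(spikes, window = 100, t_range = NULL) {
  if (inherits(spikes, "dfc_sim")) spikes <- spikes$spikes
  stopifnot(inherits(spikes, "spike_data"), window > 0)
  lim <- t_range %||% c(0, attr(spikes, "duration"))
  n_win <- floor((lim[2] - lim[1]) / window)
  if (n_win < 10) {
    abort("fewer than 10 counting windows; extend the recording or shrink `window`")
  }
  sp <- spikes[spikes$time > lim[1] & spikes$time <= lim[1] + n_win * window, ]
  n <- attr(spikes, "n_neurons")
  if (!nrow(sp)) abort("no spikes in the analysis range")
  win <- floor((sp$time - lim[1] - 1e-9) / window)
  counts <- table(factor(sp$neuron, levels = seq_len(n)),
                  factor(win, levels = 0:(n_win - 1)))
  counts <- matrix(as.numeric(counts), nrow = n)
  active <- rowSums(counts) > 0
  if (any(!active)) {
    warn(sprintf("%d silent neuron(s) excluded from the Fano factor",
                 sum(!active)))
  }
  m <- rowMeans(counts[active, , drop = FALSE])
  v <- apply(counts[active, , drop = FALSE], 1, var)
  mean(v / m)
}

#' Coefficient of variation of interspike intervals
#'
#' Per-neuron standard deviation over mean of the interspike intervals,
#' averaged over neurons with at least two intervals. `CV = 1` for Poisson
#' firing, 0 for a clock-like train.
#'
#' @inheritParams fano_factor
#' @return Mean ISI CV across eligible neurons.
#' @export
cv_isi <- function(spikes, t_range = NULL) {
  if (inherits(spikes, "dfc_sim")) spikes <- spikes$spikes
  stopifnot(inherits(spikes, "spike_data"))
  sp <- spikes
  if (!is.null(t_range)) {
    sp <- sp[sp$time >= t_range[1] & sp$time <= t_range[2], ]
  }
  if (!nrow(sp)) abort("no spikes in the analysis range")
  cvs <- sp |>
    dplyr::arrange(.data$neuron, .data$time) |>
    dplyr::group_by(.data$neuron) |>
    dplyr::summarise(n_isi = dplyr::n() - 1,
                     cv = sd(diff(.data$time)) / mean(diff(.data$time)),
                     .groups = "drop") |>
    dplyr::filter(.data$n_isi >= 2)
  if (!nrow(cvs)) {
    warn("no neuron has two or more interspike intervals")
    return(NA_real_)
  }
  mean(cvs$cv)
}

#' Oscillation index of the population activity
#'
#' Discrete power spectral density of the mean-removed population
#' spike-count series (1 ms bins by convention), `P(omega_k) =
#' |X_k|^2 / L^2`, summed over positive frequencies up to the band edge;
#' the returned descriptor is `log10 P_T`. With this normalisation `P_T`
#' equals the in-band share of the count variance, so it is invariant to
#' the series mean and to the recording duration.
#'
#' The default band edge is 125 Hz (`250 pi` rad/s); `band = "literal"`
#' instead uses `250 / pi` rad/s (about 12.7 Hz), the alternative reading
#' of the band specification. The index rises by orders of magnitude when
#' the population rate oscillates: about 1.5 for an asynchronous network
#' at `N = 10^4` and typical rates, about 3 in the synchronous-irregular
#' state.
#'
#' @param rate A tibble from [population_rate()] (its `count` column is
#'   used) or a plain numeric count series.
#' @param band `"beta"` (default, 125 Hz edge), `"literal"` (250/pi rad/s
#'   edge) or a numeric band edge in Hz.
#' @param bin Bin width of the series (ms); taken from `rate$time` when
#'   available.
#' @return `log10 P_T`.
#' @examples
#' x <- rpois(4000, 150)
#' oscillation_index(x, bin = 1)  # ~log10(0.25 * var(x))
#' @export
oscillation_index <- function(rate, band = "beta", bin = 1) {
  if (is.data.frame(rate)) {
    stopifnot("count" %in% names(rate))
    if ("time" %in% names(rate) && nrow(rate) >= 2) {
      bin <- rate$time[2] - rate$time[1]
    }
    x <- rate$count
  } else {
    x <- as.numeric(rate)
  }
  f_edge <- if (identical(band, "beta")) {
    125
  } else if (identical(band, "literal")) {
    (250 / pi) / (2 * pi)
  } else {
    stopifnot(is.numeric(band), band > 0)
    band
  }
  l <- length(x)
  f_res <- 1000 / (l * bin)  # Hz
  if (l < 8 || f_edge < 2 * f_res) {
    abort("count series too short for the requested band resolution")
  }
  x <- x - mean(x)
  p <- Mod(fft(x))^2 / l^2
  f <- (seq_len(l) - 1) * f_res
  pt <- sum(p[f > 0 & f <= f_edge])
  log10(pt)
}

#' Gaussian pulse-packet stimulus
#'
#' A pulse packet is a volley of `n_pp` input spikes jittered around a
#' centre time with standard deviation `sigma_pp`; each packet is
#' delivered in full, through an alpha-function synapse, to every target
#' neuron (common feed-forward input).
#'
#' @param centers Packet centre times `t_c` (ms); the standard probe
#'   protocol uses `200 * (1:10) + 200`.
#' @param targets Neuron ids (1-based) receiving the packets.
#' @param n_pp Spikes per packet.
#' @param sigma_pp Temporal jitter standard deviation (ms).
#' @param weight Synaptic weight per input spike (mV).
#' @param tau_s Synaptic time constant of the input (ms).
#' @param seed Integer seed.
#' @return A stimulus descriptor (list with `times`, `targets`, `weight`,
#'   `tau_s` and a `packets` tibble), usable in
#'   `simulate_network(stimuli = list(...))`.
#' @examples
#' st <- generate_pulse_packets(centers = c(100, 300), targets = 1:10,
#'                              seed = 1)
#' nrow(st$packets)
#' @export
generate_pulse_packets <- function(centers = 200 * (1:10) + 200,
                                   targets, n_pp = 100, sigma_pp = 10,
                                   weight = 1, tau_s = 1, seed = 1L) {
  stopifnot(n_pp > 0, sigma_pp >= 0, length(targets) >= 1)
  times <- local({
    set.seed(seed)
    unlist(lapply(centers, function(tc) tc + rnorm(n_pp, 0, sigma_pp)))
  })
  if (any(times < 0)) abort("a packet spike fell before time 0")
  list(times = times, targets = as.integer(targets), weight = weight,
       tau_s = tau_s,
       packets = tibble(t_c = centers, n_pp = n_pp, sigma_pp = sigma_pp))
}

#' Common-input spike train stimulus
#'
#' `n_st` equally spaced spikes spanning a window of `t_st` ms, replayed
#' identically (bit-identical times) to every target neuron at each onset.
#' Used to probe temporal (synchrony-based) processing.
#'
#' @param onsets Window onset times (ms); standard protocol
#'   `200 * (1:10) + 200`.
#' @param targets Neuron ids (1-based).
#' @param n_st Number of spikes per window.
#' @param t_st Window length (ms); spacing is `t_st / n_st`.
#' @param weight,tau_s Synaptic weight (mV) and time constant (ms).
#' @return A stimulus descriptor as in [generate_pulse_packets()].
#' @export
generate_common_input <- function(onsets = 200 * (1:10) + 200, targets,
                                  n_st = 500, t_st = 50, weight = 0.3,
                                  tau_s = 1) {
  stopifnot(n_st >= 1, t_st > 0)
  spacing <- t_st / n_st
  times <- unlist(lapply(onsets, function(t0) {
    t0 + spacing * (0:(n_st - 1))
  }))
  list(times = times, targets = as.integer(targets), weight = weight,
       tau_s = tau_s,
       windows = tibble(onset = onsets, n_st = n_st, t_st = t_st))
}

#' ROC area under the curve for packet detection
#'
#' Compares the population response sampled at `t_k + response_lag` with
#' baseline activity sampled at `t_k + baseline_lag` across packets, by
#' the area under the ROC curve: 0.5 means the response is
#' indistinguishable from baseline, 1 means full separability.
#'
#' @param rate A tibble from [population_rate()].
#' @param packet_times Packet centre times `t_k` (ms).
#' @param response_lag,baseline_lag Sampling offsets (ms).
#' @return AUC in `[0, 1]`.
#' @export
packet_response_auc <- function(rate, packet_times, response_lag = 10,
                                baseline_lag = 100) {
  stopifnot(length(packet_times) >= 2,
            all(c("time", "rate") %in% names(rate)))
  sample_at <- function(ts) {
    idx <- vapply(ts, function(t) which.min(abs(rate$time - t)),
                  integer(1))
    rate$rate[idx]
  }
  resp <- sample_at(packet_times + response_lag)
  base <- sample_at(packet_times + baseline_lag)
  roc_auc(resp, base)
}

#' Area under the ROC curve of two samples
#'
#' Threshold-free ROC analysis: thresholds are taken at all midpoints
#' between the pooled sorted samples and the resulting curve is integrated
#' by the trapezoidal rule (equivalent to the Mann-Whitney statistic, with
#' ties counted half).
#'
#' @param positive,negative Numeric samples of the two conditions.
#' @return AUC in `[0, 1]`; 0.5 when the distributions coincide.
#' @examples
#' roc_auc(c(5, 6, 7), c(1, 2, 3))  # disjoint supports: 1
#' @export
roc_auc <- function(positive, negative) {
  stopifnot(length(positive) >= 2, length(negative) >= 2)
  pooled <- sort(unique(c(positive, negative)))
  thr <- c(-Inf, (head(pooled, -1) + tail(pooled, -1)) / 2, Inf)
  tpr <- vapply(thr, function(h) mean(positive > h), numeric(1))
  fpr <- vapply(thr, function(h) mean(negative > h), numeric(1))
  ord <- order(fpr, tpr)
  sum(diff(fpr[ord]) * (head(tpr[ord], -1) + tail(tpr[ord], -1)) / 2)
}

# ---- SPIKE-distance ------------------------------------------------------

# augment a train with auxiliary edge spikes and clip to the interval
.aug_train <- function(t, interval) {
  t <- sort(t[t >= interval[1] & t <= interval[2]])
  unique(c(interval[1], t, interval[2]))
}

# pairwise SPIKE-dissimilarity profile of two augmented trains at times
# `at` (interior points of inter-spike segments)
.spike_profile_pair <- function(u, v, at) {
  near_dist <- function(x, w) {
    i <- findInterval(x, w)
    lo <- w[pmax(i, 1)]
    hi <- w[pmin(i + 1, length(w))]
    pmin(abs(x - lo), abs(hi - x))
  }
  term <- function(a, b) {
    i <- pmin(pmax(findInterval(at, a), 1), length(a) - 1)
    tp <- a[i]
    tf <- a[i + 1]
    xisi <- tf - tp
    xp <- at - tp
    xf <- tf - at
    dp <- near_dist(tp, b)
    df <- near_dist(tf, b)
    list(s = (dp * xf + df * xp) / xisi, xisi = xisi)
  }
  tu <- term(u, v)
  tv <- term(v, u)
  xm <- (tu$xisi + tv$xisi) / 2
  (tu$s * tv$xisi + tv$s * tu$xisi) / (2 * xm^2)
}

#' Time-resolved multivariate SPIKE-distance
#'
#' Parameter-free dissimilarity of a set of spike trains, averaged over
#' all train pairs and over the evaluation interval. For each pair and
#' time point the dissimilarity weighs the distances of the bracketing
#' spikes of one train to the nearest spikes of the other by the local
#' interspike intervals, normalised to lie in `[0, 1]`; 0 if and only if
#' all trains are identical. The profile is piecewise linear between
#' spikes, so its exact time average is obtained from two interior
#' evaluations per segment.
#'
#' The profile is defined on the full recording (`context`): spikes
#' outside the averaging `interval` still serve as bracketing and
#' nearest-neighbour spikes, so short windows can be averaged without
#' edge artefacts - the natural reading of windowed averages
#' `D = 1/T Int S(t) dt` of one global profile. Each train is augmented
#' with auxiliary spikes at the context edges (edge-correction
#' convention; empty trains then contribute their maximal dissimilarity
#' rather than failing).
#'
#' @param spikes A [as_spike_data()] tibble, or a list of numeric spike
#'   time vectors.
#' @param interval `c(start, end)` (ms) over which the profile is
#'   averaged.
#' @param ids Optional neuron ids (1-based) to restrict to; with spike
#'   data input, trains are built for exactly these ids (empty trains
#'   included).
#' @param context `c(start, end)` (ms) of the recording on which the
#'   profile is defined; defaults to the full recording (for spike-data
#'   input) or to `interval` (for plain train lists).
#' @return The time-averaged multivariate SPIKE-distance in `[0, 1]`.
#' @examples
#' tr <- list(c(10, 20, 30), c(10, 20, 30))
#' spike_distance(tr, interval = c(0, 40))  # identical trains: 0
#' @export
spike_distance <- function(spikes, interval, ids = NULL, context = NULL) {
  stopifnot(length(interval) == 2, interval[2] > interval[1])
  if (is.list(spikes) && !is.data.frame(spikes)) {
    trains <- lapply(spikes, as.numeric)
    context <- context %||% interval
  } else {
    stopifnot(inherits(spikes, "spike_data"))
    ids <- ids %||% seq_len(attr(spikes, "n_neurons"))
    sp <- spikes[spikes$neuron %in% ids, ]
    trains <- lapply(ids, function(i) sp$time[sp$neuron == i])
    context <- context %||% c(0, attr(spikes, "duration"))
  }
  stopifnot(context[1] <= interval[1], context[2] >= interval[2])
  if (length(trains) < 2) abort("need at least two spike trains")
  aug <- lapply(trains, .aug_train, interval = context)
  # segment grid inside the averaging interval; two interior points per
  # segment integrate the piecewise-linear profile exactly
  grid <- sort(unique(c(interval,
                        unlist(lapply(aug, function(u) {
                          u[u > interval[1] & u < interval[2]]
                        })))))
  len <- diff(grid)
  keep <- len > 1e-12
  a <- grid[-length(grid)][keep]
  l <- len[keep]
  at <- c(a + l / 4, a + 3 * l / 4)
  w <- rep(l / 2, 2)  # each interior point represents half its segment
  n <- length(aug)
  acc <- numeric(length(at))
  n_pair <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      acc <- acc + .spike_profile_pair(aug[[i]], aug[[j]], at)
      n_pair <- n_pair + 1L
    }
  }
  sum(acc / n_pair * w) / sum(w)
}

#' SPIKE-distance in stimulation and baseline windows
#'
#' Convenience wrapper computing the time-averaged multivariate
#' SPIKE-distance in a window after each stimulus onset (`D_ST`) and in a
#' baseline window displaced by `baseline_offset` (`D_BL`).
#'
#' @param spikes A [as_spike_data()] tibble.
#' @param onsets Stimulus onset times (ms).
#' @param window Window length (ms).
#' @param baseline_offset Offset of the baseline window (ms).
#' @param ids Optional neuron ids over which to evaluate.
#' @return Tibble with `onset`, `D_ST`, `D_BL`.
#' @export
spike_distance_windows <- function(spikes, onsets, window = 50,
                                   baseline_offset = 100, ids = NULL) {
  stopifnot(inherits(spikes, "spike_data"))
  ids <- ids %||% seq_len(attr(spikes, "n_neurons"))
  sp <- spikes[spikes$neuron %in% ids, ]
  trains <- lapply(ids, function(i) sp$time[sp$neuron == i])
  context <- c(0, attr(spikes, "duration"))
  ivs <- rbind(cbind(onsets, onsets + window),
               cbind(onsets + baseline_offset,
                     onsets + baseline_offset + window))
  stopifnot(max(ivs) <= context[2])
  aug <- lapply(trains, .aug_train, interval = context)
  # shared evaluation grid: two interior points per inter-spike segment of
  # the merged trains, per interval (exact for the piecewise-linear
  # profile)
  pts <- apply(ivs, 1, function(iv) {
    grid <- sort(unique(c(iv, unlist(lapply(aug, function(u) {
      u[u > iv[1] & u < iv[2]]
    })))))
    len <- diff(grid)
    keep <- len > 1e-12
    a <- grid[-length(grid)][keep]
    l <- len[keep]
    list(at = c(a + l / 4, a + 3 * l / 4), w = rep(l / 2, 2))
  })
  at_all <- unlist(lapply(pts, `[[`, "at"))
  w_all <- unlist(lapply(pts, `[[`, "w"))
  iv_of <- rep(seq_len(nrow(ivs)), vapply(pts, function(p) length(p$at),
                                          integer(1)))
  n <- length(aug)
  acc <- numeric(length(at_all))
  n_pair <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      acc <- acc + .spike_profile_pair(aug[[i]], aug[[j]], at_all)
      n_pair <- n_pair + 1L
    }
  }
  prof <- acc / n_pair
  d_iv <- vapply(seq_len(nrow(ivs)), function(k) {
    sel <- iv_of == k
    sum(prof[sel] * w_all[sel]) / sum(w_all[sel])
  }, numeric(1))
  m <- length(onsets)
  tibble(onset = onsets, D_ST = d_iv[seq_len(m)],
         D_BL = d_iv[m + seq_len(m)])
}

#' Summary metric report for a simulation
#'
#' Computes the standard descriptor set (Fano factor, ISI CV, oscillation
#' index and peak frequency of the population-rate spectrum) for one
#' simulation, optionally restricted to a time range.
#'
#' @param sim A `dfc_sim`.
#' @param window Fano-factor counting window (ms).
#' @param t_range Optional analysis range (ms).
#' @param pop Optional population restriction.
#' @return One-row tibble with `FF`, `CV`, `log10_PT`, `peak_Hz` and the
#'   mean rate.
#' @export
metric_report <- function(sim, window = 100, t_range = NULL, pop = NULL) {
  stopifnot(inherits(sim, "dfc_sim"))
  spikes <- sim$spikes
  if (!is.null(pop)) spikes <- spikes[spikes$pop == pop, ]
  lim <- t_range %||% c(0, attr(sim$spikes, "duration"))
  rate <- population_rate(sim$spikes, bin = 1, pop = pop)
  rate <- rate[rate$time > lim[1] & rate$time <= lim[2], ]
  x <- rate$count - mean(rate$count)
  p <- Mod(fft(x))^2 / length(x)^2
  f <- (seq_along(x) - 1) * 1000 / (length(x) * 1)
  inb <- f > 0 & f <= 125
  tibble(FF = fano_factor(spikes, window = window, t_range = lim),
         CV = cv_isi(spikes, t_range = lim),
         log10_PT = oscillation_index(rate),
         peak_Hz = f[inb][which.max(p[inb])],
         rate = sum(rate$count) /
           (attr(sim$spikes, "n_neurons") * (lim[2] - lim[1]) / 1000))
}
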