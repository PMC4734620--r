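# broom-style accessors for fitted/derived objects

#' Tidy the roots of an eigenvalue spectrum
#'
#' @param x A `dfc_spectrum`.
#' @param ... Unused.
#' @return Tibble with `re`, `im`, `residual`, `frequency_hz` and
#'   `stable`.
#' @export
tidy.dfc_spectrum <- function(x, ...) {
  dplyr::mutate(x$roots, frequency_hz = .data$im / (2 * pi),
                stable = .data$re < 0)
}

#' One-row summary of an eigenvalue spectrum
#'
#' @param x A `dfc_spectrum`.
#' @param ... Unused.
#' @return Tibble with root counts, the rightmost real part (the stability
#'   margin `B_cr`) and the frequency of the rightmost pair.
#' @export
glance.dfc_spectrum <- function(x, ...) {
  i <- which.max(x$roots$re)
  tibble(n_roots = nrow(x$roots),
         n_unstable = sum(x$roots$re > 0),
         rightmost = x$rightmost,
         b_cr = x$rightmost,
         frequency_hz = abs(x$roots$im[i]) / (2 * pi),
         max_residual = max(x$roots$residual))
}

#' Tidy a stability landscape
#'
#' @param x A `dfc_landscape`.
#' @param ... Unused.
#' @return The landscape as a plain tibble with a `stable` flag.
#' @export
tidy.dfc_landscape <- function(x, ...) {
  out <- as_tibble(x)
  out$stable <- out$re_max < 0
  out
}

#' One-row summary of a stability landscape
#'
#' @param x A `dfc_landscape`.
#' @param ... Unused.
#' @return Tibble with the number of stable cells, the principal domain
#'   location (effective delay, ms) and the deepest margin.
#' @export
glance.dfc_landscape <- function(x, ...) {
  dom <- landscape_domains(x)
  tibble(n_cells = nrow(x),
         n_stable = sum(x$re_max < 0, na.rm = TRUE),
         n_domains = nrow(dom),
         principal_d_eff = if (nrow(dom)) dom$d_eff_mid[1] else NA_real_,
         deepest_re_max = if (nrow(dom)) min(dom$re_max_min) else NA_real_)
}

#' One-row summary of a simulation
#'
#' @param x A `dfc_sim`.
#' @param ... Passed to [metric_report()].
#' @return The metric report with per-population rates appended.
#' @export
glance.dfc_sim <- function(x, ...) {
  m <- metric_report(x, ...)
  rates <- x$diagnostics$rates
  for (nm in names(rates)) m[[paste0("rate_", nm)]] <- rates[[nm]]
  m
}

#' @export
generics::tidy

#' @export
generics::glance
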