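# Independent oracle implementations used to cross-check the package: each
# is written directly from the defining formula, sharing no code with the
# implementation under test.

# numerical Laplace transform of a kernel by adaptive quadrature
laplace_transform <- function(kernel_fun, lambda, upper = Inf) {
  re <- integrate(function(t) kernel_fun(t) * exp(-Re(lambda) * t) *
                    cos(Im(lambda) * t), 0, upper, rel.tol = 1e-12,
                  abs.tol = 1e-14)$value
  im <- integrate(function(t) kernel_fun(t) * exp(-Re(lambda) * t) *
                    sin(Im(lambda) * t), 0, upper, rel.tol = 1e-12,
                  abs.tol = 1e-14)$value
  complex(real = re, imaginary = -im)
}

# Mann-Whitney AUC by exhaustive pair counting (ties count half)
auc_pair_count <- function(positive, negative) {
  s <- 0
  for (p in positive) {
    for (q in negative) {
      s <- s + (p > q) + 0.5 * (p == q)
    }
  }
  s / (length(positive) * length(negative))
}

# pointwise bivariate SPIKE-dissimilarity profile, straight from the
# published definition (scalar, naive; trains must already contain the
# auxiliary edge spikes)
spike_profile_naive <- function(u, v, t) {
  side <- function(a, b) {
    i <- max(which(a <= t))
    i <- min(i, length(a) - 1)
    tp <- a[i]
    tf <- a[i + 1]
    dp <- min(abs(tp - b))
    df <- min(abs(tf - b))
    xp <- t - tp
    xf <- tf - t
    list(s = (dp * xf + df * xp) / (tf - tp), isi = tf - tp)
  }
  su <- side(u, v)
  sv <- side(v, u)
  (su$s * sv$isi + sv$s * su$isi) / (2 * ((su$isi + sv$isi) / 2)^2)
}

# deterministic LIF firing rate (suprathreshold, noiseless), sp/s
lif_deterministic_rate <- function(mu, neuron) {
  mu_eff <- neuron$v_rest + mu
  1000 / (neuron$t_ref +
            neuron$tau_m * log((mu_eff - neuron$v_reset) /
                               (mu_eff - neuron$v_theta)))
}
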