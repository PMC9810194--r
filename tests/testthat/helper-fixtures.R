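# Small builders shared across test files.

tiny_rate_layer <- function(n = 10, kind = "nofeedback_esn", m_in = 1,
                            m_out = 1, gain = 1.2, tau = 10, dt = 1,
                            seed = 1, ...) {
  init_rate_network(n, kind, m_in = m_in, m_out = m_out, gain = gain,
                    tau = tau, dt = dt, seed = seed, ...)
}

# sine-drive input series evaluated on a dt-grid (for step-size studies)
sine_input <- function(t_total, dt) {
  matrix(sin(2 * pi * 0.05 * seq(dt, t_total, by = dt)), ncol = 1)
}

# direct dense oracle for the RLS inverse-correlation matrix
p_oracle <- function(alpha, rate_rows) {
  solve(diag(alpha, ncol(rate_rows)) + crossprod(rate_rows))
}

rel_frob <- function(a, b) norm(a - b, "F") / norm(b, "F")

# drive a single neuron's voltage with constant current, return spike steps
constant_drive_spikes <- function(layer, I, n_steps) {
  p <- layer$params
  st <- layer$state
  spikes <- integer(0)
  for (t in seq_len(n_steps)) {
    u <- update_voltage(p, rep(I, p$n_neurons), st)
    st$v <- u$v
    st$aux <- u$aux
    st$step_index <- st$step_index + 1L
    if (p$constants$t_ref > 0 && any(u$spiked)) {
      st$refractory_until[u$spiked] <- st$step_index +
        p$constants$t_ref / p$dt
    }
    if (u$spiked[1]) spikes <- c(spikes, st$step_index)
  }
  spikes
}
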