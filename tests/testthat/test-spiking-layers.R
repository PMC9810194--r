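test_that("initial voltages respect model-specific ranges and seeds", {
  l <- init_spiking_network(200, "lif", seed = 1)
  expect_true(all(l$state$v >= -65 & l$state$v <= -40))

  lt <- init_spiking_network(200, "theta", seed = 1)
  expect_true(all(lt$state$v > -pi & lt$state$v < pi))

  v1 <- initialize_voltage(l$params, seed = 99)
  v2 <- initialize_voltage(l$params, seed = 99)
  expect_identical(v1, v2)

  expect_error(init_spiking_network(10, "lif", tau_r = 0.02, tau_d = 0.002),
               "tau_d")
  expect_error(init_spiking_network(10, "lif", dt = 0.01, tau_r = 0.002),
               "dt")
})

test_that("a resting LIF neuron with no drive stays at rest", {
  l <- init_spiking_network(3, "lif", constants = list(I_bias = 0), seed = 2)
  st <- l$state
  st$v <- rep(l$params$constants$v_rest, 3)
  u <- update_voltage(l$params, rep(0, 3), st)
  expect_identical(u$v, st$v)
  expect_false(any(u$spiked))
})

test_that("LIF interspike interval matches the log-ratio closed form", {
  tau_m <- 0.01
  l <- init_spiking_network(1, "lif", dt = tau_m / 1e4, gain = 0,
                            feedback_scale = 0,
                            constants = list(t_ref = 0, I_bias = 0), seed = 1)
  cst <- l$params$constants
  l$state$v <- cst$v_reset
  RI <- 35
  spikes <- constant_drive_spikes(l, RI, 40000)
  isi <- mean(diff(spikes)) * l$params$dt
  pred <- tau_m * log((RI - (cst$v_reset - cst$v_rest)) /
                        (RI - (cst$v_thresh - cst$v_rest)))
  expect_lt(abs(isi - pred) / pred, 0.01)
})

test_that("theta-neuron firing period matches pi/sqrt(I)", {
  l <- init_spiking_network(1, "theta", dt = 1e-5, gain = 0,
                            feedback_scale = 0,
                            constants = list(I_bias = 0), seed = 1)
  l$state$v <- -pi
  I <- 4
  spikes <- constant_drive_spikes(l, I, 500000)
  expect_gte(length(spikes), 3)
  period <- mean(diff(spikes)) * l$params$dt
  expect_lt(abs(period - pi / sqrt(I)) / (pi / sqrt(I)), 0.01)
})

test_that("synaptic filter reproduces its double-exponential impulse response", {
  l <- init_spiking_network(1, "lif", dt = 1e-5, tau_r = 0.002, tau_d = 0.02,
                            gain = 0, feedback_scale = 0,
                            constants = list(I_bias = 0), seed = 1)
  p <- l$params
  st <- l$state
  st$syn_h <- 1 / (p$tau_r * p$tau_d)  # one spike just injected
  n <- 5000
  tr <- numeric(n)
  for (t in seq_len(n)) {
    st$syn_r <- st$syn_r * p$filt$e_d + st$syn_h * p$filt$rh
    st$syn_h <- st$syn_h * p$filt$e_r
    tr[t] <- st$syn_r
  }
  tt <- seq_len(n) * p$dt
  closed <- (exp(-tt / p$tau_d) - exp(-tt / p$tau_r)) / (p$tau_d - p$tau_r)
  expect_lt(max(abs(tr - closed)) / max(closed), 0.01)

  # with no spikes the filter decays monotonically to zero
  l2 <- init_spiking_network(4, "lif", constants = list(I_bias = 0), seed = 3)
  st2 <- l2$state
  st2$syn_r <- c(1, 2, 3, 4)
  st2$v <- rep(-65, 4)
  n_dec <- 4000  # 0.2 s, ten decay constants
  trace <- matrix(NA_real_, n_dec, 4)
  for (t in seq_len(n_dec)) {
    st2 <- step_spiking(l2$params, st2)
    trace[t, ] <- st2$syn_r
  }
  expect_true(all(diff(trace) <= 1e-15))
  expect_true(all(trace >= 0))
  expect_lt(max(trace[n_dec, ]), 1e-3)
})

test_that("zero decoders give identically zero readout", {
  l <- init_spiking_network(50, "theta", m_out = 2, gain = 20, seed = 4)
  out <- run_spiking_network(l$params, l$state, n_steps = 4000,
                             record = c("z", "spikes"))
  expect_gt(nrow(out$spikes), 0)  # it does spike
  expect_true(all(out$z == 0))    # but phi = 0 silences the readout
})

test_that("no neuron spikes twice within the refractory period", {
  l <- init_spiking_network(60, "lif", gain = 30, sparsity = 0.5,
                            constants = list(t_ref = 0.002), seed = 5)
  out <- run_spiking_network(l$params, l$state, n_steps = 4000,
                             record = "spikes")
  expect_gt(nrow(out$spikes), 50)
  by_neuron <- split(out$spikes$time_s, out$spikes$neuron_index)
  min_isi <- min(vapply(by_neuron, function(s) {
    if (length(s) < 2) Inf else min(diff(s))
  }, numeric(1)))
  expect_gte(min_isi, 0.002 - 1e-12)
})

test_that("filtered rates stay bounded on long runs", {
  l <- init_spiking_network(20, "izhikevich", gain = 10, seed = 6)
  st <- l$state
  max_r <- 0
  for (t in 1:20000) {
    st <- step_spiking(l$params, st)
    max_r <- max(max_r, max(st$syn_r))
  }
  # each spike contributes at most the unit-area impulse peak; with the
  # refractory floor on the rate this bounds the filtered trace
  peak <- 1 / (l$params$tau_d - l$params$tau_r)
  rate_cap <- 1 / l$params$constants$t_ref
  expect_lt(max_r, rate_cap * 1 + peak)
  expect_true(all(is.finite(st$v)))
})

test_that("LIF firing rate is nondecreasing in the drive current", {
  rates <- vapply(c(26, 30, 40, 60, 100), function(I) {
    l <- init_spiking_network(1, "lif", dt = 1e-4, gain = 0,
                              feedback_scale = 0,
                              constants = list(I_bias = 0), seed = 1)
    l$state$v <- l$params$constants$v_reset
    length(constant_drive_spikes(l, I, 20000))
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[5], rates[1])
})
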