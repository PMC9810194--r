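default_neuron_constants <- function(model_kind) {
  switch(model_kind,
    lif = list(tau_m = 0.01, v_rest = -65, v_reset = -65, v_thresh = -40,
               R = 1, t_ref = 0.002, I_bias = 30),
    # theta model d(theta)/dt = (1 - cos theta) + (1 + cos theta) * I;
    # constant drive I > 0 fires with period pi / sqrt(I)
    # (bias 500 ~ 7 Hz tonic baseline)
    theta = list(t_ref = 0, I_bias = 500),
    izhikevich = list(a = 0.02, b = 0.2, c = -65, d = 8, v_peak = 30,
                      t_ref = 0.002, I_bias = 5),
    stop(sprintf("unknown spiking model kind '%s'", model_kind), call. = FALSE)
  )
}

#' Initialize a spiking chaotic network layer
#'
#' Builds a network of leaky integrate-and-fire (`"lif"`), Izhikevich
#' (`"izhikevich"`) or theta (`"theta"`) neurons with static random
#' recurrent weights `omega0`, random feedback encoders `eta`, learnable
#' decoders `phi` (initialized to zero), and a double-exponential synaptic
#' filter whose output `syn_r` is both the recurrent drive and the
#' regression feature vector for RLS decoding ([spiking_fit()]).
#'
#' Total current per step:
#' `I = G * omega0^T syn_r + Q * eta^T z(t - dt) + w_in^T f_in + I_bias`.
#'
#' Default constants place a few-hundred-neuron network in an asynchronous
#' spontaneous-spiking regime (LIF: tau_m = 10 ms, threshold -40, reset
#' -65, refractory 2 ms, bias 30; theta: bias 20; Izhikevich: regular
#' spiking a=0.02, b=0.2, c=-65, d=8 with dt interpreted in seconds and the
#' canonical per-millisecond equations).
#'
#' @param n_neurons Number of neurons N.
#' @param model_kind `"lif"`, `"izhikevich"` or `"theta"`.
#' @param m_in,m_out Input/output channel counts.
#' @param dt Time step in seconds; must be well below `tau_r`.
#' @param sparsity Recurrent connection probability.
#' @param gain Static recurrent gain G.
#' @param feedback_scale Feedback encoder gain Q.
#' @param tau_r,tau_d Synaptic rise and decay constants in seconds
#'   (`tau_d > tau_r > 0`).
#' @param constants Named list overriding the per-kind neuron constants.
#' @param input_scale Scale of the uniform input weights.
#' @param seed Integer seed (weights and initial voltages).
#' @return A `spiking_layer` object: `list(params, state)`.
#' @export
init_spiking_network <- function(n_neurons,
                                 model_kind = c("lif", "izhikevich", "theta"),
                                 m_in = 0L, m_out = 1L, dt = 5e-5,
                                 sparsity = 1, gain = 10, feedback_scale = 1,
                                 tau_r = 0.002, tau_d = 0.02,
                                 constants = list(), input_scale = 1,
                                 seed = NULL) {
  model_kind <- match.arg(model_kind)
  check_that(tau_d > tau_r && tau_r > 0,
             sprintf("need tau_d > tau_r > 0, got tau_d=%g tau_r=%g",
                     tau_d, tau_r))
  check_that(dt > 0 && dt < tau_r,
             sprintf("dt (%g) must be positive and below tau_r (%g)", dt, tau_r))
  check_that(sparsity > 0 && sparsity <= 1, "sparsity must be in (0, 1]")
  N <- as.integer(n_neurons)
  cst <- utils::modifyList(default_neuron_constants(model_kind), constants)

  params <- with_seed(seed, {
    sd_w <- 1 / sqrt(sparsity * N)
    omega0 <- matrix(stats::rnorm(N * N, sd = sd_w) *
                       (stats::runif(N * N) < sparsity), N, N)
    eta <- matrix(stats::runif(m_out * N, -1, 1), m_out, N)
    w_in <- if (m_in > 0) {
      matrix(stats::runif(m_in * N, -1, 1) * input_scale, m_in, N)
    } else {
      matrix(0, 0L, N)
    }
    list(model_kind = model_kind, n_neurons = N, m_in = as.integer(m_in),
         m_out = as.integer(m_out), dt = dt, sparsity = sparsity,
         gain = gain, feedback_scale = feedback_scale,
         tau_r = tau_r, tau_d = tau_d, constants = cst,
         omega0 = omega0, eta = eta, phi = matrix(0, N, m_out),
         w_in = w_in, seed = seed,
         # exact exponential-integration coefficients for the coupled
         # double-exponential filter (not Euler)
         filt = list(e_d = exp(-dt / tau_d), e_r = exp(-dt / tau_r),
                     rh = tau_r * tau_d / (tau_r - tau_d) *
                       (exp(-dt / tau_r) - exp(-dt / tau_d))))
  })

  v0 <- initialize_voltage(params, seed = if (is.null(seed)) NULL else seed + 1L)
  state <- spiking_state_zero(params, v0)
  structure(list(params = params, state = state),
            class = c("spiking_layer", "force_layer"))
}

spiking_state_zero <- function(params, v0) {
  N <- params$n_neurons
  aux <- if (params$model_kind == "izhikevich") params$constants$b * v0
         else numeric(N)
  list(v = v0, aux = aux, refractory_until = numeric(N),
       syn_r = numeric(N), syn_h = numeric(N),
       spiked = logical(N), z = numeric(params$m_out), step_index = 0L)
}

#' Seeded initial voltages for a spiking layer
#'
#' LIF and Izhikevich neurons start uniformly between reset and threshold;
#' theta neurons start with phases uniform in (-pi, pi).
#'
#' @param params Spiking layer parameter list.
#' @param seed Integer seed.
#' @return Length-N numeric vector.
#' @export
initialize_voltage <- function(params, seed = NULL) {
  N <- params$n_neurons
  cst <- params$constants
  with_seed(seed, switch(params$model_kind,
    lif = stats::runif(N, cst$v_reset, cst$v_thresh),
    izhikevich = stats::runif(N, cst$c, cst$v_peak),
    theta = stats::runif(N, -pi, pi)
  ))
}

#' One Euler step of the neuron voltage equations
#'
#' Advances the membrane equation of the layer's neuron model under total
#' current `I`, detects threshold crossings (theta: phase crossing pi),
#' applies the reset (LIF: to `v_reset`; theta: phase wrap by -2*pi;
#' Izhikevich: v <- c, u <- u + d) and starts the refractory clock.
#' Refractory neurons are held at their current voltage/phase and cannot
#' spike.
#'
#' @param params Spiking layer parameter list.
#' @param I Length-N total current.
#' @param state Current spiking state (uses `v`, `aux`, `refractory_until`,
#'   `step_index`).
#' @return List with `v`, `spiked` (logical) and `aux`.
#' @export
update_voltage <- function(params, I, state) {
  N <- params$n_neurons
  check_that(length(I) == N, sprintf("I must have length %d", N))
  cst <- params$constants
  dt <- params$dt
  v <- state$v
  aux <- state$aux
  # refractory test is against the time at the *end* of this step
  refr <- state$refractory_until > (state$step_index + 1L)
  active <- !refr

  if (params$model_kind == "lif") {
    dv <- (-(v - cst$v_rest) + cst$R * I) * (dt / cst$tau_m)
    v[active] <- v[active] + dv[active]
    spiked <- active & (v >= cst$v_thresh)
    v[spiked] <- cst$v_reset
  } else if (params$model_kind == "theta") {
    dv <- ((1 - cos(v)) + (1 + cos(v)) * I) * dt
    v[active] <- v[active] + dv[active]
    spiked <- active & (v >= pi)
    v[spiked] <- v[spiked] - 2 * pi
  } else {  # izhikevich (canonical per-millisecond form)
    dt_ms <- dt * 1000
    dv <- (0.04 * v^2 + 5 * v + 140 - aux + I) * dt_ms
    da <- cst$a * (cst$b * v - aux) * dt_ms
    v[active] <- v[active] + dv[active]
    aux[active] <- aux[active] + da[active]
    spiked <- active & (v >= cst$v_peak)
    v[spiked] <- cst$c
    aux[spiked] <- aux[spiked] + cst$d
  }
  if (!all(is.finite(v))) {
    stop(sprintf("non-finite voltages at step %d: numerical blow-up",
                 state$step_index + 1L), call. = FALSE)
  }
  list(v = v, spiked = spiked, aux = aux)
}

#' Advance a spiking network by one step
#'
#' Accumulates the total current (static recurrent drive from the filtered
#' spike trains, feedback of the previous readout through the encoders,
#' external input, bias), updates the voltages, injects this step's spikes
#' into the double-exponential synaptic filter (exact exponential-decay
#' update; each spike increments `syn_h` by `1/(tau_r*tau_d)` giving a
#' unit-area impulse response), and reads out `z = phi^T syn_r`.
#'
#' @param params,state Components of a `spiking_layer`.
#' @param f_in_t Optional input vector of length `m_in`.
#' @return Updated spiking state.
#' @export
step_spiking <- function(params, state, f_in_t = NULL) {
  cst <- params$constants
  I <- params$gain * as_num(crossprod(params$omega0, state$syn_r)) +
    params$feedback_scale * as_num(crossprod(params$eta, state$z)) +
    cst$I_bias
  if (params$m_in > 0L) {
    check_that(!is.null(f_in_t) && length(f_in_t) == params$m_in,
               sprintf("f_in_t must have length %d", params$m_in))
    I <- I + as_num(crossprod(params$w_in, f_in_t))
  }
  upd <- update_voltage(params, I, state)
  refractory_until <- state$refractory_until
  if (cst$t_ref > 0 && any(upd$spiked)) {
    refractory_until[upd$spiked] <- state$step_index + 1L + cst$t_ref / params$dt
  }
  f <- params$filt
  syn_r <- state$syn_r * f$e_d + state$syn_h * f$rh
  syn_h <- state$syn_h * f$e_r + upd$spiked / (params$tau_r * params$tau_d)
  list(v = upd$v, aux = upd$aux, refractory_until = refractory_until,
       syn_r = syn_r, syn_h = syn_h, spiked = upd$spiked,
       z = as_num(crossprod(params$phi, syn_r)),
       step_index = state$step_index + 1L)
}

#' Run a spiking network forward (no training)
#'
#' @param params,state Components of a `spiking_layer`.
#' @param input_series T x M_in matrix, or NULL with `n_steps` for
#'   autonomous runs.
#' @param n_steps Number of steps when `input_series` is NULL.
#' @param record Any of `"z"`, `"v"`, `"syn_r"`, `"spikes"`.
#' @return List with final `state` and recorded trajectories; `spikes` is a
#'   two-column data.frame (time_s, neuron_index; 0-based indices).
#' @export
run_spiking_network <- function(params, state, input_series = NULL,
                                n_steps = NULL, record = "z") {
  if (is.null(input_series)) {
    check_that(!is.null(n_steps), "supply input_series or n_steps")
    T_len <- as.integer(n_steps)
    input_series <- matrix(0, T_len, params$m_in)
  } else {
    if (is.vector(input_series)) input_series <- matrix(input_series, ncol = 1L)
    T_len <- nrow(input_series)
    check_that(ncol(input_series) == params$m_in,
               sprintf("input_series has %d columns, layer expects %d",
                       ncol(input_series), params$m_in))
  }
  rec_z <- "z" %in% record; rec_v <- "v" %in% record
  rec_r <- "syn_r" %in% record; rec_s <- "spikes" %in% record
  Z <- if (rec_z) matrix(NA_real_, T_len, params$m_out)
  V <- if (rec_v) matrix(NA_real_, T_len, params$n_neurons)
  R <- if (rec_r) matrix(NA_real_, T_len, params$n_neurons)
  sp_t <- if (rec_s) vector("list", T_len)
  for (t in seq_len(T_len)) {
    state <- step_spiking(params, state, input_series[t, ])
    if (rec_z) Z[t, ] <- state$z
    if (rec_v) V[t, ] <- state$v
    if (rec_r) R[t, ] <- state$syn_r
    if (rec_s && any(state$spiked)) {
      sp_t[[t]] <- data.frame(time_s = t * params$dt,
                              neuron_index = which(state$spiked) - 1L)
    }
  }
  out <- list(state = state)
  if (rec_z) out$z <- Z
  if (rec_v) out$v <- V
  if (rec_r) out$syn_r <- R
  if (rec_s) {
    out$spikes <- if (length(sp <- Filter(Negate(is.null), sp_t)) > 0) {
      do.call(rbind, sp)
    } else {
      data.frame(time_s = numeric(0), neuron_index = integer(0))
    }
  }
  out
}

#' @export
reset_state.spiking_layer <- function(layer) {
  v0 <- initialize_voltage(layer$params,
                           seed = if (is.null(layer$params$seed)) NULL
                                  else layer$params$seed + 1L)
  layer$state <- spiking_state_zero(layer$params, v0)
  layer
}
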