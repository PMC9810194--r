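#' Initialize a rate-based chaotic recurrent network layer
#'
#' Builds a leaky-integrator rate network of `n_neurons` units in one of three
#' flavours: a classic echo state network with output feedback
#' (`"feedback_esn"`), the same architecture without feedback
#' (`"nofeedback_esn"`), or a connectome-constrained variant
#' (`"constrained_esn"`) whose recurrent weights are restricted to a boolean
#' mask with no self-loops. The forward dynamics are defined by
#' [step_rate()]; training is entirely separate (see [force_fit()] and
#' friends), so layers and trainers can be recombined freely.
#'
#' Recurrent weights are drawn i.i.d. zero-mean normal with standard
#' deviation `gain / sqrt(sparsity * n_neurons)` on a Bernoulli(`sparsity`)
#' support — the standard scaling that places the autonomous network in the
#' chaotic regime for `gain > 1`. Input and feedback weights are uniform on
#' `[-1, 1]` times their scale factors.
#'
#' @param n_neurons Number of units N.
#' @param layer_kind One of `"feedback_esn"`, `"nofeedback_esn"`,
#'   `"constrained_esn"`.
#' @param m_in Number of input channels (may be 0).
#' @param m_out Number of output channels.
#' @param sparsity Connection probability p in (0, 1].
#' @param gain Recurrent gain g; g > 1 gives chaotic spontaneous dynamics.
#' @param tau Membrane/rate time constant (same units as `dt`).
#' @param dt Integration step; must satisfy `tau >= dt`.
#' @param activation Activation name (default `"tanh"`).
#' @param input_scale,feedback_scale Scale factors for `w_in` and `w_F`.
#' @param mask Optional N x N logical connectivity mask, entry `[j, i]` TRUE
#'   iff neuron j is presynaptic to neuron i. Required semantics for
#'   `"constrained_esn"`: diagonal must be FALSE (no self-loops); generated
#'   at `sparsity` if not supplied.
#' @param w_out_init `"uniform"` (small random, the default) or `"zeros"`.
#' @param w_out_scale Half-width of the uniform readout initialization.
#' @param seed Integer seed; identical seeds give bit-identical weights.
#' @return A `rate_layer` object: `list(params, state)`. `params` holds the
#'   weight matrices (`w_in` M_in x N, `w_R` N x N, `w_out` N x M_out,
#'   `w_F` M_out x N), the mask, and the constants; `state` holds the
#'   currents `x`, rates `r = H(x)`, readout `z` and `step_index`.
#' @examples
#' layer <- init_rate_network(50, "nofeedback_esn", m_in = 1, seed = 1)
#' dim(layer$params$w_R)
#' @export
init_rate_network <- function(n_neurons,
                              layer_kind = c("feedback_esn", "nofeedback_esn",
                                             "constrained_esn"),
                              m_in = 1L, m_out = 1L,
                              sparsity = 1, gain = 1.5,
                              tau = 10, dt = 1,
                              activation = "tanh",
                              input_scale = 1, feedback_scale = 1,
                              mask = NULL,
                              w_out_init = c("uniform", "zeros"),
                              w_out_scale = 0.1,
                              seed = NULL) {
  layer_kind <- match.arg(layer_kind)
  w_out_init <- match.arg(w_out_init)
  check_that(n_neurons >= 1, "n_neurons must be >= 1")
  check_that(sparsity > 0 && sparsity <= 1,
             sprintf("sparsity must be in (0, 1], got %g", sparsity))
  check_that(dt > 0, "dt must be > 0")
  check_that(tau >= dt, sprintf("tau (%g) must be >= dt (%g)", tau, dt))
  N <- as.integer(n_neurons)
  act <- resolve_activation(activation)

  if (!is.null(mask)) {
    check_that(is.matrix(mask) && all(dim(mask) == c(N, N)),
               sprintf("mask must be %d x %d", N, N))
    mask <- matrix(as.logical(mask), N, N)
  }

  params <- with_seed(seed, {
    if (is.null(mask)) {
      mask <- matrix(stats::runif(N * N) < sparsity, N, N)
      if (layer_kind == "constrained_esn") diag(mask) <- FALSE
    }
    if (layer_kind == "constrained_esn") {
      check_that(!any(diag(mask)),
                 "constrained_esn mask must have a false diagonal (no self-loops)")
    }
    sd_w <- gain / sqrt(sparsity * N)
    w_R <- matrix(stats::rnorm(N * N, sd = sd_w), N, N)
    w_R[!mask] <- 0
    w_in <- if (m_in > 0) {
      matrix(stats::runif(m_in * N, -1, 1) * input_scale, m_in, N)
    } else {
      matrix(0, 0L, N)
    }
    w_F <- if (layer_kind == "feedback_esn") {
      matrix(stats::runif(m_out * N, -1, 1) * feedback_scale, m_out, N)
    } else {
      matrix(0, m_out, N)
    }
    w_out <- if (w_out_init == "zeros") {
      matrix(0, N, m_out)
    } else {
      matrix(stats::runif(N * m_out, -w_out_scale, w_out_scale), N, m_out)
    }
    list(kind = layer_kind, n_neurons = N, m_in = as.integer(m_in),
         m_out = as.integer(m_out), tau = tau, dt = dt,
         activation = activation, act = act,
         w_in = w_in, w_R = w_R, w_out = w_out, w_F = w_F,
         mask = mask, sparsity = sparsity, gain = gain, seed = seed)
  })

  state <- rate_state_zero(params)
  structure(list(params = params, state = state),
            class = c("rate_layer", "force_layer"))
}

rate_state_zero <- function(params) {
  x <- numeric(params$n_neurons)
  r <- params$act$fn(x)
  list(x = x, r = r,
       z = as_num(crossprod(params$w_out, r)),
       step_index = 0L)
}

#' Advance a rate network by one Euler step
#'
#' Applies the discrete forward pass
#' \deqn{x(t) = x(t-\Delta t) + \frac{\Delta t}{\tau}\left(-x(t-\Delta t) +
#'   w_{in}^\top f_{in}(t) + w_R^\top r(t-\Delta t) +
#'   w_F^\top z(t-\Delta t)\right)}
#' followed by `r(t) = H(x(t))` and the linear readout `z(t) = w_out^T r(t)`.
#' Feedback always uses the previous step's readout.
#'
#' @param params,state Components of a `rate_layer`.
#' @param f_in_t Input vector of length `m_in` for this step (ignored when
#'   `m_in == 0`).
#' @return The updated state list.
#' @export
step_rate <- function(params, state, f_in_t = NULL) {
  N <- params$n_neurons
  if (params$m_in > 0L) {
    check_that(!is.null(f_in_t) && length(f_in_t) == params$m_in,
               sprintf("f_in_t must have length %d", params$m_in))
    drive <- as_num(crossprod(params$w_in, f_in_t))
  } else {
    drive <- 0
  }
  rec <- as_num(crossprod(params$w_R, state$r))
  fb <- as_num(crossprod(params$w_F, state$z))
  x <- state$x + (params$dt / params$tau) * (-state$x + drive + rec + fb)
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite currents at step %d: numerical blow-up",
                 state$step_index + 1L), call. = FALSE)
  }
  r <- params$act$fn(x)
  list(x = x, r = r, z = as_num(crossprod(params$w_out, r)),
       step_index = state$step_index + 1L)
}

#' Run a rate network forward over an input series (no training)
#'
#' @param params,state Components of a `rate_layer`.
#' @param input_series T x M_in numeric matrix (or a T-vector when
#'   `m_in == 1`); use a T x 0 matrix, or `n_steps`, for autonomous runs.
#' @param n_steps Number of steps when `input_series` is NULL.
#' @param record Character vector from `c("x", "r", "z")` naming which
#'   trajectories to record.
#' @return List with the final `state` and, when recorded, matrices `x`, `r`
#'   (T x N) and `z` (T x M_out).
#' @export
run_rate_network <- function(params, state, input_series = NULL,
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
  rec_x <- "x" %in% record; rec_r <- "r" %in% record; rec_z <- "z" %in% record
  X <- if (rec_x) matrix(NA_real_, T_len, params$n_neurons)
  R <- if (rec_r) matrix(NA_real_, T_len, params$n_neurons)
  Z <- if (rec_z) matrix(NA_real_, T_len, params$m_out)
  for (t in seq_len(T_len)) {
    state <- step_rate(params, state, input_series[t, ])
    if (rec_x) X[t, ] <- state$x
    if (rec_r) R[t, ] <- state$r
    if (rec_z) Z[t, ] <- state$z
  }
  out <- list(state = state)
  if (rec_x) out$x <- X
  if (rec_r) out$r <- R
  if (rec_z) out$z <- Z
  out
}

#' Reset a layer's dynamical state to zero currents
#'
#' @param layer A `rate_layer`.
#' @return The layer with `state` re-initialized (weights untouched).
#' @export
reset_state <- function(layer) {
  UseMethod("reset_state")
}

#' @export
reset_state.rate_layer <- function(layer) {
  layer$state <- rate_state_zero(layer$params)
  layer
}
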