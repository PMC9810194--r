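#' Construct a task data object
#'
#' Container for the input series `f_in(t)`, target series `f_out(t)` and
#' optional hint channel used by every trainer. All series must share the
#' same number of rows and contain no missing values.
#'
#' @param f_in T x M_in input matrix (M_in may be 0 for autonomous targets).
#' @param f_out T x M_out target matrix.
#' @param hint Optional T x M_hint matrix of auxiliary inputs.
#' @param dt Time step of the grid (task time units).
#' @param metadata Named list (generator name, seed, parameters).
#' @return A `task_data` object.
#' @export
task_data <- function(f_in, f_out, hint = NULL, dt = 1, metadata = list()) {
  f_in <- as.matrix(f_in); f_out <- as.matrix(f_out)
  if (!is.null(hint)) hint <- as.matrix(hint)
  T_len <- nrow(f_out)
  check_that(nrow(f_in) == T_len, "f_in and f_out must share the same length")
  check_that(is.null(hint) || nrow(hint) == T_len,
             "hint must share the task length")
  check_that(!anyNA(f_in) && !anyNA(f_out) && (is.null(hint) || !anyNA(hint)),
             "task series must not contain NA/NaN")
  check_that(all(is.finite(f_out)), "f_out must be finite")
  structure(list(f_in = f_in, f_out = f_out, hint = hint,
                 dt = dt, metadata = metadata),
            class = "task_data")
}

#' @export
print.task_data <- function(x, ...) {
  cat(sprintf("task_data '%s': T=%d steps, dt=%g, M_in=%d, M_out=%d%s\n",
              x$metadata$name %||% "unnamed", nrow(x$f_out), x$dt,
              ncol(x$f_in), ncol(x$f_out),
              if (is.null(x$hint)) "" else sprintf(", M_hint=%d", ncol(x$hint))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sum-of-sines target with a brief constant input kick
#'
#' Periodic target built from four harmonics of a base frequency spanning
#' the window, normalized to `amplitude` peak. The input channel is constant
#' at `input_value` for the first `n_input_on` steps and silent afterwards,
#' so the network must sustain the oscillation autonomously. A hint channel
#' of zeros is attached (used as a dummy hint input by the full-FORCE
#' trainer and as an extra input dimension otherwise).
#'
#' @param n_steps Series length (default 801).
#' @param n_input_on Steps the input stays on (default 20).
#' @param amplitude Peak amplitude of the target.
#' @param frequencies Component frequencies in cycles per step; defaults to
#'   harmonics 1, 2, 3 and 5 of one cycle per 800 steps with 1/k amplitude
#'   weighting.
#' @param input_value Constant input level while on.
#' @param seed Kept for generator-interface uniformity; the series is a
#'   deterministic function of the other arguments.
#' @return A [task_data()] with M_in = 1, M_out = 1 and a zero hint channel.
#' @export
gen_sum_of_sines <- function(n_steps = 801L, n_input_on = 20L,
                             amplitude = 1,
                             frequencies = c(1, 2, 3, 5) / 800,
                             input_value = 1, seed = NULL) {
  check_that(length(frequencies) > 0, "frequency list must be non-empty")
  check_that(n_input_on <= n_steps, "n_input_on must be <= n_steps")
  t_grid <- seq_len(n_steps) - 1
  weights <- 1 / seq_along(frequencies)
  y <- rowSums(vapply(seq_along(frequencies),
                      function(k) weights[k] * sin(2 * pi * frequencies[k] * t_grid),
                      numeric(n_steps)))
  y <- amplitude * y / max(abs(y))
  f_in <- matrix(0, n_steps, 1L)
  if (n_input_on > 0) f_in[seq_len(n_input_on), 1L] <- input_value
  task_data(f_in = f_in, f_out = matrix(y, ncol = 1L),
            hint = matrix(0, n_steps, 1L), dt = 1,
            metadata = list(name = "sum_of_sines", seed = seed,
                            n_steps = n_steps, n_input_on = n_input_on,
                            amplitude = amplitude, frequencies = frequencies))
}

#' Lorenz attractor trajectory as an autonomous target
#'
#' Integrates the Lorenz system
#' `dx/dt = sigma (y - x)`, `dy/dt = x (rho - z) - y`, `dz/dt = x y - beta z`
#' with a fixed-step 4th-order Runge-Kutta scheme and rescales the
#' three-channel trajectory to unit-order amplitude so tanh-range readouts
#' can match it. There is no input channel (the target is internally
#' generated).
#'
#' @param duration_s Simulated duration in seconds.
#' @param dt Integration/sampling step in seconds.
#' @param sigma,rho,beta Lorenz parameters (classical chaotic defaults).
#' @param init Length-3 initial condition; when NULL a seeded jitter around
#'   `c(-8, 7, 27)` is used so repeated draws give distinct trajectories.
#' @param rescale Amplitude divisor applied to the raw trajectory
#'   (default 10).
#' @param seed Integer seed for the jittered initial condition.
#' @return A [task_data()] with M_in = 0 and M_out = 3.
#' @export
gen_lorenz <- function(duration_s = 5, dt = 1e-3,
                       sigma = 10, rho = 28, beta = 8 / 3,
                       init = NULL, rescale = 10, seed = NULL) {
  check_that(dt > 0, "dt must be > 0")
  if (is.null(init)) {
    init <- with_seed(seed, c(-8, 7, 27) + stats::runif(3, -2, 2))
  }
  check_that(length(init) == 3, "init must have length 3")
  deriv <- function(t, y, p) {
    list(c(sigma * (y[2] - y[1]),
           y[1] * (rho - y[3]) - y[2],
           y[1] * y[2] - beta * y[3]))
  }
  times <- seq(0, duration_s, by = dt)
  sol <- deSolve::ode(y = c(x = init[1], y = init[2], z = init[3]),
                      times = times, func = deriv, parms = NULL,
                      method = "rk4")
  traj <- unname(sol[, 2:4, drop = FALSE])
  if (!all(is.finite(traj))) {
    stop("Lorenz integration blew up (non-finite trajectory)", call. = FALSE)
  }
  task_data(f_in = matrix(0, nrow(traj), 0L),
            f_out = traj / rescale, dt = dt,
            metadata = list(name = "lorenz", seed = seed, sigma = sigma,
                            rho = rho, beta = beta, init = init,
                            rescale = rescale))
}

#' Delayed-response boxcar task
#'
#' The input is a boxcar of width `pulse_width_s` at a seeded random onset;
#' the target is an identical boxcar that starts `delay_s` after the input
#' turns off, so the network must hold the stimulus across the delay.
#'
#' @param duration_s Total duration (default 5 s).
#' @param dt Time step (default 1e-4 s).
#' @param pulse_width_s Boxcar width (default 0.5 s).
#' @param delay_s Gap between input offset and target onset (default 0.05 s).
#' @param amplitude Boxcar height.
#' @param seed Seed for the onset jitter (uniform over the feasible window).
#' @return A [task_data()] with M_in = 1, M_out = 1.
#' @export
gen_delayed_response <- function(duration_s = 5, dt = 1e-4,
                                 pulse_width_s = 0.5, delay_s = 0.05,
                                 amplitude = 1, seed = NULL) {
  T_len <- as.integer(round(duration_s / dt))
  pw <- as.integer(round(pulse_width_s / dt))
  dl <- as.integer(round(delay_s / dt))
  check_that(2L * pw + dl <= T_len,
             "pulse + delay + response does not fit in the duration")
  onset_max <- T_len - (2L * pw + dl)  # latest feasible 0-based onset
  onset <- with_seed(seed, as.integer(floor(stats::runif(1, 0, onset_max + 1))))
  f_in <- matrix(0, T_len, 1L)
  f_in[onset + seq_len(pw), 1L] <- amplitude
  f_out <- matrix(0, T_len, 1L)
  f_out[onset + pw + dl + seq_len(pw), 1L] <- amplitude
  task_data(f_in = f_in, f_out = f_out, dt = dt,
            metadata = list(name = "delayed_response", seed = seed,
                            duration_s = duration_s, pulse_width_s = pulse_width_s,
                            delay_s = delay_s, onset_index = onset))
}

#' Random structural connectome mask
#'
#' Bernoulli(`density`) boolean mask over the off-diagonal entries with a
#' FALSE diagonal (no self-loops). Entry `[j, i]` TRUE means neuron j
#' projects to neuron i.
#'
#' @param n_neurons Number of neurons.
#' @param density Connection probability in (0, 1].
#' @param seed Integer seed.
#' @return An N x N logical matrix.
#' @export
gen_connectome <- function(n_neurons, density, seed = NULL) {
  check_that(density > 0 && density <= 1, "density must be in (0, 1]")
  N <- as.integer(n_neurons)
  mask <- with_seed(seed, matrix(stats::runif(N * N) < density, N, N))
  diag(mask) <- FALSE
  mask
}

#' Synthetic neural recording from a known teacher network
#'
#' Emulates a calcium-imaging-like recording (N neurons by T time steps of
#' smooth, correlated rate traces) by simulating a connectome-constrained
#' teacher rate network with known weights and adding Gaussian observation
#' noise. The defaults match a whole-brain-area recording scale
#' (N = 365 neurons, T = 2500 steps at dt = 0.25 s); tests use a small
#' preset (N = 50, T = 500). The ground-truth weights and mask are returned
#' so constrained fitting can be validated as a teacher-student recovery
#' experiment.
#'
#' The teacher combines a subcritical random recurrent matrix
#' (`teacher_gain` below 1) with a planted rank-2 amplifying rotation
#' (`osc_gain` above 1 at angular frequency `osc_freq` rad per time
#' constant, projected onto the connectome support) that saturates into a
#' stable network-wide limit cycle. The recording starts after a burn-in so
#' traces are stationary, smooth and correlated across neurons — mimicking
#' the low-dimensional oscillatory structure that dominates real
#' population recordings — while remaining predictable enough that
#' recovered effective weights can be validated on held-out segments.
#'
#' @param n_neurons,n_steps,dt Recording dimensions (defaults 365, 2500,
#'   0.25 s).
#' @param connectome_density Off-diagonal connection probability.
#' @param teacher_gain Gain of the random (chaotic-background) component;
#'   kept subcritical by default so the planted mode dominates.
#' @param osc_gain,osc_freq Amplification and angular frequency (rad per
#'   tau) of the planted oscillatory mode.
#' @param tau Teacher time constant in seconds (default 4 * dt).
#' @param burn_in_steps Settling steps discarded before the recording.
#' @param noise_sd Standard deviation of additive observation noise on the
#'   rates.
#' @param seed Integer seed.
#' @return List with `task` (a [task_data()]; traces in `f_out`, no input),
#'   `weights` (teacher N x N recurrent matrix), `mask` (logical N x N) and
#'   `x0` (teacher currents at recording onset).
#' @export
gen_synthetic_recording <- function(n_neurons = 365L, n_steps = 2500L,
                                    dt = 0.25, connectome_density = 0.2,
                                    teacher_gain = 0.8,
                                    osc_gain = 1.8, osc_freq = 0.8,
                                    tau = 4 * dt, burn_in_steps = 200L,
                                    noise_sd = 0.01, seed = NULL) {
  seeds <- split_seed(seed %||% 0L, 4L)
  for (attempt in seq_len(5L)) {
    s_off <- (attempt - 1L) * 977L
    mask <- gen_connectome(n_neurons, connectome_density, seeds[1] + s_off)
    teacher <- init_rate_network(n_neurons, "constrained_esn",
                                 m_in = 0L, m_out = 1L,
                                 sparsity = connectome_density,
                                 gain = teacher_gain, tau = tau, dt = dt,
                                 mask = mask, w_out_init = "zeros",
                                 seed = seeds[2] + s_off)
    # planted rank-2 mode: amplifying rotation in the (u, v) plane,
    # restricted to the connectome support (rescaled by the density so the
    # projected mode keeps its strength)
    plant <- with_seed(seeds[4] + s_off, {
      u <- stats::rnorm(n_neurons); u <- u / sqrt(sum(u^2))
      v <- stats::rnorm(n_neurons); v <- v - sum(u * v) * u
      v <- v / sqrt(sum(v^2))
      osc_gain * (tcrossprod(u) + tcrossprod(v)) +
        osc_freq * (tcrossprod(u, v) - tcrossprod(v, u))
    })
    plant[!mask] <- 0
    teacher$params$w_R <- teacher$params$w_R + plant / connectome_density
    teacher$state$x <- with_seed(seeds[3] + s_off,
                                 stats::runif(n_neurons, -1, 1))
    teacher$state$r <- teacher$params$act$fn(teacher$state$x)
    if (burn_in_steps > 0L) {
      burn <- run_rate_network(teacher$params, teacher$state,
                               n_steps = burn_in_steps, record = character(0))
      teacher$state <- burn$state
    }
    x0 <- teacher$state$x
    sim <- run_rate_network(teacher$params, teacher$state,
                            n_steps = n_steps, record = "r")
    traces <- sim$r
    # degenerate teacher: activity (nearly) dies out or never moves
    if (stats::sd(traces[n_steps, ]) > 1e-3 &&
        mean(abs(traces[n_steps, ])) > 1e-3) {
      if (noise_sd > 0) {
        noise <- with_seed(seeds[3] + s_off + 1L,
                           matrix(stats::rnorm(length(traces), sd = noise_sd),
                                  nrow(traces), ncol(traces)))
        traces <- traces + noise
      }
      task <- task_data(f_in = matrix(0, n_steps, 0L), f_out = traces, dt = dt,
                        metadata = list(name = "synthetic_recording",
                                        seed = seed, n_neurons = n_neurons,
                                        connectome_density = connectome_density,
                                        teacher_gain = teacher_gain,
                                        osc_gain = osc_gain,
                                        osc_freq = osc_freq, tau = tau,
                                        burn_in_steps = burn_in_steps,
                                        noise_sd = noise_sd,
                                        attempt = attempt))
      return(list(task = task, weights = teacher$params$w_R,
                  mask = mask, x0 = x0))
    }
  }
  stop("teacher network activity degenerate after 5 attempts; adjust gain/density",
       call. = FALSE)
}
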