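#' Fit a connectome-constrained network to recorded neural traces
#'
#' Per-neuron FORCE fitting of effective connectivity: each model neuron i
#' is placed in one-to-one correspondence with a recorded trace, and its
#' incoming recurrent weights (restricted to the presynaptic set `B(i)`
#' given by the connectivity mask, which excludes self-loops) are trained by
#' its own RLS recursion so that the neuron's activity matches trace i. The
#' learned recurrent matrix is returned as the effective weight matrix — a
#' hypothesis for the unobservable synaptic connectivity that generated the
#' recording.
#'
#' With `teacher_forcing = TRUE` (the default) the presynaptic rates that
#' drive the recurrent input are the recorded traces themselves, so the
#' per-neuron problem stays close to a well-conditioned regression on the
#' data: the currents are propagated as
#' `x_i(t) = (1 - dt/tau) x_i(t-1) + (dt/tau) sum_j w_ji y_j(t-1)`,
#' the error is `e_i = H(x_i(t)) - y_i(t)` (or the current-space
#' difference with `match = "currents"`), and neuron i's `A^i` is
#' downdated with the leak-filtered presynaptic data rates
#' `f(t) = (1 - dt/tau) f(t-1) + (dt/tau) y(t-1)` restricted to `B(i)` —
#' exactly the sensitivity of `x_i(t)` to its incoming weights, so the
#' recursion solves the induced least-squares problem.
#' With `teacher_forcing = FALSE` the network runs closed-loop during
#' training and its own rates provide both features and errors.
#'
#' Validation re-runs the full series closed-loop (no updates) from the
#' trace-matched initial state; early stopping watches the validation MAE
#' and the best-epoch weights are restored. After training one final
#' no-update pass produces the reported outputs.
#'
#' Traces are linearly rescaled into the activation's range when they exceed
#' it (the scale is reported in the result).
#'
#' @param layer A `rate_layer` of kind `constrained_esn` with N neurons.
#' @param traces T x N numeric matrix of recorded activity, or a
#'   [task_data()] whose `f_out` holds the traces.
#' @param config A [training_config()]; `early_stopping` is honoured.
#' @param train_steps Updates only run at steps `<= train_steps` (default:
#'   the whole series), so a terminal segment can be held out.
#' @param match `"rates"` (default) matches `r` to the traces;
#'   `"currents"` matches `x` to the inverse-activation of the traces.
#' @param teacher_forcing Drive predictions with the recorded rates during
#'   training (default) instead of the network's own closed-loop rates.
#' @return List with `layer` (trained), `effective_weights` (N x N),
#'   `history`, `outputs` (T x N rates from the final no-update pass),
#'   `trace_scale`.
#' @export
bio_force_fit <- function(layer, traces, config = training_config(),
                          train_steps = NULL,
                          match = c("rates", "currents"),
                          teacher_forcing = TRUE) {
  match <- match.arg(match)
  check_that(inherits(layer, "rate_layer") &&
               layer$params$kind == "constrained_esn",
             "bio_force_fit requires a constrained_esn rate layer")
  if (inherits(traces, "task_data")) traces <- traces$f_out
  traces <- as.matrix(traces)
  params <- layer$params
  N <- params$n_neurons
  check_that(ncol(traces) == N,
             sprintf("traces have %d columns but the layer has %d neurons",
                     ncol(traces), N))
  T_len <- nrow(traces)
  train_steps <- train_steps %||% T_len
  check_that(params$m_in == 0L,
             "bio_force_fit expects an input-free layer (m_in = 0)")

  # rescale into the activation range only when the traces grossly exceed
  # it (e.g. raw dF/F units); small observation-noise overshoot is handled
  # by clipping instead, to avoid distorting the dynamics being fitted
  rng <- params$act$range
  trace_scale <- 1
  if (is.finite(rng[2])) {
    peak <- max(abs(traces))
    if (peak > 1.5 * rng[2]) {
      trace_scale <- peak / (0.9 * rng[2])
      traces <- traces / trace_scale
    }
  }
  check_that(!is.null(params$act$inverse),
             "activation must be invertible for trace-constrained fitting")
  clip <- function(y) {
    lo <- if (is.finite(rng[1])) rng[1] * 0.999 else -Inf
    hi <- if (is.finite(rng[2])) rng[2] * 0.999 else Inf
    pmin(pmax(y, lo), hi)
  }
  x_hat <- params$act$inverse(clip(traces))
  x0 <- x_hat[1, ]

  A_fam <- init_A_family(config$alpha, params$mask)
  isolated <- which(vapply(A_fam$pre, length, 1L) == 0L)
  if (length(isolated) > 0L) {
    warning(sprintf("neuron(s) %s have no presynaptic partners and are left untrained",
                    paste(isolated, collapse = ", ")))
  }
  trained <- setdiff(seq_len(N), isolated)
  k <- config$update_interval
  warm <- config$warmup_steps
  history <- new_history()
  best <- list(val = Inf, w_R = params$w_R)

  run_pass <- function(w_R) {
    p <- params; p$w_R <- w_R
    st <- rate_state_zero(p); st$x <- x0; st$r <- p$act$fn(x0)
    run_rate_network(p, st, n_steps = T_len, record = "r")$r
  }

  lam <- params$dt / params$tau
  for (epoch in seq_len(config$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    state <- rate_state_zero(params)
    state$x <- x0
    state$r <- params$act$fn(x0)
    abs_err <- 0
    n_seen <- 0L
    n_upd <- 0L
    x_tf <- x0
    feat_f <- numeric(N)  # leak-filtered data rates (weight sensitivity)
    for (t in if (teacher_forcing) 2:T_len else seq_len(T_len)) {
      if (teacher_forcing) {
        # currents propagated with the recorded rates as presynaptic drive
        yprev <- traces[t - 1L, ]
        x_tf <- (1 - lam) * x_tf + lam * as_num(crossprod(params$w_R, yprev))
        feat <- feat_f <- (1 - lam) * feat_f + lam * yprev
        r_pred <- params$act$fn(x_tf)
        err_vec <- if (match == "rates") r_pred - traces[t, ]
                   else x_tf - x_hat[t, ]
        abs_err <- abs_err + sum(abs(r_pred - traces[t, ]))
      } else {
        state <- step_rate(params, state)
        feat <- state$r
        err_vec <- if (match == "rates") state$r - traces[t, ]
                   else state$x - x_hat[t, ]
        abs_err <- abs_err + sum(abs(state$r - traces[t, ]))
      }
      n_seen <- n_seen + 1L
      if (t <= train_steps && is_update_step(t, warm, k)) {
        n_upd <- n_upd + 1L
        for (i in trained) {
          b <- A_fam$pre[[i]]
          rb <- feat[b]
          A <- rank_one_update(A_fam$A[[i]], rb)
          A_fam$A[[i]] <- A
          params$w_R[b, i] <- params$w_R[b, i] -
            err_vec[i] * as_num(A %*% rb)
        }
      }
    }
    train_mae <- abs_err / (n_seen * N)
    val_r <- run_pass(params$w_R)
    val_mae <- mae(val_r, traces)
    if (val_mae < best$val) best <- list(val = val_mae, w_R = params$w_R)
    history <- append_history(history, epoch, train_mae, val_mae, n_upd,
                              proc.time()[["elapsed"]] - t0)
    if (early_stop_now(config$early_stopping, history$val_mae)) break
  }

  params$w_R <- best$w_R
  outputs <- run_pass(params$w_R)
  layer$params <- params
  layer$state <- rate_state_zero(params)
  layer$state$x <- x0
  layer$state$r <- params$act$fn(x0)
  list(layer = layer, effective_weights = params$w_R,
       history = history, outputs = outputs * trace_scale,
       trace_scale = trace_scale)
}
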