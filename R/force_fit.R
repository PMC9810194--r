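#' Training configuration for the FORCE trainers
#'
#' @param epochs Number of passes over the task series.
#' @param update_interval Steps between RLS updates (k >= 1); updates fire at
#'   steps `warmup_steps + k, warmup_steps + 2k, ...` within each epoch.
#' @param train_output Update the readout weights?
#' @param train_recurrent Update the recurrent weights (classic FORCE;
#'   scalar outputs only)?
#' @param warmup_steps Settling steps at the start of each epoch during
#'   which the forward pass runs without any updates.
#' @param alpha RLS regularizer (P(0) = I/alpha).
#' @param early_stopping NULL, or `list(patience =, min_delta =)` applied to
#'   the validation MAE.
#' @param seed Optional seed for trainer-internal randomness (e.g. the
#'   full-FORCE target-generating network).
#' @return A `training_config` list.
#' @export
training_config <- function(epochs = 10L, update_interval = 1L,
                            train_output = TRUE, train_recurrent = FALSE,
                            warmup_steps = 0L, alpha = 1,
                            early_stopping = NULL, seed = NULL) {
  check_that(update_interval >= 1, "update_interval must be >= 1")
  check_that(warmup_steps >= 0, "warmup_steps must be >= 0")
  check_that(epochs >= 1, "epochs must be >= 1")
  check_that(alpha > 0, "alpha must be > 0")
  if (!is.null(early_stopping)) {
    check_that(is.list(early_stopping) && !is.null(early_stopping$patience),
               "early_stopping must be list(patience=, min_delta=)")
    early_stopping$min_delta <- early_stopping$min_delta %||% 0
  }
  structure(list(epochs = as.integer(epochs),
                 update_interval = as.integer(update_interval),
                 train_output = isTRUE(train_output),
                 train_recurrent = isTRUE(train_recurrent),
                 warmup_steps = as.integer(warmup_steps),
                 alpha = alpha, early_stopping = early_stopping,
                 seed = seed),
            class = "training_config")
}

new_history <- function() {
  data.frame(epoch = integer(0), train_mae = numeric(0),
             val_mae = numeric(0), n_updates = integer(0))
}

append_history <- function(h, epoch, train_mae, val_mae, n_updates, wall) {
  h2 <- rbind(h, data.frame(epoch = epoch, train_mae = train_mae,
                            val_mae = val_mae, n_updates = n_updates))
  attr(h2, "wall_time_s") <- c(attr(h, "wall_time_s"), wall)
  h2
}

# TRUE at steps where an RLS update is scheduled (1-based step index within
# an epoch): past warmup and at multiples of the update interval.
is_update_step <- function(t, warmup, k) {
  t > warmup && ((t - warmup) %% k) == 0L
}

# effective input: task input plus hint channels appended as extra inputs
task_input <- function(task, use_hint = TRUE) {
  if (use_hint && !is.null(task$hint)) cbind(task$f_in, task$hint) else task$f_in
}

early_stop_now <- function(es, val_hist) {
  if (is.null(es)) return(FALSE)
  n <- length(val_hist)
  if (n <= es$patience) return(FALSE)
  best_before <- min(val_hist[seq_len(n - es$patience)])
  recent <- val_hist[(n - es$patience + 1L):n]
  # stop when none of the recent epochs improved by more than min_delta
  all(recent >= best_before - es$min_delta)
}

#' Classic FORCE training of a rate network
#'
#' Runs the recursive-least-squares FORCE loop on an echo state network with
#' or without output feedback. Every step the forward pass is applied, then
#' at scheduled update steps the shared inverse-correlation matrix P is
#' downdated with the current rates, the a-priori error `e_- = z - f_out` is
#' computed, and the readout (and optionally the recurrent) weights receive
#' the pseudogradient update. During training the readout `z` feeds back
#' into the dynamics through `w_F` when the layer has feedback, so the error
#' is controlled at every step (closed loop).
#'
#' Network state resets to the layer's stored initial state at the start of
#' every epoch (and of every validation pass); P and the per-neuron
#' matrices persist across epochs. Validation re-runs the same input/target
#' pair without updates at the end of each epoch and reports its MAE.
#'
#' @param layer A `rate_layer` of kind `feedback_esn` or `nofeedback_esn`.
#' @param task A [task_data()]; hint channels are appended as extra inputs.
#' @param config A [training_config()].
#' @param trace_weights Record `sum(abs(w_out))` (and of `w_R` when
#'   recurrent training is on) after every step of the final epoch, as the
#'   `"weight_trace"` attribute of the history — used to verify that
#'   weights move only at scheduled update steps.
#' @return List with `layer` (trained), `history` (data.frame: epoch,
#'   train_mae, val_mae, n_updates), and `P` (final RLS matrix).
#' @export
force_fit <- function(layer, task, config = training_config(),
                      trace_weights = FALSE) {
  check_that(inherits(layer, "rate_layer"), "layer must be a rate_layer")
  check_that(layer$params$kind %in% c("feedback_esn", "nofeedback_esn"),
             sprintf("force_fit supports feedback/nofeedback ESNs, not '%s' (use bio_force_fit)",
                     layer$params$kind))
  inputs <- task_input(task)
  f_out <- as.matrix(task$f_out)
  T_len <- nrow(f_out)
  check_that(ncol(inputs) == layer$params$m_in,
             sprintf("task supplies %d input channels but layer expects %d",
                     ncol(inputs), layer$params$m_in))
  check_that(ncol(f_out) == layer$params$m_out,
             sprintf("task target has %d channels but layer has m_out=%d",
                     ncol(f_out), layer$params$m_out))
  if (config$train_recurrent) {
    check_that(layer$params$m_out == 1L,
               "recurrent FORCE training supports scalar outputs only")
  }

  params <- layer$params
  init_state <- layer$state
  k <- config$update_interval
  warm <- config$warmup_steps
  P <- init_P(config$alpha, params$n_neurons)
  A_fam <- if (config$train_recurrent) init_A_family(config$alpha, params$mask)
  history <- new_history()

  w_trace <- NULL
  for (epoch in seq_len(config$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    state <- init_state
    abs_err <- 0
    n_upd <- 0L
    do_trace <- trace_weights && epoch == config$epochs
    if (do_trace) w_trace <- numeric(T_len)
    for (t in seq_len(T_len)) {
      state <- step_rate(params, state, inputs[t, ])
      e <- compute_error(state$z, f_out[t, ])
      abs_err <- abs_err + sum(abs(e))
      if (is_update_step(t, warm, k)) {
        P <- rank_one_update(P, state$r)
        n_upd <- n_upd + 1L
        if (config$train_output) {
          params$w_out <- update_output_weights(params$w_out, e, P, state$r)
        }
        if (config$train_recurrent) {
          upd <- update_recurrent_weights(params$w_R, A_fam, e, state$r)
          params$w_R <- upd$w_R
          A_fam <- upd$A_family
        }
      }
      if (do_trace) {
        w_trace[t] <- sum(abs(params$w_out)) +
          if (config$train_recurrent) sum(abs(params$w_R)) else 0
      }
    }
    train_mae <- abs_err / (T_len * params$m_out)
    val <- run_rate_network(params, init_state, inputs, record = "z")
    val_mae <- mae(val$z, f_out)
    history <- append_history(history, epoch, train_mae, val_mae, n_upd,
                              proc.time()[["elapsed"]] - t0)
    if (early_stop_now(config$early_stopping, history$val_mae)) break
  }

  layer$params <- params
  layer$state <- init_state
  if (!is.null(w_trace)) attr(history, "weight_trace") <- w_trace
  list(layer = layer, history = history, P = P)
}

#' full-FORCE training of a no-feedback rate network
#'
#' Trains the recurrent weights of the task network so that its internal
#' recurrent currents match those of a separate target-generating network
#' that is driven by the target (and any hint inputs) with fixed random
#' weights, while simultaneously training the readout on the output error.
#' Both trainable parts share a single inverse-correlation matrix over the
#' task network's rates, so the per-step cost is O(N^2) — versus O(N^3) for
#' classic recurrent FORCE with its N per-neuron matrices.
#'
#' @param layer A `rate_layer` of kind `nofeedback_esn` (the task network).
#' @param task A [task_data()]; a hint channel (even all zeros) is appended
#'   to the input of both networks.
#' @param config A [training_config()]; `config$seed` (or the layer seed)
#'   seeds the target-generating network.
#' @param target_layer Optional `rate_layer` to use as the target-generating
#'   network (its recurrent/input weights are frozen); by default a fresh
#'   network with the task layer's architecture is drawn.
#' @param target_drive_scale Amplitude of the fixed random weights feeding
#'   the target into the generator network (uniform on the scaled
#'   `[-1, 1]`). Moderate injection (default 0.5) embeds the target in the
#'   generator's currents without saturating them; large values degrade
#'   the learned dynamics.
#' @return List with `layer` (trained task network), `history`, `P` and
#'   `target_layer` (the frozen target-generating network).
#' @export
full_force_fit <- function(layer, task, config = training_config(),
                           target_layer = NULL, target_drive_scale = 0.5) {
  check_that(inherits(layer, "rate_layer"), "layer must be a rate_layer")
  check_that(layer$params$kind == "nofeedback_esn",
             sprintf("full_force_fit requires a nofeedback_esn, got '%s'",
                     layer$params$kind))
  inputs <- task_input(task)
  f_out <- as.matrix(task$f_out)
  T_len <- nrow(f_out)
  params <- layer$params
  check_that(ncol(inputs) == params$m_in,
             sprintf("task supplies %d input channels but layer expects %d",
                     ncol(inputs), params$m_in))
  check_that(ncol(f_out) == params$m_out,
             sprintf("task target has %d channels but layer has m_out=%d",
                     ncol(f_out), params$m_out))

  # Target-generating network: same architecture and inputs, its own random
  # recurrent weights, plus fixed random weights feeding the target in.
  tg_seed <- config$seed %||% params$seed
  tg_seed <- if (is.null(tg_seed)) NULL else split_seed(tg_seed, 2L)[2]
  target_net <- target_layer %||%
    init_rate_network(params$n_neurons, "nofeedback_esn",
                      m_in = params$m_in, m_out = params$m_out,
                      sparsity = params$sparsity,
                      gain = params$gain, tau = params$tau,
                      dt = params$dt,
                      activation = params$activation,
                      w_out_init = "zeros", seed = tg_seed)
  check_that(target_net$params$n_neurons == params$n_neurons &&
               target_net$params$m_in == params$m_in,
             "target layer must match the task layer's dimensions")
  target_net$params$w_in <- params$w_in  # shared input weights
  u_D <- with_seed(if (is.null(tg_seed)) NULL else tg_seed + 1L,
                   matrix(stats::runif(params$m_out * params$n_neurons, -1, 1) *
                            target_drive_scale,
                          params$m_out, params$n_neurons))

  k <- config$update_interval
  warm <- config$warmup_steps
  P <- init_P(config$alpha, params$n_neurons)
  init_state <- layer$state
  init_tstate <- target_net$state
  tparams <- target_net$params
  history <- new_history()

  for (epoch in seq_len(config$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    state <- init_state
    tstate <- init_tstate
    abs_err <- 0
    n_upd <- 0L
    for (t in seq_len(T_len)) {
      ft <- f_out[t, ]
      # target network driven by the target signal (fixed weights)
      drive_D <- as_num(crossprod(tparams$w_in, inputs[t, ])) +
        as_num(crossprod(tparams$w_R, tstate$r)) +
        as_num(crossprod(u_D, ft))
      xD <- tstate$x + (tparams$dt / tparams$tau) * (-tstate$x + drive_D)
      tstate <- list(x = xD, r = tparams$act$fn(xD), z = tstate$z,
                     step_index = tstate$step_index + 1L)
      # task network runs free
      state <- step_rate(params, state, inputs[t, ])
      e_out <- compute_error(state$z, ft)
      abs_err <- abs_err + sum(abs(e_out))
      if (is_update_step(t, warm, k)) {
        P <- rank_one_update(P, state$r)
        n_upd <- n_upd + 1L
        Pr <- as_num(P %*% state$r)
        # internal error: task recurrent current vs. target current + drive
        e_int <- as_num(crossprod(params$w_R, state$r)) -
          (as_num(crossprod(tparams$w_R, tstate$r)) + as_num(crossprod(u_D, ft)))
        params$w_R <- params$w_R - tcrossprod(Pr, e_int)
        if (config$train_output) {
          params$w_out <- params$w_out - tcrossprod(Pr, e_out)
        }
      }
    }
    train_mae <- abs_err / (T_len * params$m_out)
    val <- run_rate_network(params, init_state, inputs, record = "z")
    val_mae <- mae(val$z, f_out)
    history <- append_history(history, epoch, train_mae, val_mae, n_upd,
                              proc.time()[["elapsed"]] - t0)
    if (early_stop_now(config$early_stopping, history$val_mae)) break
  }

  layer$params <- params
  layer$state <- init_state
  target_net$params <- tparams
  list(layer = layer, history = history, P = P, target_layer = target_net)
}

#' Forward-pass prediction and error for a trained (or untrained) layer
#'
#' Runs the layer forward over the task input without any weight updates and
#' reports the readout series and its mean absolute error against the
#' target, averaged over steps and output dimensions.
#'
#' @param object A `rate_layer`.
#' @param task A [task_data()].
#' @param compare `"readout"` compares `z` to `f_out`; `"rates"` compares
#'   the rate vector `r` to an N-channel target (constrained-network usage).
#' @param ... Unused.
#' @return List with `outputs` (T x M matrix) and `mae`.
#' @export
predict.rate_layer <- function(object, task, compare = c("readout", "rates"),
                               ...) {
  compare <- match.arg(compare)
  inputs <- task_input(task)
  check_that(ncol(inputs) == object$params$m_in,
             sprintf("task supplies %d input channels but layer expects %d",
                     ncol(inputs), object$params$m_in))
  rec <- if (compare == "readout") "z" else "r"
  out <- run_rate_network(object$params, object$state, inputs, record = rec)
  outputs <- if (compare == "readout") out$z else out$r
  list(outputs = outputs, mae = mae(outputs, task$f_out))
}
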