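#' FORCE training of a spiking network's output decoders
#'
#' Applies RLS to the decoders `phi` using the filtered spike trains
#' `syn_r` as the regression features. Every `update_interval` steps after
#' the per-epoch warmup, the shared inverse-correlation matrix is downdated
#' with `syn_r`, the a-priori error `e_- = z - f_out` is formed, and
#' `phi <- phi - (P syn_r) e_-^T`. The readout `z` feeds back into the
#' network through the encoders `eta` (scaled by Q) during both training
#' and inference, so the loop is closed throughout.
#'
#' Unlike the rate-network trainers, the spiking trainer treats the run as
#' one continuous experiment: voltages and synaptic filters persist across
#' epochs (the target simply repeats), warmup applies to the first epoch
#' only, and validation continues from a snapshot of the current state
#' with updates switched off — the warm-up / train / freeze schedule of a
#' single long spiking session.
#'
#' @param layer A `spiking_layer`.
#' @param task A [task_data()] supplying the target (and optional input).
#' @param config A [training_config()].
#' @return List with `layer` (trained decoders), `history` and `P`.
#' @export
spiking_fit <- function(layer, task, config = training_config()) {
  check_that(inherits(layer, "spiking_layer"), "layer must be a spiking_layer")
  check_that(config$update_interval >= 1L, "update interval must be >= 1 step")
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

  k <- config$update_interval
  P <- init_P(config$alpha, params$n_neurons)
  state <- layer$state
  history <- new_history()

  for (epoch in seq_len(config$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    warm <- if (epoch == 1L) config$warmup_steps else 0L
    abs_err <- 0
    n_seen <- 0L
    n_upd <- 0L
    for (t in seq_len(T_len)) {
      state <- step_spiking(params, state, inputs[t, ])
      if (t > warm) {
        e <- compute_error(state$z, f_out[t, ])
        abs_err <- abs_err + sum(abs(e))
        n_seen <- n_seen + 1L
        if (is_update_step(t, warm, k)) {
          P <- rank_one_update(P, state$syn_r)
          n_upd <- n_upd + 1L
          params$phi <- update_output_weights(params$phi, e, P, state$syn_r)
        }
      }
    }
    train_mae <- abs_err / max(1L, n_seen * params$m_out)
    # freeze updates and let the network continue from where training left it
    val <- run_spiking_network(params, state, inputs, record = "z")
    val_mae <- mae(val$z, f_out)
    history <- append_history(history, epoch, train_mae, val_mae, n_upd,
                              proc.time()[["elapsed"]] - t0)
    if (early_stop_now(config$early_stopping, history$val_mae)) break
  }

  layer$params <- params
  layer$state <- state
  list(layer = layer, history = history, P = P)
}

#' Forward-pass prediction for a spiking layer
#'
#' @param object A `spiking_layer`.
#' @param task A [task_data()].
#' @param ... Unused.
#' @return List with `outputs` (T x M_out readout) and `mae`.
#' @export
predict.spiking_layer <- function(object, task, ...) {
  inputs <- task_input(task)
  out <- run_spiking_network(object$params, object$state, inputs, record = "z")
  list(outputs = out$z, mae = mae(out$z, task$f_out))
}
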