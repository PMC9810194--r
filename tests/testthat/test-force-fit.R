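test_that("one epoch of readout training equals the ridge solution", {
  # frozen feedback-independent rates: no-feedback layer, w_out(0) = 0
  alpha <- 2
  layer <- init_rate_network(40, "nofeedback_esn", m_in = 2, m_out = 1,
                             gain = 1.2, w_out_init = "zeros", seed = 3)
  task <- gen_sum_of_sines(n_steps = 200)
  fit <- force_fit(layer, task, training_config(epochs = 1, alpha = alpha))
  rates <- run_rate_network(layer$params, layer$state,
                            cbind(task$f_in, task$hint), record = "r")$r
  w_ridge <- solve(diag(alpha, 40) + crossprod(rates),
                   crossprod(rates, task$f_out))
  expect_lt(rel_frob(fit$layer$params$w_out, w_ridge), 1e-6)
})

test_that("a zero target with zero initial readout is a fixed point", {
  layer <- init_rate_network(20, "nofeedback_esn", m_in = 1, m_out = 1,
                             w_out_init = "zeros", seed = 5)
  T_len <- 100
  task <- task_data(f_in = matrix(1, T_len, 1), f_out = matrix(0, T_len, 1))
  fit <- force_fit(layer, task, training_config(epochs = 3))
  expect_true(all(fit$layer$params$w_out == 0))
  expect_true(all(fit$history$val_mae == 0))
})

test_that("updates are gated to every k-th step after warmup", {
  layer <- init_rate_network(30, "nofeedback_esn", m_in = 2, m_out = 1,
                             seed = 6)
  task <- gen_sum_of_sines(n_steps = 317)
  for (cfg in list(c(k = 50, warm = 0), c(k = 50, warm = 17),
                   c(k = 7, warm = 100))) {
    fit <- force_fit(layer, task,
                     training_config(epochs = 1, update_interval = cfg["k"],
                                     warmup_steps = cfg["warm"]),
                     trace_weights = TRUE)
    expect_identical(fit$history$n_updates,
                     as.integer((317 - cfg[["warm"]]) %/% cfg[["k"]]))
    tr <- attr(fit$history, "weight_trace")
    changed <- which(diff(c(sum(abs(layer$params$w_out)), tr)) != 0)
    scheduled <- seq_len(317)
    scheduled <- scheduled[scheduled > cfg[["warm"]] &
                             (scheduled - cfg[["warm"]]) %% cfg[["k"]] == 0]
    expect_true(all(changed %in% scheduled))
  }
})

test_that("training reduces validation error on the sum-of-sines task", {
  task <- gen_sum_of_sines()
  layer <- init_rate_network(150, "nofeedback_esn", m_in = 2, m_out = 1,
                             gain = 1.5, seed = 1)
  fit <- force_fit(layer, task, training_config(epochs = 5))
  expect_lt(fit$history$val_mae[5], fit$history$val_mae[1])
})

test_that("identical seeds and configs give bit-identical histories", {
  task <- gen_sum_of_sines(n_steps = 150)
  h <- lapply(1:2, function(i) {
    layer <- init_rate_network(25, "feedback_esn", m_in = 2, m_out = 1,
                               seed = 9)
    force_fit(layer, task, training_config(epochs = 3))$history
  })
  expect_identical(h[[1]]$val_mae, h[[2]]$val_mae)
  expect_identical(h[[1]]$train_mae, h[[2]]$train_mae)
})

test_that("early stopping halts once validation stops improving", {
  layer <- init_rate_network(20, "nofeedback_esn", m_in = 1, m_out = 1,
                             w_out_init = "zeros", seed = 5)
  task <- task_data(f_in = matrix(1, 80, 1), f_out = matrix(0, 80, 1))
  # val MAE is identically zero, so no epoch improves on the first
  fit <- force_fit(layer, task, training_config(
    epochs = 50, early_stopping = list(patience = 3, min_delta = 0)))
  expect_lt(nrow(fit$history), 50)
  expect_equal(nrow(fit$history), 4)  # first epoch + patience
})

test_that("recurrent FORCE training rejects multi-dimensional outputs", {
  layer <- init_rate_network(10, "nofeedback_esn", m_in = 1, m_out = 2,
                             seed = 1)
  task <- task_data(f_in = matrix(0, 50, 1), f_out = matrix(0, 50, 2))
  expect_error(force_fit(layer, task,
                         training_config(train_recurrent = TRUE)),
               "scalar")
})

test_that("constrained layers are rejected by the classic trainer", {
  layer <- init_rate_network(10, "constrained_esn", m_in = 1, seed = 1)
  task <- gen_sum_of_sines(n_steps = 50)
  expect_error(force_fit(layer, task), "bio_force_fit")
})

test_that("full-FORCE accepts hints, honours the zero-error fixed point", {
  # a hint channel of zeros is just an extra input dimension
  task <- gen_sum_of_sines(n_steps = 120)
  expect_true(all(task$hint == 0))
  layer <- init_rate_network(30, "nofeedback_esn", m_in = 2, m_out = 1,
                             w_out_init = "zeros", seed = 4)
  fit <- full_force_fit(layer, task, training_config(epochs = 1, seed = 2))
  expect_s3_class(fit$target_layer, "rate_layer")

  # identical target/task networks and a zero target: nothing to learn
  l0 <- init_rate_network(15, "nofeedback_esn", m_in = 1, m_out = 1,
                          w_out_init = "zeros", seed = 8)
  ztask <- task_data(f_in = matrix(0.2, 60, 1), f_out = matrix(0, 60, 1))
  fit0 <- full_force_fit(l0, ztask, training_config(epochs = 2),
                         target_layer = l0)
  expect_equal(fit0$layer$params$w_R, l0$params$w_R, tolerance = 1e-14)
  expect_true(all(fit0$layer$params$w_out == 0))

  # wrong layer kind is refused
  lf <- init_rate_network(10, "feedback_esn", m_in = 2, m_out = 1, seed = 1)
  expect_error(full_force_fit(lf, task), "nofeedback")
})

test_that("full-FORCE matches internal currents and learns the readout", {
  task <- gen_sum_of_sines(n_steps = 400)
  layer <- init_rate_network(120, "nofeedback_esn", m_in = 2, m_out = 1,
                             gain = 1.5, seed = 2)
  fit <- full_force_fit(layer, task, training_config(epochs = 4, seed = 3))
  expect_lt(fit$history$val_mae[4], fit$history$val_mae[1])
})

test_that("prediction reports the mean absolute error contract", {
  layer <- init_rate_network(10, "nofeedback_esn", m_in = 1, m_out = 1,
                             w_out_init = "zeros", seed = 1)
  task <- task_data(f_in = matrix(0, 40, 1),
                    f_out = matrix(0.5, 40, 1))
  pred <- predict(layer, task)
  expect_equal(pred$mae, 0.5)  # z is identically zero with zero readout
  expect_equal(dim(pred$outputs), c(40, 1))

  # MAE is invariant under permutation of time steps
  set.seed(2)
  z <- matrix(rnorm(40), ncol = 1)
  f <- matrix(rnorm(40), ncol = 1)
  p <- sample(40)
  expect_equal(mae(z, f), mae(z[p, , drop = FALSE], f[p, , drop = FALSE]))
})
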