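test_that("initialization honours layer kind, sparsity scaling and seeds", {
  # no-feedback variant forces w_F to zero, keeps a dense recurrent matrix
  l <- init_rate_network(4, "nofeedback_esn", sparsity = 1, gain = 1.5,
                         seed = 7)
  expect_true(all(l$params$w_F == 0))
  expect_equal(dim(l$params$w_R), c(4, 4))

  # constrained variant: no self-loops
  mask <- gen_connectome(4, 1, seed = 3)
  lc <- init_rate_network(4, "constrained_esn", mask = mask, seed = 7)
  expect_true(all(diag(lc$params$w_R) == 0))
  expect_false(any(diag(lc$params$mask)))

  # recurrent entries ~ N(0, g^2/(p N)) on Bernoulli(p) support
  lb <- init_rate_network(400, "nofeedback_esn", sparsity = 0.1, gain = 1.5,
                          seed = 1)
  nz <- lb$params$w_R[lb$params$w_R != 0]
  expect_equal(sd(nz), 1.5 / sqrt(0.1 * 400), tolerance = 0.1)
  expect_equal(mean(lb$params$w_R != 0), 0.1, tolerance = 0.1)

  # identical seeds give bit-identical weights
  l1 <- init_rate_network(30, "feedback_esn", seed = 42)
  l2 <- init_rate_network(30, "feedback_esn", seed = 42)
  expect_identical(l1$params$w_R, l2$params$w_R)
  expect_identical(l1$params$w_out, l2$params$w_out)

  expect_error(init_rate_network(4, "nosuchkind"))
  expect_error(init_rate_network(4, "feedback_esn", sparsity = 0),
               "sparsity")
  expect_error(init_rate_network(4, "feedback_esn", mask = matrix(TRUE, 3, 3)),
               "mask")
  expect_error(init_rate_network(4, "feedback_esn", tau = 0.5, dt = 1),
               "tau")
})

test_that("forward step reproduces the leaky Euler update", {
  # zero fixed point
  l <- tiny_rate_layer(5, gain = 0, w_out_init = "zeros")
  l$params$w_in[] <- 0
  st <- step_rate(l$params, l$state, 0)
  expect_identical(st$x, rep(0, 5))
  expect_identical(st$z, 0)

  # memoryless limit tau = dt: decay cancels exactly, for arbitrary weights
  lm <- tiny_rate_layer(6, kind = "feedback_esn", m_in = 2, tau = 1, dt = 1,
                        seed = 9)
  st0 <- lm$state
  st0$x <- rnorm(6); st0$r <- tanh(st0$x)
  st0$z <- as.numeric(crossprod(lm$params$w_out, st0$r))
  f <- c(0.3, -0.8)
  st1 <- step_rate(lm$params, st0, f)
  expected <- as.numeric(crossprod(lm$params$w_in, f) +
                           crossprod(lm$params$w_R, st0$r) +
                           crossprod(lm$params$w_F, st0$z))
  expect_equal(st1$x, expected, tolerance = 1e-15)

  # single Euler step: N=1, tau=10*dt, unit drive -> x = 0.1
  l1 <- init_rate_network(1, "nofeedback_esn", m_in = 1, gain = 0, tau = 10,
                          dt = 1, w_out_init = "zeros", seed = 1)
  l1$params$w_in[] <- 1
  s <- step_rate(l1$params, l1$state, 1)
  expect_equal(s$x, 0.1)

  # state invariants r = H(x), z = w_out^T r
  lr <- tiny_rate_layer(8, m_in = 1, seed = 2)
  s2 <- step_rate(lr$params, lr$state, 0.5)
  expect_identical(s2$r, tanh(s2$x))
  expect_identical(s2$z, as.numeric(crossprod(lr$params$w_out, s2$r)))

  expect_error(step_rate(lr$params, lr$state, c(1, 2)), "length")
})

test_that("non-finite currents abort with the step index", {
  l <- init_rate_network(4, "nofeedback_esn", m_in = 1, gain = 3, tau = 1,
                         dt = 1, activation = "identity", seed = 5)
  st <- l$state
  st$x <- rep(1e300, 4)
  st$r <- st$x
  expect_error(run_rate_network(l$params, st, n_steps = 50),
               "non-finite currents at step")
})

test_that("running a network is deterministic and decays when subcritical", {
  l <- tiny_rate_layer(40, gain = 0.5, seed = 11)
  st <- l$state
  st$x <- local({ set.seed(4); rnorm(40) })
  st$r <- tanh(st$x)
  out <- run_rate_network(l$params, st, n_steps = 500, record = c("x", "z"))
  expect_lt(sqrt(sum(out$state$x^2)), sqrt(sum(st$x^2)))

  out2 <- run_rate_network(l$params, st, n_steps = 500, record = c("x", "z"))
  expect_identical(out$x, out2$x)

  # empty input: no steps, state untouched
  empty <- run_rate_network(l$params, st, n_steps = 0, record = "z")
  expect_identical(empty$state, st)
  expect_equal(nrow(empty$z), 0)
})

test_that("halving the step shows first-order convergence to the flow", {
  # fixed tau, smooth input; reference at dt/100
  run_endpoint <- function(dt, t_total = 50) {
    l <- init_rate_network(8, "nofeedback_esn", m_in = 1, gain = 1.2,
                           tau = 5, dt = dt, seed = 3)
    run_rate_network(l$params, l$state, sine_input(t_total, dt),
                     record = character(0))$state$x
  }
  ref <- run_endpoint(0.01)
  e1 <- sqrt(sum((run_endpoint(1) - ref)^2))
  e2 <- sqrt(sum((run_endpoint(0.5) - ref)^2))
  expect_gt(e1 / e2, 1.8)  # Euler: halving dt about halves the error
})

test_that("masked-out recurrent entries stay exactly zero", {
  mask <- gen_connectome(20, 0.3, seed = 6)
  l <- init_rate_network(20, "constrained_esn", m_in = 0, sparsity = 0.3,
                         mask = mask, seed = 8)
  expect_true(all(l$params$w_R[!mask] == 0))
  out <- run_rate_network(l$params, l$state, n_steps = 100, record = "z")
  expect_true(all(l$params$w_R[!mask] == 0))

  # and through constrained training
  rec <- gen_synthetic_recording(n_neurons = 20, n_steps = 100, dt = 0.25,
                                 seed = 5)
  lc <- init_rate_network(20, "constrained_esn", m_in = 0, sparsity = 0.2,
                          gain = 0.8, tau = 1, dt = 0.25, mask = rec$mask,
                          w_out_init = "zeros", seed = 2)
  fit <- bio_force_fit(lc, rec$task, training_config(epochs = 2))
  expect_true(all(fit$effective_weights[!rec$mask] == 0))
})
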