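params <- scenario_params()

test_that("voltage traces relax exponentially toward the held potential", {
  # fixed point
  expect_equal(update_voltage_traces(-55, -55, 0.1, 10), -55)
  # step response: u(t) = V1 * (1 - exp(-t/tau)) from u(0) = 0
  u <- 0; V1 <- -40; tau <- 10; dt <- 0.1
  for (k in 1:500) u <- update_voltage_traces(u, V1, dt, tau)
  expect_lt(abs(u - V1 * (1 - exp(-50 / tau))), 1e-8)
  # fast-filter limit: tau = dt/100 tracks V within 1%
  u2 <- update_voltage_traces(-70, -50, 0.1, 0.001)
  expect_lt(abs(u2 - (-50)) / 20, 0.01)
})

test_that("spike traces decay and jump by alpha per spike", {
  # pure decay
  x <- 2
  for (k in 1:100) x <- update_spike_traces(x, 0, 0.1, 15, alpha = 1)
  expect_equal(x, 2 * exp(-10 / 15), tolerance = 1e-12)
  # one spike from zero: x(t0 + D) = alpha * exp(-D / tau)
  x <- update_spike_traces(0, 1, 0.1, 15, alpha = 1)
  for (k in 1:50) x <- update_spike_traces(x, 0, 0.1, 15, alpha = 1)
  expect_equal(x, exp(-5 / 15), tolerance = 1e-12)
})

test_that("stationary mean of a Poisson-driven spike trace is alpha*r*tau", {
  set.seed(4)
  tau <- 15; alpha <- 1; dt <- 0.1; r <- 0.02   # spk/ms
  x <- 0; acc <- 0; n <- 200000
  for (k in seq_len(n)) {
    x <- update_spike_traces(x, stats::rpois(1, r * dt), dt, tau, alpha)
    acc <- acc + x
  }
  expect_lt(abs(acc / n - alpha * r * tau) / (alpha * r * tau), 0.05)
})

test_that("the closed-form potentiation integral matches numeric quadrature", {
  set.seed(8)
  for (k in 1:40) {
    v0 <- runif(1, -75, -40); V <- runif(1, -75, -35); dt <- 0.1
    tx <- runif(1, 3, 20); tv <- runif(1, 3, 12)
    thp <- -49; thd <- runif(1, -70, -55)
    f <- function(t) {
      v <- V + (v0 - V) * exp(-t / tv)
      exp(-t / tx) * max(V - thp, 0) * max(v - thd, 0)
    }
    num <- stats::integrate(Vectorize(f), 0, dt, rel.tol = 1e-12)$value
    cf <- ltp_window_integral(v0, V, dt, tx, tv, thp, thd)
    expect_lt(abs(cf - num), 1e-12 + 1e-8 * abs(num))
  }
})

test_that("rectifiers kill plasticity when all voltages are subthreshold", {
  W <- matrix(0.01, 3, 4)
  r <- voltage_stdp_step(W, NULL, pre_spikes = c(1, 0, 2, 1),
                         x_pre = rep(1, 4),
                         u_post = rep(-75, 3), v_post = rep(-75, 3),
                         V_post = rep(-75, 3), dt = 0.1, params = params,
                         tau_x = params$tau_x_EE)
  expect_equal(r$W, W)
})

test_that("a presynaptic spike depresses by exactly A_LTD * (u - theta_LTD)", {
  W <- matrix(0.01, 1, 1)
  u <- params$theta_LTD + 1    # 1 mV above the depression threshold
  r <- voltage_stdp_step(W, NULL, pre_spikes = 1, x_pre = 0,
                         u_post = u, v_post = -75, V_post = -75,
                         dt = 0.1, params = params)
  expect_equal(r$W[1, 1], 0.01 - params$A_LTD * 1, tolerance = 1e-15)
})

test_that("weight updates clip to bounds and report the clip count", {
  W <- matrix(1e-4, 2, 2)
  r <- voltage_stdp_step(W, NULL, pre_spikes = c(5, 5), x_pre = c(0, 0),
                         u_post = c(-40, -40), v_post = c(-75, -75),
                         V_post = c(-75, -75), dt = 0.1, params = params,
                         bounds = c(0, 1))
  expect_true(all(r$W >= 0))
  expect_equal(r$clipped, 4L)
})

test_that("inhibitory rule balances at y_E = 2*alpha*r0*tau_y", {
  offset <- 2 * params$alpha * params$r_0 * params$tau_y
  W <- matrix(0.1, 2, 2)
  r <- inhibitory_plasticity_step(W, NULL, pre_spikes = c(1, 1),
                                  post_spikes = c(0, 0),
                                  y_post = rep(offset, 2), y_pre = c(0, 0),
                                  params = params)
  expect_equal(r$W, W)
  # silent postsynaptic neuron: net depression
  r2 <- inhibitory_plasticity_step(W, NULL, pre_spikes = c(1, 1),
                                   post_spikes = c(0, 0),
                                   y_post = c(0, 0), y_pre = c(0, 0),
                                   params = params)
  expect_true(all(r2$W < W))
  # postsynaptic spike potentiates via the presynaptic trace
  r3 <- inhibitory_plasticity_step(W, NULL, pre_spikes = c(0, 0),
                                   post_spikes = c(1, 1),
                                   y_post = c(0, 0), y_pre = c(0.5, 0.5),
                                   params = params)
  expect_true(all(r3$W > W))
})

test_that("normalization restores incoming sums exactly and handles edge cases", {
  set.seed(21)
  n <- 30
  adj <- matrix(runif(n * n) < 0.4, n, n); diag(adj) <- FALSE
  W0 <- matrix(runif(n * n, 0, 0.02) * adj, n, n)
  K <- rowSums(W0)
  Wp <- W0 + matrix(rnorm(n * n, 0, 0.004), n, n) * adj
  r <- normalize_incoming(Wp, K, adj)
  expect_lt(max(abs(rowSums(r$W) - K)), 1e-10)

  # already-normalized matrix is unchanged
  r2 <- normalize_incoming(W0, K, adj)
  expect_equal(r2$W, W0, tolerance = 1e-14)

  # single incoming edge: the weight becomes exactly K
  adj1 <- matrix(FALSE, 2, 2); adj1[1, 2] <- TRUE
  W1 <- matrix(0, 2, 2); W1[1, 2] <- 0.9
  r3 <- normalize_incoming(W1, K = c(0.5, 0), adj1)
  expect_equal(r3$W[1, 2], 0.5)
  expect_equal(r3$residual[2], 0)   # no incoming edges: skipped
})

test_that("scenario integration is invariant to the step size", {
  sc <- make_plasticity_scenario(list(T_ms = 200, seg_ms = 10, seed = 5,
                                      pre_rate_hz = 40, post_rate_hz = 40))
  a <- run_plasticity_scenario(sc, 0.1, params, rule = "stdp")
  b <- run_plasticity_scenario(sc, 0.01, params, rule = "stdp")
  expect_gt(abs(a$dW_ltd), 0)       # the scenario actually exercises LTD
  expect_lt(abs(a$dW_ltd - b$dW_ltd) / abs(b$dW_ltd), 1e-9)
  expect_lt(abs(a$dW - b$dW) / abs(b$dW), 1e-9)

  ai <- run_plasticity_scenario(sc, 0.1, params, rule = "inhib",
                                d = params$delay$EI)
  bi <- run_plasticity_scenario(sc, 0.01, params, rule = "inhib",
                                d = params$delay$EI)
  expect_lt(abs(ai$dW - bi$dW) / max(abs(bi$dW), 1e-12), 1e-9)
})

test_that("scenario runner matches the dense fine-grid reference", {
  sc <- make_plasticity_scenario(list(T_ms = 200, seg_ms = 10, seed = 17,
                                      pre_rate_hz = 40, post_rate_hz = 40))
  impl <- run_plasticity_scenario(sc, 0.1, params, rule = "stdp")
  ref <- stdp_reference_dense(sc, 0.001, params)
  expect_lt(abs(impl$dW - ref$dW) / abs(ref$dW), 1e-4)

  impl_i <- run_plasticity_scenario(sc, 0.1, params, rule = "inhib",
                                    d = params$delay$EI)
  ref_i <- inhib_reference_dense(sc, 0.001, params)
  expect_lt(abs(impl_i$dW - ref_i$dW) / max(abs(ref_i$dW), 1e-12), 1e-6)
})
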