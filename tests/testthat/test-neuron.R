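ep <- clock_config("desk")$neuron$E
ip <- clock_config("desk")$neuron$I
syn <- clock_config("desk")$synapse

test_that("resting potential is a fixed point of the membrane equations", {
  st <- neuron_state_exc(ep)
  r <- step_excitatory(st, Q = 0, dt = 0.1, ep)
  # the exponential term at rest is exp((E_L - V_T0)/Delta_T) ~ e^-9: negligible
  expect_lt(abs(r$state$V - ep$E_L), 1e-3)
  expect_false(r$spike)

  sti <- neuron_state_inh(ip)
  ri <- step_inhibitory(sti, Q = 0, dt = 0.1, ip)
  expect_equal(ri$state$V, ip$E_L)
})

test_that("subthreshold relaxation matches the closed-form exponential", {
  # start 5 mV above rest; threshold moved far away so the spike-initiation
  # term is truly negligible and the pure leak pathway is what is measured
  epf <- ep; epf$V_T0 <- 0
  V0 <- epf$E_L + 5
  st <- neuron_state_exc(epf, V = V0)
  dt <- 0.1
  for (k in 1:300) st <- step_excitatory(st, 0, dt, epf)$state
  expected <- epf$E_L + 5 * exp(-30 / epf$tau_m)
  expect_lt(abs(st$V - expected) / abs(5 * exp(-30 / epf$tau_m)), 1e-6)

  sti <- neuron_state_inh(ip, V = ip$E_L + 5)
  for (k in 1:300) sti <- step_inhibitory(sti, 0, dt, ip)$state
  expect_equal(sti$V, ip$E_L + 5 * exp(-30 / ip$tau_m), tolerance = 1e-8)
})

test_that("constant suprathreshold drive spikes periodically, matching a fine-grid reference", {
  run_period <- function(dt, params, Q) {
    st <- neuron_state_inh(params)
    spikes <- c()
    t <- 0
    for (k in seq_len(round(400 / dt))) {
      r <- step_inhibitory(st, Q, dt, params)
      st <- r$state
      t <- t + dt
      if (r$spike) spikes <- c(spikes, t)
    }
    mean(diff(spikes))
  }
  Q <- 1.2  # mV/ms, drives V_inf to -38 > threshold
  p_coarse <- run_period(0.1, ip, Q)
  p_fine <- run_period(0.001, ip, Q)
  expect_lt(abs(p_coarse - p_fine) / p_fine, 0.02)
})

test_that("threshold crossing resets and enters the refractory period", {
  st <- neuron_state_inh(ip, V = ip$E_L)
  r <- step_inhibitory(st, Q = 10, dt = 0.1, ip)  # massive drive
  # drive until spike
  n <- 0
  while (!r$spike && n < 1000) { r <- step_inhibitory(r$state, 10, 0.1, ip); n <- n + 1 }
  expect_true(r$spike)
  expect_equal(r$state$V, ip$V_reset)
  expect_gt(r$state$refrac, 0)
  # during refractoriness the membrane stays clamped
  r2 <- step_inhibitory(r$state, 10, 0.1, ip)
  expect_equal(r2$state$V, ip$V_reset)
  expect_false(r2$spike)
})

test_that("a single spike produces the analytic conductance kernel", {
  w <- 0.37
  st <- conductance_state(1)
  dt <- 0.1
  st <- update_conductances(st, w_exc = w, w_inh = 0, dt = dt, syn = syn)
  kernel <- function(t) {
    syn$c_K * (exp(-t / syn$tau_d_exc) - exp(-t / syn$tau_r_exc)) /
      (syn$tau_d_exc - syn$tau_r_exc)
  }
  # delivery at the step boundary: K(0) = 0
  expect_lt(abs(conductances(st, syn)$exc - w * kernel(0)), 1e-12)
  for (k in 1:200) {
    st <- update_conductances(st, 0, 0, dt, syn)
    expect_lt(abs(conductances(st, syn)$exc - w * kernel(k * dt)), 1e-8)
  }
})

test_that("conductances superpose linearly and channels stay segregated", {
  dt <- 0.1
  # two spikes, 5 ms apart
  s2 <- conductance_state(1)
  s2 <- update_conductances(s2, 1, 0, dt, syn)
  for (k in 1:49) s2 <- update_conductances(s2, 0, 0, dt, syn)
  s2 <- update_conductances(s2, 1, 0, dt, syn)
  # superposition: single-spike copies
  k1 <- conductance_state(1); k1 <- update_conductances(k1, 1, 0, dt, syn)
  for (k in 1:50) k1 <- update_conductances(k1, 0, 0, dt, syn)
  k2 <- conductance_state(1); k2 <- update_conductances(k2, 1, 0, dt, syn)
  for (k in 1:30) {
    s2 <- update_conductances(s2, 0, 0, dt, syn)
    k1 <- update_conductances(k1, 0, 0, dt, syn)
    k2 <- update_conductances(k2, 0, 0, dt, syn)
    expect_equal(conductances(s2, syn)$exc,
                 conductances(k1, syn)$exc + conductances(k2, syn)$exc,
                 tolerance = 1e-12)
  }
  # inhibitory spikes never touch the excitatory channel
  si <- conductance_state(1)
  si <- update_conductances(si, 0, 5, dt, syn)
  expect_equal(conductances(si, syn)$exc, 0)
  expect_gte(conductances(si, syn)$inh + 1e-15, 0)

  # no input ever -> identically zero
  s0 <- conductance_state(3)
  for (k in 1:10) s0 <- update_conductances(s0, numeric(3), numeric(3), dt, syn)
  expect_equal(conductances(s0, syn)$exc, numeric(3))
})

test_that("synaptic current pulls toward the channel reversal potentials", {
  g <- list(exc = 0.1, inh = 0)
  expect_gt(synaptic_current(g, -70, syn), 0)   # excitation depolarizes
  g <- list(exc = 0, inh = 0.1)
  expect_lt(synaptic_current(g, -60, syn), 0)   # inhibition below E_rev pulls down
  expect_gt(synaptic_current(g, -80, syn), 0)   # but reverses below E_rev_inh
})
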