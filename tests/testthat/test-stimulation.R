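test_that("sequential schedule has the documented period and windows", {
  cfg <- clock_config("full")
  sch <- sequential_schedule(cfg, T_ms = 2000)
  expect_equal(sch$period_ms, 30 * (9 + 6))   # 450 ms

  # cluster 0 is excited during [0, 9), in a gap at t = 10
  r0 <- rate_at(sch, "E", 1, 5)
  expect_equal(unname(r0["exc"]), 22500)
  expect_equal(unname(r0["inh"]), 0)
  r0g <- rate_at(sch, "E", 1, 10)
  expect_equal(unname(r0g["exc"]), 0)
  expect_equal(unname(r0g["inh"]), 4500)

  # cluster 1 (neurons 81..160) is excited during [15, 24)
  r1 <- rate_at(sch, "E", 100, 16)
  expect_equal(unname(r1["exc"]), 22500)

  # inhibitory neurons are driven throughout
  expect_equal(unname(rate_at(sch, "I", 3, 123.4)["exc"]),
               cfg$protocol$rates$excI)
})

test_that("phase-1 complementarity: every E neuron gets exactly one drive", {
  cfg <- clock_config("desk")
  sch <- sequential_schedule(cfg, T_ms = cfg$protocol$t_stim * 200)
  ts <- seq(0.05, sch$period_ms - 0.05, by = 2.45)
  for (nr in c(1L, 55L, 200L)) {
    for (t in ts) {
      r <- rate_at(sch, "E", nr, t)
      expect_true(xor(r["exc"] > 0, r["inh"] > 0),
                  info = sprintf("neuron %d t %.2f", nr, t))
    }
  }
})

test_that("single-cluster degenerate schedule cycles every t_stim + t_gap", {
  cfg <- clock_config("desk", network = list(N_E = 20L, N_C = 1L, N_I = 10L))
  sch <- sequential_schedule(cfg, 100)
  expect_equal(sch$period_ms, 15)
  expect_equal(unname(rate_at(sch, "E", 1, 3)["exc"]), 22500)
  expect_equal(unname(rate_at(sch, "E", 1, 12)["inh"]), 4500)
})

test_that("spontaneous schedule is constant per population", {
  cfg <- clock_config("desk")
  sch <- spontaneous_schedule(cfg, 500)
  expect_equal(unname(rate_at(sch, "E", 7, 321)["exc"]), cfg$protocol$rates$exc2E)
  expect_equal(unname(rate_at(sch, "I", 7, 12)["exc"]), cfg$protocol$rates$excI)
  expect_equal(unname(rate_at(sch, "E", 7, 12)["inh"]), 0)
  # zero duration -> empty schedule
  s0 <- spontaneous_schedule(cfg, 0)
  expect_equal(s0$duration_ms, 0)
  expect_equal(unname(rate_at(s0, "E", 1, 0)["exc"]), 0)
})

test_that("read-out schedule follows the element windows", {
  cfg <- clock_config("full")
  sq <- sequence_spec(c("A", "B", "C", "B", "A"), t_element = 75, lead = 25)
  expect_equal(presentation_duration(sq), 400)
  sch <- readout_schedule(sq, cfg, n_repeats = 3)
  expect_equal(sch$period_ms, 450)

  # element 0 = A: supervisor 1 hot in [25, 100)
  expect_equal(unname(rate_at(sch, "S", 1, 30)["exc"]), 10000)
  expect_equal(unname(rate_at(sch, "S", 1, 120)["exc"]), 1000)
  # A appears again at position 4: [325, 400)
  expect_equal(unname(rate_at(sch, "S", 1, 330)["exc"]), 10000)
  # B's supervisor (neuron 2) hot in window 1 and 3
  expect_equal(unname(rate_at(sch, "S", 2, 110)["exc"]), 10000)
  expect_equal(unname(rate_at(sch, "S", 2, 260)["exc"]), 10000)
  expect_equal(unname(rate_at(sch, "S", 2, 30)["exc"]), 1000)
  # interneurons constant
  expect_equal(unname(rate_at(sch, "H", 1, 200)["exc"]), 1000)
  # periodic repetition
  expect_equal(unname(rate_at(sch, "S", 1, 450 + 30)["exc"]), 10000)
})

test_that("presentation longer than the clock cycle is rejected", {
  cfg <- clock_config("full")
  sq <- sequence_spec(rep(c("A", "B"), 3), t_element = 75, lead = 25)  # 475 ms
  expect_error(readout_schedule(sq, cfg, 1), "exceed")
})

test_that("empty sequence gives lead time only at baseline rates", {
  cfg <- clock_config("full")
  sq <- sequence_spec(character(0), t_element = 75, lead = 25)
  sch <- readout_schedule(sq, cfg, 1)
  expect_equal(unname(rate_at(sch, "S", 1, 10)["exc"]), 1000)
  expect_equal(unname(rate_at(sch, "S", 1, 300)["exc"]), 1000)
})

test_that("Poisson sampling matches the scheduled intensity", {
  cfg <- clock_config("desk", network = list(N_E = 20L, N_C = 1L, N_I = 2L))
  # 9 ms window at 22.5k spk/s: mean count 202.5 per neuron per round
  sch <- sequential_schedule(cfg, 15 * 40)   # 40 rounds
  ev <- sample_poisson(sch, dt = 0.1, seed = 11)
  exc <- ev[ev$channel == "exc" & ev$population == "E" & ev$neuron == 1, ]
  per_round <- tapply(exc$count, floor(exc$t_ms / 15), sum)
  expect_length(per_round, 40)
  mu <- 22500 / 1000 * 9
  se <- sqrt(mu / 40)
  expect_lt(abs(mean(per_round) - mu), 3 * se)

  # determinism and the zero-rate case
  ev2 <- sample_poisson(sch, dt = 0.1, seed = 11)
  expect_identical(ev, ev2)
  cfg0 <- clock_config("desk", protocol = list(rates = list(exc1E = 0, inhE = 0,
                                                            excI = 0)))
  s0 <- sequential_schedule(cfg0, 150)
  expect_equal(nrow(sample_poisson(s0, 0.1, seed = 1)), 0L)
})

test_that("full-scale round arithmetic: 8000 rounds per hour", {
  cfg <- clock_config("full")
  P <- cfg$network$N_C * (cfg$protocol$t_stim + cfg$protocol$t_gap)
  expect_equal(floor(3600 * 1000 / P), 8000)
})
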