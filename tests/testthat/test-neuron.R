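test_that("the resting state (-70, -14) is a fixed point and attracts nearby states", {
  st <- izh_step(neuron_state(v = -70, u = -14), neuron_params(), I_total = 0,
                 dt = 0.1)
  expect_equal(st$v, -70)
  expect_equal(st$u, -14)
  expect_false(st$spiked_now)

  # numerical convergence from a nearby start, via the engine
  net <- new_network(
    data.frame(id = "N1", a = 0.02, b = 0.2, c = -65, d = 8, g = 20, D = 0,
               bias = 0, stringsAsFactors = FALSE), empty_synapses())
  net$state$v <- -65
  net$state$u <- -13
  run <- run_network(net, NULL, duration = 500, sample_period = 0)
  expect_equal(run$net$state$v, -70, tolerance = 1e-6)
  expect_equal(run$net$state$u, -14, tolerance = 1e-6)
})

test_that("threshold crossing resets v to c, increments u by d and the trace by 1", {
  # a state that integrates past 30 mV in one step under strong current
  st <- neuron_state(v = 29, u = -10, s_post = 0.2)
  out <- izh_step(st, neuron_params(), I_total = 200, dt = 0.1)
  expect_true(out$spiked_now)
  expect_equal(out$v, -65)
  expect_equal(out$s_post, 1.2)
  # u reset is u_post + d where u_post is the integrated value
  v_cross <- 29 + 0.1 * (0.04 * 29^2 + 5 * 29 + 140 - (-10) + 200)
  expect_equal(out$u, (-10 + 0.1 * 0.02 * (0.2 * v_cross - (-10))) + 8)
  expect_error(izh_step(neuron_state(v = NaN), neuron_params(), 0, 0.1),
               "non-finite")
})

test_that("no reported membrane potential is ever >= 30 after a step", {
  net <- build_motif("chain2", init_w = 1, D = 5.5)
  run <- run_network(net, pulse_train("N1"), duration = 5000)
  expect_true(all(run$net$state$v < 30))
  st <- neuron_state(v = 29.9, u = -16)
  for (k in 1:2000) {
    st <- izh_step(st, neuron_params(), I_total = 10, dt = 0.1)
    expect_lt(st$v, 30)
  }
})

test_that("spike rate under constant current is non-decreasing in I", {
  counts <- vapply(c(4, 6, 8, 10, 12), function(I)
    length(run_single_neuron(I, duration = 1000)), numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[5], counts[1])
})

test_that("halving dt changes 1-s spike counts by at most one spike", {
  n1 <- length(run_single_neuron(10, 1000, dt = 0.1))
  n2 <- length(run_single_neuron(10, 1000, dt = 0.05))
  expect_lte(abs(n1 - n2), 1)
  # independent fine-step reference integration
  n_ref <- izh_euler_spike_count(10, 1000, dt = 0.01)
  expect_lte(abs(n1 - n_ref), 1)
})

test_that("noise current has the requested first two moments and is reproducible", {
  expect_identical(noise_current(0, n = 10), rep(0, 10))
  set.seed(42)
  x <- noise_current(5.5, n = 1e6)
  expect_lt(abs(mean(x)), 4 * sqrt(5.5 / 1e6))
  expect_lt(abs(var(x) - 5.5) / 5.5, 0.02)
  set.seed(99)
  a <- noise_current(2, n = 100)
  set.seed(99)
  b <- noise_current(2, n = 100)
  expect_identical(a, b)
  expect_error(noise_current(-1), "variance")
})

test_that("the driving current is the plain sum of its three components", {
  expect_identical(total_current(0, 0, 0), 0)
  expect_identical(total_current(1.5, -2.0, 40.0), 39.5)
  expect_error(total_current(Inf, 0, 0))
})

test_that("a 3-ms square pulse delivers its amplitude only inside the window", {
  # one pulse per 100 ms; a single suprathreshold pulse evokes exactly one
  # spike shortly after onset, and none elsewhere
  spikes <- run_single_neuron(0, 1000)
  expect_length(spikes, 0)
  net <- new_network(
    data.frame(id = "N1", a = 0.02, b = 0.2, c = -65, d = 8, g = 20, D = 0,
               bias = 0, stringsAsFactors = FALSE), empty_synapses())
  run <- run_network(net, pulse_train("N1", amplitude = 15), duration = 1000)
  expect_equal(nrow(run$spikes), 10)
  expect_true(all((run$spikes$time_ms %% 100) < 10))
})
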