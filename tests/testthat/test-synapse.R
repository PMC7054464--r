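test_that("the active fraction decays as a pure exponential between arrivals", {
  p <- synapse_params()
  s <- synapse("N1", "N2", w = 0.5)
  s$y <- 0.5
  s$x <- 0.5
  for (k in 1:100) s <- tm_step(s, p, dt = 0.1, FALSE)
  expect_equal(s$y, 0.5 * exp(-1), tolerance = 1e-12)
})

test_that("transmitter release conserves synaptic resources", {
  p <- synapse_params()
  s <- synapse("N1", "N2", w = 0.5)
  s0 <- s
  s <- tm_step(s, p, dt = 0.1, spike_arrived = TRUE)
  jump <- s$y - s0$y * exp(-0.1 / p$tau_I)
  expect_lte(jump, 1)
  expect_gt(jump, 0)
  # what entered y left x (up to the recovery inflow this step, here ~0)
  expect_equal(s$x + s$y, 1, tolerance = 1e-12)
  # x + y + inactive = 1 at every step of a random train
  set.seed(3)
  for (k in 1:2000) {
    s <- tm_step(s, p, dt = 0.1, spike_arrived = runif(1) < 0.05)
    z <- 1 - s$x - s$y
    expect_gte(s$x, -1e-12); expect_lte(s$x, 1 + 1e-12)
    expect_gte(s$y, -1e-12); expect_gte(z, -1e-12)
  }
})

test_that("the stepped 10-Hz steady state matches the inter-spike recursion within 1%", {
  p <- synapse_params()
  s <- synapse("N1", "N2", w = 1)
  jump <- NA_real_
  for (pulse in 1:21) {
    for (k in 1:999) s <- tm_step(s, p, dt = 0.1, FALSE)
    y_pre <- s$y * exp(-0.1 / p$tau_I)
    s <- tm_step(s, p, dt = 0.1, TRUE)
    jump <- s$y - y_pre
  }
  fp <- tm_periodic_fixed_point(100, p)
  expect_equal(jump, fp$release, tolerance = 0.01)
})

test_that("synaptic current is the signed weighted sum g * w * y", {
  expect_identical(synaptic_current(list()), 0)
  e <- synapse("N1", "N3", w = 0.5, g = 20); e$y <- 0.1
  expect_equal(synaptic_current(list(e)), 1.0)
  i <- synapse("N2", "N3", w = 1, g = -20, plastic = FALSE); i$y <- 0.05
  expect_equal(synaptic_current(list(e, i)), 0)
})

test_that("single-pairing weight changes match the closed forms to 1e-12", {
  p <- synapse_params()
  # pre arrival 10 ms before post: dw = lambda (1 - w) e^(-1)
  w_pot <- stdp_replay(arrival_times = 10, post_times = 20, w0 = 0, params = p)
  expect_equal(w_pot, 0.001 * exp(-1), tolerance = 1e-12)
  # post 10 ms before pre arrival: dw = -lambda alpha w e^(-1)
  w_dep <- stdp_replay(arrival_times = 20, post_times = 10, w0 = 0.5, params = p)
  expect_equal(w_dep - 0.5, -0.001 * 5 * 0.5 * exp(-1), tolerance = 1e-12)
  # trivial no-trace and soft-bound cases
  expect_equal(stdp_replay(numeric(0), 10, 0.3, p), 0.3)
  expect_equal(stdp_replay(10, numeric(0), 0.3, p), 0.3)
  expect_equal(stdp_replay(10, 20, 1, p), 1)   # (1 - w) clamps potentiation
  expect_equal(stdp_replay(20, 10, 0, p), 0)   # multiplicative floor
})

test_that("stdp update operations respect traces, bounds and plasticity flags", {
  p <- synapse_params()
  s <- synapse("N1", "N3", w = 0.4)
  s$s_pre <- exp(-1)
  expect_equal(stdp_on_post_spike(s, p)$w, 0.4 + 0.001 * 0.6 * exp(-1))
  expect_equal(stdp_on_pre_arrival(s, p, s_post_value = 2)$w,
               0.4 - 0.001 * 5 * 0.4 * 2)
  fixed <- synapse("N1", "N3", w = 0.4, plastic = FALSE)
  fixed$s_pre <- 5
  expect_equal(stdp_on_post_spike(fixed, p)$w, 0.4)
  expect_equal(stdp_on_pre_arrival(fixed, p, 5)$w, 0.4)
})

test_that("depression/potentiation asymmetry at w = 0.5 equals alpha exactly", {
  p <- synapse_params()
  pot <- stdp_replay(10, 20, 0.5, p) - 0.5
  dep <- 0.5 - stdp_replay(20, 10, 0.5, p)
  expect_equal(dep / pot, p$alpha * 0.5 / (1 - 0.5), tolerance = 1e-12)
})

test_that("weights stay inside [0, 1] for arbitrary dense event sequences", {
  set.seed(7)
  p <- synapse_params(lambda = 0.2, alpha = 5) # exaggerated rate stresses bounds
  for (i in 1:25) {
    tr <- random_trains(n_max = 50, horizon_ms = 100)
    for (w0 in c(0, 0.5, 1)) {
      w <- stdp_replay(tr$arr, tr$post, w0, p)
      expect_gte(w, 0)
      expect_lte(w, 1)
    }
  }
})
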