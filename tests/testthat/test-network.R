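test_that("motif builders produce the documented topologies and delays", {
  sc <- build_motif("shortcut")
  expect_equal(nrow(sc$neurons), 3)
  expect_equal(nrow(sc$synapses), 3)
  d31 <- sc$synapses$delay_ms[sc$synapses$pre == "N1" & sc$synapses$post == "N3"]
  d21 <- sc$synapses$delay_ms[sc$synapses$pre == "N1" & sc$synapses$post == "N2"]
  d32 <- sc$synapses$delay_ms[sc$synapses$pre == "N2" & sc$synapses$post == "N3"]
  expect_lt(d31, d21 + d32)
  expect_true(all(sc$synapses$plastic))
  expect_true(all(sc$synapses$g == 20))

  expect_equal(nrow(build_motif("chain2")$synapses), 1)
  c3 <- build_motif("chain3")
  expect_equal(c3$synapses$delay_ms, c(3, 3)) # two-hop latency 6 ms
  expect_error(build_motif("shortcut", delay_shortcut = 6), "shorter")
  expect_error(build_motif("loop"))
})

test_that("the conditioning circuit starts below the CS-transmission threshold", {
  set.seed(1)
  net <- build_conditioning_snn()
  pl <- net$synapses[net$synapses$plastic, ]
  expect_setequal(paste(pl$pre, pl$post), c("N1 N3", "N2 N3"))
  # untrained: CS alone cannot excite the US neuron (deterministic probe)
  run <- run_network(net, pulse_train("N1"), duration = 1000,
                     plastic = FALSE, noise = FALSE)
  expect_equal(unname(run$spike_counts[["N3"]]), 0)
  # saturated coupling: CS alone fires N3 (and the motoneuron) on every pulse
  run2 <- run_network(set_weight(net, "N1", "N3", 1), pulse_train("N1"),
                      duration = 1000, plastic = FALSE, noise = FALSE)
  expect_gte(run2$spike_counts[["N3"]], 10)
  expect_gte(run2$spike_counts[["M"]], 10)
})

test_that("the seven-neuron sensorimotor network matches its wiring contract", {
  set.seed(2)
  net <- build_robot_snn()
  s <- net$synapses
  getrow <- function(p, q) s[s$pre == p & s$post == q, ]
  expect_equal(getrow("N3", "N4")$w, 1)
  expect_equal(getrow("N3", "N4")$g, -20)
  expect_equal(getrow("N4", "N3")$w, 1)
  expect_equal(getrow("N4", "N3")$g, -20)
  expect_false(getrow("N3", "N4")$plastic)
  expect_equal(getrow("N1", "N4")$delay_ms, 4.2)
  expect_equal(getrow("N2", "N3")$delay_ms, 4.2)
  expect_equal(getrow("N1", "N3")$delay_ms, 3)
  pl <- s[s$plastic, ]
  expect_setequal(paste(pl$pre, pl$post),
                  c("N1 N3", "N2 N4", "N1 N4", "N2 N3"))
  expect_true(all(pl$w >= 0.07 & pl$w <= 0.14))
  # reflex arc and tonic drive
  expect_equal(getrow("N3", "N5")$w, 1)
  expect_equal(getrow("N4", "N6")$w, 1)
  expect_equal(net$neurons$bias[net$neurons$id == "N7"], 6)
})

test_that("simulations are bit-reproducible under a fixed seed", {
  runs <- lapply(1:2, function(i) {
    set.seed(77)
    net <- build_robot_snn()
    run_network(net, pulse_train("N1"), duration = 3000)
  })
  expect_identical(runs[[1]]$spikes, runs[[2]]$spikes)
  expect_identical(runs[[1]]$net$synapses$w, runs[[2]]$net$synapses$w)
})

test_that("no synaptic effect precedes emission time plus axonal delay", {
  net <- build_motif("chain2", init_w = 1, D = 0)
  run <- run_network(net, pulse_train("N1", t_off_ms = 50), duration = 300)
  t1 <- min(run$spikes$time_ms[run$spikes$neuron == "N1"])
  t2 <- min(run$spikes$time_ms[run$spikes$neuron == "N2"])
  expect_gte(t2, t1 + 3)
})

test_that("a single step advances the clock by dt and leaves the logs empty", {
  net <- build_motif("chain2", D = 0)
  run <- run_network(net, NULL, duration = 0.1, sample_period = 0)
  expect_equal(run$net$t, 0.1)
  expect_equal(nrow(run$spikes), 0)
  expect_equal(nrow(run$weights), 0)
})

test_that("splitting a run across calls preserves the delay queue and state", {
  net <- build_motif("shortcut", D = 0)
  one <- run_network(net, pulse_train("N1"), duration = 2000, sample_period = 0)
  two_a <- run_network(net, pulse_train("N1"), duration = 1001.5,
                       sample_period = 0)
  two_b <- run_network(two_a$net, pulse_train("N1"), duration = 998.5,
                       sample_period = 0)
  expect_equal(two_b$net$synapses$w, one$net$synapses$w, tolerance = 1e-12)
  expect_equal(two_b$net$state$v, one$net$state$v, tolerance = 1e-12)
  expect_equal(two_b$net$t, one$net$t)
})

test_that("the shortcut motif depresses the long-path terminal synapse", {
  set.seed(9)
  net <- build_motif("shortcut", D = 0)
  w0 <- setNames(net$synapses$w, paste0(net$synapses$pre, "->", net$synapses$post))
  run <- run_network(net, pulse_train("N1"), duration = 20000,
                     sample_period = 1000, record_spikes = FALSE)
  w1 <- setNames(run$net$synapses$w, names(w0))
  expect_lt(w1[["N2->N3"]], w0[["N2->N3"]])
  expect_gt(w1[["N1->N3"]], w0[["N1->N3"]])
  expect_gt(w1[["N1->N2"]], w0[["N1->N2"]])
  # weight log is ordered, in range, and covers all synapses
  expect_true(all(run$weights$w >= 0 & run$weights$w <= 1))
  expect_true(!is.unsorted(run$weights$time_ms))
  expect_setequal(unique(run$weights$synapse), names(w0))
})

test_that("chain weights grow monotonically under one-sided stimulation", {
  set.seed(10)
  net <- build_motif("chain3", D = 0)
  run <- run_network(net, pulse_train("N1"), duration = 30000,
                     sample_period = 1000, record_spikes = FALSE)
  for (lab in unique(run$weights$synapse)) {
    tr <- run$weights$w[run$weights$synapse == lab]
    expect_true(all(diff(tr) >= -1e-12), info = lab)
  }
})

test_that("left-right relabelling mirrors the weight trajectories", {
  run_one <- function(side) {
    set.seed(33)
    net <- build_robot_snn(n7_bias = 0)
    # make the plastic starting weights symmetric so mirroring is exact
    for (p in list(c("N1", "N3"), c("N2", "N4"))) net <- set_weight(net, p[1], p[2], 0.1)
    for (p in list(c("N1", "N4"), c("N2", "N3"))) net <- set_weight(net, p[1], p[2], 0.1)
    cs <- cs_neuron_for(side, "PA")
    us <- us_neuron_for(side)
    run <- run_network(net, paired_train(cs, us, lag_ms = 10,
                                         duration_ms = 20000),
                       duration = 20000, sample_period = 0,
                       record_spikes = FALSE, noise = FALSE)
    run$net
  }
  left <- run_one("left")
  right <- run_one("right")
  expect_equal(get_weight(left, "N1", "N3"), get_weight(right, "N2", "N4"),
               tolerance = 1e-10)
  expect_equal(get_weight(left, "N2", "N3"), get_weight(right, "N1", "N4"),
               tolerance = 1e-10)
})
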