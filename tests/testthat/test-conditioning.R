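test_that("the CS-alone probe is frozen: repeated probing changes no weight", {
  set.seed(13)
  net <- build_robot_snn(n7_bias = 0)
  w0 <- net$synapses$w
  for (i in 1:100) probe_cs_alone(net, "left", "PA")
  expect_identical(net$synapses$w, w0)
  # and the probe itself returns a fresh verdict without touching the caller
  res <- replicate(5, probe_cs_alone(net, "right", "PA"))
  expect_identical(net$synapses$w, w0)
  expect_true(all(res == res[1]))
})

test_that("an untrained network fails the probe; a saturated one passes it", {
  set.seed(14)
  net <- build_robot_snn(n7_bias = 0)
  expect_false(probe_cs_alone(net, "left", "PA"))
  trained <- set_weight(net, "N1", "N3", 1)
  expect_true(probe_cs_alone(trained, "left", "PA"))
  # lateralisation: saturating the *diagonal* must not count as learning
  wrong <- set_weight(set_weight(net, "N1", "N4", 1), "N1", "N3", 1)
  expect_false(probe_cs_alone(wrong, "left", "PA"))
})

test_that("without stimulation, weights only drift within the noise bound", {
  set.seed(15)
  net <- build_robot_snn(n7_bias = 0)
  w0 <- net$synapses$w
  run <- run_network(net, NULL, duration = 20000, sample_period = 0,
                     record_spikes = FALSE)
  # spontaneous activity at D = 5.5 is ~0.02 Hz; chance pairings move a
  # weight by at most a few lambda
  expect_lt(max(abs(run$net$synapses$w - w0)), 0.01)
})

test_that("a short conditioning run returns coherent probe and weight records", {
  set.seed(16)
  net <- build_robot_snn(n7_bias = 0)
  sch <- conditioning_schedule("PA", episode_ms = 4000, n_cycles = 4)
  out <- run_classical_conditioning(net, sch, stop_when_learned = FALSE)
  expect_s3_class(out, "classical_run")
  expect_equal(out$probes$cycle, 1:4)
  expect_equal(out$probes$side, c("left", "right", "left", "right"))
  expect_equal(nrow(out$metrics), 4)
  expect_true(all(out$weights$w >= 0 & out$weights$w <= 1))
  # paired stimulation moves the trained couplings upward from the start
  expect_gt(out$metrics$w_P[4], out$metrics$w_P[1] - 1e-9)
})

test_that("probe thresholds and schedule defaults are internally consistent", {
  sch <- conditioning_schedule("PA")
  expect_equal(sch$probe_min_spikes, 5) # one spike per two pulses over 1 s
  expect_equal(sch$episode_ms, 20000)
  expect_equal(sch$lag_ms, 10)
})
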