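test_that("sonars trigger inside their cones at 15 cm and not elsewhere", {
  empty <- arena(5, 5, spawn = c(2.5, 2.5, 0))
  rb <- robot_state(2.5, 2.5, 0)
  expect_identical(unname(sense(empty, rb)), rep(FALSE, 4))

  # obstacle 0.10 m ahead-left of the body, inside the left cone only
  ob <- snnanimat:::regular_poly(2.5 + 0.22 * cos(0.35), 2.5 + 0.22 * sin(0.35),
                                 0.03, 4)
  a2 <- arena(5, 5, obstacles = list(ob), spawn = c(2.5, 2.5, 0))
  fl <- sense(a2, rb)
  expect_true(fl[["sonarL"]])
  expect_false(fl[["sonarR"]])
  expect_false(fl[["touchL"]] || fl[["touchR"]])

  # beyond 15 cm from the body: silent
  ob_far <- snnanimat:::regular_poly(2.5 + 0.40 * cos(0.35),
                                     2.5 + 0.40 * sin(0.35), 0.03, 4)
  a3 <- arena(5, 5, obstacles = list(ob_far), spawn = c(2.5, 2.5, 0))
  expect_false(any(sense(a3, rb)[c("sonarL", "sonarR")]))
})

test_that("the bumper reports front-half contact on the correct side", {
  # overlap on the right-front
  ob <- snnanimat:::regular_poly(2.58, 2.43, 0.04, 4)
  a2 <- arena(5, 5, obstacles = list(ob), spawn = c(2, 2, 0))
  fl <- sense(a2, robot_state(2.5, 2.5, 0))
  expect_true(fl[["touchR"]])
  expect_false(fl[["touchL"]])
  # the same contact behind the robot does not register
  fl_back <- sense(a2, robot_state(2.5, 2.5, pi))
  expect_false(fl_back[["touchL"]] || fl_back[["touchR"]])
})

test_that("sensor flags map to the documented stimulus channels", {
  fl <- c(sonarL = FALSE, sonarR = FALSE, touchL = TRUE, touchR = FALSE)
  pr <- sensors_to_stimuli(fl, "PA")
  expect_equal(pr$neuron, "N3")
  expect_equal(pr$phase_ms, 10)

  both <- sensors_to_stimuli(c(sonarL = TRUE, sonarR = FALSE, touchL = TRUE,
                               touchR = FALSE), "PA")
  expect_setequal(both$neuron, c("N1", "N3"))
  expect_equal(both$phase_ms[both$neuron == "N3"] -
                 both$phase_ms[both$neuron == "N1"], 10)
  # DA wiring sends the left sonar to N2; the US mapping never moves
  da <- sensors_to_stimuli(c(sonarL = TRUE, sonarR = FALSE, touchL = TRUE,
                             touchR = FALSE), "DA")
  expect_setequal(da$neuron, c("N2", "N3"))
  expect_equal(nrow(sensors_to_stimuli(setNames(rep(FALSE, 4),
    c("sonarL", "sonarR", "touchL", "touchR")))), 0)
})

test_that("motoneuron activity maps to wheels as slow-down / reverse / straight", {
  straight <- motors_from_snn(14, 0, 0)
  expect_equal(straight[["left"]], straight[["right"]])
  expect_gt(straight[["left"]], 0)
  # F = 0 and N5 firing: right wheel reverses, robot turns right in place
  turn <- motors_from_snn(0, 1, 0)
  expect_lt(turn[["right"]], 0)
  expect_equal(turn[["left"]], 0)
  # symmetric drive: no net turn
  sym <- motors_from_snn(14, 0.5, 0.5)
  expect_equal(sym[["left"]], sym[["right"]])
  # clamping at v_max
  expect_equal(motors_from_snn(1000, 0, 0)[["left"]], 0.2)
  expect_equal(motors_from_snn(0, 10, 0)[["right"]], -0.2)
})

test_that("an open arena yields a straight trajectory and no collisions", {
  set.seed(17)
  net <- build_robot_snn(D = 0)
  big <- arena(5, 5, spawn = c(2.5, 2.5, 0.3))
  run <- run_operant(big, net, duration_s = 10)
  expect_equal(nrow(run$collisions), 0)
  expect_false(any(run$sonar_on$on))
  expect_lt(diff(range(run$trajectory$heading)), 1e-6)
  dx <- diff(run$trajectory$x)
  dy <- diff(run$trajectory$y)
  expect_lt(max(abs(atan2(dy, dx) - 0.3)), 1e-6)
})

test_that("the unconditional reflex turns the robot away from the touched side", {
  set.seed(18)
  net <- build_robot_snn(D = 0)
  # drive straight at a wall slightly angled so the left bumper half hits
  a2 <- arena(2, 2, spawn = c(1.0, 0.3, pi / 2 + 0.1))
  run <- run_operant(a2, net, duration_s = 30)
  expect_gte(nrow(run$collisions), 1)
  tr <- run$trajectory
  for (i in seq_len(min(5, nrow(run$collisions)))) {
    t0 <- run$collisions$t_s[i]
    side <- run$collisions$side[i]
    h0 <- tr$heading[which.min(abs(tr$t_s - t0))]
    h1 <- tr$heading[which.min(abs(tr$t_s - (t0 + 1)))]
    if (side == "left") expect_lt(h1, h0) else expect_gt(h1, h0)
  }
})

test_that("weights trained by classical conditioning transfer to collision avoidance", {
  set.seed(19)
  naive <- build_robot_snn()
  trained <- naive
  trained <- set_weight(trained, "N1", "N3", 0.8)
  trained <- set_weight(trained, "N2", "N4", 0.8)
  trained <- set_weight(trained, "N1", "N4", 0.03)
  trained <- set_weight(trained, "N2", "N3", 0.03)
  run_n <- run_operant(default_arena(), naive, duration_s = 90)
  set.seed(19)
  run_t <- run_operant(default_arena(), trained, duration_s = 90)
  expect_lt(nrow(run_t$collisions), nrow(run_n$collisions))
})

test_that("frontal both-sonar stimulation yields lower selectivity than lateral", {
  run_one <- function(both) {
    set.seed(20)
    net <- build_robot_snn(n7_bias = 0)
    sch <- conditioning_schedule("PA", episode_ms = 10000, n_cycles = 10,
                                 both_cs = both)
    out <- run_classical_conditioning(net, sch, stop_when_learned = FALSE)
    last <- out$metrics[nrow(out$metrics), ]
    selectivity(last$w_P, last$w_D, "PA")$ratio
  }
  expect_gt(run_one(FALSE), run_one(TRUE))
})

test_that("the arena fixture generator honours its clearance contract", {
  set.seed(30)
  for (i in 1:5) {
    ar <- random_arena(3)
    expect_length(ar$obstacles, 3)
    centres <- t(vapply(ar$obstacles, colMeans, numeric(2)))
    radii <- vapply(seq_along(ar$obstacles), function(j)
      max(sqrt(rowSums((ar$obstacles[[j]] - rep(centres[j, ], each =
        nrow(ar$obstacles[[j]])))^2))), numeric(1))
    if (nrow(centres) > 1) {
      dmat <- as.matrix(dist(centres))
      for (a in 1:2) for (b in (a + 1):3)
        expect_gte(dmat[a, b] - radii[a] - radii[b], 6 * 0.09 - 1e-9)
    }
    for (ob in ar$obstacles)
      expect_true(all(ob >= 0 & ob <= 1.5))
  }
  # infeasible request fails loudly instead of looping forever
  expect_error(random_arena(20, max_tries = 50), "clearances")
})

test_that("learning time is the onset of a collision-free window with sonar activity", {
  fake <- structure(list(
    collisions = data.frame(t_s = c(10, 20, 30)),
    sonar_on = data.frame(t_s = seq(0, 199.9, by = 0.1), on = TRUE),
    duration_s = 200), class = "operant_run")
  expect_equal(learning_time(fake), 30 / 60, tolerance = 1e-6)
  # without continuing sonar activations the window does not count
  fake$sonar_on$on <- fake$sonar_on$t_s < 25
  expect_true(is.na(learning_time(fake)))
  # no clean window at all
  fake2 <- structure(list(
    collisions = data.frame(t_s = seq(5, 195, by = 20)),
    sonar_on = data.frame(t_s = seq(0, 199.9, by = 0.1), on = TRUE),
    duration_s = 200), class = "operant_run")
  expect_true(is.na(learning_time(fake2)))
})
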