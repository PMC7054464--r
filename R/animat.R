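#' Rectangular arena with polygonal obstacles
#'
#' @param width,height arena size (m).
#' @param obstacles list of convex polygons, each an `n x 2` matrix of
#'   vertices (m), all inside the bounds.
#' @param spawn robot spawn pose `c(x, y, heading_rad)`; must not be inside
#'   an obstacle.
#' @return An object of class `arena`.
#' @export
arena <- function(width = 1, height = 1, obstacles = list(),
                  spawn = c(0.12, 0.12, 0.8)) {
  for (ob in obstacles) {
    stopifnot(is.matrix(ob), ncol(ob) == 2, nrow(ob) >= 3)
    if (any(ob[, 1] < 0 | ob[, 1] > width | ob[, 2] < 0 | ob[, 2] > height))
      stop("obstacle vertices must lie inside the arena bounds")
    if (point_in_poly(spawn[1], spawn[2], ob))
      stop("spawn pose lies inside an obstacle")
  }
  structure(list(width = width, height = height, obstacles = obstacles,
                 spawn = spawn), class = "arena")
}

point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((poly[i, 2] > py) != (poly[j, 2] > py)) &&
        (px < (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) /
           (poly[j, 2] - poly[i, 2]) + poly[i, 1]))
      inside <- !inside
    j <- i
  }
  inside
}

regular_poly <- function(cx, cy, r, n, rot = 0) {
  a <- rot + 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + r * cos(a), cy + r * sin(a))
}

#' The default 1 m x 1 m arena with three convex obstacles
#'
#' A water-maze-sized square arena with three small convex obstacles
#' (square, triangle, pentagon), the layout used for operant conditioning.
#'
#' @return An `arena`.
#' @export
default_arena <- function() {
  arena(1, 1, obstacles = list(
    regular_poly(0.32, 0.60, 0.075, 4, rot = pi / 4),
    regular_poly(0.68, 0.60, 0.075, 3, rot = pi / 6),
    regular_poly(0.50, 0.28, 0.075, 5)),
    spawn = c(0.12, 0.12, 0.8))
}

#' Random arena fixture generator
#'
#' Emits randomised obstacle layouts by rejection sampling: convex regular
#' polygons with 3-6 vertices, pairwise edge-to-edge clearance of at least
#' `min_gap` (default three robot diameters, so every inter-obstacle
#' corridor is passable with margin) and a wall clearance of `wall_gap`.
#' Draws from the current RNG state.
#'
#' @param n_obstacles number of obstacles.
#' @param width,height arena size (m). The default is larger than the
#'   1-m square used in the conditioning experiments because three obstacles
#'   with full three-diameter corridors do not fit in 1 m; pass a smaller
#'   `min_gap` to generate tighter layouts.
#' @param size_range obstacle circumradius range (m).
#' @param robot_radius robot body radius (m), sets the corridor unit.
#' @param min_gap minimum edge-to-edge clearance between obstacles (m).
#' @param wall_gap minimum obstacle clearance from the walls (m).
#' @param max_tries rejection-sampling budget.
#' @return An `arena`.
#' @export
#' @examples
#' set.seed(1)
#' random_arena(3)
random_arena <- function(n_obstacles = 3, width = 1.5, height = 1.5,
                         size_range = c(0.04, 0.07), robot_radius = 0.09,
                         min_gap = 6 * robot_radius,
                         wall_gap = 1.5 * robot_radius,
                         max_tries = 5000) {
  centres <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  polys <- list()
  tries <- 0
  while (length(polys) < n_obstacles) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("could not place ", n_obstacles, " obstacles with the requested ",
           "clearances; enlarge the arena or relax min_gap")
    r <- runif(1, size_range[1], size_range[2])
    cx <- runif(1, wall_gap + r, width - wall_gap - r)
    cy <- runif(1, wall_gap + r, height - wall_gap - r)
    if (nrow(centres) > 0) {
      gaps <- sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2) - radii - r
      if (any(gaps < min_gap)) next
    }
    n_v <- sample(3:6, 1)
    polys[[length(polys) + 1]] <- regular_poly(cx, cy, r, n_v, runif(1, 0, 2 * pi))
    centres <- rbind(centres, c(cx, cy))
    radii <- c(radii, r)
  }
  spawn <- c(0.12, 0.12, runif(1, 0, 2 * pi))
  arena(width, height, obstacles = polys, spawn = spawn)
}

arena_segments <- function(a) {
  segs <- rbind(c(0, 0, a$width, 0), c(a$width, 0, a$width, a$height),
                c(a$width, a$height, 0, a$height), c(0, a$height, 0, 0))
  for (ob in a$obstacles) {
    n <- nrow(ob)
    segs <- rbind(segs, cbind(ob, ob[c(2:n, 1), , drop = FALSE]))
  }
  segs
}

#' Differential-drive robot state
#'
#' @param x,y position (m).
#' @param heading heading (rad, counter-clockwise from +x).
#' @param radius body radius (m).
#' @param v_max wheel speed limit (m/s).
#' @param sonar_range sonar trigger distance from the body (m).
#' @param sonar_mount sonar mounting angle from the heading (rad; the left
#'   sonar points at `heading + sonar_mount`, the right at
#'   `heading - sonar_mount`). The cones overlap ahead, so frontal obstacles
#'   trigger both sonars.
#' @param sonar_half_angle half-angle of each sonar's narrow sensing cone
#'   (rad). With the default mount angle equal to the half-angle, the two
#'   fans are contiguous and cover about +/-40 degrees around the heading.
#' @return An object of class `robot_state`.
#' @export
robot_state <- function(x = 0.12, y = 0.12, heading = 0.8, radius = 0.09,
                        v_max = 0.2, sonar_range = 0.15, sonar_mount = 0.35,
                        sonar_half_angle = 0.35) {
  structure(list(x = x, y = y, heading = heading, radius = radius,
                 v_max = v_max, sonar_range = sonar_range,
                 sonar_mount = sonar_mount,
                 sonar_half_angle = sonar_half_angle,
                 wheel_l = 0, wheel_r = 0), class = "robot_state")
}

#' Read the robot's sensors
#'
#' Sonars are narrow ray-cast cones triggering when an obstacle (or wall)
#' edge is within `sonar_range` of the body; the bumper reports touch on the
#' half (left/right of the heading) where the body is in contact.
#'
#' @param arena_obj an [arena()].
#' @param robot a [robot_state()].
#' @return Named logical vector `c(sonarL, sonarR, touchL, touchR)`.
#' @export
#' @examples
#' sense(arena(1, 1), robot_state(x = 0.5, y = 0.5))
sense <- function(arena_obj, robot) {
  s <- animat_sense_cpp(robot$x, robot$y, robot$heading, robot$radius,
                        arena_segments(arena_obj), robot$sonar_range,
                        robot$sonar_mount, robot$sonar_half_angle,
                        7L, 1e-3)
  c(sonarL = s$sonarL, sonarR = s$sonarR, touchL = s$touchL, touchR = s$touchR)
}

#' Translate sensor flags into a stimulus-program fragment
#'
#' Active sonars drive their CS neuron with a 10-Hz pulse train phase-locked
#' to the global clock; active touch sensors drive their US neuron with the
#' same train lagged `lag_ms` (default 10 ms) behind the sonar phase, so
#' that simultaneous sonar + touch reproduces the paired CS-US protocol.
#'
#' @param flags named logicals from [sense()].
#' @param wiring sonar-to-CS wiring, `"PA"` or `"DA"`.
#' @param amplitude pulse amplitude.
#' @param lag_ms US phase lag behind the CS phase (ms).
#' @param t_on_ms,t_off_ms gate window (ms, global clock) — usually the
#'   current control slice.
#' @return A stimulus program fragment (possibly zero rows).
#' @export
sensors_to_stimuli <- function(flags, wiring = "PA", amplitude = 15,
                               lag_ms = 10, t_on_ms = 0, t_off_ms = Inf) {
  parts <- list()
  if (isTRUE(flags[["sonarL"]]))
    parts <- c(parts, list(pulse_train(cs_neuron_for("left", wiring),
                                       amplitude, phase_ms = 0,
                                       t_on_ms = t_on_ms, t_off_ms = t_off_ms)))
  if (isTRUE(flags[["sonarR"]]))
    parts <- c(parts, list(pulse_train(cs_neuron_for("right", wiring),
                                       amplitude, phase_ms = 0,
                                       t_on_ms = t_on_ms, t_off_ms = t_off_ms)))
  if (isTRUE(flags[["touchL"]]))
    parts <- c(parts, list(pulse_train("N3", amplitude, phase_ms = lag_ms,
                                       t_on_ms = t_on_ms, t_off_ms = t_off_ms)))
  if (isTRUE(flags[["touchR"]]))
    parts <- c(parts, list(pulse_train("N4", amplitude, phase_ms = lag_ms,
                                       t_on_ms = t_on_ms, t_off_ms = t_off_ms)))
  do.call(stimulus_program, parts)
}

#' Map motoneuron activity to wheel speeds
#'
#' Forward speed is proportional to the tonic neuron N7's recent firing rate
#' `F`; the steering motoneurons subtract from their motor: N5 slows (or
#' reverses) the right wheel, N6 the left wheel, turning the robot away from
#' the active side's stimulus.
#'
#' @param rate_f recent N7 firing rate (Hz).
#' @param drive5,drive6 released-transmitter traces of N5 / N6 (decaying
#'   spike traces, dimensionless).
#' @param k_f forward gain (m/s per Hz).
#' @param k_m steering gain (m/s per unit drive).
#' @param v_max wheel speed limit (m/s); wheels clamp to `[-v_max, v_max]`
#'   and may go negative (reverse).
#' @return Named vector `c(left, right)` of wheel speeds (m/s).
#' @export
#' @examples
#' motors_from_snn(10, 0, 0)       # straight
#' motors_from_snn(0, 1, 0)        # right wheel reverses: turn right in place
motors_from_snn <- function(rate_f, drive5, drive6, k_f = 0.01, k_m = 0.6,
                            v_max = 0.2) {
  v <- k_f * rate_f
  wl <- max(-v_max, min(v_max, v - k_m * drive6))
  wr <- max(-v_max, min(v_max, v - k_m * drive5))
  c(left = wl, right = wr)
}

#' Closed-loop operant conditioning in an obstacle arena
#'
#' Runs the full sense -> stimulate -> simulate -> actuate loop: every
#' control period (default 10 ms) the sensors are read, active sensors
#' drive phase-locked pulse trains into the network, the network is
#' advanced by one control period (plasticity on), motoneuron activity is
#' mapped to wheel speeds, and a differential-drive Euler step moves the
#' robot; on contact the robot stops at the obstacle and the unconditional
#' reflex (US -> motoneuron) turns it away. Collisions (touch onsets) and
#' the trajectory (sampled at `traj_hz`) are logged, along with the four
#' plastic weights once per second.
#'
#' @param arena_obj an [arena()].
#' @param net an `snn_network` from [build_robot_snn()] with N7 enabled.
#' @param duration_s simulated time (s).
#' @param wiring initial sonar wiring (`"PA"` or `"DA"`).
#' @param swap_at_s optional time (s) at which the sonar connections are
#'   swapped mid-run (relearning experiment); `NULL` for none.
#' @param robot a [robot_state()]; defaults to the arena's spawn pose.
#' @param control_period_ms sensor/motor refresh period (ms).
#' @param amplitude stimulus pulse amplitude.
#' @param k_f,k_m,tau_motor_ms,tau_rate_ms actuation constants: forward and
#'   steering gains, motoneuron drive-trace decay and the N7 rate-estimate
#'   time constant.
#' @param rate_f0 initial N7 rate estimate (Hz), roughly its tonic rate.
#' @param traj_hz trajectory sampling rate (Hz).
#' @return An object of class `operant_run`: `trajectory` (data.frame
#'   `t_s, x, y, heading, touchL, touchR`), `collisions` (data.frame
#'   `t_s, x, y, side`), `weights` (data.frame `t_s, w31, w42, w41, w32,
#'   w_P, w_D`), `sonar_on` (data.frame `t_s, on`, per control step), the
#'   final `net`, `wiring` and the run parameters.
#' @export
run_operant <- function(arena_obj, net, duration_s, wiring = "PA",
                        swap_at_s = NULL, robot = NULL,
                        control_period_ms = 10, amplitude = 15,
                        k_f = 0.01, k_m = 0.6, tau_motor_ms = 30,
                        tau_rate_ms = 500, rate_f0 = 14, traj_hz = 29) {
  stopifnot(inherits(arena_obj, "arena"), inherits(net, "snn_network"))
  if (net$neurons$bias[net$neurons$id == "N7"] <= 0)
    warning("N7 has no tonic drive; the robot will not move forward")
  if (is.null(robot))
    robot <- robot_state(arena_obj$spawn[1], arena_obj$spawn[2],
                         arena_obj$spawn[3])
  segs <- arena_segments(arena_obj)
  cp <- control_period_ms
  dt <- net$dt
  n_slices <- as.integer(round(duration_s * 1000 / cp))
  nidx <- match(paste0("N", 1:7), net$neurons$id)
  if (anyNA(nidx)) stop("run_operant needs the seven-neuron network N1..N7")
  wlog_pairs <- rbind(c("N1", "N3"), c("N2", "N4"), c("N1", "N4"),
                      c("N2", "N3"))
  wlog_syn <- apply(wlog_pairs, 1, function(p)
    which(net$synapses$pre == p[1] & net$synapses$post == p[2]))
  topo <- list(
    pre = match(net$synapses$pre, net$neurons$id) - 1L,
    post = match(net$synapses$post, net$neurons$id) - 1L,
    g = as.numeric(net$synapses$g),
    delay_steps = as.integer(round(net$synapses$delay_ms / dt)),
    plastic = as.integer(net$synapses$plastic),
    wlog_syn = as.integer(wlog_syn - 1L))
  pars <- c(list(a = net$neurons$a, b = net$neurons$b, c = net$neurons$c,
                 d = net$neurons$d, bias = net$neurons$bias,
                 D = net$neurons$D,
                 noise_scale = if (net$noise_per_time) 1 / dt else 1),
            unclass(net$params))
  st <- net$state
  st$w <- as.numeric(net$synapses$w)
  out <- operant_loop_cpp(
    st, topo, pars, dt, round(net$t / dt), segs,
    c(robot$x, robot$y, robot$heading, robot$radius, robot$v_max,
      robot$sonar_range, robot$sonar_mount, robot$sonar_half_angle, 7, 1e-3),
    c(cp, amplitude, 10, 100, 3, k_f, k_m, tau_motor_ms, tau_rate_ms,
      rate_f0, max(1, round(1000 / traj_hz / cp)), max(1L, as.integer(1000 / cp))),
    as.integer(nidx - 1L), n_slices,
    if (is.null(swap_at_s)) -1L else as.integer(round(swap_at_s * 1000 / cp)),
    as.integer(wiring == "PA"), arena_obj$width, arena_obj$height)
  net$state <- list(v = out$v, u = out$u, s_post = out$s_post,
                    x = out$x, y = out$y, uf = out$uf, s_pre = out$s_pre,
                    pending = out$pending)
  net$synapses$w <- out$w
  net$t <- out$t0_step_new * dt
  robot$x <- out$pose[1]; robot$y <- out$pose[2]; robot$heading <- out$pose[3]
  tr <- out$trajectory
  cm <- out$collisions
  wm <- out$wlog
  weights <- data.frame(t_s = wm[, 1], w31 = wm[, 2], w42 = wm[, 3],
                        w41 = wm[, 4], w32 = wm[, 5])
  weights$w_P <- (weights$w31 + weights$w42) / 2
  weights$w_D <- (weights$w41 + weights$w32) / 2
  structure(list(
    trajectory = data.frame(t_s = tr[, 1], x = tr[, 2], y = tr[, 3],
                            heading = tr[, 4], touchL = tr[, 5] > 0,
                            touchR = tr[, 6] > 0),
    collisions = data.frame(t_s = cm[, 1], x = cm[, 2], y = cm[, 3],
                            side = c("left", "right")[cm[, 4]]),
    weights = weights,
    sonar_on = data.frame(t_s = (seq_len(n_slices) - 1) * cp / 1000,
                          on = out$sonar_on > 0),
    net = net, wiring = if (out$wiring_pa == 1) "PA" else "DA",
    robot = robot, duration_s = duration_s, control_period_ms = cp),
    class = "operant_run")
}

#' @export
print.operant_run <- function(x, ...) {
  cat("<operant_run> ", x$duration_s, " s, ", nrow(x$collisions),
      " collisions, final wiring ", x$wiring, "\n", sep = "")
  lt <- learning_time(x)
  cat("  learning time: ",
      if (is.na(lt)) "not reached" else sprintf("%.2f min", lt), "\n", sep = "")
  invisible(x)
}

#' Operant learning time
#'
#' The first moment after which a sliding window of `window_s` seconds
#' contains zero collisions while sonar activations continue (the robot is
#' still encountering obstacles, but avoids them). `NA` if no such window
#' fits in the run.
#'
#' @param run an `operant_run`.
#' @param window_s window length (s).
#' @return Learning time in minutes (simulated), or `NA`.
#' @export
learning_time <- function(run, window_s = 60) {
  dur <- run$duration_s
  ct <- run$collisions$t_s
  son <- run$sonar_on
  candidates <- sort(unique(c(0, ct + 1e-9)))
  candidates <- candidates[candidates + window_s <= dur + 1e-9]
  for (tc in candidates) {
    if (any(ct > tc & ct <= tc + window_s)) next
    if (!any(son$on[son$t_s >= tc & son$t_s < tc + window_s])) next
    return(tc / 60)
  }
  NA_real_
}
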