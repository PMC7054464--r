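#' Classical-conditioning schedule
#'
#' Describes the paired CS-US protocol on the seven-neuron sensorimotor
#' network: alternating left/right stimulation episodes ("cycles"), the
#' CS-channel wiring, and the CS-alone probe used to decide when the
#' association is learned. One cycle is one paired-stimulation episode on
#' one side (default 20 s = 200 paired pulses at 10 Hz).
#'
#' @param wiring `"PA"` (left sonar -> N1, right -> N2; learning potentiates
#'   the parallel couplings) or `"DA"` (swapped; learning potentiates the
#'   diagonal couplings). The US mapping is fixed: left touch -> N3, right
#'   touch -> N4.
#' @param episode_ms duration of one stimulation episode (ms).
#' @param n_cycles cycle budget.
#' @param lag_ms US lag after each CS pulse (ms); negative values put the US
#'   *before* the CS (the order that impairs learning).
#' @param amplitude pulse amplitude.
#' @param rate_hz pulse rate (Hz).
#' @param width_ms pulse width (ms).
#' @param start_side side stimulated on the first cycle.
#' @param both_cs stimulate both CS neurons each episode (emulates frontal
#'   approaches where both sonars see the obstacle; degrades selectivity).
#' @param probe_ms CS-alone probe duration (ms).
#' @param probe_min_spikes spikes required of the correct US neuron during a
#'   probe (default: one per two pulses); the contralateral US neuron must
#'   stay below the same count for correct lateralisation.
#' @return An object of class `conditioning_schedule`.
#' @export
conditioning_schedule <- function(wiring = c("PA", "DA"), episode_ms = 20000,
                                  n_cycles = 16, lag_ms = 10, amplitude = 15,
                                  rate_hz = 10, width_ms = 3,
                                  start_side = c("left", "right"),
                                  both_cs = FALSE, probe_ms = 1000,
                                  probe_min_spikes = NULL) {
  wiring <- match.arg(wiring)
  start_side <- match.arg(start_side)
  stopifnot(episode_ms > 0, n_cycles >= 1)
  if (abs(lag_ms) >= 1000 / rate_hz)
    stop("|lag| must be below the inter-pulse interval")
  if (is.null(probe_min_spikes))
    probe_min_spikes <- ceiling(probe_ms / (1000 / rate_hz) / 2)
  structure(list(wiring = wiring, episode_ms = episode_ms,
                 n_cycles = n_cycles, lag_ms = lag_ms, amplitude = amplitude,
                 rate_hz = rate_hz, width_ms = width_ms,
                 start_side = start_side, both_cs = both_cs,
                 probe_ms = probe_ms, probe_min_spikes = probe_min_spikes),
            class = "conditioning_schedule")
}

#' Map a body side to its CS / US neuron
#'
#' US wiring is anatomically fixed (left touch -> N3, right touch -> N4);
#' CS wiring depends on how the sonars are connected (`"PA"` or `"DA"`).
#'
#' @param side `"left"` or `"right"`.
#' @param wiring `"PA"` or `"DA"`.
#' @return A neuron id.
#' @export
cs_neuron_for <- function(side, wiring = "PA") {
  side <- match.arg(side, c("left", "right"))
  if (wiring == "PA") c(left = "N1", right = "N2")[[side]]
  else c(left = "N2", right = "N1")[[side]]
}

#' @rdname cs_neuron_for
#' @export
us_neuron_for <- function(side) {
  side <- match.arg(side, c("left", "right"))
  c(left = "N3", right = "N4")[[side]]
}

#' Swap the sonar-to-CS-neuron mapping
#'
#' Exchanges which sonar feeds which CS neuron (PA <-> DA); the US mapping
#' is untouched. Emulates physically switching the sonar connections, the
#' environmental change that forces relearning. Applying it twice restores
#' the original schedule.
#'
#' @param schedule a [conditioning_schedule()].
#' @return The schedule with the opposite wiring.
#' @export
swap_cs_inputs <- function(schedule) {
  schedule$wiring <- if (schedule$wiring == "PA") "DA" else "PA"
  schedule
}

#' CS-alone probe: has the association been learned?
#'
#' Stimulates one side's CS neuron alone (plasticity frozen, noise off, so
#' the probe is deterministic and never trains) and checks that the correct
#' US neuron fires at least `min_spikes` while the contralateral US neuron
#' stays below that count (correct lateralisation). The probe leaves the
#' caller's network untouched.
#'
#' @param net an `snn_network` built by [build_robot_snn()].
#' @param side `"left"` or `"right"`.
#' @param wiring CS wiring, `"PA"` or `"DA"`.
#' @param duration_ms probe duration (ms).
#' @param amplitude pulse amplitude.
#' @param rate_hz pulse rate (Hz).
#' @param min_spikes pass threshold (default one spike per two pulses).
#' @return `TRUE` if the side's association is learned.
#' @export
probe_cs_alone <- function(net, side, wiring = "PA", duration_ms = 1000,
                           amplitude = 15, rate_hz = 10, min_spikes = NULL) {
  if (is.null(min_spikes))
    min_spikes <- ceiling(duration_ms / (1000 / rate_hz) / 2)
  cs <- cs_neuron_for(side, wiring)
  us_ok <- us_neuron_for(side)
  us_other <- setdiff(c("N3", "N4"), us_ok)
  prog <- pulse_train(cs, amplitude = amplitude, rate_hz = rate_hz,
                      phase_ms = net$t, t_on_ms = net$t)
  run <- run_network(net, prog, duration = duration_ms, sample_period = 0,
                     plastic = FALSE, noise = FALSE, record_spikes = FALSE)
  run$spike_counts[[us_ok]] >= min_spikes &&
    run$spike_counts[[us_other]] < min_spikes
}

#' Run classical (Pavlovian) conditioning
#'
#' Alternates paired CS-US episodes on the left and right sides. After each
#' cycle both sides are probed CS-alone (frozen, deterministic). Learning is
#' declared at the first cycle where both probes pass and keep passing for
#' one confirmation cycle. The tonic forward-drive neuron N7 should be
#' disabled (`n7_bias = 0` in [build_robot_snn()]); the run proceeds either
#' way since N7 has no synapses.
#'
#' @param net an `snn_network` from [build_robot_snn()].
#' @param schedule a [conditioning_schedule()].
#' @param stop_when_learned stop after the confirmation cycle instead of
#'   exhausting the budget.
#' @param sample_period_ms weight-log sampling period (ms).
#' @return An object of class `classical_run`: `probes` (data.frame `cycle`,
#'   `side`, `passL`, `passR`), `weights` (long data.frame), `metrics`
#'   (per-cycle `w_P`, `w_D`), `cycles_to_learn` (integer, `NA` if the
#'   budget was exhausted — a sentinel, not an error), the final `net` and
#'   the `schedule`.
#' @export
#' @examples
#' \donttest{
#' set.seed(7)
#' net <- build_robot_snn(n7_bias = 0)
#' out <- run_classical_conditioning(net, conditioning_schedule("PA"))
#' out$cycles_to_learn
#' }
run_classical_conditioning <- function(net, schedule,
                                       stop_when_learned = TRUE,
                                       sample_period_ms = 100) {
  stopifnot(inherits(net, "snn_network"),
            inherits(schedule, "conditioning_schedule"))
  sides <- rep(c(schedule$start_side,
                 setdiff(c("left", "right"), schedule$start_side)),
               length.out = schedule$n_cycles)
  probes <- data.frame(cycle = integer(0), side = character(0),
                       passL = logical(0), passR = logical(0))
  metrics <- data.frame(cycle = integer(0), w_P = numeric(0), w_D = numeric(0))
  wlogs <- vector("list", schedule$n_cycles)
  lag <- schedule$lag_ms
  for (cyc in seq_len(schedule$n_cycles)) {
    side <- sides[cyc]
    cs <- cs_neuron_for(side, schedule$wiring)
    us <- us_neuron_for(side)
    if (lag >= 0) {
      prog <- paired_train(cs, us, lag_ms = lag,
                           duration_ms = schedule$episode_ms, start_ms = net$t,
                           amplitude = schedule$amplitude,
                           rate_hz = schedule$rate_hz,
                           width_ms = schedule$width_ms)
    } else {
      # inverse order: US pulses precede CS pulses by |lag|
      prog <- paired_train(us, cs, lag_ms = -lag,
                           duration_ms = schedule$episode_ms, start_ms = net$t,
                           amplitude = schedule$amplitude,
                           rate_hz = schedule$rate_hz,
                           width_ms = schedule$width_ms)
    }
    if (schedule$both_cs) {
      other_cs <- setdiff(c("N1", "N2"), cs)
      prog <- rbind(prog, pulse_train(other_cs, schedule$amplitude,
                                      schedule$rate_hz, schedule$width_ms,
                                      phase_ms = net$t, t_on_ms = net$t,
                                      t_off_ms = net$t + schedule$episode_ms))
    }
    run <- run_network(net, prog, duration = schedule$episode_ms,
                       sample_period = sample_period_ms, plastic = TRUE,
                       noise = TRUE, record_spikes = FALSE)
    net <- run$net
    wlogs[[cyc]] <- run$weights
    pl <- probe_cs_alone(net, "left", schedule$wiring,
                         duration_ms = schedule$probe_ms,
                         amplitude = schedule$amplitude,
                         rate_hz = schedule$rate_hz,
                         min_spikes = schedule$probe_min_spikes)
    pr <- probe_cs_alone(net, "right", schedule$wiring,
                         duration_ms = schedule$probe_ms,
                         amplitude = schedule$amplitude,
                         rate_hz = schedule$rate_hz,
                         min_spikes = schedule$probe_min_spikes)
    probes <- rbind(probes, data.frame(cycle = cyc, side = side,
                                       passL = pl, passR = pr))
    wpwd <- coupling_means(get_weight(net, "N1", "N3"),
                           get_weight(net, "N2", "N4"),
                           get_weight(net, "N1", "N4"),
                           get_weight(net, "N2", "N3"))
    metrics <- rbind(metrics, data.frame(cycle = cyc, w_P = wpwd[["w_P"]],
                                         w_D = wpwd[["w_D"]]))
    if (stop_when_learned &&
        !is.na(cycles_to_learn(probes$passL & probes$passR))) break
  }
  structure(list(
    probes = probes, metrics = metrics,
    weights = do.call(rbind, Filter(Negate(is.null), wlogs)),
    cycles_to_learn = cycles_to_learn(probes$passL & probes$passR),
    net = net, schedule = schedule), class = "classical_run")
}

#' @export
print.classical_run <- function(x, ...) {
  cat("<classical_run> wiring ", x$schedule$wiring, ", ",
      nrow(x$probes), " cycles run; cycles to learn: ",
      ifelse(is.na(x$cycles_to_learn), "not learned (budget exhausted)",
             x$cycles_to_learn), "\n", sep = "")
  if (nrow(x$metrics) > 0) {
    last <- x$metrics[nrow(x$metrics), ]
    cat(sprintf("  final w_P = %.3f, w_D = %.3f, selectivity w_P/w_D = %.2f\n",
                last$w_P, last$w_D, last$w_P / max(last$w_D, 1e-6)))
  }
  invisible(x)
}
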