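#' Periodic pulse-train stimulus
#'
#' Square current pulses of `width_ms` (default 3 ms) delivered at
#' `rate_hz` (default 10 Hz) to one neuron, gated by an on/off window.
#' All times are on the network's global clock, so trains started in
#' different simulation slices stay phase-locked.
#'
#' @param neuron target neuron id.
#' @param amplitude pulse amplitude (current units). The default 15 is
#'   suprathreshold for a 3-ms pulse at default neuron parameters and evokes
#'   exactly one spike per pulse (one pulse = one spike, temporal coding).
#' @param rate_hz pulse rate (Hz).
#' @param width_ms pulse width (ms); must be shorter than the inter-pulse
#'   interval.
#' @param phase_ms onset of the first pulse (ms, global clock); pulses recur
#'   every `1000/rate_hz` ms thereafter.
#' @param t_on_ms,t_off_ms gate window (ms, global clock); the train is
#'   silent outside `[t_on_ms, t_off_ms)`.
#' @return A one-row stimulus program (data.frame); combine with
#'   [stimulus_program()] or `rbind`.
#' @export
#' @examples
#' pulse_train("N1", amplitude = 15)
pulse_train <- function(neuron, amplitude = 15, rate_hz = 10, width_ms = 3,
                        phase_ms = 0, t_on_ms = 0, t_off_ms = Inf) {
  stopifnot(rate_hz > 0, width_ms > 0, amplitude >= 0)
  period <- 1000 / rate_hz
  if (width_ms >= period)
    stop("pulse width must be shorter than the inter-pulse interval")
  data.frame(neuron = neuron, amplitude = amplitude, period_ms = period,
             width_ms = width_ms, phase_ms = phase_ms, t_on_ms = t_on_ms,
             t_off_ms = t_off_ms, stringsAsFactors = FALSE)
}

#' Combine stimulus fragments into one program
#'
#' @param ... stimulus program fragments ([pulse_train()], [paired_train()],
#'   or other programs); `NULL`s are dropped.
#' @return A stimulus program (data.frame, possibly zero rows).
#' @export
stimulus_program <- function(...) {
  parts <- Filter(Negate(is.null), list(...))
  if (length(parts) == 0) return(pulse_train("x")[0, ])
  do.call(rbind, parts)
}

#' Paired CS-US pulse trains
#'
#' The associative stimulation protocol: CS pulses at 10 Hz to the CS
#' neuron, and US pulses at the same rate to the US neuron, each delayed
#' `lag_ms` (default 10 ms) after the corresponding CS pulse — short enough
#' that the CS-evoked presynaptic spike arrives at the US neuron just before
#' the US-evoked postsynaptic spike, which is the timing STDP potentiates.
#'
#' @param cs_neuron,us_neuron target neuron ids.
#' @param lag_ms US lag after each CS pulse (ms); must be shorter than the
#'   inter-pulse interval.
#' @param duration_ms episode duration (ms): CS pulses fall in
#'   `[start_ms, start_ms + duration_ms)`.
#' @param start_ms episode start on the global clock (ms).
#' @param amplitude pulse amplitude.
#' @param rate_hz pulse rate (Hz).
#' @param width_ms pulse width (ms).
#' @return A two-row stimulus program.
#' @export
#' @examples
#' paired_train("N1", "N3", lag_ms = 10, duration_ms = 1000)
paired_train <- function(cs_neuron, us_neuron, lag_ms = 10, duration_ms,
                         start_ms = 0, amplitude = 15, rate_hz = 10,
                         width_ms = 3) {
  period <- 1000 / rate_hz
  if (lag_ms < 0 || lag_ms >= period)
    stop("the CS-US lag must lie in [0, ", period, ") ms")
  rbind(
    pulse_train(cs_neuron, amplitude, rate_hz, width_ms,
                phase_ms = start_ms, t_on_ms = start_ms,
                t_off_ms = start_ms + duration_ms),
    pulse_train(us_neuron, amplitude, rate_hz, width_ms,
                phase_ms = start_ms + lag_ms, t_on_ms = start_ms,
                t_off_ms = start_ms + duration_ms + lag_ms))
}

#' Pulse onset times of a program channel within a window
#'
#' @param channel one row of a stimulus program.
#' @param from_ms,to_ms window (ms, global clock); onsets in `[from, to)`.
#' @return Numeric vector of pulse onset times (ms).
#' @export
pulse_onsets <- function(channel, from_ms = 0, to_ms) {
  lo <- max(from_ms, channel$t_on_ms, channel$phase_ms)
  hi <- min(to_ms, channel$t_off_ms)
  if (hi <= lo) return(numeric(0))
  k_lo <- ceiling((lo - channel$phase_ms - 1e-9) / channel$period_ms)
  k_hi <- floor((hi - channel$phase_ms - 1e-9) / channel$period_ms)
  if (k_hi < k_lo) return(numeric(0))
  channel$phase_ms + channel$period_ms * (k_lo:k_hi)
}

# internal: program data.frame -> integer-step matrix for the engine
program_matrix <- function(program, net) {
  if (is.null(program) || nrow(program) == 0)
    return(matrix(numeric(0), ncol = 7))
  idx <- match(program$neuron, net$neurons$id)
  if (anyNA(idx))
    stop("stimulus targets unknown neuron(s): ",
         paste(unique(program$neuron[is.na(idx)]), collapse = ", "))
  dt <- net$dt
  cap <- function(x) pmin(x, 9e15 * dt)
  cbind(idx - 1,
        program$amplitude,
        round(program$period_ms / dt),
        round(program$width_ms / dt),
        round(cap(program$phase_ms) / dt),
        round(cap(program$t_on_ms) / dt),
        round(cap(program$t_off_ms) / dt))
}
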