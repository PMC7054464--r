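#' Izhikevich neuron parameters
#'
#' Parameter set for the two-variable Izhikevich model
#' \deqn{dv/dt = 0.04 v^2 + 5 v + 140 - u + I, \quad du/dt = a (b v - u),}
#' with the reset `v >= 30  =>  v <- c, u <- u + d`. The defaults
#' (`a = 0.02, b = 0.2, c = -65, d = 8`) give a regular-spiking cortical
#' neuron: silent without drive, tonically spiking under constant current.
#'
#' @param a recovery-variable rate (1/ms scale).
#' @param b coupling of `v` into `u`.
#' @param c reset potential (mV).
#' @param d recovery increment at spike.
#' @param g synaptic scaling factor of the neuron's *outgoing* synapses:
#'   `+20` for excitatory neurons, `-20` for inhibitory ones.
#' @param D variance of the zero-mean white Gaussian noise current. By
#'   convention the noise is one draw per integration step with variance `D`
#'   (see [run_network()] for the per-unit-time alternative).
#' @return An object of class `neuron_params` (a named list).
#' @export
#' @examples
#' p <- neuron_params()
#' izh_step(neuron_state(), p, I_total = 0, dt = 0.1)
neuron_params <- function(a = 0.02, b = 0.2, c = -65, d = 8, g = 20, D = 0) {
  if (!g %in% c(20, -20))
    warning("g is conventionally +20 (excitatory) or -20 (inhibitory)")
  if (D < 0) stop("noise variance D must be >= 0")
  structure(list(a = a, b = b, c = c, d = d, g = g, D = D),
            class = "neuron_params")
}

#' Single-neuron state
#'
#' @param v membrane potential (mV).
#' @param u recovery variable.
#' @param s_post postsynaptic STDP trace (dimensionless, >= 0).
#' @param last_spike_time time of the most recent spike (ms) or `NA`.
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(v = -70, u = -14, s_post = 0, last_spike_time = NA_real_) {
  structure(list(v = v, u = u, spiked_now = FALSE, s_post = s_post,
                 last_spike_time = last_spike_time),
            class = "neuron_state")
}

#' One forward-Euler step of the Izhikevich model
#'
#' Advances `(v, u)` by one step of size `dt` under total current `I_total`,
#' applying the threshold/reset rule. On a spike the postsynaptic STDP trace
#' `s_post` is incremented by 1 (unit-area delta convention). Equation 1 is
#' integrated in a single Euler step; the recovery update uses the freshly
#' updated `v`, matching the published reference scheme for this model.
#'
#' @param state a [neuron_state()].
#' @param params a [neuron_params()].
#' @param I_total total driving current (noise + synaptic + stimulus).
#' @param dt step size (ms), > 0.
#' @param t current time (ms), used only to record the spike time.
#' @return The updated `neuron_state`; `spiked_now` flags a reset this step.
#' @export
izh_step <- function(state, params, I_total, dt, t = NA_real_) {
  stopifnot(dt > 0)
  if (!is.finite(state$v) || !is.finite(state$u) || !is.finite(I_total))
    stop("non-finite state or current in izh_step (v=", state$v,
         ", u=", state$u, ", I=", I_total, ")")
  v <- state$v + dt * (0.04 * state$v^2 + 5 * state$v + 140 - state$u + I_total)
  u <- state$u + dt * params$a * (params$b * v - state$u)
  if (v >= 30) {
    state$v <- params$c
    state$u <- u + params$d
    state$spiked_now <- TRUE
    state$s_post <- state$s_post + 1
    state$last_spike_time <- t
  } else {
    state$v <- v
    state$u <- u
    state$spiked_now <- FALSE
  }
  state
}

#' Gaussian noise current
#'
#' One (or `n`) zero-mean Gaussian draw(s) with variance `D`, the stochastic
#' term of the driving current `I(t) = xi(t) + I_syn(t) + I_stml(t)`. Under
#' the default per-step convention the draw is used as-is for one integration
#' step; with `per_time = TRUE` the variance is interpreted per unit time and
#' the draw is scaled by `1/sqrt(dt)`.
#'
#' @param D noise variance (current^2 units), >= 0.
#' @param dt integration step (ms); only used when `per_time = TRUE`.
#' @param n number of draws.
#' @param per_time interpret `D` as variance per unit time instead of per step.
#' @return Numeric vector of length `n`; exactly 0 when `D = 0`.
#' @export
#' @examples
#' set.seed(1)
#' noise_current(5.5)
noise_current <- function(D, dt = 0.1, n = 1, per_time = FALSE) {
  if (D < 0) stop("noise variance D must be >= 0")
  if (D == 0) return(rep(0, n))
  rnorm(n, mean = 0, sd = sqrt(if (per_time) D / dt else D))
}

#' Total driving current
#'
#' @param noise noise current `xi(t)`.
#' @param syn synaptic current `I_syn(t)`.
#' @param stim stimulus current `I_stml(t)`.
#' @return Their sum.
#' @export
total_current <- function(noise, syn, stim) {
  stopifnot(is.finite(noise), is.finite(syn), is.finite(stim))
  noise + syn + stim
}

#' Simulate a single isolated neuron under constant current
#'
#' Convenience wrapper around the engine: one neuron, no synapses, constant
#' bias current `I`, optional noise.
#'
#' @param I constant driving current.
#' @param duration simulated time (ms).
#' @param dt step (ms).
#' @param params a [neuron_params()].
#' @return Numeric vector of spike times (ms).
#' @export
#' @examples
#' length(run_single_neuron(10, duration = 1000)) # regular spiking
run_single_neuron <- function(I, duration, dt = 0.1, params = neuron_params()) {
  net <- new_network(
    neurons = data.frame(id = "N1", a = params$a, b = params$b, c = params$c,
                         d = params$d, g = params$g, D = params$D, bias = I,
                         stringsAsFactors = FALSE),
    synapses = empty_synapses(), dt = dt)
  run_network(net, program = NULL, duration = duration)$spikes$time_ms
}
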