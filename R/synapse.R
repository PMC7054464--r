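#' Synapse and plasticity parameters
#'
#' Time constants of the Tsodyks-Markram short-term dynamics and of the
#' trace-based STDP rule, shared by all synapses of a network.
#'
#' @param tau_I decay constant of postsynaptic currents (ms).
#' @param tau_rec recovery time from synaptic depression (ms).
#' @param tau_facil facilitation time constant (ms).
#' @param tau_S STDP spiking-trace time constant (ms).
#' @param lambda STDP learning rate.
#' @param alpha STDP asymmetry parameter (depression/potentiation ratio).
#' @param U baseline release probability of the facilitation variable. Not a
#'   published value for this circuit; the conventional 0.5 is used and the
#'   parameter is exposed here.
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(tau_I = 10, tau_rec = 50, tau_facil = 1000,
                           tau_S = 10, lambda = 0.001, alpha = 5, U = 0.5) {
  stopifnot(tau_I > 0, tau_rec > 0, tau_facil > 0, tau_S > 0,
            lambda > 0, alpha > 0, U > 0, U <= 1)
  structure(list(tau_I = tau_I, tau_rec = tau_rec, tau_facil = tau_facil,
                 tau_S = tau_S, lambda = lambda, alpha = alpha, U = U),
            class = "synapse_params")
}

#' A single synapse record
#'
#' Directed weighted connection with short-term-plasticity state and the
#' delayed presynaptic STDP trace. Weights live in `[0, 1]`; the sign and
#' scale of transmission come from the factor `g` inherited from the
#' presynaptic neuron's role (`+20` excitatory, `-20` inhibitory). Only
#' excitatory synapses may be plastic.
#'
#' @param pre,post neuron ids.
#' @param w initial weight in `[0, 1]`.
#' @param g scaling factor (`+20` or `-20`).
#' @param delay_ms axonal conduction delay (ms), > 0.
#' @param plastic logical; STDP-driven?
#' @param U baseline release probability (initialises the facilitation state).
#' @return An object of class `synapse` with TM state `x = 1, y = 0, u_f = U`
#'   and presynaptic trace `s_pre = 0`.
#' @export
synapse <- function(pre, post, w, g = 20, delay_ms = 3, plastic = TRUE, U = 0.5) {
  stopifnot(w >= 0, w <= 1, delay_ms > 0)
  if (plastic && g < 0) stop("inhibitory synapses are always fixed")
  structure(list(pre = pre, post = post, w = w, g = g, delay_ms = delay_ms,
                 plastic = plastic, x = 1, y = 0, u_f = U, s_pre = 0),
            class = "synapse")
}

#' One step of Tsodyks-Markram short-term dynamics
#'
#' Three-pool formulation: recovered resources `x`, active fraction `y`
#' (the released transmitter driving the postsynaptic current) and the
#' implicit inactive pool `1 - x - y`. Between arrivals `y` decays with
#' `tau_I` into the inactive pool, the inactive pool recovers into `x` with
#' `tau_rec`, and the facilitation variable `u_f` relaxes to its baseline `U`
#' with `tau_facil`. On a spike arrival `u_f` is facilitated
#' (`u_f <- u_f + U (1 - u_f)`) and the fraction `u_f * x` moves from `x` to
#' `y`. Decays are exact exponentials applied by operator splitting, so
#' `x + y + inactive = 1` holds to machine precision.
#'
#' @param syn a [synapse()].
#' @param params a [synapse_params()].
#' @param dt step (ms), > 0.
#' @param spike_arrived did a presynaptic spike arrive this step?
#' @return The updated synapse.
#' @export
#' @examples
#' s <- synapse("N1", "N2", w = 0.5)
#' s$y <- 0.5
#' for (i in 1:100) s <- tm_step(s, synapse_params(), dt = 0.1, FALSE)
#' s$y # = 0.5 * exp(-1)
tm_step <- function(syn, params, dt, spike_arrived = FALSE) {
  stopifnot(dt > 0)
  yn <- syn$y * exp(-dt / params$tau_I)
  z <- 1 - syn$x - yn
  syn$x <- syn$x + z * (1 - exp(-dt / params$tau_rec))
  syn$y <- yn
  syn$u_f <- params$U + (syn$u_f - params$U) * exp(-dt / params$tau_facil)
  if (spike_arrived) {
    syn$u_f <- syn$u_f + params$U * (1 - syn$u_f)
    rel <- syn$u_f * syn$x
    syn$y <- syn$y + rel
    syn$x <- syn$x - rel
  }
  if (syn$x < -1e-12 || syn$x > 1 + 1e-12 || syn$y < -1e-12 || syn$y > 1 + 1e-12)
    stop("Tsodyks-Markram state left [0, 1]: x = ", syn$x, ", y = ", syn$y)
  syn
}

#' Synaptic current from a set of incoming synapses
#'
#' The weighted sum `I_syn = sum_j g_j w_j y_j` over all presynaptic
#' connections of a neuron.
#'
#' @param incoming a list of [synapse()] objects (possibly empty).
#' @return The summed current.
#' @export
#' @examples
#' s <- synapse("N1", "N2", w = 0.5, g = 20)
#' s$y <- 0.1
#' synaptic_current(list(s)) # 1
synaptic_current <- function(incoming) {
  if (length(incoming) == 0) return(0)
  sum(vapply(incoming, function(s) s$g * s$w * s$y, numeric(1)))
}

#' STDP update on a postsynaptic spike (potentiation)
#'
#' Multiplicative soft-bounded potentiation: `w <- w + lambda (1 - w) s_pre`,
#' where `s_pre` is the *delayed* presynaptic trace (incremented at arrival
#' time, emission + delay). Called exactly when the postsynaptic neuron
#' fires; a no-op on non-plastic synapses.
#'
#' @param syn a [synapse()].
#' @param params a [synapse_params()].
#' @return The updated synapse (`w` stays in `[0, 1]`).
#' @export
stdp_on_post_spike <- function(syn, params) {
  if (!isTRUE(syn$plastic)) return(syn)
  syn$w <- min(1, max(0, syn$w + params$lambda * (1 - syn$w) * syn$s_pre))
  syn
}

#' STDP update on a presynaptic spike arrival (depression)
#'
#' Multiplicative depression: `w <- w - lambda alpha w s_post`, applied when
#' a presynaptic spike *arrives* (emission time + axonal delay), reading the
#' postsynaptic trace `s_post`. The arrival-time convention is what couples
#' plasticity to path latency and produces the shortest-pathway rule; it
#' must not be simplified to emission time.
#'
#' @param syn a [synapse()].
#' @param params a [synapse_params()].
#' @param s_post_value current value of the postsynaptic neuron's trace.
#' @return The updated synapse (`w` stays in `[0, 1]`).
#' @export
stdp_on_pre_arrival <- function(syn, params, s_post_value) {
  if (!isTRUE(syn$plastic)) return(syn)
  syn$w <- min(1, max(0, syn$w - params$lambda * params$alpha * syn$w * s_post_value))
  syn
}

#' Replay a plastic synapse through the engine's trace-based STDP path
#'
#' Runs the same per-step trace logic the simulation engine uses on one
#' synapse, given explicit presynaptic *arrival* times and postsynaptic
#' spike times (all on the `dt` grid). Same-step coincidences apply
#' potentiation first, then depression; traces are incremented after the
#' updates that consume them, so a spike never pairs with itself.
#'
#' @param arrival_times presynaptic arrival times (ms; emission + delay).
#' @param post_times postsynaptic spike times (ms).
#' @param w0 initial weight.
#' @param params a [synapse_params()].
#' @param dt step (ms).
#' @return Final weight.
#' @export
stdp_replay <- function(arrival_times, post_times, w0,
                        params = synapse_params(), dt = 0.1) {
  stdp_replay_cpp(as.integer(round(arrival_times / dt)),
                  as.integer(round(post_times / dt)),
                  w0, dt, params$tau_S, params$lambda, params$alpha)
}

#' Steady state of the Tsodyks-Markram map under periodic arrivals
#'
#' Closed-form fixed point of the exact inter-spike recursion for a periodic
#' arrival train with inter-spike interval `isi`: between arrivals
#' `y(t) = y0 e^{-t/tau_I}`, the inactive pool obeys a linear two-exponential
#' transfer into `x`, and at each arrival `u_f` facilitates and `u_f x`
#' is released. Returns the per-arrival release (jump of `y`) at steady
#' state. Used as an independent check of the stepped simulation.
#'
#' @param isi inter-arrival interval (ms).
#' @param params a [synapse_params()].
#' @param n_iter iterations of the map (converges geometrically).
#' @return List with steady-state `x`, `u_f` (pre-release) and `release`.
#' @export
tm_periodic_fixed_point <- function(isi, params = synapse_params(), n_iter = 200) {
  fI <- exp(-isi / params$tau_I)
  fR <- exp(-isi / params$tau_rec)
  fF <- exp(-isi / params$tau_facil)
  U <- params$U
  # exact solution of dz/dt = y/tau_I - z/tau_rec with y(t) = y0 exp(-t/tau_I)
  cc <- params$tau_rec / (params$tau_rec - params$tau_I)
  x <- 1; y <- 0; u <- U
  for (i in seq_len(n_iter)) {
    u_spk <- u + U * (1 - u)
    rel <- u_spk * x
    x1 <- x - rel; y1 <- y + rel; z1 <- 1 - x1 - y1
    y2 <- y1 * fI
    z2 <- z1 * fR + y1 * cc * (fR - fI)
    x <- 1 - y2 - z2
    y <- y2
    u <- U + (u_spk - U) * fF
  }
  list(x = x, u_f = u + U * (1 - u), release = (u + U * (1 - u)) * x, y = y)
}
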