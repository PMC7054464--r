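#' Construct a spiking network
#'
#' Assembles neurons and synapses into a simulatable network with a global
#' clock, a spike-arrival delay queue and per-synapse short-term-plasticity
#' and STDP-trace state. Neurons start at the resting fixed point
#' `(v, u) = (-70, -14)`; synapses start with full resources
#' (`x = 1, y = 0, u_f = U`) and zero traces.
#'
#' @param neurons data.frame with columns `id, a, b, c, d, g, D, bias`
#'   (one row per neuron; ids unique; `bias` is a constant current, used
#'   e.g. for the tonic forward-drive neuron).
#' @param synapses data.frame with columns `pre, post, w, g, delay_ms,
#'   plastic` (directed; `(pre, post)` pairs unique; delays > 0, rounded to
#'   the nearest multiple of `dt`).
#' @param dt integration step (ms). Default 0.1 ms so that 3-ms pulses and
#'   3 / 4.2-ms axonal delays are integer numbers of steps.
#' @param params a [synapse_params()].
#' @param noise_per_time if `TRUE` (default), interpret the noise variance
#'   `D` as per unit time (per-step draws scaled by `1/sqrt(dt)`), so the
#'   integrated noise effect is independent of `dt`; `FALSE` uses one draw
#'   of variance `D` per step, which at sub-millisecond `dt` renders the
#'   noise inert.
#' @return An object of class `snn_network`.
#' @export
new_network <- function(neurons, synapses, dt = 0.1, params = synapse_params(),
                        noise_per_time = TRUE) {
  stopifnot(is.data.frame(neurons), is.data.frame(synapses), dt > 0)
  need_n <- c("id", "a", "b", "c", "d", "g", "D", "bias")
  if (!all(need_n %in% names(neurons)))
    stop("neurons must have columns: ", paste(need_n, collapse = ", "))
  if (anyDuplicated(neurons$id)) stop("neuron ids must be unique")
  need_s <- c("pre", "post", "w", "g", "delay_ms", "plastic")
  if (!all(need_s %in% names(synapses)))
    stop("synapses must have columns: ", paste(need_s, collapse = ", "))
  if (nrow(synapses) > 0) {
    if (anyDuplicated(synapses[, c("pre", "post")]))
      stop("(pre, post) pairs must be unique")
    if (!all(synapses$pre %in% neurons$id) || !all(synapses$post %in% neurons$id))
      stop("synapse endpoints must be declared neurons")
    if (any(synapses$w < 0 | synapses$w > 1)) stop("weights must lie in [0, 1]")
    if (any(synapses$plastic & synapses$g < 0))
      stop("inhibitory synapses are always fixed (non-plastic)")
    if (any(round(synapses$delay_ms / dt) < 1))
      stop("delays must be at least one step")
  }
  if (any(neurons$D < 0)) stop("noise variance D must be >= 0")
  n_syn <- nrow(synapses)
  net <- structure(list(
    neurons = neurons, synapses = synapses, dt = dt, t = 0,
    params = params, noise_per_time = noise_per_time,
    state = list(
      v = rep(-70, nrow(neurons)), u = rep(-14, nrow(neurons)),
      s_post = rep(0, nrow(neurons)),
      x = rep(1, n_syn), y = rep(0, n_syn), uf = rep(params$U, n_syn),
      s_pre = rep(0, n_syn),
      pending = matrix(numeric(0), ncol = 3))),
    class = "snn_network")
  net
}

#' @export
print.snn_network <- function(x, ...) {
  cat("<snn_network> ", nrow(x$neurons), " neurons, ", nrow(x$synapses),
      " synapses, t = ", x$t, " ms, dt = ", x$dt, " ms\n", sep = "")
  if (nrow(x$synapses) > 0) {
    s <- x$synapses
    cat(sprintf("  %s->%s w=%.3f g=%+.0f delay=%.1f%s\n", s$pre, s$post, s$w,
                s$g, s$delay_ms, ifelse(s$plastic, " [plastic]", "")),
        sep = "")
  }
  invisible(x)
}

#' Zero-row synapse table with the required columns
#' @return Empty data.frame usable in [new_network()].
#' @export
empty_synapses <- function() {
  data.frame(pre = character(0), post = character(0), w = numeric(0),
             g = numeric(0), delay_ms = numeric(0), plastic = logical(0),
             stringsAsFactors = FALSE)
}

neuron_row <- function(id, g = 20, D = 0, bias = 0, p = neuron_params()) {
  data.frame(id = id, a = p$a, b = p$b, c = p$c, d = p$d, g = g, D = D,
             bias = bias, stringsAsFactors = FALSE)
}

syn_row <- function(pre, post, w, g = 20, delay_ms = 3, plastic = TRUE) {
  data.frame(pre = pre, post = post, w = w, g = g, delay_ms = delay_ms,
             plastic = plastic, stringsAsFactors = FALSE)
}

#' Build a feedforward motif
#'
#' The three canonical motifs used to demonstrate how delay-aware STDP
#' treats alternative spike-conducting routes:
#' * `chain2`: N1 -> N2;
#' * `chain3`: N1 -> N2 -> N3;
#' * `shortcut`: `chain3` plus the direct link N1 -> N3, whose delay
#'   (`delay_shortcut`, default 3 ms) is strictly shorter than the two-hop
#'   latency (3 + 3 ms), so spikes via the direct route reach N3 first and
#'   the late two-hop input N2 -> N3 is depressed (shortest-pathway rule).
#'
#' All synapses are excitatory and plastic.
#'
#' @param kind one of `"chain2"`, `"chain3"`, `"shortcut"`.
#' @param init_w initial weight of every synapse (default 0.5, strong enough
#'   to conduct activity along the chain).
#' @param D per-neuron noise variance.
#' @param delay_parallel per-hop delay (ms).
#' @param delay_shortcut delay of the direct N1 -> N3 link (ms); must be
#'   shorter than twice `delay_parallel`.
#' @param dt integration step (ms).
#' @param params a [synapse_params()].
#' @return An `snn_network`.
#' @export
#' @examples
#' build_motif("shortcut")
build_motif <- function(kind = c("shortcut", "chain2", "chain3"),
                        init_w = 0.5, D = 0, delay_parallel = 3,
                        delay_shortcut = 3, dt = 0.1,
                        params = synapse_params()) {
  kind <- match.arg(kind)
  if (kind == "shortcut" && delay_shortcut >= 2 * delay_parallel)
    stop("the shortcut delay must be shorter than the two-hop latency")
  ids <- switch(kind, chain2 = c("N1", "N2"), c("N1", "N2", "N3"))
  neurons <- do.call(rbind, lapply(ids, neuron_row, g = 20, D = D))
  synapses <- syn_row("N1", "N2", init_w, delay_ms = delay_parallel)
  if (kind != "chain2")
    synapses <- rbind(synapses, syn_row("N2", "N3", init_w, delay_ms = delay_parallel))
  if (kind == "shortcut")
    synapses <- rbind(synapses, syn_row("N1", "N3", init_w, delay_ms = delay_shortcut))
  new_network(neurons, synapses, dt = dt, params = params)
}

#' Build the four-neuron associative-conditioning circuit
#'
#' Two bidirectionally coupled CS neurons (N1, N2), one US neuron (N3) and a
#' motoneuron (M). The CS -> US couplings `w31`, `w32` are plastic and start
#' below the transmission threshold, so a CS alone cannot fire N3 before
#' training; the US -> motoneuron reflex is fixed at `w = 1` and always
#' works. Initial plastic weights are drawn uniformly from `init_w_range`
#' using the current RNG state.
#'
#' @param init_w_range range of the initial plastic weights (sub-threshold).
#' @param D per-neuron noise variance (the intermediate value 5.5 is the
#'   regime in which conditioning is robust).
#' @param n12_w weight of the fixed bidirectional CS-CS couplings.
#' @param dt integration step (ms).
#' @param params a [synapse_params()].
#' @return An `snn_network`.
#' @export
build_conditioning_snn <- function(init_w_range = c(0.07, 0.14), D = 5.5,
                                   n12_w = 0.5, dt = 0.1,
                                   params = synapse_params()) {
  w0 <- runif(2, init_w_range[1], init_w_range[2])
  neurons <- rbind(neuron_row("N1", D = D), neuron_row("N2", D = D),
                   neuron_row("N3", D = D), neuron_row("M", D = D))
  synapses <- rbind(
    syn_row("N1", "N2", n12_w, plastic = FALSE),
    syn_row("N2", "N1", n12_w, plastic = FALSE),
    syn_row("N1", "N3", w0[1], plastic = TRUE),
    syn_row("N2", "N3", w0[2], delay_ms = 4.2, plastic = TRUE),
    syn_row("N3", "M", 1, plastic = FALSE))
  new_network(neurons, synapses, dt = dt, params = params)
}

#' Build the seven-neuron sensorimotor network of the animat
#'
#' Two CS (sonar) neurons N1, N2; two US (touch) neurons N3, N4; two
#' steering motoneurons N5 (right motor) and N6 (left motor); and the tonic
#' forward-drive neuron N7 (constant suprathreshold bias, its firing rate F
#' sets the forward speed). Structure:
#' * plastic excitatory CS -> US synapses `w31, w41, w32, w42` ("parallel"
#'   N1 -> N3 and N2 -> N4 with 3-ms delays, "diagonal" N1 -> N4 and
#'   N2 -> N3 with 4.2-ms delays, proportional to interneuron distance);
#' * fixed bidirectional excitatory coupling N1 <-> N2 (synaptic
#'   competition between the CS channels);
#' * fixed mutual inhibition N3 <-> N4 (`w = 1, g = -20`; neuronal
#'   competition, lateralises the response);
#' * fixed excitatory reflex synapses N3 -> N5 and N4 -> N6 (`w = 1`).
#'
#' Initial plastic weights are drawn uniformly from `init_w_range` using the
#' current RNG state: sub-threshold, so an untrained CS evokes no motor
#' response.
#'
#' @param init_w_range range of initial plastic weights.
#' @param D per-neuron noise variance.
#' @param n12_w weight of the fixed CS <-> CS couplings.
#' @param n12_plastic make the CS <-> CS couplings STDP-driven (off by
#'   default: STDP on these couplings degrades selectivity).
#' @param n7_bias constant drive of the tonic neuron N7 (0 disables forward
#'   motion, as in classical conditioning).
#' @param dt integration step (ms).
#' @param params a [synapse_params()].
#' @return An `snn_network`.
#' @export
#' @examples
#' set.seed(1)
#' net <- build_robot_snn()
#' subset(net$synapses, plastic)
build_robot_snn <- function(init_w_range = c(0.07, 0.14), D = 5.5,
                            n12_w = 0.5, n12_plastic = FALSE, n7_bias = 6,
                            dt = 0.1, params = synapse_params()) {
  w0 <- runif(4, init_w_range[1], init_w_range[2])
  neurons <- rbind(
    neuron_row("N1", D = D), neuron_row("N2", D = D),
    neuron_row("N3", D = D), neuron_row("N4", D = D),
    neuron_row("N5", D = D), neuron_row("N6", D = D),
    neuron_row("N7", D = D, bias = n7_bias))
  synapses <- rbind(
    syn_row("N1", "N3", w0[1], delay_ms = 3.0, plastic = TRUE),   # parallel
    syn_row("N2", "N4", w0[2], delay_ms = 3.0, plastic = TRUE),   # parallel
    syn_row("N1", "N4", w0[3], delay_ms = 4.2, plastic = TRUE),   # diagonal
    syn_row("N2", "N3", w0[4], delay_ms = 4.2, plastic = TRUE),   # diagonal
    syn_row("N1", "N2", n12_w, plastic = n12_plastic),
    syn_row("N2", "N1", n12_w, plastic = n12_plastic),
    syn_row("N3", "N4", 1, g = -20, plastic = FALSE),
    syn_row("N4", "N3", 1, g = -20, plastic = FALSE),
    syn_row("N3", "N5", 1, plastic = FALSE),
    syn_row("N4", "N6", 1, plastic = FALSE))
  new_network(neurons, synapses, dt = dt, params = params)
}

#' Get or set a weight by synapse endpoints
#' @param net an `snn_network`.
#' @param pre,post neuron ids.
#' @return `get_weight`: the weight; `set_weight`: the modified network.
#' @export
get_weight <- function(net, pre, post) {
  i <- which(net$synapses$pre == pre & net$synapses$post == post)
  if (length(i) != 1) stop("no synapse ", pre, "->", post)
  net$synapses$w[i]
}

#' @rdname get_weight
#' @param w new weight in `[0, 1]`.
#' @export
set_weight <- function(net, pre, post, w) {
  stopifnot(w >= 0, w <= 1)
  i <- which(net$synapses$pre == pre & net$synapses$post == post)
  if (length(i) != 1) stop("no synapse ", pre, "->", post)
  net$synapses$w[i] <- w
  net
}

syn_labels <- function(net) {
  if (nrow(net$synapses) == 0) return(character(0))
  paste0(net$synapses$pre, "->", net$synapses$post)
}

#' Run the closed fixed-step simulation loop
#'
#' Advances the network clock in steps of `dt`. Per step: STDP traces and
#' short-term-plasticity variables decay; queued spike arrivals are
#' delivered (facilitation + transmitter release); currents are evaluated
#' (stimulus pulses, per-neuron Gaussian noise, bias, synaptic `g w y`);
#' neurons are integrated and reset; potentiation is applied for every
#' postsynaptic spike, then depression for every presynaptic arrival;
#' finally traces are incremented and outgoing arrivals enqueued at
#' `t + delay`. Bit-reproducible for a fixed RNG seed.
#'
#' @param net an `snn_network`.
#' @param program a stimulus program ([stimulus_program()], [pulse_train()],
#'   [paired_train()]) or `NULL` for no stimulation.
#' @param duration simulated time (ms), > 0.
#' @param sample_period weight-sampling period (ms); 0 disables the weight
#'   log. Default 100 ms (one inter-pulse interval).
#' @param plastic apply STDP? Set `FALSE` to freeze all weights (probes).
#' @param noise draw noise currents? `FALSE` forces `D = 0` for this run.
#' @param record_spikes keep the spike log (disable for long quiet runs).
#' @return A list of class `snn_run`: `spikes` (data.frame `neuron`,
#'   `time_ms`), `weights` (data.frame `time_ms`, `synapse`, `w`),
#'   `spike_counts` (named vector), and `net`, the updated network whose
#'   clock has advanced by `duration`.
#' @export
#' @examples
#' net <- build_motif("chain2", D = 0)
#' run <- run_network(net, pulse_train("N1", amplitude = 40), duration = 1000)
#' run$spike_counts
run_network <- function(net, program = NULL, duration, sample_period = 100,
                        plastic = TRUE, noise = TRUE, record_spikes = TRUE) {
  stopifnot(inherits(net, "snn_network"), duration > 0)
  dt <- net$dt
  n_steps <- as.integer(round(duration / dt))
  stim <- program_matrix(program, net)
  topo <- list(
    pre = match(net$synapses$pre, net$neurons$id) - 1L,
    post = match(net$synapses$post, net$neurons$id) - 1L,
    g = as.numeric(net$synapses$g),
    delay_steps = as.integer(round(net$synapses$delay_ms / dt)),
    plastic = as.integer(net$synapses$plastic))
  pars <- c(list(a = net$neurons$a, b = net$neurons$b, c = net$neurons$c,
                 d = net$neurons$d, bias = net$neurons$bias,
                 D = if (noise) net$neurons$D else rep(0, nrow(net$neurons)),
                 noise_scale = if (net$noise_per_time) 1 / dt else 1),
            unclass(net$params))
  st <- net$state
  st$w <- as.numeric(net$synapses$w)
  sample_every <- if (sample_period > 0) as.integer(round(sample_period / dt)) else 0L
  out <- engine_run_cpp(st, topo, pars, stim, n_steps, dt,
                        round(net$t / dt), plastic, sample_every,
                        record_spikes)
  net$state <- list(v = out$v, u = out$u, s_post = out$s_post,
                    x = out$x, y = out$y, uf = out$uf, s_pre = out$s_pre,
                    pending = out$pending)
  net$synapses$w <- out$w
  net$t <- out$t0_step_new * dt
  labs <- syn_labels(net)
  weights <- if (sample_every > 0 && length(out$wlog_t) > 0 && length(labs) > 0) {
    data.frame(time_ms = rep(out$wlog_t, each = length(labs)),
               synapse = rep(labs, times = length(out$wlog_t)),
               w = as.vector(t(out$wlog_w)), stringsAsFactors = FALSE)
  } else {
    data.frame(time_ms = numeric(0), synapse = character(0), w = numeric(0))
  }
  structure(list(
    spikes = data.frame(neuron = net$neurons$id[out$spike_id],
                        time_ms = out$spike_t, stringsAsFactors = FALSE),
    weights = weights,
    spike_counts = setNames(out$spike_count, net$neurons$id),
    net = net), class = "snn_run")
}

#' @export
print.snn_run <- function(x, ...) {
  cat("<snn_run> ", nrow(x$spikes), " spikes, clock at t = ", x$net$t,
      " ms\n", sep = "")
  print(x$spike_counts)
  invisible(x)
}
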