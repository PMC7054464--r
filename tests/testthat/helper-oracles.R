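# Independent oracles, kept deliberately separate from the package's
# implementation paths.

# Plain-R forward-Euler integration of the Izhikevich model at an arbitrary
# (typically much finer) step; returns the spike count.
izh_euler_spike_count <- function(I, duration_ms, dt, a = 0.02, b = 0.2,
                                  c = -65, d = 8) {
  v <- -70; u <- -14; n <- 0
  for (k in seq_len(round(duration_ms / dt))) {
    vn <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
    un <- u + dt * a * (b * vn - u)
    if (vn >= 30) {
      v <- c; u <- un + d; n <- n + 1
    } else {
      v <- vn; u <- un
    }
  }
  n
}

# Brute-force chronological all-pairs STDP oracle: replays pre-ARRIVAL and
# post-spike events in time order, summing exponential trace contributions
# over all earlier events with the same w-dependence as the rule. Same-time
# coincidences: potentiation first, then depression; neither sees the
# same-time event of the other kind.
stdp_allpairs_oracle <- function(arrival_times, post_times, w0,
                                 params = synapse_params()) {
  w <- w0
  tau <- params$tau_S
  times <- sort(unique(c(arrival_times, post_times)))
  past_arr <- numeric(0)
  past_post <- numeric(0)
  for (t in times) {
    n_post <- sum(post_times == t)
    n_arr <- sum(arrival_times == t)
    for (q in seq_len(n_post)) {
      s_pre <- sum(exp(-(t - past_arr) / tau))
      w <- min(1, max(0, w + params$lambda * (1 - w) * s_pre))
    }
    for (q in seq_len(n_arr)) {
      s_post <- sum(exp(-(t - past_post) / tau))
      w <- min(1, max(0, w - params$lambda * params$alpha * w * s_post))
    }
    past_post <- c(past_post, rep(t, n_post))
    past_arr <- c(past_arr, rep(t, n_arr))
  }
  w
}

# random spike-train instance on the dt grid
random_trains <- function(n_max = 50, horizon_ms = 500, dt = 0.1) {
  n_a <- sample(0:n_max, 1)
  n_p <- sample(0:n_max, 1)
  list(arr = sort(sample(seq(0, horizon_ms, by = dt), n_a)),
       post = sort(sample(seq(0, horizon_ms, by = dt), n_p)))
}

# the exact two-window collision-rate comparison used in several tests
window_count <- function(times, from, to) sum(times >= from & times < to)
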