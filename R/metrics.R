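#' Mean parallel and diagonal coupling weights
#'
#' Channel-selectivity summary of the four plastic CS -> US couplings:
#' `w_P = (w31 + w42)/2` (parallel) and `w_D = (w41 + w32)/2` (diagonal).
#'
#' @param w31,w42,w41,w32 weights in `[0, 1]` (`wij` = coupling from neuron
#'   j to neuron i).
#' @return Named numeric vector `c(w_P, w_D)`.
#' @export
#' @examples
#' coupling_means(0.8, 0.6, 0.2, 0.4) # w_P = 0.7, w_D = 0.3
coupling_means <- function(w31, w42, w41, w32) {
  w <- c(w31 = w31, w42 = w42, w41 = w41, w32 = w32)
  if (any(!is.finite(w)) || any(w < 0 | w > 1))
    stop("all weights must lie in [0, 1]")
  c(w_P = (w31 + w42) / 2, w_D = (w41 + w32) / 2)
}

#' Channel selectivity
#'
#' Ratio and difference of the parallel and diagonal mean weights, oriented
#' by the wiring so PA and DA runs are comparable: for `"PA"` learning the
#' parallel couplings are the "correct" ones (`S = w_P / w_D`), for `"DA"`
#' the diagonal ones (`S = w_D / w_P`).
#'
#' @param w_P,w_D mean parallel / diagonal weights.
#' @param wiring `"PA"` or `"DA"`.
#' @param eps denominator floor below which the ratio is `NA`.
#' @return List with `ratio`, `diff` and the `wiring` orientation.
#' @export
selectivity <- function(w_P, w_D, wiring = "PA", eps = 1e-6) {
  num <- if (wiring == "PA") w_P else w_D
  den <- if (wiring == "PA") w_D else w_P
  list(ratio = if (den > eps) num / den else NA_real_,
       diff = num - den, wiring = wiring)
}

#' Windowed collision rate
#'
#' Counts events in consecutive windows and normalises to events per
#' minute.
#'
#' @param event_times_s event times (s).
#' @param window_s window length (s), > 0.
#' @param duration_s total observation time (s); defaults to the last full
#'   window containing an event.
#' @return data.frame with `window_start_s`, `n` and `rate_per_min`.
#' @export
#' @examples
#' collision_rate(c(10, 30, 50, 70, 90, 110), window_s = 120, duration_s = 240)
collision_rate <- function(event_times_s, window_s, duration_s = NULL) {
  stopifnot(window_s > 0)
  if (is.null(duration_s))
    duration_s <- if (length(event_times_s)) max(event_times_s) else window_s
  starts <- seq(0, max(0, duration_s - window_s), by = window_s)
  n <- vapply(starts, function(s)
    sum(event_times_s >= s & event_times_s < s + window_s), integer(1))
  data.frame(window_start_s = starts, n = n,
             rate_per_min = n / window_s * 60)
}

#' First cycle at which learning is established
#'
#' Scans ordered per-cycle probe outcomes (both sides passing) and returns
#' the first cycle that passes and keeps passing for `confirm` further
#' cycles; `NA` (a sentinel, not an error) if the budget is exhausted.
#'
#' @param pass_both logical vector, one entry per cycle.
#' @param confirm number of confirmation cycles required (default 1).
#' @return Integer cycle index or `NA`.
#' @export
#' @examples
#' cycles_to_learn(c(FALSE, FALSE, TRUE, TRUE)) # 3
cycles_to_learn <- function(pass_both, confirm = 1) {
  n <- length(pass_both)
  for (i in seq_len(max(0, n - confirm))) {
    if (all(pass_both[i:(i + confirm)])) return(i)
  }
  NA_integer_
}
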