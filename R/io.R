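#' Write / read a network topology as JSON
#'
#' Nodes carry roles and neuron parameters; edges carry weight, scaling
#' factor, delay and the plasticity flag. Dynamic state (membrane
#' potentials, traces, pending arrivals) is not serialised: a read network
#' starts from rest with the stored weights.
#'
#' @param net an `snn_network`.
#' @param path output file.
#' @return `write_network_json` returns `path` invisibly;
#'   `read_network_json` returns an `snn_network`.
#' @export
write_network_json <- function(net, path) {
  obj <- list(dt = net$dt,
              params = unclass(net$params),
              noise_per_time = net$noise_per_time,
              neurons = net$neurons, synapses = net$synapses)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(synapse_params, obj$params)
  new_network(as.data.frame(obj$neurons), as.data.frame(obj$synapses),
              dt = obj$dt, params = params,
              noise_per_time = isTRUE(obj$noise_per_time))
}

#' Synapse table of a network
#'
#' The serialisable weight table (`pre, post, w, g, delay_ms, plastic`),
#' suitable for checkpointing and for weight-trajectory logs.
#'
#' @param net an `snn_network`.
#' @param path optional CSV output file.
#' @return The synapse data.frame (invisibly if written to `path`).
#' @export
synapse_table <- function(net, path = NULL) {
  tab <- net$synapses[, c("pre", "post", "w", "g", "delay_ms", "plastic")]
  if (!is.null(path)) {
    write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Read a run configuration (YAML or JSON)
#'
#' Flat, schema-checked configuration used by the command-line interface.
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list of class `run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a named list of configuration values.
#' @export
validate_run_config <- function(cfg = list()) {
  defaults <- list(
    seed = 1L, dt = 0.1, D = 5.5, noise_per_time = FALSE,
    U = 0.5, tau_I = 10, tau_rec = 50, tau_facil = 1000, tau_S = 10,
    lambda = 0.001, alpha = 5,
    amplitude = 15, lag_ms = 10, rate_hz = 10, width_ms = 3,
    episode_ms = 20000, n_cycles = 16, wiring = "PA",
    init_w_min = 0.07, init_w_max = 0.14, n12_w = 0.5, n7_bias = 6,
    motif = "shortcut", motif_init_w = 0.5, motif_duration_s = 200,
    arena = "default", n_obstacles = 3, duration_s = 360,
    swap_at_s = NA_real_, control_period_ms = 10,
    k_f = 0.01, k_m = 0.6, tau_motor_ms = 30, tau_rate_ms = 500,
    rate_f0 = 14)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- modifyList(defaults, cfg)
  structure(out, class = "run_config")
}

#' Reproducibility manifest
#'
#' Captures the configuration, its MD5 hash, the seed and the package
#' version; rerunning from the manifest reproduces all outputs exactly.
#'
#' @param cfg a `run_config`.
#' @param path optional JSON output file.
#' @return The manifest list (invisibly if written).
#' @export
run_manifest <- function(cfg, path = NULL) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg)[order(names(cfg))], tmp,
                       auto_unbox = TRUE, digits = NA)
  man <- list(config = unclass(cfg),
              config_md5 = unname(tools::md5sum(tmp)),
              package = "snnanimat",
              version = as.character(utils::packageVersion("snnanimat")))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
    return(invisible(man))
  }
  man
}

#' Write a run summary as JSON
#'
#' @param summary named list (seed, schedule, cycles to learn, final
#'   weights, probe outcomes, ...).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
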