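#' Bundled run configuration
#'
#' Collects every module's parameter set in one object. The defaults
#' reproduce the study conditions: a 160/40 excitatory/inhibitory network,
#' R = 400 MOhm, C = 10 pF, tau_ip = 100 ms, initial Vthr = 0.2 V,
#' C_IP = 15 fires/s, sigma = 0.3, W in [0, 2], Vthr in [0.125, 0.4] V,
#' T_bin = 150 ms, F_poisson = 150 Hz.
#'
#' @param network a [network_config()].
#' @param plasticity a [plasticity_config()].
#' @param neuron a [neuron_params()].
#' @param synapse a [synapse_params()].
#' @param encoding an [encoding_config()].
#' @param waveform a [waveform_spec()] for the `generate` command.
#' @param ridge readout ridge penalty (default `1e-6`).
#' @param eps_practical relative offset of the deployable threshold above
#'   `D_thr_no` (default 0.05): `D_thr = D_thr_no * (1 + eps)` is usable
#'   when `D_thr_ab` is unknown.
#' @return A list of class `run_config`.
#' @export
run_config <- function(network = network_config(),
                       plasticity = plasticity_config(),
                       neuron = neuron_params(),
                       synapse = synapse_params(),
                       encoding = encoding_config(),
                       waveform = waveform_spec(),
                       ridge = 1e-6, eps_practical = 0.05) {
  stopifnot(ridge >= 0, eps_practical >= 0)
  structure(list(network = network, plasticity = plasticity,
                 neuron = neuron, synapse = synapse, encoding = encoding,
                 waveform = waveform, ridge = ridge,
                 eps_practical = eps_practical),
            class = "run_config")
}

#' Learning-rate grids of the study
#'
#' `SLR` is the SDSP step grid `c(0.1, 0.2, 0.5, 1.0, 2.0)`; `Pthr` the
#' threshold step grid `c(0.025, 0.05, 0.1, 0.3)` volts.
#'
#' @return Named list with elements `SLR` and `Pthr`.
#' @export
learning_rate_grids <- function() {
  list(SLR = c(0.1, 0.2, 0.5, 1.0, 2.0),
       Pthr = c(0.025, 0.05, 0.1, 0.3))
}

strip_class <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_class)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Write a run configuration as YAML
#'
#' Sections mirror the module structure (`network`, `plasticity`, `neuron`,
#' `synapse`, `encoding`, `waveform`, plus scalar options).
#'
#' @param config a [run_config()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  cfg <- strip_class(unclass(config))
  cfg$waveform$beat_shape <- as.list(config$waveform$beat_shape)
  if (!is.null(config$waveform$anomalies))
    cfg$waveform$anomalies <- as.list(config$waveform$anomalies)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Missing fields fall back to the packaged defaults, so a config file only
#' needs to state what it overrides.
#'
#' @param path YAML file written by [write_run_config()] (or by hand).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  d <- run_config()
  merge1 <- function(def, over) {
    if (is.null(over)) return(def)
    for (nm in names(over)) def[[nm]] <- over[[nm]]
    def
  }
  wf <- merge1(unclass(d$waveform), raw$waveform)
  if (!is.null(raw$waveform$beat_shape))
    wf$beat_shape <- as.data.frame(raw$waveform$beat_shape)
  if (!is.null(raw$waveform$anomalies))
    wf$anomalies <- as.data.frame(raw$waveform$anomalies)
  run_config(
    network = do.call(network_config, merge1(list(), raw$network)),
    plasticity = do.call(plasticity_config, merge1(list(), raw$plasticity)),
    neuron = do.call(neuron_params,
                     merge1(list(), raw$neuron[names(raw$neuron) %in%
                       names(formals(neuron_params))])),
    synapse = do.call(synapse_params,
                      merge1(list(), raw$synapse[names(raw$synapse) %in%
                        names(formals(synapse_params))])),
    encoding = do.call(encoding_config, merge1(list(), raw$encoding)),
    waveform = do.call(waveform_spec, wf[names(wf) %in%
                                           names(formals(waveform_spec))]),
    ridge = if (is.null(raw$ridge)) d$ridge else raw$ridge,
    eps_practical = if (is.null(raw$eps_practical)) d$eps_practical
                    else raw$eps_practical)
}
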