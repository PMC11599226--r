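#' Network architecture configuration
#'
#' The middle layer is a randomly connected recurrent network of 80%
#' excitatory and 20% inhibitory LIF neurons. Input-layer neurons project to
#' excitatory neurons only. Each potential edge is drawn independently with
#' its projection's connection probability; inhibitory neurons never connect
#' to inhibitory neurons (`P_II = 0`).
#'
#' @param N_exc number of excitatory neurons (default 160).
#' @param N_inh number of inhibitory neurons (default 40).
#' @param N_input number of input-layer neurons (default 100).
#' @param P_in input-to-excitatory connection probability (default 0.1).
#' @param P_EE,P_EI,P_IE,P_II recurrent connection probabilities (defaults
#'   5%, 2%, 10%, 0).
#' @param dt integration step in seconds (default 0.1 ms).
#' @param allow_autapses keep E-to-E self-connections (default `FALSE`).
#' @return A list of class `network_config`.
#' @export
network_config <- function(N_exc = 160, N_inh = 40, N_input = 100,
                           P_in = 0.1, P_EE = 0.05, P_EI = 0.02,
                           P_IE = 0.10, P_II = 0, dt = 1e-4,
                           allow_autapses = FALSE) {
  probs <- c(P_in, P_EE, P_EI, P_IE, P_II)
  stopifnot(all(probs >= 0), all(probs <= 1), dt > 0)
  if (P_II != 0)
    stop("P_II must be 0: inhibitory neurons do not connect to each other")
  if (N_exc + N_inh <= 0) stop("network must contain at least one neuron")
  if (N_input <= 0) stop("N_input must be positive")
  structure(list(N_exc = N_exc, N_inh = N_inh, N_input = N_input,
                 P_in = P_in, P_EE = P_EE, P_EI = P_EI, P_IE = P_IE,
                 P_II = P_II, dt = dt,
                 allow_autapses = isTRUE(allow_autapses)),
            class = "network_config")
}

#' Build a random excitatory/inhibitory spiking network
#'
#' Draws the connection masks Bernoulli(P) per projection and initializes
#' weights and thresholds: all active E-to-E weights start at exactly 1.0
#' (the plastic projection), all other active weights are drawn
#' Uniform(0, Wmax), and every firing threshold starts at `Vthr0` with the
#' learning thresholds at `Vthr0 / 2`. Uses R's RNG: call `set.seed()` first
#' for reproducible wiring.
#'
#' @param cfg a [network_config()].
#' @param plast a [plasticity_config()].
#' @param neuron a [neuron_params()]; shared by both populations.
#' @param syn a [synapse_params()]; the same time constant and charge scale
#'   are used for every projection (inhibitory synapses flip the sign).
#' @param Vthr0 initial firing threshold in volts (default 0.2).
#' @return A list of class `srnn_network` holding masks, weights, thresholds
#'   and parameter sets. Weight matrices are oriented presynaptic x
#'   postsynaptic; entries outside the mask are zero and ignored.
#' @export
build_network <- function(cfg = network_config(),
                          plast = plasticity_config(),
                          neuron = neuron_params(),
                          syn = synapse_params(),
                          Vthr0 = 0.2) {
  ne <- cfg$N_exc; ni <- cfg$N_inh; nin <- cfg$N_input
  draw_mask <- function(npre, npost, p) {
    matrix(runif(npre * npost) < p, nrow = npre, ncol = npost)
  }
  m_in <- draw_mask(nin, ne, cfg$P_in)
  m_ee <- draw_mask(ne, ne, cfg$P_EE)
  if (!cfg$allow_autapses && ne > 0) diag(m_ee) <- FALSE
  m_ei <- draw_mask(ne, ni, cfg$P_EI)
  m_ie <- draw_mask(ni, ne, cfg$P_IE)
  rand_w <- function(mask) {
    w <- matrix(0, nrow(mask), ncol(mask))
    w[mask] <- runif(sum(mask), 0, plast$Wmax)
    w
  }
  w_in <- rand_w(m_in)
  w_ei <- rand_w(m_ei)
  w_ie <- rand_w(m_ie)
  w_ee <- matrix(0, ne, ne)
  w_ee[m_ee] <- 1.0
  structure(list(
    cfg = cfg, plast = plast, neuron = neuron, syn = syn,
    m_in = m_in, w_in = w_in, m_ee = m_ee, w_ee = w_ee,
    m_ei = m_ei, w_ei = w_ei, m_ie = m_ie, w_ie = w_ie,
    Vthr = rep(Vthr0, ne + ni)), class = "srnn_network")
}

#' @export
print.srnn_network <- function(x, ...) {
  cat(sprintf(
    "srnn_network: %d excitatory + %d inhibitory neurons, %d inputs\n",
    x$cfg$N_exc, x$cfg$N_inh, x$cfg$N_input))
  cat(sprintf("  active synapses: in->E %d, E->E %d, E->I %d, I->E %d\n",
              sum(x$m_in), sum(x$m_ee), sum(x$m_ei), sum(x$m_ie)))
  cat(sprintf("  Vthr range [%.3f, %.3f] V; E->E weights [%.3f, %.3f]\n",
              min(x$Vthr), max(x$Vthr),
              if (any(x$m_ee)) min(x$w_ee[x$m_ee]) else NA,
              if (any(x$m_ee)) max(x$w_ee[x$m_ee]) else NA))
  invisible(x)
}

#' Run the clock-driven network simulation
#'
#' Composes the per-step dynamics and learning rules over `n_steps` steps of
#' size `dt`: decay synaptic currents and calcium traces; deliver external
#' input spikes; deliver recurrent spikes fired in the previous step
#' (inhibitory with negative sign), applying SDSP at active E-to-E synapses
#' on each presynaptic arrival; integrate the membranes with the exact
#' exponential update; detect threshold crossings; and apply event-driven IP
#' plus threshold synchronization on each excitatory fire. With
#' `plasticity_on = FALSE` the weights and thresholds are returned bitwise
#' unchanged (frozen network).
#'
#' @param network an `srnn_network` from [build_network()].
#' @param input_raster a data frame with integer column `step` (0-based) and
#'   `neuron` (0-based input-neuron index), sorted by `step`, e.g. from
#'   [gen_input_raster()]. May be empty.
#' @param T total simulated time in seconds; `n_steps = round(T / dt)`.
#' @param plasticity_on logical master switch; when `TRUE` the individual
#'   `sdsp_enabled` / `ip_enabled` flags of the plasticity config apply.
#' @param state optional initial dynamic state (a `state` element of a
#'   previous result) to continue from; defaults to rest.
#' @param trace_neuron optional 0-based global neuron index whose membrane
#'   potential is recorded every step (for diagnostics).
#' @return A list of class `srnn_run` with elements `spikes` (data frame
#'   `time`, `neuron`; 0-based global indices, excitatory first), `network`
#'   (with updated `w_ee` and `Vthr`), `state` (final dynamic state),
#'   `events` (plasticity event counts) and `T`, `dt`.
#' @export
run_network <- function(network, input_raster = NULL, T, plasticity_on = TRUE,
                        state = NULL, trace_neuron = -1L) {
  stopifnot(inherits(network, "srnn_network"), T >= 0)
  cfg <- network$cfg
  n <- cfg$N_exc + cfg$N_inh
  n_steps <- as.integer(round(T / cfg$dt))
  if (is.null(input_raster)) {
    in_step <- integer(0); in_neuron <- integer(0)
  } else {
    stopifnot(all(c("step", "neuron") %in% names(input_raster)))
    if (is.unsorted(input_raster$step))
      input_raster <- input_raster[order(input_raster$step), ]
    if (nrow(input_raster) > 0 &&
        (min(input_raster$neuron) < 0 ||
         max(input_raster$neuron) >= cfg$N_input))
      stop("input raster neuron index out of range")
    in_step <- as.integer(input_raster$step)
    in_neuron <- as.integer(input_raster$neuron)
  }
  if (is.null(state)) {
    state <- list(Vmem = rep(0, n), Cfire = rep(0, n),
                  Isyn_e = rep(0, n), Isyn_i = rep(0, n),
                  ref = rep(0L, n))
  }
  pl <- network$plast
  prm <- list(R = network$neuron$R, C = network$neuron$C,
              vreset = network$neuron$Vreset, tref = network$neuron$tref,
              tau_syn = network$syn$tau_syn, alpha = network$syn$alpha,
              tau_ip = pl$tau_ip,
              sdsp_on = plasticity_on && pl$sdsp_enabled,
              ip_on = plasticity_on && pl$ip_enabled,
              lr_sdsp = pl$LR_SDSP, wmax = pl$Wmax, lr_thr = pl$LR_thr,
              vthr_min = pl$Vthr_min, vthr_max = pl$Vthr_max,
              c_ip = pl$C_IP, sigma = pl$sigma,
              ca_increment_before_ip = pl$ca_increment_before_ip,
              raw_cfire_compare = pl$raw_cfire_compare,
              sdsp_during_refractory = pl$sdsp_during_refractory,
              trace_neuron = as.integer(trace_neuron))
  res <- cpp_sim_run(cfg$N_exc, cfg$N_inh,
                     network$m_in, network$w_in,
                     network$m_ee, network$w_ee,
                     network$m_ei, network$w_ei,
                     network$m_ie, network$w_ie,
                     network$Vthr, state$Vmem, state$Cfire,
                     state$Isyn_e, state$Isyn_i, state$ref,
                     in_step, in_neuron, n_steps, cfg$dt, prm)
  network$w_ee <- res$w_ee
  network$Vthr <- res$vthr
  out <- list(
    spikes = data.frame(time = (res$spk_step + 1) * cfg$dt,
                        neuron = res$spk_neuron),
    network = network,
    state = list(Vmem = res$vmem, Cfire = res$cfire,
                 Isyn_e = res$isyn_e, Isyn_i = res$isyn_i, ref = res$ref),
    events = res$events, T = T, dt = cfg$dt)
  if (!is.null(res$vmem_trace)) out$vmem_trace <- res$vmem_trace
  class(out) <- "srnn_run"
  out
}

#' Per-bin firing rates from a spike raster
#'
#' @param spikes data frame with columns `time` (s) and `neuron` (0-based).
#' @param T_bin bin width in seconds (positive).
#' @param T total duration covered in seconds; bins are
#'   `[0, T_bin), [T_bin, 2 T_bin), ...` and the number of bins is
#'   `round(T / T_bin)`.
#' @param n_neurons number of neurons (columns of the result).
#' @param neurons optional subset of 0-based neuron indices to keep (in
#'   order), e.g. `0:(N_exc-1)` for the excitatory population.
#' @return A numeric matrix, bins x neurons, in fires per second.
#' @export
bin_rates <- function(spikes, T_bin, T, n_neurons, neurons = NULL) {
  stopifnot(T_bin > 0, T > 0, n_neurons > 0)
  n_bins <- as.integer(round(T / T_bin))
  if (is.null(neurons)) neurons <- 0:(n_neurons - 1)
  counts <- matrix(0, n_bins, length(neurons))
  keep <- spikes$neuron %in% neurons
  if (any(keep)) {
    bin <- pmin(floor(spikes$time[keep] / T_bin), n_bins - 1) + 1
    col <- match(spikes$neuron[keep], neurons)
    tab <- table(factor(bin, levels = seq_len(n_bins)),
                 factor(col, levels = seq_along(neurons)))
    counts <- counts + unclass(tab)
  }
  dimnames(counts) <- NULL
  counts / T_bin
}

#' Single-neuron homeostasis demonstration
#'
#' Drives one IP-regulated excitatory LIF neuron with constant-rate Poisson
#' input through `n_syn` unit-weight synapses and simulates for `T` seconds.
#' Used to show that the event-driven stepwise threshold rule pulls the
#' time-averaged firing rate into the healthy band around `C_IP`.
#'
#' @param rate_per_syn Poisson rate of each input neuron in fires/s.
#' @param n_syn number of input neurons, each connected with weight `w_in`.
#' @param w_in weight of every input synapse (default 2). Large unitary
#'   kicks keep the rate-vs-threshold curve shallow enough for the discrete
#'   threshold steps to resolve the target band.
#' @param T simulated time in seconds.
#' @param plast a [plasticity_config()].
#' @param neuron a [neuron_params()].
#' @param syn a [synapse_params()]; the demo uses the 5% PSP calibration so
#'   that, together with the weight-2 inputs, the discrete threshold steps
#'   resolve the target band.
#' @param dt step in seconds.
#' @param Vthr0 initial firing threshold (V).
#' @return List with `spikes` (data frame), `rate_final_third` (mean firing
#'   rate over the final third of the run, fires/s), `Vthr_final`, `T`, and
#'   the full `srnn_run` result as `run`.
#' @export
ip_homeostasis_demo <- function(rate_per_syn = 120, n_syn = 10, T = 60, w_in = 2,
                                plast = plasticity_config(),
                                neuron = neuron_params(),
                                syn = synapse_params(
                                  alpha = calibrate_alpha(frac = 0.05)),
                                dt = 1e-4, Vthr0 = 0.2) {
  cfg <- network_config(N_exc = 1, N_inh = 1, N_input = n_syn, P_in = 1,
                        P_EE = 0, P_EI = 0, P_IE = 0, dt = dt)
  net <- build_network(cfg, plast, neuron, syn, Vthr0 = Vthr0)
  net$w_in[] <- w_in  # deterministic drive: identical input synapses
  enc <- encoding_config(F_poisson = rate_per_syn, T_bin = T, dt = dt)
  raster <- gen_input_raster(rate_per_syn, enc, n_syn)
  run <- run_network(net, raster, T, plasticity_on = TRUE)
  sp <- run$spikes[run$spikes$neuron == 0, ]
  last <- sp$time > (2 / 3) * T
  list(spikes = sp,
       rate_final_third = sum(last) / (T / 3),
       Vthr_final = run$network$Vthr[1],
       T = T, run = run)
}

#' Write/read a spike raster as two-column text
#'
#' Plain-text serialization of spike events: `time_s`, then the 0-based
#' neuron index, one spike per row.
#'
#' @param spikes data frame with columns `time` and `neuron`.
#' @param path destination file.
#' @return `path` (writer) or the spikes data frame (reader), invisibly.
#' @export
write_raster <- function(spikes, path) {
  write.table(data.frame(time_s = spikes$time, neuron = spikes$neuron),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  df <- read.delim(path)
  data.frame(time = as.numeric(df[[1]]), neuron = as.integer(df[[2]]))
}
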