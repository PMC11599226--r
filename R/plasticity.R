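#' Plasticity configuration
#'
#' Bundles the parameters of the two learning rules. SDSP steps a plastic
#' weight by `LR_SDSP` on each presynaptic spike, in the direction given by
#' the postsynaptic membrane potential relative to the learning thresholds;
#' weights are clipped to `[0, Wmax]`. Event-driven IP steps the firing
#' threshold by `LR_thr` each time the neuron fires, in the direction given
#' by the calcium trace relative to the healthy activity band
#' `[(1 - sigma/2), (1 + sigma/2)] * C_IP`; thresholds are clipped to
#' `[Vthr_min, Vthr_max]`.
#'
#' @param LR_SDSP SDSP weight step (default 2.0, the headline
#'   configuration: with `Wmax = 2` the weights are binary). The study grid
#'   is `c(0.1, 0.2, 0.5, 1.0, 2.0)`.
#' @param Wmax weight ceiling (default 2).
#' @param LR_thr IP threshold step in volts. The study grid is
#'   `c(0.025, 0.05, 0.1, 0.3)`; `0.3` with the default bounds gives binary
#'   thresholds `{0.125, 0.4}`.
#' @param Vthr_min,Vthr_max firing-threshold bounds in volts
#'   (defaults 0.125 and 0.4).
#' @param C_IP homeostatic target activity in fires per second (default 15).
#' @param sigma half-width factor of the healthy band (default 0.3, i.e.
#'   +/-15% around `C_IP`); no IP step is taken inside the band.
#' @param tau_ip calcium-trace time constant in seconds (default 100 ms).
#' @param sdsp_enabled,ip_enabled master switches for the two rules.
#' @param raw_cfire_compare if `TRUE`, compare the calcium trace directly
#'   against `(1 +/- sigma/2) * C_IP`; the default (`FALSE`) compares against
#'   `(1 +/- sigma/2) * C_IP * tau_ip`, i.e. treats `Cfire / tau_ip` as the
#'   rate estimate so `C_IP` keeps its units of fires per second.
#' @param ca_increment_before_ip if `TRUE`, the triggering spike's +1 calcium
#'   increment is applied before the IP comparison. The default (`FALSE`)
#'   compares first: for irregular firing the pre-increment trace sampled at
#'   spike times is an unbiased estimate of `rate * tau_ip`, so the rule
#'   regulates the rate to `C_IP` itself.
#' @param sdsp_during_refractory if `TRUE` (default), SDSP also acts when the
#'   postsynaptic neuron is refractory; its membrane then sits at the reset
#'   potential, below `VLthrDOWN`, so such arrivals depress.
#' @return A list of class `plasticity_config`.
#' @export
plasticity_config <- function(LR_SDSP = 2.0, Wmax = 2, LR_thr = 0.025,
                              Vthr_min = 0.125, Vthr_max = 0.4, C_IP = 15,
                              sigma = 0.3, tau_ip = 0.1,
                              sdsp_enabled = TRUE, ip_enabled = TRUE,
                              raw_cfire_compare = FALSE,
                              ca_increment_before_ip = FALSE,
                              sdsp_during_refractory = TRUE) {
  stopifnot(LR_SDSP > 0, LR_SDSP <= Wmax, LR_thr > 0,
            Vthr_min > 0, Vthr_min < Vthr_max,
            sigma >= 0, sigma < 2, tau_ip > 0, C_IP > 0)
  structure(list(LR_SDSP = LR_SDSP, Wmax = Wmax, LR_thr = LR_thr,
                 Vthr_min = Vthr_min, Vthr_max = Vthr_max, C_IP = C_IP,
                 sigma = sigma, tau_ip = tau_ip,
                 sdsp_enabled = isTRUE(sdsp_enabled),
                 ip_enabled = isTRUE(ip_enabled),
                 raw_cfire_compare = isTRUE(raw_cfire_compare),
                 ca_increment_before_ip = isTRUE(ca_increment_before_ip),
                 sdsp_during_refractory = isTRUE(sdsp_during_refractory)),
            class = "plasticity_config")
}

#' SDSP weight update on a presynaptic spike
#'
#' Applied when a presynaptic spike arrives at a plastic synapse:
#' potentiate by `LR_SDSP` if the postsynaptic membrane potential exceeds
#' `VLthrUP`, depress by `LR_SDSP` if it is below `VLthrDOWN`, otherwise
#' leave the weight unchanged. The result is clipped to `[0, Wmax]`.
#' `Vmem_post` must be sampled before the arriving spike's own current acts
#' on the postsynaptic membrane.
#'
#' @param W current weight.
#' @param Vmem_post postsynaptic membrane potential (V).
#' @param VLthrUP,VLthrDOWN learning thresholds (V).
#' @param cfg a [plasticity_config()].
#' @return The updated weight.
#' @export
sdsp_update <- function(W, Vmem_post, VLthrUP, VLthrDOWN, cfg) {
  if (Vmem_post > VLthrUP) {
    W <- W + cfg$LR_SDSP
  } else if (Vmem_post < VLthrDOWN) {
    W <- W - cfg$LR_SDSP
  }
  min(max(W, 0), cfg$Wmax)
}

#' Event-driven stepwise IP update of the firing threshold
#'
#' Invoked when the (excitatory) neuron fires. The activity estimate
#' `Cfire / tau_ip` is compared against the healthy band
#' `[(1 - sigma/2), (1 + sigma/2)] * C_IP`: above the band the threshold is
#' raised by `LR_thr`, below it lowered by `LR_thr`, inside it left alone.
#' The threshold is clipped to `[Vthr_min, Vthr_max]`. Learning thresholds
#' are not touched here; call [sync_thresholds()] immediately afterwards.
#'
#' @param state a [neuron_state()]; `state$Cfire` is the trace value to
#'   compare (the caller decides whether the triggering spike's +1 increment
#'   has already been applied, see `ca_increment_before_ip`).
#' @param cfg a [plasticity_config()].
#' @return The updated `neuron_state`.
#' @export
ip_update <- function(state, cfg) {
  target <- if (cfg$raw_cfire_compare) cfg$C_IP else cfg$C_IP * cfg$tau_ip
  if (state$Cfire > (1 + cfg$sigma / 2) * target) {
    state$Vthr <- min(state$Vthr + cfg$LR_thr, cfg$Vthr_max)
  } else if (state$Cfire < (1 - cfg$sigma / 2) * target) {
    state$Vthr <- max(state$Vthr - cfg$LR_thr, cfg$Vthr_min)
  }
  state
}

#' Synchronize the SDSP learning thresholds to the firing threshold
#'
#' Sets `VLthrUP = VLthrDOWN = Vthr / 2`. Called after every IP step so the
#' ordering `VLthrDOWN <= VLthrUP < Vthr` — required for correct concurrent
#' operation of SDSP and IP — holds at all times. (If the learning thresholds
#' were fixed while IP lowered `Vthr` beneath them, every arriving spike
#' would depress and all plastic weights would decay to zero.)
#'
#' @param Vthr firing threshold (V), positive.
#' @return Named numeric vector with elements `VLthrUP` and `VLthrDOWN`.
#' @export
sync_thresholds <- function(Vthr) {
  stopifnot(Vthr > 0)
  c(VLthrUP = Vthr / 2, VLthrDOWN = Vthr / 2)
}
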