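#' Leaky integrate-and-fire neuron parameters
#'
#' The membrane follows `C dVmem/dt = I_in - Vmem/R`. When `Vmem` strictly
#' exceeds the firing threshold the neuron fires, resets to `Vreset`, and is
#' clamped there for the refractory period `tref` regardless of input.
#'
#' @param C membrane capacitance in farads (default 10 pF).
#' @param R membrane resistance in ohms (default 400 MOhm); the membrane time
#'   constant is `R * C` (4 ms at the defaults).
#' @param Vreset reset potential in volts. The comparator-reset convention of
#'   analog LIF circuits is a reset to 0 V, which is the default.
#' @param tref refractory period in seconds (default 3 ms). Must be positive:
#'   it bounds the maximum firing rate by roughly `1/tref`.
#' @param is_excitatory logical; inhibitory neurons deliver negative synaptic
#'   current and are exempt from intrinsic plasticity.
#' @return A list of class `neuron_params`.
#' @export
neuron_params <- function(C = 10e-12, R = 400e6, Vreset = 0, tref = 3e-3,
                          is_excitatory = TRUE) {
  stopifnot(C > 0, R > 0, tref >= 0, is.finite(R * C))
  structure(list(C = C, R = R, Vreset = Vreset, tref = tref,
                 is_excitatory = isTRUE(is_excitatory)),
            class = "neuron_params")
}

#' Exponential-current synapse parameters
#'
#' A presynaptic spike injects charge through
#' `tau_syn dIsyn/dt = -Isyn + alpha * W * delta(t - t_spike)`: the current
#' jumps by `alpha * W / tau_syn` and then decays exponentially, so the total
#' delivered charge per spike is `alpha * W`.
#'
#' @param tau_syn synaptic time constant in seconds (default 5 ms).
#' @param alpha charge scale in coulombs per unit weight. The default is
#'   calibrated with [calibrate_alpha()] so that a single spike through a
#'   weight-1 synapse depolarizes a resting membrane by 20% of the initial
#'   0.2 V firing threshold — strong enough that recurrent connections
#'   shape the network state rather than merely perturbing it (see the
#'   methods vignette).
#' @param sign +1 for an excitatory source, -1 for inhibitory.
#' @return A list of class `synapse_params`.
#' @export
synapse_params <- function(tau_syn = 5e-3, alpha = NULL, sign = 1) {
  stopifnot(tau_syn > 0, sign %in% c(-1, 1))
  if (is.null(alpha)) alpha <- calibrate_alpha(frac = 0.2, tau_syn = tau_syn)
  stopifnot(alpha > 0)
  structure(list(tau_syn = tau_syn, alpha = alpha, sign = sign),
            class = "synapse_params")
}

#' Calibrate the synaptic charge scale from a target peak depolarization
#'
#' Solves for `alpha` such that a single spike through a weight-`W` synapse
#' produces a peak membrane depolarization of `frac * Vthr0` on a resting
#' neuron. The postsynaptic potential is the double exponential
#' `V(t) = (R I0 / tau_m) (exp(-t/tau_syn) - exp(-t/tau_m)) / (1/tau_m - 1/tau_syn)`
#' with `I0 = alpha W / tau_syn`, whose peak has the closed form used here
#' (the equal-time-constant limit is handled separately).
#'
#' @param frac target peak depolarization as a fraction of `Vthr0`
#'   (default 0.2).
#' @param Vthr0 reference firing threshold in volts (default 0.2).
#' @param W synaptic weight at which to calibrate (default 1).
#' @param tau_syn synaptic time constant in seconds.
#' @param params [neuron_params()] supplying `R` and `C`.
#' @return `alpha` in coulombs.
#' @export
calibrate_alpha <- function(frac = 0.2, Vthr0 = 0.2, W = 1, tau_syn = 5e-3,
                            params = neuron_params()) {
  stopifnot(frac > 0, Vthr0 > 0, W > 0, tau_syn > 0)
  tau_m <- params$R * params$C
  peak_per_I0 <- psp_peak_gain(tau_m, tau_syn, params$R)
  frac * Vthr0 * tau_syn / (peak_per_I0 * W)
}

# Peak of the membrane response to a unit current jump decaying with tau_syn,
# per unit I0 (volts per ampere).
psp_peak_gain <- function(tau_m, tau_syn, R) {
  if (isTRUE(all.equal(tau_m, tau_syn))) {
    # degenerate equal-tau case: V(t) = (R I0 / tau) t exp(-t/tau)
    return(R * exp(-1))
  }
  a <- 1 / tau_m
  b <- 1 / tau_syn
  tpk <- log(a / b) / (a - b)
  (R * a / (a - b)) * (exp(-b * tpk) - exp(-a * tpk))
}

#' One membrane integration step (exact exponential update)
#'
#' Advances `Vmem` by `dt` under a constant input current, using the exact
#' solution of the leaky-integrator ODE:
#' `Vmem <- Vmem * exp(-dt/RC) + I_in * R * (1 - exp(-dt/RC))`.
#' A refractory neuron stays clamped at `Vreset` regardless of input.
#'
#' @param state a `neuron_state` from [neuron_state()].
#' @param I_in input current in amperes, held constant over the step.
#' @param dt step size in seconds (must be positive).
#' @param params a [neuron_params()].
#' @param now current simulation time in seconds (start of the step).
#' @return The updated `neuron_state`.
#' @export
step_membrane <- function(state, I_in, dt, params, now = 0) {
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number")
  if (now + dt <= state$refractory_until + 1e-15) {
    state$Vmem <- params$Vreset
  } else {
    d <- exp(-dt / (params$R * params$C))
    state$Vmem <- state$Vmem * d + I_in * params$R * (1 - d)
  }
  state
}

#' Per-neuron dynamic state
#'
#' @param Vmem membrane potential (V).
#' @param Vthr firing threshold (V).
#' @param VLthrUP,VLthrDOWN SDSP learning thresholds (V); kept synchronized at
#'   `Vthr/2` by [sync_thresholds()].
#' @param Cfire calcium-like activity trace (dimensionless leaky spike count).
#' @param refractory_until absolute time (s) until which the membrane is
#'   clamped at the reset potential.
#' @return A list of class `neuron_state`.
#' @export
neuron_state <- function(Vmem = 0, Vthr = 0.2, VLthrUP = Vthr / 2,
                         VLthrDOWN = Vthr / 2, Cfire = 0,
                         refractory_until = -Inf) {
  stopifnot(VLthrDOWN <= VLthrUP, VLthrUP < Vthr, Cfire >= 0)
  structure(list(Vmem = Vmem, Vthr = Vthr, VLthrUP = VLthrUP,
                 VLthrDOWN = VLthrDOWN, Cfire = Cfire,
                 refractory_until = refractory_until),
            class = "neuron_state")
}

#' Threshold crossing check, reset and calcium increment
#'
#' Fires iff `Vmem > Vthr` strictly (a tie does not fire). On fire the
#' membrane is reset to `Vreset`, the refractory clamp is armed for `tref`,
#' and the calcium trace is incremented by 1 (the delta-pulse of the trace
#' ODE integrated over the spike).
#'
#' @inheritParams step_membrane
#' @return A list with `fired` (logical) and `state` (updated `neuron_state`).
#' @export
check_fire <- function(state, params, now) {
  fired <- now >= state$refractory_until && state$Vmem > state$Vthr
  if (fired) {
    state$Vmem <- params$Vreset
    state$refractory_until <- now + params$tref
    state$Cfire <- state$Cfire + 1
  }
  list(fired = fired, state = state)
}

#' Exponential decay of a synaptic current over one step
#'
#' @param I_syn current in amperes.
#' @param dt step size in seconds (positive).
#' @param params a [synapse_params()].
#' @return The decayed current `I_syn * exp(-dt/tau_syn)`.
#' @export
step_syn_current <- function(I_syn, dt, params) {
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number")
  I_syn * exp(-dt / params$tau_syn)
}

#' Synaptic current jump on a presynaptic spike
#'
#' Integrating the delta drive through the synapse ODE makes the current jump
#' by `sign * alpha * W / tau_syn`; the total delivered charge per spike is
#' `sign * alpha * W`.
#'
#' @param I_syn current in amperes.
#' @param W synaptic weight (dimensionless, in `[0, Wmax]`).
#' @param params a [synapse_params()].
#' @return The updated current.
#' @export
on_presyn_spike_current <- function(I_syn, W, params) {
  I_syn + params$sign * params$alpha * W / params$tau_syn
}

#' Exponential decay of the calcium trace over one step
#'
#' The trace obeys `tau_ip dCfire/dt = -Cfire + sum_spikes delta(t - t_fire)`;
#' the +1 spike increments are applied in [check_fire()], this function only
#' decays. Its long-run mean under stationary firing at rate `r` is
#' `r * tau_ip`.
#'
#' @param Cfire current trace value (non-negative).
#' @param dt step size in seconds (positive).
#' @param tau_ip trace time constant in seconds (default 100 ms; a single
#'   time constant serves both the calcium and IP roles).
#' @return The decayed trace.
#' @export
step_calcium <- function(Cfire, dt, tau_ip = 0.1) {
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number")
  Cfire * exp(-dt / tau_ip)
}
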