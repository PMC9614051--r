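#' Neuron dynamics
#'
#' Excitatory (E), read-out (R) and supervisor (S) neurons are adaptive
#' exponential integrate-and-fire units:
#' `dV/dt = (E_L - V + Delta_T * exp((V - V_T)/Delta_T)) / tau_m
#'          - gamma * a + Q`,
#' with an adaptive threshold `V_T` that jumps by `A_T` at each spike and
#' relaxes back with `tau_T`, and a spike-triggered adaptation current `a`
#' (expressed here in mV/ms, i.e. already normalized by the membrane
#' capacitance) that jumps by `b_a` and decays with `tau_a`.  Only E
#' neurons carry adaptation (`gamma = 1`); R and S have `gamma = 0`.
#' Inhibitory (I) and interneuron (H) units are leaky integrate-and-fire:
#' `dV/dt = (E_L - V)/tau_m + Q` with a fixed threshold.
#'
#' Integration is exponential-Euler on the linear part with the exponential
#' spike-initiation term evaluated explicitly, its argument capped, and a
#' numerical ceiling `V_peak` at which a spike is declared and the membrane
#' is reset — the membrane can never run away to nonphysical values.
#'
#' @name neuron_dynamics
NULL

# cap on the exponential's argument; e^16 per step is far beyond any
# ceiling, so detection fires while V stays finite
EXP_ARG_CAP <- 16

#' Create an excitatory-type neuron state
#' @param params the `neuron$E` sublist of a [clock_config()].
#' @param V initial membrane potential; defaults to the resting potential.
#' @return list with `V`, `V_T`, `a`, `refrac` (remaining refractory ms).
#' @export
neuron_state_exc <- function(params, V = params$E_L) {
  list(V = V, V_T = params$V_T0, a = 0, refrac = 0)
}

#' Advance an excitatory-type neuron one step
#'
#' @param state as from [neuron_state_exc()].
#' @param Q total input current term (mV/ms), constant over the step.
#' @param dt step (ms).
#' @param params the `neuron$E` sublist of a [clock_config()].
#' @param gamma adaptation coupling: 1 for E, 0 for R and S roles.
#' @return list `state` (updated), `spike` (logical).
#' @export
step_excitatory <- function(state, Q, dt, params, gamma = 1) {
  spike <- FALSE
  if (state$refrac > 1e-12) {
    state$refrac <- max(0, state$refrac - dt)
    state$V <- params$V_reset
  } else {
    arg <- min((state$V - state$V_T) / params$Delta_T, EXP_ARG_CAP)
    drive <- params$Delta_T / params$tau_m * exp(arg) - gamma * state$a + Q
    Vinf <- params$E_L + params$tau_m * drive
    V_new <- Vinf + (state$V - Vinf) * exp(-dt / params$tau_m)
    if (!is.finite(V_new)) {
      stop(sprintf("non-finite membrane potential after step (V was %.3f mV)",
                   state$V), call. = FALSE)
    }
    if (V_new >= params$V_peak) {
      spike <- TRUE
      V_new <- params$V_reset
      if (gamma > 0) {            # adaptation is an E-only mechanism
        state$V_T <- state$V_T + params$A_T
        state$a <- state$a + params$b_a
      }
      state$refrac <- params$t_ref
    }
    state$V <- V_new
  }
  # threshold and adaptation relax regardless of refractoriness
  state$V_T <- params$V_T0 + (state$V_T - params$V_T0) * exp(-dt / params$tau_T)
  state$a <- state$a * exp(-dt / params$tau_a)
  list(state = state, spike = spike)
}

#' Create an inhibitory-type neuron state
#' @param params the `neuron$I` sublist of a [clock_config()].
#' @param V initial membrane potential; defaults to the resting potential.
#' @export
neuron_state_inh <- function(params, V = params$E_L) {
  list(V = V, refrac = 0)
}

#' Advance an inhibitory-type neuron one step
#' @param state as from [neuron_state_inh()].
#' @param Q input current term (mV/ms), constant over the step.
#' @param dt step (ms).
#' @param params the `neuron$I` sublist of a [clock_config()].
#' @return list `state`, `spike`.
#' @export
step_inhibitory <- function(state, Q, dt, params) {
  spike <- FALSE
  if (state$refrac > 1e-12) {
    state$refrac <- max(0, state$refrac - dt)
    state$V <- params$V_reset
  } else {
    Vinf <- params$E_L + params$tau_m * Q
    V_new <- Vinf + (state$V - Vinf) * exp(-dt / params$tau_m)
    if (!is.finite(V_new)) {
      stop(sprintf("non-finite membrane potential after step (V was %.3f mV)",
                   state$V), call. = FALSE)
    }
    if (V_new >= params$V_th) {
      spike <- TRUE
      V_new <- params$V_reset
      state$refrac <- params$t_ref
    }
    state$V <- V_new
  }
  list(state = state, spike = spike)
}

#' Synaptic conductance channels
#'
#' Each neuron carries strictly segregated excitatory and inhibitory
#' conductance channels.  A channel's conductance is the convolution of
#' its weighted, delay-resolved input spike train with the unitless
#' double-exponential kernel
#' `K(t) = c_K * (exp(-t/tau_d) - exp(-t/tau_r)) / (tau_d - tau_r)`,
#' implemented as the equivalent two-state linear ODE system (states `zd`,
#' `zr`, both incremented by the synaptic weight at spike delivery and
#' decaying exactly with their time constants).  `c_K = 1 ms` absorbs the
#' kernel's 1/ms so the conductance is unitless.
#'
#' @param n number of neurons.
#' @return list of numeric vectors `zd_exc`, `zr_exc`, `zd_inh`, `zr_inh`.
#' @export
conductance_state <- function(n) {
  list(zd_exc = numeric(n), zr_exc = numeric(n),
       zd_inh = numeric(n), zr_inh = numeric(n))
}

#' Advance conductance channels one step
#'
#' Decays all channel states exactly over `dt`, then adds this step's
#' delivered spike weights.  Excitatory and inhibitory inputs enter their
#' own channels and are never summed into one accumulator; an inhibitory
#' spike can therefore never raise the excitatory conductance, and
#' conductances remain non-negative by construction (checked).
#'
#' @param state as from [conductance_state()].
#' @param w_exc,w_inh summed weights of excitatory/inhibitory spikes
#'   delivered to each neuron at this step boundary.
#' @param dt step (ms).
#' @param syn the `synapse` sublist of a [clock_config()].
#' @return updated state.
#' @export
update_conductances <- function(state, w_exc, w_inh, dt, syn) {
  state$zd_exc <- state$zd_exc * exp(-dt / syn$tau_d_exc) + w_exc
  state$zr_exc <- state$zr_exc * exp(-dt / syn$tau_r_exc) + w_exc
  state$zd_inh <- state$zd_inh * exp(-dt / syn$tau_d_inh) + w_inh
  state$zr_inh <- state$zr_inh * exp(-dt / syn$tau_r_inh) + w_inh
  g <- conductances(state, syn)
  if (any(g$exc < -1e-12) || any(g$inh < -1e-12)) {
    stop("negative synaptic conductance encountered", call. = FALSE)
  }
  state
}

#' Read the unitless conductances of both channels
#' @param state conductance state.
#' @param syn the `synapse` sublist of a [clock_config()].
#' @return list of numeric vectors `exc`, `inh`.
#' @export
conductances <- function(state, syn) {
  list(exc = syn$c_K * (state$zd_exc - state$zr_exc) /
         (syn$tau_d_exc - syn$tau_r_exc),
       inh = syn$c_K * (state$zd_inh - state$zr_inh) /
         (syn$tau_d_inh - syn$tau_r_inh))
}

#' Synaptic input current term from conductances
#'
#' `Q = (g_exc * (E_rev_exc - V) + g_inh * (E_rev_inh - V)) / c_q`, in
#' mV/ms; `c_q = 1 ms` is the capacitance-normalizing constant.
#'
#' @param g list `exc`, `inh` from [conductances()].
#' @param V membrane potential(s), mV.
#' @param syn the `synapse` sublist of a [clock_config()].
#' @return numeric vector of current terms (mV/ms).
#' @export
synaptic_current <- function(g, V, syn) {
  (g$exc * (syn$E_rev_exc - V) + g$inh * (syn$E_rev_inh - V)) / syn$c_q
}
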