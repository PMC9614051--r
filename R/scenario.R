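#' Integrate a plasticity rule over a scripted scenario
#'
#' Runs one synapse through a [make_plasticity_scenario()] script at step
#' size `dt`, using the production step semantics: depression and the
#' inhibitory rule's terms as per-spike jumps evaluated at trace left
#' limits, potentiation via the exact within-step integral
#' ([ltp_window_integral()]), and exact exponential trace updates.  The
#' synaptic delay `d` shifts the presynaptic spike train; delayed arrivals
#' falling beyond the script are dropped.  Because every term is either an
#' exact jump or an exact integral, the cumulative weight change is
#' invariant to `dt` (any divisor of the scenario lattice) up to
#' floating-point rounding.
#'
#' Voltage traces start at the script's initial voltage; spike traces
#' start at zero.
#'
#' @param sc a `plasticity_scenario`.
#' @param dt integration step (ms); must divide the scenario lattice.
#' @param params plasticity parameter list (see [clock_config()]
#'   `$plasticity`).
#' @param rule `"stdp"` (voltage-based, EE/RE) or `"inhib"` (target-rate,
#'   EI).
#' @param tau_x presynaptic trace constant for `"stdp"`.
#' @param d synaptic delay (ms); default from `params$delay$EE`.
#' @return list: `dW` (total weight change), `dW_ltd`, `dW_ltp`
#'   (for `"stdp"`), `n_pre`, `n_post` (spike counts used).
#' @export
run_plasticity_scenario <- function(sc, dt, params, rule = c("stdp", "inhib"),
                                    tau_x = params$tau_x_EE,
                                    d = params$delay$EE) {
  rule <- match.arg(rule)
  if (abs(sc$grid_ms / dt - round(sc$grid_ms / dt)) > 1e-9) {
    stop("dt must divide the scenario lattice grid_ms", call. = FALSE)
  }
  n <- round(sc$T_ms / dt)
  step_of <- function(times) {
    s <- round(times / dt)
    s[s >= 0 & s < n]
  }
  pre_steps <- step_of(sc$pre_spikes + d)
  post_steps <- step_of(sc$post_spikes)
  pre_count <- tabulate(pre_steps + 1L, nbins = n)
  post_count <- tabulate(post_steps + 1L, nbins = n)

  if (rule == "stdp") {
    u <- v <- sc$V_seg[1]
    x <- 0
    dW_ltd <- dW_ltp <- 0
    eu <- exp(-dt / params$tau_u); ev <- exp(-dt / params$tau_v)
    ex <- exp(-dt / tau_x)
    for (k in seq_len(n)) {
      ck <- pre_count[k]
      if (ck > 0) {
        dW_ltd <- dW_ltd - params$A_LTD * max(u - params$theta_LTD, 0) * ck
        x <- x + params$alpha * ck
      }
      V <- scenario_voltage(sc, (k - 1) * dt)
      if (x > 0 && V > params$theta_LTP) {
        dW_ltp <- dW_ltp + params$A_LTP * x *
          ltp_window_integral(v, V, dt, tau_x, params$tau_v,
                              params$theta_LTP, params$theta_LTD)
      }
      u <- u + (V - u) * (1 - eu)
      v <- v + (V - v) * (1 - ev)
      x <- x * ex
    }
    list(dW = dW_ltd + dW_ltp, dW_ltd = dW_ltd, dW_ltp = dW_ltp,
         n_pre = sum(pre_count), n_post = sum(post_count))
  } else {
    yE <- yI <- 0
    offset <- 2 * params$alpha * params$r_0 * params$tau_y
    ey <- exp(-dt / params$tau_y)
    dW <- 0
    for (k in seq_len(n)) {
      cpre <- pre_count[k]; cpost <- post_count[k]
      if (cpre > 0) dW <- dW + params$A_inh * (yE - offset) * cpre
      if (cpost > 0) dW <- dW + params$A_inh * yI * cpost
      # jumps occur at the spike instant (start of step), then decay
      yE <- (yE + params$alpha * cpost) * ey
      yI <- (yI + params$alpha * cpre) * ey
    }
    list(dW = dW, n_pre = sum(pre_count), n_post = sum(post_count))
  }
}
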