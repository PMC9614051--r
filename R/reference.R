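#' Dense fine-grid reference integrators
#'
#' Brute-force integrators for the two plasticity rules, used as the
#' independent cross-check for [run_plasticity_scenario()].  They share
#' nothing with the production path beyond the rule definitions: traces
#' are advanced per fine step and the continuous potentiation term is
#' accumulated by trapezoidal quadrature of the literal integrand
#' `x(t) * max(V - theta_LTP, 0) * max(v(t) - theta_LTD, 0)`, rather than
#' by the closed-form within-step integral.  At `dt_fine` two orders of
#' magnitude below the trace time constants, quadrature error is far below
#' the comparison tolerances used in the tests.
#'
#' @param sc a [make_plasticity_scenario()] scenario.
#' @param dt_fine fine integration step (ms); must divide the scenario
#'   lattice.
#' @param params plasticity parameter list.
#' @param tau_x presynaptic trace constant (stdp rule).
#' @param d synaptic delay (ms).
#' @return list with `dW` (and `dW_ltd`/`dW_ltp` for stdp).
#' @name reference
NULL

#' @rdname reference
#' @export
stdp_reference_dense <- function(sc, dt_fine, params,
                                 tau_x = params$tau_x_EE,
                                 d = params$delay$EE) {
  n <- round(sc$T_ms / dt_fine)
  arr <- round((sc$pre_spikes + d) / dt_fine)
  arr <- arr[arr >= 0 & arr < n]
  pre_count <- tabulate(arr + 1L, nbins = n)
  u <- v <- sc$V_seg[1]
  x <- 0
  dW_ltd <- dW_ltp <- 0
  eu <- exp(-dt_fine / params$tau_u); ev <- exp(-dt_fine / params$tau_v)
  ex <- exp(-dt_fine / tau_x)
  integrand <- function(x, V, v) {
    x * max(V - params$theta_LTP, 0) * max(v - params$theta_LTD, 0)
  }
  for (k in seq_len(n)) {
    ck <- pre_count[k]
    if (ck > 0) {
      dW_ltd <- dW_ltd - params$A_LTD * max(u - params$theta_LTD, 0) * ck
      x <- x + params$alpha * ck
    }
    V <- scenario_voltage(sc, (k - 1) * dt_fine)
    f0 <- integrand(x, V, v)
    # advance to the end of the fine step (left limits of the next boundary)
    u <- u + (V - u) * (1 - eu)
    v <- v + (V - v) * (1 - ev)
    x <- x * ex
    f1 <- integrand(x, V, v)
    dW_ltp <- dW_ltp + params$A_LTP * (f0 + f1) / 2 * dt_fine
  }
  list(dW = dW_ltd + dW_ltp, dW_ltd = dW_ltd, dW_ltp = dW_ltp)
}

#' @rdname reference
#' @export
inhib_reference_dense <- function(sc, dt_fine, params, d = params$delay$EI) {
  n <- round(sc$T_ms / dt_fine)
  arr <- round((sc$pre_spikes + d) / dt_fine)
  arr <- arr[arr >= 0 & arr < n]
  pre_count <- tabulate(arr + 1L, nbins = n)
  post <- round(sc$post_spikes / dt_fine)
  post <- post[post >= 0 & post < n]
  post_count <- tabulate(post + 1L, nbins = n)
  yE <- yI <- 0
  offset <- 2 * params$alpha * params$r_0 * params$tau_y
  ey <- exp(-dt_fine / params$tau_y)
  dW <- 0
  for (k in seq_len(n)) {
    if (pre_count[k] > 0) dW <- dW + params$A_inh * (yE - offset) * pre_count[k]
    if (post_count[k] > 0) dW <- dW + params$A_inh * yI * post_count[k]
    yE <- (yE + params$alpha * post_count[k]) * ey
    yI <- (yI + params$alpha * pre_count[k]) * ey
  }
  list(dW = dW)
}
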