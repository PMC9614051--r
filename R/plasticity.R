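#' Plasticity rules
#'
#' Three rules shape the network:
#'
#' 1. **Voltage-based STDP** (EE and RE synapses): depression is a jump of
#'    `-A_LTD * max(u_i - theta_LTD, 0)` at each delayed presynaptic spike,
#'    where `u_i` is a slow low-pass of the postsynaptic potential;
#'    potentiation accrues continuously as
#'    `A_LTP * x_j(t-d) * max(V_i - theta_LTP, 0) * max(v_i - theta_LTD, 0)`,
#'    with `x_j` a low-pass presynaptic spike trace and `v_i` a fast voltage
#'    low-pass.  Spike-train terms are Dirac impulses and are integrated as
#'    per-spike jumps, never as rate-times-dt products, so the result does
#'    not depend on the integration step.
#' 2. **Inhibitory plasticity with a target rate** (EI synapses): on each
#'    delayed presynaptic (inhibitory) spike the weight jumps by
#'    `A_inh * (y_i^E - 2*alpha*r_0*tau_y)`; on each postsynaptic
#'    (excitatory) spike by `A_inh * y_j^I`.  The constant offset makes the
#'    rule depress when the excitatory neuron fires below its target rate
#'    `r_0` and potentiate above it.
#' 3. **Synaptic normalization** (EE): at regular intervals each excitatory
#'    neuron's summed incoming EE weight is reset subtractively to its
#'    initial value `K_i`.
#'
#' All trace updates use exact exponential relaxation, and the continuous
#' potentiation term is integrated in closed form within each step, so the
#' accumulated weight change on a fixed spike/voltage scenario is invariant
#' to the step size up to floating-point rounding.
#'
#' @name plasticity
NULL

#' Update low-pass voltage traces
#'
#' Relaxes `u` (and analogously `v`) toward the current membrane potential
#' with an exact exponential step: `u <- u + (V - u) * (1 - exp(-dt/tau))`,
#' the closed-form solution of `du/dt = (V - u)/tau` for `V` held constant
#' over the step.
#'
#' @param u trace vector (mV).
#' @param V membrane potential vector (mV), held constant over the step.
#' @param dt step (ms).
#' @param tau trace time constant (ms).
#' @return updated trace vector.
#' @export
update_voltage_traces <- function(u, V, dt, tau) {
  u + (V - u) * (1 - exp(-dt / tau))
}

#' Update low-pass spike traces
#'
#' Decays the trace exactly over one step and then adds `alpha` per spike
#' occurring at the end-of-step boundary: integrating
#' `dx/dt = alpha * s(t) - x/tau` through a spike's delta function gives a
#' jump of exactly `alpha`, independent of `dt`.
#'
#' @param x trace vector.
#' @param n_spikes spike counts per entry for this step.
#' @param dt step (ms).
#' @param tau trace time constant (ms).
#' @param alpha impulse scale (1/ms).
#' @return updated trace vector.
#' @export
update_spike_traces <- function(x, n_spikes, dt, tau, alpha = 1) {
  x * exp(-dt / tau) + alpha * n_spikes
}

#' Closed-form within-step potentiation integral
#'
#' Computes `int_0^dt exp(-t/tau_x) * max(V - theta_LTP, 0) *
#' max(v(t) - theta_LTD, 0) dt` for `V` constant over the step and
#' `v(t) = V + (v0 - V) exp(-t/tau_v)`, handling the possible sign change
#' of the rectified term inside the window analytically.  Multiplying the
#' result by `A_LTP * x_j(t0)` gives the potentiation accrued by one
#' synapse over one step.
#'
#' @param v0 fast voltage trace at step start (mV).
#' @param V postsynaptic potential, constant over the step (mV).
#' @param dt step (ms).
#' @param tau_x presynaptic trace time constant (ms).
#' @param tau_v fast voltage-trace time constant (ms).
#' @param theta_LTP,theta_LTD voltage thresholds (mV).
#' @return scalar (or vector over `v0`/`V`) integral value, units mV^2 * ms.
#' @export
ltp_window_integral <- function(v0, V, dt, tau_x, tau_v, theta_LTP, theta_LTD) {
  gate <- pmax(V - theta_LTP, 0)
  A <- V - theta_LTD
  B <- v0 - V
  tau_h <- 1 / (1 / tau_x + 1 / tau_v)
  seg <- function(a, b) {
    A * tau_x * (exp(-a / tau_x) - exp(-b / tau_x)) +
      B * tau_h * (exp(-a / tau_h) - exp(-b / tau_h))
  }
  h0 <- A + B                      # v(0) - theta_LTD
  h1 <- A + B * exp(-dt / tau_v)   # v(dt) - theta_LTD
  n <- max(length(v0), length(V))
  gate <- rep_len(gate, n); A <- rep_len(A, n); B <- rep_len(B, n)
  h0 <- rep_len(h0, n); h1 <- rep_len(h1, n)
  out <- numeric(n)
  pos_both <- h0 >= 0 & h1 >= 0
  out[pos_both] <- seg(0, dt)[pos_both]
  crossing <- xor(h0 > 0, h1 > 0)
  if (any(crossing)) {
    for (i in which(crossing)) {
      ts <- tau_v * log(B[i] / (-A[i]))   # h(t*) = 0; valid when signs differ
      ts <- min(max(ts, 0), dt)
      s <- function(a, b) {
        A[i] * tau_x * (exp(-a / tau_x) - exp(-b / tau_x)) +
          B[i] * tau_h * (exp(-a / tau_h) - exp(-b / tau_h))
      }
      out[i] <- if (h0[i] > 0) s(0, ts) else s(ts, dt)
    }
  }
  gate * pmax(out, 0)
}

#' One step of voltage-based STDP for a weight matrix
#'
#' Applies the depression jumps for the delayed presynaptic spikes of this
#' step and the closed-form potentiation integral, then clips to bounds.
#' Rows are postsynaptic (targets), columns presynaptic (sources); entries
#' without an edge (per `adj`) are left untouched.
#'
#' @param W weight matrix (targets x sources).
#' @param adj logical adjacency matrix, same shape; `NULL` means all-to-all.
#' @param pre_spikes integer vector of delayed presynaptic spike counts
#'   arriving at the start of this step (length = sources).
#' @param x_pre delayed presynaptic spike traces at step start, after the
#'   jumps of this step's arrivals (length = sources).
#' @param u_post,v_post slow/fast postsynaptic voltage traces at step start.
#' @param V_post postsynaptic membrane potential, constant over the step.
#' @param dt step (ms).
#' @param params plasticity parameter list (uses `A_LTD`, `A_LTP`,
#'   `theta_LTD`, `theta_LTP`, `tau_v`, and the class trace constant
#'   passed as `tau_x`).
#' @param tau_x presynaptic trace time constant for this class (ms).
#' @param bounds numeric length-2 `c(W_min, W_max)` or `NULL` for no clip.
#' @return list with updated `W` and `clipped`, the number of entries that
#'   hit a bound.
#' @export
voltage_stdp_step <- function(W, adj = NULL, pre_spikes, x_pre,
                              u_post, v_post, V_post, dt, params,
                              tau_x = params$tau_x_EE, bounds = NULL) {
  ltd_post <- params$A_LTD * pmax(u_post - params$theta_LTD, 0)
  ltp_post <- params$A_LTP *
    ltp_window_integral(v_post, V_post, dt, tau_x, params$tau_v,
                        params$theta_LTP, params$theta_LTD)
  dW <- -outer(ltd_post, as.numeric(pre_spikes)) + outer(ltp_post, x_pre)
  if (!is.null(adj)) dW[!adj] <- 0
  W2 <- W + dW
  clipped <- 0L
  if (!is.null(bounds)) {
    sel <- if (is.null(adj)) TRUE else adj
    low <- W2 < bounds[1] & sel; high <- W2 > bounds[2] & sel
    clipped <- sum(low) + sum(high)
    W2[low] <- bounds[1]; W2[high] <- bounds[2]
  }
  list(W = W2, clipped = clipped)
}

#' One step of inhibitory plasticity (target-rate rule) for a weight matrix
#'
#' Purely spike-triggered: each delayed presynaptic (inhibitory) spike
#' contributes `A_inh * (y_post^E - 2*alpha*r_0*tau_y)` to its column; each
#' postsynaptic (excitatory) spike contributes `A_inh * y_pre^I` to its
#' row.  Trace values are read at their pre-jump (left-limit) values.
#'
#' @param W weight matrix (E targets x I sources).
#' @param adj logical adjacency or `NULL`.
#' @param pre_spikes delayed inhibitory spike counts (length = sources).
#' @param post_spikes excitatory spike counts this step (length = targets).
#' @param y_post,y_pre excitatory/inhibitory spike-rate traces (left limits).
#' @param params plasticity parameter list (`A_inh`, `alpha`, `r_0`, `tau_y`).
#' @param bounds `c(W_min, W_max)` or `NULL`.
#' @return list with updated `W` and `clipped` count.
#' @export
inhibitory_plasticity_step <- function(W, adj = NULL, pre_spikes, post_spikes,
                                       y_post, y_pre, params, bounds = NULL) {
  offset <- 2 * params$alpha * params$r_0 * params$tau_y
  dW <- params$A_inh * outer(y_post - offset, as.numeric(pre_spikes)) +
    params$A_inh * outer(as.numeric(post_spikes), y_pre)
  if (!is.null(adj)) dW[!adj] <- 0
  W2 <- W + dW
  clipped <- 0L
  if (!is.null(bounds)) {
    sel <- if (is.null(adj)) TRUE else adj
    low <- W2 < bounds[1] & sel; high <- W2 > bounds[2] & sel
    clipped <- sum(low) + sum(high)
    W2[low] <- bounds[1]; W2[high] <- bounds[2]
  }
  list(W = W2, clipped = clipped)
}

#' Subtractive synaptic normalization of incoming EE weights
#'
#' For each target neuron `i` with `l_i` incoming edges, subtracts
#' `((sum_k W_ik) - K_i) / l_i` from every existing incoming weight, which
#' restores `sum_k W_ik = K_i` exactly (to machine precision) before
#' clipping; weights are then clipped to bounds and the residual row-sum
#' deviation introduced by clipping is reported rather than iteratively
#' corrected.  Neurons without incoming edges are skipped.
#'
#' @param W dense EE weight matrix (targets x sources).
#' @param K per-target normalization targets (initial incoming sums).
#' @param adj logical adjacency matrix marking existing edges.
#' @param bounds `c(W_min, W_max)` or `NULL` for no clipping.
#' @return list: `W` (normalized, clipped), `residual` (per-row post-clip
#'   deviation of the sum from `K`), `clipped` (entry count).
#' @export
normalize_incoming <- function(W, K, adj, bounds = NULL) {
  l <- rowSums(adj)
  rs <- rowSums(W * adj)
  corr <- ifelse(l > 0, (rs - K) / pmax(l, 1), 0)
  W2 <- W - corr * adj          # recycles corr down columns of adj rows
  W2[!adj] <- 0
  clipped <- 0L
  if (!is.null(bounds)) {
    low <- W2 < bounds[1] & adj; high <- W2 > bounds[2] & adj
    clipped <- sum(low) + sum(high)
    W2[low] <- bounds[1]; W2[high] <- bounds[2]
  }
  residual <- rowSums(W2 * adj) - K
  residual[l == 0] <- 0
  list(W = W2, residual = residual, clipped = clipped)
}
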