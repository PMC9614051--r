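#' Deterministic synthetic fixtures
#'
#' Generators for idealized inputs with known properties: ring-structured
#' weight matrices with closed-form spectra, ground-truth sequential
#' rasters, and scripted voltage/spike scenarios for the plasticity rules.
#' Every fixture is fully reproducible from its parameters and seed; none
#' are stored on disk.
#'
#' @name fixtures
NULL

#' Idealized feedforward ring weight matrix
#'
#' Block matrix over `N_C` clusters of `m` neurons: every entry of a
#' diagonal block equals `w_intra`, every entry of a superdiagonal block
#' (target cluster `i+1`, source cluster `i`, with wrap-around) equals
#' `w_ff`, all else zero.  Rows are targets, columns sources.  Its nonzero
#' eigenvalues are `m * (w_intra + w_ff * omega^k)` for the `N_C`-th roots
#' of unity `omega^k` — with `w_intra = 0`, exactly `m * w_ff` times the
#' roots of unity, the idealized "leading ring" of a learned clock.
#'
#' @param N_C number of clusters.
#' @param m neurons per cluster.
#' @param w_intra within-cluster weight.
#' @param w_ff feedforward (cluster `i` to `i+1`) weight.
#' @return dense square matrix of dimension `N_C * m`.
#' @export
make_ring_matrix <- function(N_C, m, w_intra, w_ff) {
  if (N_C <= 0 || m <= 0) stop("N_C and m must be positive", call. = FALSE)
  C <- diag(w_intra, N_C)
  C[cbind(seq_len(N_C) %% N_C + 1L, seq_len(N_C))] <- w_ff  # target i+1 <- source i
  kronecker(C, matrix(1, m, m))
}

#' Ground-truth sequential raster
#'
#' Builds a spike record in which the clusters fire strictly one after the
#' other: in each cycle, cluster `c` (0-based) owns the window
#' `[c * per_cluster_ms, (c+1) * per_cluster_ms)`, and each of its neurons
#' emits `spikes_per_window` evenly spaced spikes inside it, optionally
#' jittered.  The implied period is `N_C * per_cluster_ms`.
#'
#' @param N_C number of clusters.
#' @param per_cluster_ms activation window per cluster (ms).
#' @param n_cycles number of full cycles.
#' @param jitter standard deviation of Gaussian spike-time jitter (ms).
#' @param neurons_per_cluster neurons per cluster.
#' @param spikes_per_window spikes per neuron per activation.
#' @param seed RNG seed (used only when `jitter > 0`).
#' @return a spike record `data.frame` (`population`, `neuron`, `t_ms`)
#'   with the cluster labels attached as attribute `cluster_label`
#'   (0-based, per neuron).
#' @export
make_sequential_raster <- function(N_C, per_cluster_ms, n_cycles, jitter = 0,
                                   neurons_per_cluster = 5,
                                   spikes_per_window = 3, seed = 1L) {
  if (per_cluster_ms <= 0) stop("per_cluster_ms must be > 0", call. = FALSE)
  set.seed(seed)
  P <- N_C * per_cluster_ms
  rows <- list()
  if (n_cycles > 0) {
    offs <- (seq_len(spikes_per_window) - 0.5) / spikes_per_window * per_cluster_ms
    for (cyc in 0:(n_cycles - 1L)) {
      for (c0 in 0:(N_C - 1L)) {
        base <- cyc * P + c0 * per_cluster_ms
        for (nn in seq_len(neurons_per_cluster)) {
          t <- base + offs
          if (jitter > 0) t <- t + stats::rnorm(length(t), 0, jitter)
          rows[[length(rows) + 1L]] <- data.frame(
            population = "E", neuron = c0 * neurons_per_cluster + nn,
            t_ms = t, stringsAsFactors = FALSE)
        }
      }
    }
  }
  rec <- if (length(rows)) do.call(rbind, rows) else
    data.frame(population = character(0), neuron = integer(0),
               t_ms = numeric(0), stringsAsFactors = FALSE)
  rec <- rec[rec$t_ms >= 0, , drop = FALSE]
  rec <- rec[order(rec$t_ms, rec$neuron), , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "cluster_label") <- rep(0:(N_C - 1L), each = neurons_per_cluster)
  rec
}

#' Scripted plasticity scenario
#'
#' A scenario scripts the postsynaptic membrane potential as a piecewise-
#' constant function on a segment grid, plus presynaptic and postsynaptic
#' spike times, for driving the plasticity rules outside the full network.
#' Segment boundaries and spike times sit on the `grid_ms` lattice so the
#' same scenario can be integrated exactly at any step size dividing
#' `grid_ms`.
#'
#' @param spec a list; either explicit fields `V_seg` (voltages, mV, one
#'   per segment), `seg_ms` (segment length), `pre_spikes`, `post_spikes`
#'   (times, ms) — or generator fields `T_ms`, `seg_ms`, `V_range`,
#'   `pre_rate_hz`, `post_rate_hz`, `seed` for a randomized scenario.
#' @param grid_ms time lattice (ms); defaults to 0.1.
#' @return object of class `plasticity_scenario`: `T_ms`, `seg_ms`,
#'   `V_seg`, `pre_spikes`, `post_spikes`, `grid_ms`.
#' @export
make_plasticity_scenario <- function(spec, grid_ms = 0.1) {
  snap <- function(t) round(t / grid_ms) * grid_ms
  if (!is.null(spec$V_seg)) {
    sc <- list(T_ms = length(spec$V_seg) * spec$seg_ms, seg_ms = spec$seg_ms,
               V_seg = spec$V_seg,
               pre_spikes = snap(spec$pre_spikes %||% numeric(0)),
               post_spikes = snap(spec$post_spikes %||% numeric(0)),
               grid_ms = grid_ms)
  } else {
    T_ms <- spec$T_ms %||% 200
    seg_ms <- spec$seg_ms %||% 10
    set.seed(spec$seed %||% 1L)
    nseg <- ceiling(T_ms / seg_ms)
    Vr <- spec$V_range %||% c(-75, -40)
    V_seg <- stats::runif(nseg, Vr[1], Vr[2])
    draw_times <- function(rate_hz) {
      n <- stats::rpois(1, rate_hz / 1000 * T_ms)
      sort(unique(snap(stats::runif(n, 0, T_ms - grid_ms))))
    }
    sc <- list(T_ms = nseg * seg_ms, seg_ms = seg_ms, V_seg = V_seg,
               pre_spikes = draw_times(spec$pre_rate_hz %||% 20),
               post_spikes = draw_times(spec$post_rate_hz %||% 20),
               grid_ms = grid_ms)
  }
  if (any(abs(sc$seg_ms / grid_ms - round(sc$seg_ms / grid_ms)) > 1e-9)) {
    stop("seg_ms must be a multiple of grid_ms", call. = FALSE)
  }
  class(sc) <- "plasticity_scenario"
  sc
}

#' Evaluate a scenario's scripted voltage at time t
#' @param sc a `plasticity_scenario`.
#' @param t time (ms).
#' @return voltage (mV); times beyond the script hold the last segment.
#' @export
scenario_voltage <- function(sc, t) {
  idx <- pmin(pmax(floor(t / sc$seg_ms + 1e-9), 0) + 1L, length(sc$V_seg))
  sc$V_seg[idx]
}
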