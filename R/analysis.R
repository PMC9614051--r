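#' Cluster-block means of a weight matrix
#'
#' Averages the EE weight matrix over cluster pairs: entry `(a, b)` is the
#' mean weight over *existing* edges from cluster `b` to cluster `a`
#' (rows are targets, columns sources).  Absent edges are excluded from
#' the mean; a block with no edges at all is reported as `NA`, not zero.
#'
#' @param W dense EE weight matrix (targets x sources).
#' @param labels 0-based per-neuron cluster labels (length = ncol = nrow).
#' @param adj logical adjacency matrix marking existing edges; if `NULL`,
#'   nonzero weights are treated as the edge set (structural zeros are
#'   then indistinguishable from absent edges).
#' @return object of class `cluster_block_matrix`: `means` and `counts`,
#'   both `N_C x N_C`.
#' @export
cluster_block_means <- function(W, labels, adj = NULL) {
  if (is.null(adj)) adj <- W != 0
  N_C <- max(labels) + 1L
  f_t <- factor(labels, levels = 0:(N_C - 1L))
  # aggregate by target (rows) then source (columns)
  S <- rowsum(W * adj, f_t)
  S <- t(rowsum(t(S), f_t))
  Cn <- rowsum(adj + 0, f_t)
  Cn <- t(rowsum(t(Cn), f_t))
  means <- ifelse(Cn > 0, S / Cn, NA_real_)
  dimnames(means) <- dimnames(Cn) <- NULL
  structure(list(means = means, counts = Cn), class = "cluster_block_matrix")
}

#' @export
print.cluster_block_matrix <- function(x, ...) {
  cat(sprintf("<cluster_block_matrix> %d x %d blocks, %d edges\n",
              nrow(x$means), ncol(x$means), sum(x$counts)))
  invisible(x)
}

#' Feedforward ordering statistics of a block matrix
#'
#' Summarizes the learned ring structure: mean block weight within
#' clusters (`intra`), on the feedforward superdiagonal (target `i+1`,
#' source `i`, wrap-around included; `ff`), on the feedback subdiagonal
#' (`fb`), and over all remaining distant blocks (`far`).  A trained clock
#' shows `ff > fb > far`.
#'
#' @param bm a `cluster_block_matrix`.
#' @return list `intra`, `ff`, `fb`, `far` (block-mean averages).
#' @export
feedforward_ordering <- function(bm) {
  M <- bm$means
  N_C <- nrow(M)
  a <- row(M) - 1L; b <- col(M) - 1L
  isdiag <- a == b
  isff <- a == (b + 1L) %% N_C
  isfb <- a == (b - 1L + N_C) %% N_C
  far <- !(isdiag | isff | isfb)
  list(intra = mean(M[isdiag], na.rm = TRUE),
       ff = mean(M[isff], na.rm = TRUE),
       fb = mean(M[isfb], na.rm = TRUE),
       far = mean(M[far], na.rm = TRUE))
}

#' Eigenspectrum of the full signed weight matrix
#'
#' Computes all eigenvalues of the signed RNN weight matrix (excitatory
#' source columns positive, inhibitory negative; see
#' [full_weight_matrix()]) and classifies them: the `N_C` eigenvalues of
#' largest modulus form the leading set — for a learned cyclic feedforward
#' structure they trace a ring through the right half-plane (an idealized
#' ring matrix has them exactly on `m * w_ff` times the roots of unity,
#' which is why modulus rather than real part selects the full ring) —
#' the conjugate pair with the most negative real part among the remainder
#' is the E-I balance pair, and the rest is the bulk, whose radius is
#' estimated as the largest modulus among bulk eigenvalues.
#'
#' @param W square signed weight matrix.
#' @param N_C number of clusters (size of the leading set).
#' @return object of class `spectrum_result`: `values` (complex, all),
#'   `ring`, `balance_pair`, `bulk`, `bulk_radius`.
#' @export
full_spectrum <- function(W, N_C) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) {
    stop("full_spectrum requires a square matrix", call. = FALSE)
  }
  ev <- eigen(W, only.values = TRUE)$values
  ev <- as.complex(ev)
  ord <- order(-Mod(ev))
  ring <- ev[ord[seq_len(min(N_C, length(ev)))]]
  rest <- ev[ord[-seq_len(min(N_C, length(ev)))]]
  balance <- if (length(rest)) {
    rmin <- min(Re(rest))
    rest[abs(Re(rest) - rmin) < 1e-9 * max(1, abs(rmin))]
  } else complex(0)
  bulk <- if (length(rest)) {
    keep <- !(rest %in% balance)
    rest[keep]
  } else complex(0)
  structure(list(values = ev, ring = ring, balance_pair = balance,
                 bulk = bulk,
                 bulk_radius = if (length(bulk)) max(Mod(bulk)) else 0),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("<spectrum_result> %d eigenvalues; ring of %d (max Re %.4g), bulk radius %.4g\n",
              length(x$values), length(x$ring), max(Re(x$ring)), x$bulk_radius))
  invisible(x)
}

#' Clock metrics from a spike record
#'
#' Estimates the sequential dynamics of the clock from an excitatory spike
#' record: per-cluster population rates (Gaussian-smoothed), activation
#' episodes (maximal runs where one cluster's rate is the arg-max and
#' exceeds a threshold), the clock period (mean interval between
#' successive activation onsets of cluster 0, the phase reference), the
#' mean activation duration, and a sequentiality score — the fraction of
#' episode transitions that go from cluster `i` to `i+1 (mod N_C)`.
#'
#' The estimator is invariant to a uniform time shift of all spikes.
#' If no cluster ever crosses the threshold, the result carries status
#' `"no sequential dynamics"` rather than NaNs.
#'
#' @param spikes spike record `data.frame` with `population`, `neuron`,
#'   `t_ms` (only rows with `population == "E"` are used).
#' @param labels 0-based cluster label per excitatory neuron.
#' @param bin_ms rate histogram bin (ms).
#' @param sigma_ms Gaussian smoothing width (ms).
#' @param threshold_hz per-neuron activation threshold (Hz).
#' @return object of class `clock_metrics`: `status`, `period_ms`,
#'   `periods`, `activation_ms`, `score`, `episodes` (data.frame:
#'   `cluster`, `onset_ms`, `offset_ms`), `onsets0` (cluster-0 onsets).
#' @export
clock_metrics <- function(spikes, labels, bin_ms = 0.5, sigma_ms = 2,
                          threshold_hz = 30) {
  N_C <- max(labels) + 1L
  es <- spikes[spikes$population == "E", , drop = FALSE]
  none <- structure(list(status = "no sequential dynamics",
                         period_ms = NA_real_, periods = numeric(0),
                         activation_ms = NA_real_, score = NA_real_,
                         episodes = data.frame(), onsets0 = numeric(0)),
                    class = "clock_metrics")
  if (!nrow(es)) return(none)
  t0 <- min(es$t_ms)
  tt <- es$t_ms - t0                     # translation invariance
  T_ms <- max(tt) + bin_ms
  nb <- ceiling(T_ms / bin_ms)
  cl <- labels[es$neuron] + 1L
  counts <- matrix(0, N_C, nb)
  ij <- cbind(cl, pmin(floor(tt / bin_ms) + 1L, nb))
  for (k in seq_len(nrow(ij))) counts[ij[k, 1], ij[k, 2]] <- counts[ij[k, 1], ij[k, 2]] + 1
  n_per <- tabulate(labels + 1L, nbins = N_C)
  # Gaussian smoothing kernel on the bin grid
  half <- max(1L, ceiling(3 * sigma_ms / bin_ms))
  kern <- stats::dnorm(seq(-half, half) * bin_ms, sd = sigma_ms)
  kern <- kern / sum(kern)
  rates <- t(apply(counts, 1, function(x) {
    y <- stats::filter(x, kern, sides = 2)
    y[is.na(y)] <- 0
    as.numeric(y)
  }))
  # per-neuron Hz: counts per bin / (n_per * bin_ms) * 1000
  rates <- rates / (pmax(n_per, 1L) * bin_ms) * 1000
  top <- apply(rates, 2, which.max) - 1L
  topr <- rates[cbind(top + 1L, seq_len(nb))]
  active <- topr >= threshold_hz
  if (!any(active)) return(none)
  # maximal runs of a constant active arg-max cluster
  runs <- rle(ifelse(active, top, -1L))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values >= 0
  episodes <- data.frame(cluster = runs$values[keep],
                         onset_ms = (starts[keep] - 1L) * bin_ms + t0,
                         offset_ms = ends[keep] * bin_ms + t0)
  if (!nrow(episodes)) return(none)
  trans_ok <- diff(episodes$cluster) %% N_C == 1
  score <- if (nrow(episodes) > 1) mean(trans_ok) else NA_real_
  onsets0 <- episodes$onset_ms[episodes$cluster == 0L]
  periods <- diff(onsets0)
  structure(list(status = "ok",
                 period_ms = if (length(periods)) mean(periods) else NA_real_,
                 periods = periods,
                 activation_ms = mean(episodes$offset_ms - episodes$onset_ms),
                 score = score, episodes = episodes, onsets0 = onsets0),
            class = "clock_metrics")
}

#' @export
print.clock_metrics <- function(x, ...) {
  if (x$status != "ok") {
    cat("<clock_metrics>", x$status, "\n")
  } else {
    cat(sprintf("<clock_metrics> period %.1f ms (%d cycles), activation %.1f ms, score %.2f\n",
                x$period_ms, length(x$periods), x$activation_ms, x$score))
  }
  invisible(x)
}

#' Decode replayed sequences from read-out spikes
#'
#' Partitions read-out spikes into clock cycles (boundaries given by the
#' phase-reference onsets, e.g. `clock_metrics()$onsets0`), orders each
#' cycle's spikes in time, maps read-out neurons to their sequence
#' elements, and collapses consecutive spikes of the same neuron into one
#' element occurrence whose spike count is reported.  A cycle with no
#' read-out spikes decodes to an empty sequence; if no cycle contains any
#' spikes the result carries status `"decode failure"`.
#'
#' @param spikes spike record with `population == "R"` rows (others are
#'   ignored); `neuron` indexes the read-out population 1-based.
#' @param alphabet character vector mapping read-out neuron `k` to element
#'   `alphabet[k]`.
#' @param cycle_bounds_ms ascending vector of cycle boundary times; cycle
#'   `k` is `[cycle_bounds_ms[k], cycle_bounds_ms[k+1])`.
#' @return object of class `replay_decoding`: `status`, `cycles` (list of
#'   `list(elements, counts)`), `consistent` (all non-empty cycles decode
#'   identically), `decoded` (the common sequence if consistent).
#' @export
decode_replay <- function(spikes, alphabet, cycle_bounds_ms) {
  rs <- spikes[spikes$population == "R", , drop = FALSE]
  if (!nrow(rs) || length(cycle_bounds_ms) < 2) {
    return(structure(list(status = "decode failure", cycles = list(),
                          consistent = FALSE, decoded = character(0)),
                     class = "replay_decoding"))
  }
  cycles <- list()
  for (k in seq_len(length(cycle_bounds_ms) - 1L)) {
    sel <- rs$t_ms >= cycle_bounds_ms[k] & rs$t_ms < cycle_bounds_ms[k + 1L]
    cyc <- rs[sel, , drop = FALSE]
    cyc <- cyc[order(cyc$t_ms), , drop = FALSE]
    if (!nrow(cyc)) {
      cycles[[k]] <- list(elements = character(0), counts = integer(0))
    } else {
      r <- rle(cyc$neuron)
      cycles[[k]] <- list(elements = alphabet[r$values], counts = r$lengths)
    }
  }
  nonempty <- Filter(function(c) length(c$elements) > 0, cycles)
  if (!length(nonempty)) {
    return(structure(list(status = "decode failure", cycles = cycles,
                          consistent = FALSE, decoded = character(0)),
                     class = "replay_decoding"))
  }
  seqs <- vapply(nonempty, function(c) paste(c$elements, collapse = ""), "")
  consistent <- length(unique(seqs)) == 1L
  structure(list(status = "ok", cycles = cycles, consistent = consistent,
                 decoded = if (consistent) nonempty[[1]]$elements else character(0)),
            class = "replay_decoding")
}

#' @export
print.replay_decoding <- function(x, ...) {
  if (x$status != "ok") {
    cat("<replay_decoding>", x$status, "\n")
  } else {
    cat(sprintf("<replay_decoding> %d cycles, consistent: %s, decoded: %s\n",
                length(x$cycles), x$consistent, paste(x$decoded, collapse = "")))
  }
  invisible(x)
}
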