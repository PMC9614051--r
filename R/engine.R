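#' Simulation engine
#'
#' [run_phase()] advances the full network through one protocol phase with
#' the compiled time-stepped core: delayed spike delivery, conductance and
#' membrane updates, the plasticity rules flagged for the phase, periodic
#' synaptic normalization, and spike/voltage recording.  The higher-level
#' drivers [train_clock()], [train_readout()] and [replay()] chain phases
#' into the three-stage learning workflow.  State persists across a phase
#' (there is no periodic reset of state variables) and can be chained
#' between phases.
#'
#' @name engine
NULL

POP_CODES <- c("E", "I", "R", "S", "H")

pop_offsets <- function(topology) {
  c(E = 0L, I = topology$N_E, R = topology$N_E + topology$N_I,
    S = topology$N_E + topology$N_I + topology$N_R,
    H = topology$N_E + topology$N_I + topology$N_R * 2L)
}

# compile a stimulus_schedule into the engine's periodic interval program
compile_program <- function(schedule, cfg, topology) {
  dt <- cfg$protocol$dt
  off <- pop_offsets(topology)
  wext <- cfg$weights$external
  b <- schedule$blocks
  period_steps <- max(1L, round(schedule$period_ms / dt))
  breaks <- sort(unique(c(0, b$t_start, b$t_end)))
  breaks <- breaks[breaks < schedule$period_ms]
  break_steps <- as.integer(round(breaks / dt))
  blocks <- vector("list", length(breaks))
  for (k in seq_along(breaks)) {
    mid <- breaks[k] + dt / 4
    act <- b[b$t_start <= mid & b$t_end > mid, , drop = FALSE]
    if (nrow(act)) {
      rows <- matrix(0, nrow(act), 5)
      for (r in seq_len(nrow(act))) {
        pop <- act$population[r]
        ch <- if (act$channel[r] == "exc") 0 else 1
        wx <- if (pop == "E") {
          if (ch == 0) wext$E_exc else wext$E_inh
        } else wext[[pop]]
        rows[r, ] <- c(off[[pop]] + act$lo[r] - 1L,
                       off[[pop]] + act$hi[r] - 1L,
                       ch, act$rate_hz[r] / 1000 * dt, wx)
      }
      blocks[[k]] <- rows
    } else {
      blocks[[k]] <- matrix(0, 0, 5)
    }
  }
  list(period_steps = period_steps, break_steps = break_steps,
       blocks = blocks)
}

phase_flags <- function(phase) {
  switch(phase,
    clock1 = ,
    clock2 = list(EE = TRUE, EI = TRUE, RE = FALSE, frozen = FALSE, norm = TRUE),
    readout = list(EE = FALSE, EI = FALSE, RE = TRUE, frozen = FALSE, norm = FALSE),
    replay = ,
    frozen = list(EE = FALSE, EI = FALSE, RE = FALSE, frozen = TRUE, norm = FALSE),
    stop("unknown phase: ", phase, call. = FALSE)
  )
}

engine_classes <- function(topology, synapses, cfg, flags) {
  pops <- c(E = 0L, I = 1L, R = 2L, S = 3L, H = 4L)
  exc_src <- c(E = TRUE, I = FALSE, R = TRUE, S = TRUE, H = FALSE)
  dt <- cfg$protocol$dt
  out <- list()
  for (cl in names(topology$edges)) {
    e <- topology$edges[[cl]]
    pp <- class_populations(cl)
    plastic <- isTRUE(synapses$plastic[[cl]]) && isTRUE(flags[[cl]])
    bnd <- synapses$bounds[[cl]] %||% c(-Inf, Inf)
    out[[cl]] <- list(
      name = cl, src_pop = pops[[pp$source]], tgt_pop = pops[[pp$target]],
      src = as.integer(e[, "src"] - 1L), tgt = as.integer(e[, "tgt"] - 1L),
      w = as.numeric(synapses$W[[cl]]),
      delay_steps = as.integer(round(topology$delay[[cl]] / dt)),
      plastic = plastic, exc = exc_src[[pp$source]],
      wmin = bnd[1], wmax = bnd[2])
  }
  unname(out)
}

#' Run one simulation phase
#'
#' @param topology a [build_connectivity()] result.
#' @param synapses a [init_weights()] result (or the updated state returned
#'   by a previous phase).
#' @param schedule a `stimulus_schedule` covering the phase.
#' @param cfg the [clock_config()].
#' @param phase one of `"clock1"`, `"clock2"` (EE and EI plastic, EE
#'   normalization on), `"readout"` (only RE plastic — the clock is
#'   frozen), `"replay"`/`"frozen"` (all plasticity off).
#' @param duration_ms simulated duration; defaults to the schedule's.
#' @param state optional neuron/trace state from a previous phase to
#'   continue from.
#' @param record_spikes record spikes (logical).
#' @param rec_from_ms start of the spike-recording window (ms).
#' @param record_V optional list(ids = global 0-based neuron ids,
#'   every_ms = sampling interval) for membrane-potential traces.
#' @param trigger optional list enabling cycle-locked stimulation: fields
#'   `ids` (global 0-based neuron ids of the reference cluster),
#'   `window_ms`, `count_min`, `refractory_ms`; when the reference cluster
#'   fires `count_min` spikes within `window_ms`, the stimulus program
#'   restarts from position zero (and holds at its end otherwise).
#' @param seed RNG seed for this phase's Poisson input; `NULL` leaves the
#'   RNG state untouched.
#' @return list: `spikes` (data.frame `population`, `neuron`, `t_ms`),
#'   `synapses` (updated), `state` (chainable), `stats` (clip counts,
#'   normalization residual), `V_rec`.
#' @export
run_phase <- function(topology, synapses, schedule, cfg, phase,
                      duration_ms = schedule$duration_ms, state = NULL,
                      record_spikes = TRUE, rec_from_ms = 0,
                      record_V = NULL, trigger = NULL, seed = NULL) {
  dt <- cfg$protocol$dt
  flags <- phase_flags(phase)
  if (isTRUE(synapses$frozen)) {
    flags$EE <- flags$EI <- flags$RE <- FALSE
    flags$frozen <- TRUE
    flags$norm <- FALSE
  }
  n_steps <- as.integer(round(duration_ms / dt))
  prog <- compile_program(schedule, cfg, topology)
  eE <- cfg$neuron$E; eI <- cfg$neuron$I
  ecfg <- list(
    n_E = topology$N_E, n_I = topology$N_I, n_R = topology$N_R,
    dt = dt, n_steps = n_steps,
    neuronE = c(tau_m = eE$tau_m, E_L = eE$E_L, Delta_T = eE$Delta_T,
                V_T0 = eE$V_T0, A_T = eE$A_T, tau_T = eE$tau_T,
                V_peak = eE$V_peak, V_reset = eE$V_reset,
                t_ref_steps = round(eE$t_ref / dt),
                tau_a = eE$tau_a, b_a = eE$b_a),
    neuronI = c(tau_m = eI$tau_m, E_L = eI$E_L, V_th = eI$V_th,
                V_reset = eI$V_reset, t_ref_steps = round(eI$t_ref / dt)),
    syn = unlist(cfg$synapse),
    plast = c(A_LTD = cfg$plasticity$A_LTD, A_LTP = cfg$plasticity$A_LTP,
              theta_LTD = cfg$plasticity$theta_LTD,
              theta_LTP = cfg$plasticity$theta_LTP,
              tau_u = cfg$plasticity$tau_u, tau_v = cfg$plasticity$tau_v,
              tau_x_EE = cfg$plasticity$tau_x_EE,
              tau_x_RE = cfg$plasticity$tau_x_RE,
              alpha = cfg$plasticity$alpha, A_inh = cfg$plasticity$A_inh,
              r_0 = cfg$plasticity$r_0, tau_y = cfg$plasticity$tau_y),
    frozen = flags$frozen,
    norm_on = flags$norm,
    norm_steps = as.integer(round(cfg$plasticity$tau_norm / dt)),
    K = synapses$K,
    classes = engine_classes(topology, synapses, cfg, flags),
    program = prog,
    trigger = if (is.null(trigger)) {
      list(on = FALSE, ids = integer(0), window_steps = 1L,
           count_min = 1L, refractory_steps = 1L)
    } else {
      list(on = TRUE, ids = as.integer(trigger$ids),
           window_steps = max(1L, as.integer(round(trigger$window_ms / dt))),
           count_min = as.integer(trigger$count_min),
           refractory_steps = max(1L, as.integer(round(trigger$refractory_ms / dt))))
    },
    record_spikes = record_spikes,
    rec_from_step = as.integer(round(rec_from_ms / dt)),
    record_V = if (is.null(record_V)) {
      list(ids = integer(0), every = 0L)
    } else {
      list(ids = as.integer(record_V$ids),
           every = max(1L, as.integer(round(record_V$every_ms / dt))))
    },
    state = state
  )
  if (!is.null(seed)) set.seed(seed)
  res <- .engine_run(ecfg)
  spikes <- data.frame(
    population = POP_CODES[res$spike_pop + 1L],
    neuron = res$spike_id, t_ms = res$spike_t, stringsAsFactors = FALSE)
  syn2 <- synapses
  for (cl in names(res$weights)) syn2$W[[cl]] <- res$weights[[cl]]
  list(spikes = spikes, synapses = syn2, state = res$state,
       stats = list(clipped = res$clipped,
                    norm_residual_max = res$norm_residual_max,
                    norm_events = res$norm_events),
       V_rec = res$V_rec)
}

#' Train the clock (phases 1 and 2)
#'
#' Builds the topology, initializes weights, drives the RNN with the
#' sequential cluster stimulation for phase 1 and with unstructured
#' spontaneous input for phase 2 (EE and EI plastic throughout, EE
#' normalization every `tau_norm`), then freezes all clock weights.
#'
#' @param cfg a [clock_config()].
#' @param seeds list with `topology`, `stimulus` entries; defaults to
#'   `cfg$seeds`.
#' @param record_tail_s seconds of phase-2 spike recording to keep (from
#'   the end), for diagnostics.
#' @return list: `topology`, `synapses` (frozen), `state`, `spikes2`
#'   (phase-2 tail), `stats1`, `stats2`.
#' @export
train_clock <- function(cfg, seeds = cfg$seeds, record_tail_s = 5) {
  topo <- build_connectivity(cfg, seed = seeds$topology)
  syn <- init_weights(topo, cfg)
  p1_ms <- cfg$protocol$phase1_s * 1000
  p2_ms <- cfg$protocol$phase2_s * 1000
  r1 <- NULL
  state <- NULL
  if (p1_ms > 0) {
    sch1 <- sequential_schedule(cfg, p1_ms)
    r1 <- run_phase(topo, syn, sch1, cfg, "clock1", record_spikes = FALSE,
                    seed = seeds$stimulus)
    syn <- r1$synapses
    state <- r1$state
  }
  r2 <- NULL
  if (p2_ms > 0) {
    sch2 <- spontaneous_schedule(cfg, p2_ms)
    r2 <- run_phase(topo, syn, sch2, cfg, "clock2", state = state,
                    record_spikes = TRUE,
                    rec_from_ms = max(0, p2_ms - record_tail_s * 1000),
                    seed = seeds$stimulus + 1L)
    syn <- r2$synapses
    state <- r2$state
  }
  syn$frozen <- TRUE
  list(topology = topo, synapses = syn, state = state,
       spikes2 = if (is.null(r2)) NULL else r2$spikes,
       stats1 = if (is.null(r1)) NULL else r1$stats,
       stats2 = if (is.null(r2)) NULL else r2$stats)
}

# reference-cluster trigger spec used to lock stimulation to the clock
clock_trigger <- function(topology, cfg) {
  m <- topology$N_E %/% topology$N_C
  P <- topology$N_C * (cfg$protocol$t_stim + cfg$protocol$t_gap)
  list(ids = 0:(m - 1L), window_ms = 3, count_min = max(3L, round(0.3 * m)),
       refractory_ms = 0.6 * P)
}

#' Train the read-out layer on a sequence
#'
#' With the clock weights frozen, first lets the network settle into
#' sequential dynamics under spontaneous input (warmup), then repeatedly
#' presents the sequence by driving each element's supervisor neuron at
#' `excS` for `t_element` ms (baseline `baseS` otherwise) while the
#' interneurons receive constant drive.  Presentations are locked to the
#' clock: the supervisor program restarts each time the reference cluster
#' (cluster 0) activates, so every element appears at the same time
#' relative to the first cluster in every cycle.  Only the RE connections
#' are plastic, following the voltage-based STDP rule without
#' weight-dependent potentiation.
#'
#' @param clock result of [train_clock()] (or a compatible list with
#'   `topology`, `synapses`, `state`).
#' @param seq a [sequence_spec()]; its alphabet size must not exceed `N_R`
#'   and its presentation must fit within one clock cycle.
#' @param cfg the [clock_config()].
#' @param seed RNG seed for the stimulus; defaults to `cfg$seeds$stimulus + 2`.
#' @param train_s training duration in seconds; defaults to
#'   `cfg$protocol$readout_s`.
#' @return list: `topology`, `synapses` (RE trained, still frozen clock),
#'   `state`, `seq`, `spikes` (training-phase record), `stats`.
#' @export
train_readout <- function(clock, seq, cfg,
                          seed = cfg$seeds$stimulus + 2L,
                          train_s = cfg$protocol$readout_s) {
  topo <- clock$topology
  syn <- clock$synapses
  # clock connections stay frozen; RE must learn
  syn$frozen <- FALSE
  warm_ms <- cfg$protocol$warmup_ms
  state <- clock$state
  if (warm_ms > 0) {
    wsch <- spontaneous_schedule(cfg, warm_ms)
    wr <- run_phase(topo, syn, wsch, cfg, "frozen", state = state,
                    record_spikes = FALSE, seed = seed)
    state <- wr$state
  }
  P <- topo$N_C * (cfg$protocol$t_stim + cfg$protocol$t_gap)
  n_rep <- ceiling(train_s * 1000 / P)
  sch <- readout_schedule(seq, cfg, n_rep, clock_period_ms = P)
  rr <- run_phase(topo, syn, sch, cfg, "readout",
                  duration_ms = train_s * 1000, state = state,
                  record_spikes = TRUE,
                  trigger = clock_trigger(topo, cfg), seed = seed + 1L)
  syn2 <- rr$synapses
  syn2$frozen <- TRUE
  list(topology = topo, synapses = syn2, state = rr$state, seq = seq,
       spikes = rr$spikes, stats = rr$stats)
}

#' Replay with spontaneous input only
#'
#' Freezes all weights, silences supervisors and interneurons, and drives
#' only the RNN with spontaneous input; the clock cycles autonomously and
#' the read-out neurons fire purely from their learned RE weights.
#'
#' @param trained result of [train_readout()] (or `train_clock()` for
#'   clock-only replay).
#' @param cfg the [clock_config()].
#' @param duration_s replay duration (s); defaults to
#'   `cfg$protocol$replay_s`.
#' @param seed stimulus seed; defaults to `cfg$seeds$stimulus + 9`.
#' @return list: `spikes` (all populations), `state`.
#' @export
replay <- function(trained, cfg, duration_s = cfg$protocol$replay_s,
                   seed = cfg$seeds$stimulus + 9L) {
  syn <- trained$synapses
  syn$frozen <- TRUE
  sch <- spontaneous_schedule(cfg, duration_s * 1000)
  rr <- run_phase(trained$topology, syn, sch, cfg, "replay",
                  state = trained$state, record_spikes = TRUE, seed = seed)
  list(spikes = rr$spikes, state = rr$state)
}

#' Decode a replay run
#'
#' Convenience pipeline: estimates the clock metrics from the replayed
#' excitatory raster, uses the reference-cluster (cluster 0) activation
#' onsets as cycle boundaries, and decodes the read-out spike order within
#' each cycle.  Episode detection occasionally misses a reference-cluster
#' activation (its smoothed rate dips under the threshold for one cycle);
#' an inter-onset interval close to an integer multiple of the median
#' period is therefore filled in by interpolated boundaries before
#' decoding, so a missed detection does not merge two clock cycles.
#'
#' @param replay_spikes spike record from [replay()].
#' @param topology the network topology (for cluster labels).
#' @param seq the trained [sequence_spec()].
#' @param ... passed to [clock_metrics()].
#' @return list: `metrics` (a `clock_metrics`), `decoding`
#'   (a `replay_decoding`), `cycle_bounds_ms` (the boundaries used).
#' @export
decode_replay_run <- function(replay_spikes, topology, seq, ...) {
  cm <- clock_metrics(replay_spikes, topology$cluster_label, ...)
  bounds <- if (cm$status == "ok") fill_onset_gaps(cm$onsets0) else numeric(0)
  dec <- if (length(bounds) >= 2) {
    decode_replay(replay_spikes, seq$alphabet, bounds)
  } else {
    decode_replay(replay_spikes[0, ], seq$alphabet, numeric(0))
  }
  list(metrics = cm, decoding = dec, cycle_bounds_ms = bounds)
}

# insert interpolated boundaries where an inter-onset interval is close to
# an integer multiple (>= 2) of the median period
fill_onset_gaps <- function(onsets) {
  if (length(onsets) < 3) return(onsets)
  med <- stats::median(diff(onsets))
  out <- onsets[1]
  for (k in 2:length(onsets)) {
    gap <- onsets[k] - onsets[k - 1]
    m <- round(gap / med)
    if (m >= 2 && abs(gap / m - med) < 0.25 * med) {
      out <- c(out, onsets[k - 1] + gap / m * seq_len(m - 1))
    }
    out <- c(out, onsets[k])
  }
  out
}
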