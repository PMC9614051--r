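#' Stimulus schedules
#'
#' A `stimulus_schedule` is a piecewise-constant Poisson rate function per
#' neuron and channel, represented as a block table with columns
#' `population` ("E", "I", "R", "S", "H"), `lo`/`hi` (1-based neuron range
#' within the population), `t_start`/`t_end` (ms, within one period),
#' `channel` ("exc" or "inh"), and `rate_hz`.  Periodic schedules repeat
#' their block table every `period_ms` for `duration_ms` total.
#'
#' @name stimulus_schedule
NULL

new_schedule <- function(blocks, duration_ms, period_ms) {
  blocks <- blocks[blocks$t_end > blocks$t_start & blocks$rate_hz > 0, , drop = FALSE]
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, duration_ms = duration_ms,
                 period_ms = period_ms),
            class = "stimulus_schedule")
}

sched_block <- function(population, lo, hi, t_start, t_end, channel, rate_hz) {
  data.frame(population = population, lo = as.integer(lo), hi = as.integer(hi),
             t_start = t_start, t_end = t_end, channel = channel,
             rate_hz = rate_hz, stringsAsFactors = FALSE)
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("<stimulus_schedule> duration %g ms, period %g ms, %d blocks\n",
              x$duration_ms, x$period_ms, nrow(x$blocks)))
  invisible(x)
}

#' Sequential cluster stimulation (clock-learning phase 1)
#'
#' Builds the periodic phase-1 drive: clusters are excited one by one in
#' ascending order, each for `t_stim` ms at rate `exc1E`, with a `t_gap` ms
#' gap before the next cluster's window; the full round has period
#' `N_C * (t_stim + t_gap)`.  Whenever a cluster is not receiving
#' excitatory drive — including the gaps — each of its neurons receives
#' external inhibitory input at rate `inhE` instead, so at every instant
#' every excitatory neuron receives exactly one of the two drives.
#' Inhibitory neurons receive constant excitatory drive at rate `excI`
#' throughout.
#'
#' Cluster `c` (0-based) is excited during
#' `[k*P + c*(t_stim+t_gap), k*P + c*(t_stim+t_gap) + t_stim)` for every
#' round `k` — the full `t_stim` window, with the gap following it (and
#' hence preceding the next cluster's activation).
#'
#' @param cfg a [clock_config()].
#' @param T_ms total schedule duration in ms; defaults to phase-1 duration.
#' @return a `stimulus_schedule`.
#' @export
sequential_schedule <- function(cfg, T_ms = cfg$protocol$phase1_s * 1000) {
  if (T_ms < 0) stop("schedule duration must be >= 0", call. = FALSE)
  pr <- cfg$protocol; nw <- cfg$network
  check_dt_multiple(c(pr$t_stim, pr$t_gap), pr$dt, "t_stim/t_gap")
  slot <- pr$t_stim + pr$t_gap
  P <- nw$N_C * slot
  m <- nw$N_E %/% nw$N_C
  blocks <- list()
  for (c0 in 0:(nw$N_C - 1L)) {
    lo <- c0 * m + 1L; hi <- (c0 + 1L) * m
    on <- c0 * slot
    blocks[[length(blocks) + 1L]] <-
      sched_block("E", lo, hi, on, on + pr$t_stim, "exc", pr$rates$exc1E)
    if (on > 0) {
      blocks[[length(blocks) + 1L]] <-
        sched_block("E", lo, hi, 0, on, "inh", pr$rates$inhE)
    }
    if (on + pr$t_stim < P) {
      blocks[[length(blocks) + 1L]] <-
        sched_block("E", lo, hi, on + pr$t_stim, P, "inh", pr$rates$inhE)
    }
  }
  blocks[[length(blocks) + 1L]] <-
    sched_block("I", 1L, nw$N_I, 0, P, "exc", pr$rates$excI)
  new_schedule(do.call(rbind, blocks), T_ms, P)
}

#' Spontaneous (unstructured) drive (clock-learning phase 2, warmup, replay)
#'
#' Constant excitatory Poisson drive to every RNN neuron: rate `exc2E` for
#' excitatory and `excI` for inhibitory neurons, for the whole duration.
#'
#' @param cfg a [clock_config()].
#' @param T_ms duration in ms; defaults to phase-2 duration.
#' @return a `stimulus_schedule`.
#' @export
spontaneous_schedule <- function(cfg, T_ms = cfg$protocol$phase2_s * 1000) {
  if (T_ms < 0) stop("schedule duration must be >= 0", call. = FALSE)
  pr <- cfg$protocol; nw <- cfg$network
  if (T_ms == 0) {
    return(new_schedule(sched_block("E", 1L, 1L, 0, 0, "exc", 0), 0, 1))
  }
  blocks <- rbind(
    sched_block("E", 1L, nw$N_E, 0, T_ms, "exc", pr$rates$exc2E),
    sched_block("I", 1L, nw$N_I, 0, T_ms, "exc", pr$rates$excI)
  )
  new_schedule(blocks, T_ms, T_ms)
}

#' Specify a sequence over an alphabet
#'
#' @param elements character vector of sequence elements in presentation
#'   order, e.g. `c("A","B","C","B","A")`.  Each distinct element maps to
#'   exactly one read-out/supervisor/interneuron triple, in order of first
#'   appearance sorted alphabetically.
#' @param t_element presentation duration per element (ms).
#' @param lead lead time before the first element within each clock cycle (ms).
#' @return an object of class `sequence_spec`.
#' @export
sequence_spec <- function(elements, t_element = 75, lead = 25) {
  if (!is.character(elements)) elements <- as.character(elements)
  alphabet <- sort(unique(elements))
  structure(list(elements = elements, alphabet = alphabet,
                 map = match(elements, alphabet),
                 t_element = t_element, lead = lead),
            class = "sequence_spec")
}

#' @export
print.sequence_spec <- function(x, ...) {
  cat(sprintf("<sequence_spec> %s (alphabet %s), %g ms/element + %g ms lead = %g ms\n",
              paste(x$elements, collapse = ""), paste(x$alphabet, collapse = ""),
              x$t_element, x$lead, presentation_duration(x)))
  invisible(x)
}

#' Total presentation duration of a sequence (lead + elements), ms
#' @param seq a `sequence_spec`.
#' @export
presentation_duration <- function(seq) {
  seq$lead + length(seq$elements) * seq$t_element
}

#' Read-out training schedule
#'
#' Builds the periodic supervisor/interneuron drive used while the frozen
#' clock runs under spontaneous input.  In each repetition (locked to
#' clock-period boundaries), element `k`'s supervisor neuron receives rate
#' `excS` during `[lead + k*t_element, lead + (k+1)*t_element)` and the
#' baseline rate `baseS` at all other times; interneurons receive constant
#' drive `excH`.  RNN spontaneous drive (`exc2E`, `excI`) is included so the
#' schedule fully describes the training-phase input.
#'
#' The presentation must fit inside one clock cycle: a sequence whose
#' `lead + length * t_element` exceeds `clock_period_ms` is rejected,
#' because each element must appear at the same time relative to the
#' activation of the first cluster in every cycle.
#'
#' @param seq a [sequence_spec()].
#' @param cfg a [clock_config()].
#' @param n_repeats number of clock cycles of training drive.
#' @param clock_period_ms the clock period to lock repetitions to; defaults
#'   to the phase-1 stimulation period `N_C * (t_stim + t_gap)`.
#' @return a `stimulus_schedule` over populations E, I, S, H.
#' @export
readout_schedule <- function(seq, cfg, n_repeats,
                             clock_period_ms =
                               cfg$network$N_C * (cfg$protocol$t_stim + cfg$protocol$t_gap)) {
  pr <- cfg$protocol
  pres <- presentation_duration(seq)
  if (pres > clock_period_ms) {
    stop(sprintf(paste0("sequence presentation (%g ms) exceeds the clock period ",
                        "(%g ms); the presentation time of a sequence may not ",
                        "exceed the duration of a clock cycle"),
                 pres, clock_period_ms), call. = FALSE)
  }
  nA <- length(seq$alphabet)
  if (nA > cfg$network$N_R) {
    stop(sprintf("sequence alphabet size %d exceeds configured N_R = %d",
                 nA, cfg$network$N_R), call. = FALSE)
  }
  P <- clock_period_ms
  blocks <- list()
  # supervisor windows: element k -> supervisor seq$map[k]
  n_el <- length(seq$elements)
  for (s in seq_len(cfg$network$N_R)) {
    wins <- if (n_el) which(seq$map == s) else integer(0)
    cuts <- sort(unique(c(0, seq$lead + (wins - 1L) * seq$t_element,
                          seq$lead + wins * seq$t_element, P)))
    for (j in seq_len(length(cuts) - 1L)) {
      mid <- (cuts[j] + cuts[j + 1L]) / 2
      active <- any(mid >= seq$lead + (wins - 1L) * seq$t_element &
                    mid < seq$lead + wins * seq$t_element)
      blocks[[length(blocks) + 1L]] <-
        sched_block("S", s, s, cuts[j], cuts[j + 1L], "exc",
                    if (active) pr$rates$excS else pr$rates$baseS)
    }
  }
  blocks[[length(blocks) + 1L]] <-
    sched_block("H", 1L, cfg$network$N_R, 0, P, "exc", pr$rates$excH)
  blocks[[length(blocks) + 1L]] <-
    sched_block("E", 1L, cfg$network$N_E, 0, P, "exc", pr$rates$exc2E)
  blocks[[length(blocks) + 1L]] <-
    sched_block("I", 1L, cfg$network$N_I, 0, P, "exc", pr$rates$excI)
  new_schedule(do.call(rbind, blocks), n_repeats * P, P)
}

#' Query the scheduled rate for one neuron at one time
#'
#' @param schedule a `stimulus_schedule`.
#' @param population population tag.
#' @param neuron 1-based neuron index within the population.
#' @param t time in ms (absolute; periodic schedules wrap).
#' @return named numeric `c(exc = , inh = )` in spk/s.
#' @export
rate_at <- function(schedule, population, neuron, t) {
  out <- c(exc = 0, inh = 0)
  if (t < 0 || t >= schedule$duration_ms) return(out)
  tp <- t %% schedule$period_ms
  b <- schedule$blocks
  hit <- b$population == population & b$lo <= neuron & b$hi >= neuron &
    b$t_start <= tp & b$t_end > tp
  for (i in which(hit)) out[[b$channel[i]]] <- out[[b$channel[i]]] + b$rate_hz[i]
  out
}

#' Sample external Poisson spike counts from a schedule
#'
#' Draws, for every neuron and every time bin of width `dt`, a full Poisson
#' count at the scheduled rate (not a Bernoulli thinning — at the protocol's
#' rates more than one external spike per 0.1 ms bin is common).  Intended
#' for audits and tests; the simulation engine samples the same law
#' internally.
#'
#' @param schedule a `stimulus_schedule`.
#' @param dt bin width, ms.
#' @param seed RNG seed.
#' @param T_ms optional truncation of the sampled duration.
#' @return a `data.frame` with one row per nonzero bin: `population`,
#'   `neuron`, `t_ms` (bin start), `channel`, `count`.
#' @export
sample_poisson <- function(schedule, dt, seed = 1L, T_ms = schedule$duration_ms) {
  set.seed(seed)
  T_ms <- min(T_ms, schedule$duration_ms)
  n_steps <- round(T_ms / dt)
  out <- list()
  b <- schedule$blocks
  P <- schedule$period_ms
  for (i in seq_len(nrow(b))) {
    lam <- b$rate_hz[i] / 1000 * dt      # expected count per bin
    if (lam == 0) next
    # bins whose start falls inside this block, over all periods
    starts0 <- seq(b$t_start[i], b$t_end[i] - dt / 2, by = dt)
    n_per <- max(1, ceiling(T_ms / P))
    for (k in 0:(n_per - 1L)) {
      starts <- k * P + starts0
      starts <- starts[starts < T_ms]
      if (!length(starts)) next
      for (nr in b$lo[i]:b$hi[i]) {
        cnt <- stats::rpois(length(starts), lam)
        nz <- which(cnt > 0L)
        if (length(nz)) {
          out[[length(out) + 1L]] <- data.frame(
            population = b$population[i], neuron = nr,
            t_ms = starts[nz], channel = b$channel[i], count = cnt[nz],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(population = character(0), neuron = integer(0),
                      t_ms = numeric(0), channel = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$t_ms, res$population, res$neuron), , drop = FALSE]
}

#' Export a schedule as TSV for audit
#' @param schedule a `stimulus_schedule`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# neuroclock stimulus schedule v1 (neuron ranges 1-based)",
               sprintf("# duration_ms=%g period_ms=%g",
                       schedule$duration_ms, schedule$period_ms)), con)
  utils::write.table(schedule$blocks, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

check_dt_multiple <- function(x, dt, what) {
  bad <- abs(x / dt - round(x / dt)) > 1e-9
  if (any(bad)) {
    stop(sprintf("%s not an integer multiple of dt = %g ms", what, dt),
         call. = FALSE)
  }
  invisible(TRUE)
}
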