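#!/usr/bin/env Rscript
# Long-running validation at the published full scale: 2400 excitatory
# neurons in 30 clusters, 600 inhibitory neurons, 1 h sequential + 1 h
# spontaneous clock learning, 12 s of ABCBA read-out training, then replay.
# Asserted targets: clock period ~470 ms (+-10%), per-cluster activation
# ~15 ms, and about one read-out spike per element during replay.  Expect
# many hours of compute on one core; intermediate artifacts are written
# next to --out.
#
# Usage: Rscript scripts/validate_full_scale.R [--seed <int>] [--out <dir>]

suppressPackageStartupMessages(library(neuroclock))

args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(flag, default) {
  i <- match(flag, args)
  if (!is.na(i) && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_opt("--seed", "1"))
out_dir <- get_opt("--out", "results/full_scale")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- clock_config("full")
cfg$seeds <- list(topology = seed, stimulus = seed + 100L,
                  dynamics = seed + 200L)

message("training the clock (1 h + 1 h biological)...")
clock <- train_clock(cfg)
write_weights(clock$topology, clock$synapses,
              file.path(out_dir, "clock_weights"), cfg)

cm <- clock_metrics(clock$spikes2, clock$topology$cluster_label)
message(sprintf("clock period %.1f ms, activation %.1f ms, score %.2f",
                cm$period_ms, cm$activation_ms, cm$score))

sq <- sequence_spec(c("A", "B", "C", "B", "A"),
                    t_element = cfg$protocol$t_element,
                    lead = cfg$protocol$lead)
message("training the read-out (12 s biological)...")
tr <- train_readout(clock, sq, cfg)
rp <- replay(tr, cfg, duration_s = 5)
write_spikes(rp$spikes, file.path(out_dir, "replay_spikes.tsv"), cfg)
dec <- decode_replay_run(rp$spikes, tr$topology, sq)
per_cycle <- vapply(dec$decoding$cycles,
                    function(c) paste(c$elements, collapse = ""), "")
hits <- per_cycle == paste(sq$elements, collapse = "")
counts <- unlist(lapply(dec$decoding$cycles[hits], `[[`, "counts"))

result <- list(
  clock_period_ms = cm$period_ms,
  activation_ms = cm$activation_ms,
  sequentiality_score = cm$score,
  replay_correct_fraction = mean(hits),
  replay_spikes_per_element = mean(counts),
  period_in_470_pm_10pct = !is.na(cm$period_ms) &&
    abs(cm$period_ms - 470) / 470 <= 0.10
)
write_metrics(result, file.path(out_dir, "validation.json"))
str(result)
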