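# Small configurations and scenario parameter sets shared across tests.

tiny_cfg <- function(...) {
  base <- list(network = list(N_E = 40L, N_I = 20L, N_C = 4L, N_R = 2L),
               protocol = list(phase1_s = 1, phase2_s = 1, readout_s = 1,
                               replay_s = 0.5))
  over <- neuroclock:::merge_config(base, list(...))
  do.call(clock_config, c(list(preset = "desk"), over))
}

# plasticity parameters with rates large enough that scenario weight
# changes are well above floating-point noise
scenario_params <- function() {
  p <- clock_config("desk")$plasticity
  p$A_LTD <- 1e-4
  p$A_LTP <- 1e-5
  p$A_inh <- 1e-3
  p
}
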