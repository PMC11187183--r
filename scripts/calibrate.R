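#!/usr/bin/env Rscript
# ISI calibration sweep for the MP-network model.
#
# The membrane constants beyond the synaptic time constants are free model
# parameters; this script sweeps the input amplitude over its operating range
# and reports the pooled inter-spike-interval statistics of the driven
# network so they can be compared against the configured target profile
# (defaults below: mean ISI 40-60 ms, CV 0.1-0.5, the quasi-tonic regime the
# decision rule requires).  Run after changing any neuron parameter.
#
# Usage: Rscript scripts/calibrate.R [--seed <int>] [--t_end <s>]

suppressPackageStartupMessages(library(persistlick))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(seed = 1L, t_end = 2)
i <- 1L
while (i <= length(args)) {
  if (args[i] == "--seed") { opt$seed <- as.integer(args[i + 1L]); i <- i + 2L }
  else if (args[i] == "--t_end") { opt$t_end <- as.numeric(args[i + 1L]); i <- i + 2L }
  else stop("unknown argument: ", args[i])
}

target <- list(mean_isi = c(0.040, 0.060), cv = c(0.1, 0.5))

cat(sprintf("%8s %10s %8s %8s %8s\n",
            "amp_pA", "rate_Hz", "mISI_ms", "CV", "in_target"))
for (amp in c(50, 75, 100, 125, 150, 175, 200)) {
  net <- build_network(network_config(seed = opt$seed))
  sim <- simulate_network(net, input_protocol(delay = 0.05, amplitude = amp,
                                              duration = opt$t_end),
                          seed = opt$seed)
  s <- isi_summary(sim)
  ok <- !is.na(s$mean_isi) &&
    s$mean_isi >= target$mean_isi[1] && s$mean_isi <= target$mean_isi[2] &&
    s$cv_isi >= target$cv[1] && s$cv_isi <= target$cv[2]
  cat(sprintf("%8.0f %10.2f %8.1f %8.2f %8s\n",
              amp, s$rate_hz, 1000 * s$mean_isi, s$cv_isi, ok))
}
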