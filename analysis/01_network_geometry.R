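#!/usr/bin/env Rscript
# Wiring geometry of the spatial network: wrapped-Gaussian kernels and the
# realized connection frequency versus distance for the feedforward and
# recurrent projections (stable vs. spatially broadened inhibition).
# Writes: results/connection_vs_distance.csv, results/kernel_profiles.csv

library(spikecomms)
dir.create("results", showWarnings = FALSE)

scale <- 0.2
seed <- 101
cfg <- standard_params(scale)
sz <- spikecomms:::layer_sizes(cfg)
input <- grid_layer(sz$n_input, "input")
e_lay <- grid_layer(sz$n_e, "E")
i_lay <- grid_layer(sz$n_i, "I")

projections <- list(
  ffwd = list(pre = input, post = e_lay, sigma = 0.05, p_bar = 0.1),
  recE = list(pre = e_lay, post = e_lay, sigma = 0.1, p_bar = 0.01),
  recI = list(pre = i_lay, post = e_lay, sigma = 0.1, p_bar = 0.04),
  recI_broad = list(pre = i_lay, post = e_lay, sigma = 0.3, p_bar = 0.04)
)

prof <- do.call(rbind, lapply(names(projections), function(nm) {
  p <- projections[[nm]]
  syn <- sample_synapses(p$pre, p$post, p$sigma, p$p_bar,
                         seed_stream(seed, nm))
  cbind(projection = nm,
        connection_vs_distance(syn, p$pre, p$post, n_bins = 25))
}))
write.csv(prof, "results/connection_vs_distance.csv", row.names = FALSE)

u <- seq(0, 0.5, by = 0.005)
kern <- do.call(rbind, lapply(c(ffwd = 0.05, rec = 0.1, rec_broad = 0.3),
  function(s) data.frame(sigma = s, u = u, g = wrapped_gaussian(u, s))))
write.csv(kern, "results/kernel_profiles.csv", row.names = FALSE)

message("Feedforward connections concentrate within ~0.1 grid units; ",
        "broadening sigma_I from 0.1 to 0.3 spreads inhibition across ",
        "most of the domain (see results/connection_vs_distance.csv).")
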