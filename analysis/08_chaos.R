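#!/usr/bin/env Rscript
# Frozen-input test for macroscopic chaos: two receiver trials differing only
# in the excitatory cells' initial voltages, compared through the normalized
# difference of disc-averaged population rates at several spatial scales.
# Writes: results/chaos_delta.csv, results/chaos_grid_traces.csv

library(spikecomms)
dir.create("results", showWarnings = FALSE)

scale <- 0.1
radii <- c(0.025, 0.05, 0.1, 0.2, 0.5)
seed <- 808

rows <- list(); traces <- list()
for (type in c("standard", "spatial", "temporal")) {
  res <- chaos_test(type, scale = scale, radii = radii, duration = 20,
                    seed = seed_stream(seed, type), n_discs = 5)
  rows[[type]] <- cbind(type = type, res$table,
                        grid_delta = res$grid_delta)
  traces[[type]] <- data.frame(type = type,
                               bin = seq_len(nrow(res$grid_traces)),
                               res$grid_traces)
}
write.csv(do.call(rbind, rows), "results/chaos_delta.csv", row.names = FALSE)
write.csv(do.call(rbind, traces), "results/chaos_grid_traces.csv",
          row.names = FALSE)
message("Normalized trial-to-trial differences Delta(r):")
print(do.call(rbind, rows), row.names = FALSE, digits = 3)
message("Spatial destabilization is unreliable only at small radii ",
        "(microscopic chaos); slow inhibition adds whole-grid (macroscopic) ",
        "unreliability.")
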