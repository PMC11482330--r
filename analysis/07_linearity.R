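#!/usr/bin/env Rscript
# Superposition test of input-output linearity: responses to two
# complementary half-grid input patterns versus the response to their sum,
# for a spatially and a temporally destabilized output layer.
# Writes: results/linearity.csv, results/linearity_abs_diff.csv

library(spikecomms)
dir.create("results", showWarnings = FALSE)

scale <- 0.1
n_trials <- 5
seed <- 707

rows <- list(); dists <- list()
for (type in c("spatial", "temporal")) {
  res <- linearity_test(type, scale = scale, n_trials = n_trials,
                        duration = 20, seed = seed_stream(seed, type))
  rows[[type]] <- data.frame(type = type, mu = res$mu, sd = res$sd,
                             n_trials = n_trials)
  dists[[type]] <- data.frame(type = type, abs_diff = res$abs_diff)
}
out <- do.call(rbind, rows)
write.csv(out, "results/linearity.csv", row.names = FALSE)
write.csv(do.call(rbind, dists), "results/linearity_abs_diff.csv",
          row.names = FALSE)
message("Mean |nu_sum - nu_homo| (Hz) over trials:")
print(out, row.names = FALSE, digits = 3)
message("Spatial destabilization breaks superposition (large rate ",
        "reshuffling); temporal destabilization approximately preserves it.")
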