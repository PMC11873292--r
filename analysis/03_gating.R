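#!/usr/bin/env Rscript
# Flow-cytometry gating of simulated growth-plate events.
#
# Draws synthetic bimodal log-intensity events with the skeletal
# stem/progenitor fractions reported for reporter-positive resting
# chondrocytes (~18% SSC, ~29.3% pre-BCSP, ~2.8% BCSP within
# viable Lin- mCherry+ cells) and recovers them through the default
# gating tree.

suppressPackageStartupMessages(library(panrc))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
dir.create("results", showWarnings = FALSE)

fractions <- c(SSC = 0.18, preBCSP = 0.293, BCSP = 0.028)
n_events <- 5000

ev <- generate_flow_events(n_events, fractions, seed = seed)
g <- evaluate_gates(ev$events, default_gating_tree(), denominator = "mCherry+")

out <- data.frame(population = names(g$counts),
                  events = as.integer(g$counts),
                  pct_of_denominator = as.numeric(g$pct),
                  simulated_pct = 100 * fractions[names(g$counts)])
write.csv(out, "results/gating.csv", row.names = FALSE)

cat("Gated", n_events, "events (seed", seed, "), denominator",
    g$denominator, "=", g$denominator_count, "events\n\n")
print(out, digits = 3, row.names = FALSE)
cat("\nRecovered percentages track the simulated fractions up to binomial\n")
cat("sampling noise; table written to results/gating.csv\n")
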