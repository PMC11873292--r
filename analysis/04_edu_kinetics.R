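#!/usr/bin/env Rscript
# EdU pulse-chase label retention: slow vs fast cyclers.
#
# Simulates the published design — 8 consecutive daily EdU injections,
# sampling 1, 4 and 14 days after the last — for a slow-cycling
# reporter-positive resting population (200 h mean cycle) and a
# fast-cycling reporter-negative columnar population (30 h), with label
# scored undetectable after more than 4 post-labeling divisions.

suppressPackageStartupMessages(library(panrc))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
dir.create("results", showWarnings = FALSE)

tc <- simulate_edu(edu_config(seed = seed))
write.csv(tc, "results/edu_timecourse.csv", row.names = FALSE)

cat("EdU+ fraction per population per chase day (seed", seed, "):\n\n")
print(tc, digits = 3, row.names = FALSE)
fast14 <- tc$edu_fraction[tc$population == "mCherryNeg" & tc$chase_day == 14]
slow14 <- tc$edu_fraction[tc$population == "mCherryPos" & tc$chase_day == 14]
cat(sprintf(
  "\nAt +14 d the fast population retains %.1f%% vs %.1f%% in the slow\n",
  100 * fast14, 100 * slow14))
cat("population: rapid cycling dilutes the label below detection while\n")
cat("slow cyclers retain it. Table written to results/edu_timecourse.csv\n")
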