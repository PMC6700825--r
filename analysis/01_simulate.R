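#!/usr/bin/env Rscript
# Stage 1: simulate the screening cohort.
#
# Draws the default fixed-count synthetic cohort: 3270 pregnancies
# screened at 11+0 to 13+6 weeks, with 8 early-PE (5 delivering SGA),
# 35 late-PE (10 SGA) and 84 SGA-without-PE outcomes, marker MoM
# distributions per outcome group, per-arm blood-pressure series and
# maternal characteristics. Writes results/cohort.csv.

suppressPackageStartupMessages(library(pescreen))

seed <- 1101L
dir.create("results", showWarnings = FALSE)

cfg <- default_generator_config()
cohort <- generate_cohort(cfg, seed = seed)
write_cohort(cohort, "results/cohort.csv")

n <- nrow(cohort)
tab <- table(cohort$pe_status)
cat(sprintf("cohort: %d pregnancies (seed %d)\n", n, seed))
cat(sprintf("  early PE: %d (%.2f%%)   late PE: %d (%.2f%%)   total PE: %.2f%%\n",
            tab[["early"]], 100 * tab[["early"]] / n,
            tab[["late"]], 100 * tab[["late"]] / n,
            100 * sum(tab[c("early", "late")]) / n))
cat(sprintf("  SGA: %d, of which %d with PE and %d (%.2f%%) without\n",
            sum(cohort$sga), sum(cohort$sga & cohort$pe_status != "none"),
            sum(cohort$sga & cohort$pe_status == "none"),
            100 * sum(cohort$sga & cohort$pe_status == "none") / n))
cat("wrote results/cohort.csv\n")
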