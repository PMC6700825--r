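#!/usr/bin/env Rscript
# Stage 3: per-pregnancy risk calculation.
#
# Runs the four-step workflow on every pregnancy: prior risk from the
# five maternal factors, marker likelihood ratio under the fitted
# Gaussian hypothesis pair, posterior risk on the odds scale, separately
# for the early and late horizon. Writes results/risks.csv.

suppressPackageStartupMessages(library(pescreen))

cohort <- read_cohort("results/cohort.csv")
model <- read_risk_model("results/model.yaml")

panel <- compute_mom_panel(cohort, model$median)
risks <- score_cohort(cohort, panel, model$prior, model$gaussian)
write.csv(risks, "results/risks.csv", row.names = FALSE)

cat(sprintf("scored %d pregnancies\n", nrow(risks)))
cat(sprintf("median posterior risk: early %s, late %s\n",
            format_risk(median(risks$posterior_early)),
            format_risk(median(risks$posterior_late))))
pos <- screen_positive(risks$posterior_early, 20) |
  screen_positive(risks$posterior_late, 20)
cat(sprintf("screen-positive at the 1:20 program cutoff: %d (%.1f%%)\n",
            sum(pos), 100 * mean(pos)))
cat("wrote results/risks.csv\n")
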