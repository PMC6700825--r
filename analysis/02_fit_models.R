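#!/usr/bin/env Rscript
# Stage 2: MoM computation and model fitting.
#
# Computes adjusted, truncated MoM values for MAP, PLGF and PAPP-A under
# the shipped gestational-age median model, summarises them per outcome
# group (median/IQR with Mann-Whitney tests against the unaffected
# group), and fits the multivariate-Gaussian marker model per
# hypothesis. Also refits the median model from the cohort's unaffected
# pregnancies as a calibration check. Writes results/model.yaml and
# results/table_markers.csv.

suppressPackageStartupMessages(library(pescreen))

cohort <- read_cohort("results/cohort.csv")
cfg <- default_generator_config()

panel <- compute_mom_panel(cohort, cfg$median_model)
tab <- summarize_group_moms(cohort, panel)
write.csv(tab, "results/table_markers.csv", row.names = FALSE)

fmt <- function(g, mk) {
  r <- tab[tab$group == g & tab$marker == mk, ]
  sprintf("%.2f (%.2f-%.2f)", r$median, r$q1, r$q3)
}
cat("adjusted MoM by group [median (IQR)]:\n")
for (g in c("Unaffected by PE", "PE", "Early PE", "Late PE", "SGA without PE")) {
  cat(sprintf("  %-18s PLGF %s  PAPP-A %s  MAP %s\n",
              g, fmt(g, "plgf"), fmt(g, "pappa"), fmt(g, "map")))
}

group <- c(none = "unaffected", early = "early", late = "late")[as.character(cohort$pe_status)]
gauss <- fit_gaussian_model(log_mom_matrix(panel), group)
model <- risk_model(cfg$median_model, default_prior_model(), gauss)
write_risk_model(model, "results/model.yaml")

refit <- fit_median_model(cohort)
cat(sprintf("\nrefitted GA slopes (log10/day): PLGF %.4f, PAPP-A %.4f, MAP %.5f\n",
            refit$coef$plgf["slope"], refit$coef$pappa["slope"],
            refit$coef$map["slope"]))
cat(sprintf("refitted weight slopes (log10 MoM/kg): PLGF %.4f, PAPP-A %.4f\n",
            refit$weight_slope[["plgf"]], refit$weight_slope[["pappa"]]))
cat("wrote results/model.yaml, results/table_markers.csv\n")
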