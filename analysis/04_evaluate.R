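#!/usr/bin/env Rscript
# Stage 4: screening performance.
#
# ROC/AUC of prior versus posterior risks per horizon with paired DeLong
# comparison and best cutoffs (highest mean of sensitivity and
# specificity), then subgroup detection rates and PPVs at fixed FPRs of
# 5/10/15% with exact binomial CIs. Writes results/table_auc.csv,
# results/table_fixed_fpr.csv and results/roc_coordinates.csv.

suppressPackageStartupMessages(library(pescreen))

cohort <- read_cohort("results/cohort.csv")
risks <- read.csv("results/risks.csv")

auc_rows <- list(); coords <- list()
for (h in c("early", "late")) {
  lab <- cohort$pe_status == h
  for (kind in c("prior", "posterior")) {
    sc <- risks[[paste0(kind, "_", h)]]
    roc <- roc_auc(sc, lab)
    bc <- best_cutoff(roc)
    auc_rows[[paste(h, kind)]] <- data.frame(
      horizon = h, risk = kind, auc = roc$auc,
      auc_lo = roc$auc_ci[1], auc_hi = roc$auc_ci[2],
      best_cutoff = format_risk(bc$threshold), dr = bc$dr, fpr = bc$fpr,
      dr_at_1_20 = 100 * mean(screen_positive(sc[lab], 20))
    )
    coords[[paste(h, kind)]] <- data.frame(
      horizon = h, risk = kind, threshold = roc$thresholds,
      sensitivity = roc$sensitivity, specificity = roc$specificity
    )
  }
  cmp <- compare_auc(risks[[paste0("posterior_", h)]],
                     risks[[paste0("prior_", h)]], lab)
  cat(sprintf(
    "%s PE: AUC prior %.3f vs posterior %.3f (DeLong p = %.3g)\n",
    h, auc_rows[[paste(h, "prior")]]$auc,
    auc_rows[[paste(h, "posterior")]]$auc, cmp$p
  ))
  bcp <- auc_rows[[paste(h, "posterior")]]
  cat(sprintf("  best posterior cutoff %s: DR %.2f%%, FPR %.2f%%; DR at 1:20 %.2f%%\n",
              bcp$best_cutoff, bcp$dr, bcp$fpr, bcp$dr_at_1_20))
}
write.csv(do.call(rbind, auc_rows), "results/table_auc.csv", row.names = FALSE)
write.csv(do.call(rbind, coords), "results/roc_coordinates.csv", row.names = FALSE)

pe <- cohort$pe_status
sga <- cohort$sga
early_del <- cohort$ga_delivery_weeks < 34
perf <- rbind(
  cbind(horizon = "early", performance_table(
    risks$posterior_early, pe == "early",
    list("Early PE" = pe == "early",
         "Early PE with SGA" = pe == "early" & sga,
         "Early PE with AGA" = pe == "early" & !sga,
         "Early SGA" = sga & early_del,
         "Early SGA without PE" = sga & early_del & pe == "none"))),
  cbind(horizon = "late", performance_table(
    risks$posterior_late, pe == "late",
    list("Late PE" = pe == "late",
         "Late PE with SGA" = pe == "late" & sga,
         "Late PE with AGA" = pe == "late" & !sga,
         "Late SGA" = sga & !early_del,
         "Late SGA without PE" = sga & !early_del & pe == "none")))
)
write.csv(perf, "results/table_fixed_fpr.csv", row.names = FALSE)

cat("\ndetection at fixed FPR [DR% (95% CI)]:\n")
for (r in which(perf$subgroup %in% c("Early PE", "Late PE") & perf$fpr_target == 10)) {
  cat(sprintf("  %-8s at 10%% FPR (cutoff %s): %.2f%% (%.2f-%.2f), PPV %.2f%%\n",
              perf$subgroup[r], perf$cutoff[r], perf$dr[r],
              perf$dr_lo[r], perf$dr_hi[r], perf$ppv[r]))
}
cat("wrote results/table_auc.csv, results/table_fixed_fpr.csv, results/roc_coordinates.csv\n")
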