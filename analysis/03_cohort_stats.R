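#!/usr/bin/env Rscript

# Stage 3: cohort statistics on the reconstructed scans. Reproduces the
# study's comparisons: per-group per-view mean contralateral ratios, the
# one-way ANOVA of breast averages across views, the two-way (group x view,
# Type-II) ANOVA of breast average / separation / breast area, and pooled
# t-tests on the contralateral ratios. Requires results/scans.csv from
# stage 2.

suppressMessages(library(mwbreast))

scans <- read.csv("results/scans.csv")
summary <- read.csv("results/subject_summary.csv")
report <- cohort_report(list(scans = scans, summary = summary))

for (nm in names(report)) {
  p <- file.path("results", paste0(nm, ".csv"))
  write.csv(report[[nm]], p, row.names = FALSE)
  cat("Wrote", p, "\n")
}

cat("\nGroup-mean contralateral ratios by view:\n")
print(report$group_view_ratios, row.names = FALSE)

gv <- report$group_view_ratios
h_cc <- gv$mean_rho[gv$group == "healthy" & gv$view_type == "CC"]
c_cc <- gv$mean_rho[gv$group == "cancer" & gv$view_type == "CC"]
cat(sprintf(
  "\nRecovered CC means: healthy %.3f, cancer %.3f (clinical: 1.05, 1.15)\n",
  h_cc, c_cc))

tt <- report$tests
cc_test <- tt[tt$test == "t_rho_healthy_vs_cancer_CC", ]
cat(sprintf(
  "Healthy vs cancer CC ratio: t = %.2f, p = %.2g (%s at 0.05)\n",
  cc_test$value, cc_test$p_value,
  if (is.finite(cc_test$p_value) && cc_test$p_value < 0.05)
    "significant" else "not significant"))
mlo_test <- tt[tt$test == "t_rho_healthy_vs_cancer_MLO", ]
cat(sprintf("Healthy vs cancer MLO ratio: t = %.2f, p = %.2g\n",
            mlo_test$value, mlo_test$p_value))
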