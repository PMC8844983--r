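#!/usr/bin/env Rscript
# Step 2: concordance and agreement analysis.
#
# Reads the cohort written by 01_simulate_cohort.R (or any cohort CSV in
# the same dialect, e.g. a transcription of a real study's per-patient
# table), runs ICD-10 rule matching, and reports top-1/top-5 agreement
# with Agresti-Coull intervals plus the per-category performance block
# (accuracy, sensitivity, specificity, AC1).

suppressPackageStartupMessages(library(dxconcord))

if (!file.exists("results/cohort.csv")) {
  stop("run analysis/01_simulate_cohort.R first")
}

cohort <- read_cohort("results/cohort.csv")

usab <- utils::read.csv("results/usability.csv")
sus <- as.matrix(usab[, grep("^sus_", names(usab))])
feedback <- as.matrix(usab[, grep("^fb_", names(usab))])

report <- evaluate_study(cohort, sus = sus, feedback = feedback)
print(report)

report_json(report, "results/report.json")
writeLines(report_markdown(report), "results/report.md")
cat("report written to results/report.json and results/report.md\n")
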