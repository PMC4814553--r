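#!/usr/bin/env Rscript
# Stage 6 — collate the study report.
#
# Gathers the behavior table, explained-variance and R-squared tables,
# the evidence table, and the group tests into one Markdown report.

suppressPackageStartupMessages(library(bistabledcm))

md <- c("# Synthetic bias-training DCM study", "")
section <- function(title, df, digits = 3) {
  c(paste("##", title), "",
    knitr_kable_fallback(df, digits), "")
}
knitr_kable_fallback <- function(df, digits) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  body <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(header, sep, body)
}

beh <- read.table("results/behavior.tsv", header = TRUE, sep = "\t")
md <- c(md, section("Behavior (bias ratios)", beh))
cmp <- cohort_compare(beh$bias_ratio, beh$cohort)
md <- c(md, sprintf("Cohort comparison of bias ratios: Welch t = %.2f, p = %.4g, Cohen's d = %.2f.",
                    cmp$t, cmp$p, cmp$d), "")

ve <- read.table("results/roi/explained_variance.tsv", header = TRUE, sep = "\t")
md <- c(md, section("ROI eigenvariates: percent variance explained", ve))

r2 <- read.table("results/r2_table.tsv", header = TRUE, sep = "\t")
md <- c(md, section("Model-1 fit: average coefficient of determination", r2))

evl <- read.table("results/evidence.tsv", header = TRUE, sep = "\t")
md <- c(md, section("Free energies (nats)", evl))

gt <- read.table("results/group_tests.tsv", header = TRUE, sep = "\t")
md <- c(md, section("Group parameter tests", gt))

hemo <- read.table("results/hemodynamic_tests.tsv", header = TRUE, sep = "\t")
md <- c(md, section("Hemodynamic age comparisons (Welch, uncorrected)", hemo))

writeLines(md, "results/report.md")
cat("wrote results/report.md\n")
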