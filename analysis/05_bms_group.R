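#!/usr/bin/env Rscript
# Stage 5 — Bayesian model selection and group statistics.
#
# Random-effects BMS over the four-model evidence (overall and per
# cohort), per-subject winning models, one-sample tests of the winning
# model's pre-switch modulations and driving inputs per cohort, and the
# eight Welch tests of hemodynamic decay / transit time between cohorts.

suppressPackageStartupMessages(library(bistabledcm))

manifest <- read.table("results/cohort/manifest.tsv", header = TRUE, sep = "\t")
long <- read.table("results/evidence.tsv", header = TRUE, sep = "\t")
Fm <- with(long, tapply(F, list(subject, model), identity))
Fm <- Fm[manifest$subject, , drop = FALSE]
ev <- evidence_table(Fm, subject = manifest$subject, cohort = manifest$cohort)

seeds <- derive_seeds(1112, 3, stream = "bms")
bms_all <- rfx_bms(ev, seed = seeds[1])
cat("exceedance probabilities (all subjects):\n")
print(round(bms_all$exceedance, 4))
for (ch in c("young", "older")) {
  sel <- manifest$cohort == ch
  b <- rfx_bms(evidence_table(Fm[sel, , drop = FALSE],
                              subject = manifest$subject[sel]),
               seed = seeds[2])
  cat(sprintf("%s cohort exceedance: %s\n", ch,
              paste(round(b$exceedance, 4), collapse = " ")))
}
cat("per-subject winning models (all):", subject_winning_counts(bms_all), "\n")
ffx <- ffx_bms(ev)
cat("fixed-effects posterior:", round(ffx$posterior, 4), "\n")

spec1 <- build_model_space()$model1
posts <- lapply(manifest$subject, function(id)
  read_posterior(sprintf("results/posteriors/%s_model1.json", id), spec1))
names(posts) <- manifest$subject

addresses <- c(
  "B[preswitch_block3][LIN<-MTG]",
  "C[LIN,amb_block1]", "C[PRE,amb_block1]",
  "C[LIN,amb_block3]", "C[IOF,amb_block3]"
)
rows <- list()
for (a in addresses) for (ch in c("young", "older")) {
  g <- group_parameter_test(posts, a, cohort = ch, cohorts = manifest$cohort)
  rows[[paste(a, ch)]] <- data.frame(parameter = a, cohort = ch, n = g$n,
                                     mean = g$mean, t = g$t, p = g$p, d = g$d)
}
gt <- do.call(rbind, rows)
write.table(gt, "results/group_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\ngroup parameter tests (one-sample t against zero):\n")
print(gt, row.names = FALSE, digits = 3)

hemo <- hemodynamic_group_compare(posts, manifest$cohort)
write.table(hemo, "results/hemodynamic_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\nhemodynamic decay/transit-time age effects: min uncorrected p = %.3f over %d tests\n",
            min(hemo$p), nrow(hemo)))

r2 <- t(vapply(posts, `[[`, numeric(4), "R2"))
r2_tab <- rbind(young = colMeans(r2[manifest$cohort == "young", , drop = FALSE]),
                older = colMeans(r2[manifest$cohort == "older", , drop = FALSE]),
                overall = colMeans(r2))
write.table(data.frame(group = rownames(r2_tab), round(r2_tab, 3)),
            "results/r2_table.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat("\naverage coefficient of determination (model 1):\n")
print(round(r2_tab, 3))
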