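#!/usr/bin/env Rscript
# Stage 4 — invert the four-model space on every subject.
#
# Rebuilds each subject's stimulus functions from the events, runs
# variational Laplace for models 1-4 on the region series, and writes one
# posterior JSON per subject x model plus the group evidence table.
# This is the slow stage (about 48 gradient-based inversions).

suppressPackageStartupMessages(library(bistabledcm))

manifest <- read.table("results/cohort/manifest.tsv", header = TRUE, sep = "\t")
space <- build_model_space()
dir.create("results/posteriors", showWarnings = FALSE, recursive = TRUE)

Fm <- matrix(NA_real_, nrow(manifest), 4,
             dimnames = list(manifest$subject, names(space)))
for (i in seq_len(nrow(manifest))) {
  id <- manifest$subject[i]
  ev <- read_events(file.path("results/cohort", id, "events.tsv"))
  ts <- read_timeseries(file.path("results/cohort", id, "bold_regions.tsv"))
  inputs <- build_stimulus_functions(ev, microtime_step = ts$TR / 16,
                                     duration = session_duration())
  for (m in names(space)) {
    post <- variational_laplace(space[[m]], ts, inputs)
    write_posterior(post, file.path("results/posteriors",
                                    sprintf("%s_%s.json", id, m)))
    Fm[id, m] <- post$F
    cat(sprintf("%s %s: F = %.2f, mean R2 = %.2f, %d iterations%s\n",
                id, m, post$F, mean(post$R2), post$iterations,
                if (post$converged) "" else " (not converged)"))
  }
}
ev_tab <- evidence_table(Fm, subject = manifest$subject,
                         cohort = manifest$cohort)
write_evidence(ev_tab, "results/evidence.tsv")
cat("wrote results/evidence.tsv\n")
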