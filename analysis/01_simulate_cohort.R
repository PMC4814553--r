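#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic cohort.
#
# Generates a bias-training cohort (6 young + 6 older at desk scale; the
# full design is 14 + 16) under the model-1 ground truth: per-subject
# percept press streams for the two ambiguous blocks, the full session
# event table, and 4-region BOLD at TR = 2 s. Everything derives from one
# master seed; rerunning reproduces every file byte-identically.

suppressPackageStartupMessages(library(bistabledcm))

out <- "results/cohort"
config <- cohort_config(n_young = 6, n_older = 6, seed = 1112)
cohort <- suppressWarnings(generate_cohort(config))

dir.create(out, recursive = TRUE, showWarnings = FALSE)
manifest <- do.call(rbind, lapply(cohort$subjects, function(s) {
  sd <- file.path(out, s$id)
  dir.create(sd, showWarnings = FALSE)
  write_events(s$events, file.path(sd, "events.tsv"))
  write_timeseries(s$bold, file.path(sd, "bold_regions.tsv"))
  data.frame(subject = s$id, cohort = s$cohort, seed = s$seed,
             n_press_b1 = sum(s$events$condition == "press_block1"),
             n_press_b3 = sum(s$events$condition == "press_block3"))
}))
write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("wrote %d subjects (%d young, %d older) to %s\n",
            nrow(manifest), config$n_young, config$n_older, out))
cat(sprintf("session: %d s, %d BOLD samples per region at TR = %g s\n",
            session_duration(), floor(session_duration() / config$TR), config$TR))
print(manifest, row.names = FALSE)
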