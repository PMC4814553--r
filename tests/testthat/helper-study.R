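# The model/parameter-recovery study (12 synthetic subjects, 4 models)
# is shared by several acceptance checks; compute it once per test run.
study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (is.null(study_cache$study)) {
    study_cache$study <- suppressWarnings(
      run_recovery_study(n_young = 6, n_older = 6, seed = 101)
    )
  }
  study_cache$study
}
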