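#' Pipeline configuration
#'
#' Schema-validated configuration binding the pipeline stages. Unknown
#' keys are rejected; every stochastic stage traces back to the master
#' seed.
#'
#' @param cohort a [cohort_config()] (or a list of overrides for one).
#' @param models integer indices into the four-model space to invert.
#' @param use_voxels run the ROI voxel + eigenvariate extraction stage
#'   (otherwise the region series enter inversion directly).
#' @param inversion list of [variational_laplace()] options.
#' @param bms list: `alpha0`, `n_draws`.
#' @param out_dir where `run_pipeline()` writes its artifacts.
#' @param ... reserved; unknown keys are an error.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), models = 1:4,
                            use_voxels = FALSE,
                            inversion = list(), bms = list(alpha0 = 1, n_draws = 1e6),
                            out_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    stop_dim(paste("unknown configuration keys:", paste(names(extra), collapse = ", ")))
  if (is.list(cohort) && !inherits(cohort, "cohort_config"))
    cohort <- do.call(cohort_config, cohort)
  stopifnot(all(models %in% 1:4))
  structure(list(cohort = cohort, models = sort(unique(models)),
                 use_voxels = isTRUE(use_voxels), inversion = inversion,
                 bms = utils::modifyList(list(alpha0 = 1, n_draws = 1e6), bms),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level keys matching the arguments of
#'   [pipeline_config()].
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulate the cohort, compute behavioral summaries and the cohort
#' bias-ratio comparison, (optionally) extract adjusted ROI
#' eigenvariates, invert the selected models per subject, run
#' random-effects model selection overall and per cohort, and test the
#' headline group parameters. Deterministic: identical configurations
#' give byte-identical summaries.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with `behavior`, `evidence`,
#'   `bms`, `group_tests`, `r2_table`, per-subject posteriors, and a
#'   `summary` list (what [pipeline_summary_json()] serializes). When
#'   `config$out_dir` is set, artifacts (events, series, evidence,
#'   summary JSON) are also written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cc <- config$cohort
  cohort <- generate_cohort(cc, voxels = config$use_voxels)
  subjects <- cohort$subjects
  cohorts <- vapply(subjects, `[[`, "", "cohort")

  # --- behavior ----------------------------------------------------------
  ratios <- vapply(subjects, function(s)
    bias_ratio(s$records$block1, s$records$block3), numeric(1))
  included <- filter_subjects(lapply(subjects, `[[`, "records"))
  cmp <- cohort_compare(ratios, cohorts)
  behavior <- list(bias_ratio = ratios, cohorts = cohorts, included = included,
                   compare = cmp)

  # --- series entering inversion ----------------------------------------
  series_for <- function(s) {
    if (!config$use_voxels) return(s$bold)
    X <- build_design_matrix(s$events, T_scans = nrow(s$bold$Y), TR = s$bold$TR)
    Y <- vapply(dcm_regions(), function(rg) {
      vfit <- fit_glm(s$voxels[[rg]]$Y, X)
      roi_eigenvariate(s$voxels[[rg]], vfit)$series
    }, numeric(nrow(s$bold$Y)))
    region_timeseries(Y, s$bold$TR, dcm_regions())
  }

  # --- inversion ---------------------------------------------------------
  space <- build_model_space()[config$models]
  posteriors <- lapply(subjects, function(s) {
    dat <- series_for(s)
    lapply(space, function(spec)
      variational_laplace(spec, dat, s$inputs, options = config$inversion))
  })
  Fm <- t(vapply(posteriors, function(ps) vapply(ps, `[[`, 0, "F"),
                 numeric(length(space))))
  colnames(Fm) <- names(space)
  ev <- evidence_table(Fm, subject = names(subjects), cohort = cohorts)

  # --- model selection ---------------------------------------------------
  seeds <- derive_seeds(cc$seed, 3, stream = "bms")
  bms_all <- rfx_bms(ev, alpha0 = config$bms$alpha0, seed = seeds[1],
                     n_draws = config$bms$n_draws)
  sub_bms <- function(which, seed) {
    sel <- cohorts == which
    rfx_bms(evidence_table(Fm[sel, , drop = FALSE],
                           subject = names(subjects)[sel],
                           cohort = cohorts[sel]),
            alpha0 = config$bms$alpha0, seed = seed, n_draws = config$bms$n_draws)
  }
  bms_young <- if (sum(cohorts == "young") >= 1) sub_bms("young", seeds[2]) else NULL
  bms_older <- if (sum(cohorts == "older") >= 1) sub_bms("older", seeds[3]) else NULL

  # --- group statistics on the first selected model ----------------------
  lead <- names(space)[1]
  lead_post <- lapply(posteriors, `[[`, lead)
  group_tests <- list()
  if (lead == "model1") {
    addr <- c(mtg_lin_block3 = "B[preswitch_block3][LIN<-MTG]",
              c_lin_block1 = "C[LIN,amb_block1]",
              c_pre_block1 = "C[PRE,amb_block1]",
              c_lin_block3 = "C[LIN,amb_block3]")
    for (nm in names(addr)) for (ch in unique(cohorts)) {
      group_tests[[paste(nm, ch, sep = "_")]] <-
        group_parameter_test(lead_post, addr[[nm]], cohort = ch, cohorts = cohorts)
    }
  }
  hemo <- hemodynamic_group_compare(lead_post, cohorts)

  r2 <- t(vapply(lead_post, `[[`, numeric(4), "R2"))
  r2_table <- rbind(young = colMeans(r2[cohorts == "young", , drop = FALSE]),
                    older = colMeans(r2[cohorts == "older", , drop = FALSE]),
                    overall = colMeans(r2))

  summary <- list(
    n_young = cc$n_young, n_older = cc$n_older, seed = cc$seed,
    models = names(space),
    included_subjects = length(included),
    mean_bias_young = mean(ratios[cohorts == "young"]),
    mean_bias_older = mean(ratios[cohorts == "older"]),
    bias_p = cmp$p, bias_d = cmp$d,
    exceedance_all = as.list(bms_all$exceedance),
    exceedance_young = if (!is.null(bms_young)) as.list(bms_young$exceedance),
    exceedance_older = if (!is.null(bms_older)) as.list(bms_older$exceedance),
    winning_counts = as.list(subject_winning_counts(bms_all)),
    r2 = apply(r2_table, 1, as.list),
    group_tests = lapply(group_tests, function(g)
      list(t = g$t, p = g$p, mean = g$mean, d = g$d, n = g$n)),
    hemodynamic_p = setNames(as.list(hemo$p), paste(hemo$parameter, hemo$region, sep = "_"))
  )

  res <- structure(list(behavior = behavior, evidence = ev,
                        bms = list(all = bms_all, young = bms_young, older = bms_older),
                        posteriors = posteriors, group_tests = group_tests,
                        hemodynamics = hemo, r2_table = r2_table,
                        summary = summary, config = config),
                   class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_artifacts(res, cohort, config$out_dir)
  res
}

#' Serialize the pipeline summary to canonical JSON
#'
#' @param result a [run_pipeline()] result.
#' @return a JSON string (byte-identical for identical configurations).
#' @export
pipeline_summary_json <- function(result) {
  jsonlite::toJSON(result$summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_pipeline_artifacts <- function(res, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    sd <- file.path(out_dir, s$id)
    dir.create(sd, showWarnings = FALSE)
    write_events(s$events, file.path(sd, "events.tsv"))
    write_timeseries(s$bold, file.path(sd, "bold_regions.tsv"))
  }
  write_evidence(res$evidence, file.path(out_dir, "evidence.tsv"))
  writeLines(pipeline_summary_json(res), file.path(out_dir, "summary.json"))
  invisible(out_dir)
}
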