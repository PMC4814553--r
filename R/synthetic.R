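#' Configuration of a synthetic cohort study
#'
#' Defines the study conditions the generator emulates: two cohorts (14
#' young, 16 older by default), lognormal percept holding times whose
#' post-training face medians are scaled by a cohort bias-ratio target
#' (young susceptible to the face-bias training, older resistant), and a
#' model-1 ground-truth DCM per cohort. In the young truth the
#' pre-switch modulations are zero and the training effect appears only
#' in the driving inputs (negative drive to LIN and PRE before training,
#' to LIN only after); in the older truth a positive top-down
#' MTG-to-LIN modulation of the post-training pre-switch input appears,
#' plus negative post-training drive to LIN and IOF.
#'
#' Default noise levels: neuronal innovations of scale 0.01 Hz per
#' sqrt(s) — endogenous fluctuations present but an order of magnitude
#' below the evoked drive, the regime in which the deterministic
#' variational-Laplace inversion (which absorbs them into its AR(1)+white
#' noise model) remains a faithful estimator — and BOLD observation noise
#' of 0.25 percent signal change (about a fifth of the typical
#' evoked-response standard deviation under the default truth, a moderate
#' single-subject ROI signal-to-noise).
#'
#' @param n_young,n_older cohort sizes (defaults 14 and 16).
#' @param face_median_ms,vase_median_ms pre-training lognormal medians.
#' @param sigma_log lognormal log-scale sd of holding times.
#' @param bias_young,bias_older cohort bias-ratio targets applied to the
#'   post-training face median (young > 1, older < 1).
#' @param first_press_median_ms,first_press_sigma latency of the initial
#'   percept report.
#' @param innovation_sd,obs_noise_sd noise scales handed to the
#'   ground-truth simulation.
#' @param preswitch_b1_sd,preswitch_b3_sd between-subject sd of the
#'   heterogeneous pre-switch modulations (bottom-up block-1 and top-down
#'   block-3); both have zero group mean except the older cohort's
#'   MTG-to-LIN block-3 entry, which is centered at +0.4 Hz.
#' @param TR,microtime_bins sampling grid.
#' @param n_voxels,voxel_noise_sd ROI voxel-block generation settings.
#' @param seed master seed; all per-subject seeds derive from it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_young = 14, n_older = 16,
                          face_median_ms = 4000, vase_median_ms = 4000,
                          sigma_log = 0.5,
                          bias_young = 1.6, bias_older = 0.92,
                          first_press_median_ms = 1000, first_press_sigma = 0.3,
                          innovation_sd = 0.01, obs_noise_sd = 0.25,
                          preswitch_b1_sd = 0.3, preswitch_b3_sd = 0.2,
                          TR = 2, microtime_bins = 16L,
                          n_voxels = 12, voxel_noise_sd = 0.15,
                          seed = 1112) {
  stopifnot(n_young >= 2, n_older >= 2, face_median_ms > 0, vase_median_ms > 0,
            bias_young > 0, bias_older > 0)
  structure(list(n_young = n_young, n_older = n_older,
                 face_median_ms = face_median_ms, vase_median_ms = vase_median_ms,
                 sigma_log = sigma_log, bias_young = bias_young,
                 bias_older = bias_older,
                 first_press_median_ms = first_press_median_ms,
                 first_press_sigma = first_press_sigma,
                 innovation_sd = innovation_sd, obs_noise_sd = obs_noise_sd,
                 preswitch_b1_sd = preswitch_b1_sd,
                 preswitch_b3_sd = preswitch_b3_sd,
                 TR = TR, microtime_bins = microtime_bins,
                 n_voxels = n_voxels, voxel_noise_sd = voxel_noise_sd,
                 seed = seed),
            class = "cohort_config")
}

#' Ground-truth DCM parameters per cohort
#'
#' Model-1 structure. The shared intrinsic matrix has excitatory
#' bottom-up and mildly inhibitory top-down couplings around -0.5 Hz
#' self-decay. Effect sizes: the older cohort's top-down
#' B(preswitch_block3)[LIN<-MTG] is +0.4 Hz; negative driving entries
#' are -0.025 Hz and unspecified driving entries take a baseline of
#' +0.035 Hz, chosen so that the sustained 60-s stimulation keeps the
#' steady-state inflow of every region well inside the balloon model's
#' physiological domain and the evoked BOLD within a realistic +/- 3
#' percent (block boxcar inputs integrate the drive for 60 s, so
#' per-event rates this small still produce strong responses through the
#' network gain).
#'
#' Every subject carries heterogeneous pre-switch modulations on both
#' inputs — bottom-up block-1 entries from N(0, `preswitch_b1_sd`^2) and
#' top-down block-3 entries from N(0, `preswitch_b3_sd`^2) — reflecting
#' that the winning model's modulations exist in every subject while only
#' the older cohort's MTG-to-LIN block-3 entry has a consistent group
#' direction (mean +0.4 Hz). Group tests therefore measure cross-subject
#' consistency, not per-subject existence.
#'
#' @param cohort `"young"` or `"older"`.
#' @param config a [cohort_config()] (noise scales, modulation
#'   heterogeneity).
#' @param spec the model-1 [dcm_spec()] (default from
#'   [build_model_space()]).
#' @param subject_seed optional integer; when given, the subject's
#'   heterogeneous pre-switch modulations are drawn reproducibly (when
#'   `NULL` they are zero and only the group-mean effects remain).
#' @return a [dcm_params()].
#' @export
ground_truth_params <- function(cohort = c("young", "older"),
                                config = cohort_config(),
                                spec = build_model_space()$model1,
                                subject_seed = NULL) {
  cohort <- match.arg(cohort)
  rg <- dcm_regions()
  A <- matrix(0, 4, 4, dimnames = list(rg, rg))
  diag(A) <- -0.5
  A["PRE", "LIN"] <- 0.18; A["MTG", "LIN"] <- 0.15; A["IOF", "LIN"] <- 0.10
  A["LIN", "PRE"] <- 0.12; A["MTG", "PRE"] <- 0.10; A["IOF", "PRE"] <- 0.15
  A["LIN", "MTG"] <- -0.10; A["PRE", "MTG"] <- -0.05
  A["LIN", "IOF"] <- -0.08; A["PRE", "IOF"] <- -0.12
  C <- matrix(0.035, 4, 2, dimnames = list(rg, dcm_driving_inputs()))
  B <- lapply(spec$B_masks, function(m) matrix(0, 4, 4, dimnames = list(rg, rg)))
  if (cohort == "young") {
    C["LIN", "amb_block1"] <- -0.025
    C["PRE", "amb_block1"] <- -0.025
    C["LIN", "amb_block3"] <- -0.025
    C["PRE", "amb_block3"] <- 0
  } else {
    C["LIN", "amb_block3"] <- -0.025
    C["IOF", "amb_block3"] <- -0.025
    B$preswitch_block3["LIN", "MTG"] <- 0.4
  }
  if (!is.null(subject_seed)) {
    mask1 <- spec$B_masks$preswitch_block1
    mask3 <- spec$B_masks$preswitch_block3
    draws <- withr::with_seed(subject_seed,
      list(b1 = rnorm(sum(mask1), 0, config$preswitch_b1_sd),
           b3 = rnorm(sum(mask3), 0, config$preswitch_b3_sd)))
    B$preswitch_block1[mask1] <- draws$b1
    B$preswitch_block3[mask3] <- B$preswitch_block3[mask3] + draws$b3
  }
  dcm_params(spec, A = A, B = B, C = C,
             innovation_sd = config$innovation_sd,
             obs_noise_sd = config$obs_noise_sd)
}

#' Session skeleton event table
#'
#' Block 1: six 60-s ambiguous trials each followed by 6 s fixation;
#' block 2: sixteen 16-s non-ambiguous trials each followed by 4 s
#' fixation; block 3 as block 1. Total 6x66 + 16x20 + 6x66 = 1112 s.
#'
#' @return an [event_table()] of stimulus and fixation events.
#' @export
generate_session_events <- function() {
  rows <- list()
  t <- 0
  add <- function(onset, duration, condition, trial)
    rows[[length(rows) + 1]] <<- data.frame(onset = onset, duration = duration,
                                            condition = condition, trial_index = trial)
  for (i in 1:6) { add(t, 60, "amb_block1", i); add(t + 60, 6, "fixation", i); t <- t + 66 }
  for (i in 1:16) { add(t, 16, "nonamb_block2", i); add(t + 16, 4, "fixation", i); t <- t + 20 }
  for (i in 1:6) { add(t, 60, "amb_block3", i); add(t + 60, 6, "fixation", i); t <- t + 66 }
  df <- do.call(rbind, rows)
  event_table(df$onset, df$duration, df$condition, trial_index = df$trial_index)
}

# lognormal medians per percept for one cohort and block
percept_medians_ms <- function(config, cohort, block) {
  face <- config$face_median_ms
  if (block == 3)
    face <- face * if (cohort == "young") config$bias_young else config$bias_older
  c(face = face, vase = config$vase_median_ms)
}

#' Generate press streams for one subject and block
#'
#' Per 60-s trial: the initial percept is Bernoulli(0.5) and reported
#' after a short lognormal latency; percepts then alternate with
#' lognormal holding times (cohort- and block-specific face median,
#' shared vase median), truncated at the trial end. Trials failing the
#' three-switch inclusion criterion are regenerated (bounded retries), so
#' generated subjects always pass [filter_subjects()].
#'
#' @param config a [cohort_config()].
#' @param cohort `"young"` or `"older"`.
#' @param block 1 or 3.
#' @param seed integer seed.
#' @param n_trials number of trials (default 6).
#' @return a [percept_record()].
#' @export
generate_press_streams <- function(config, cohort, block, seed, n_trials = 6) {
  med <- percept_medians_ms(config, cohort, block) / 1000
  if (4 * max(med) > 60)
    stop_dim("holding-time median too long to allow three switches in a 60-s trial")
  sdl <- config$sigma_log
  withr::with_seed(seed, {
    trials <- lapply(seq_len(n_trials), function(i) {
      for (try in 1:100) {
        t0 <- rlnorm(1, log(config$first_press_median_ms / 1000),
                     config$first_press_sigma)
        percept <- if (runif(1) < 0.5) "face" else "vase"
        times <- t0; percepts <- percept
        t <- t0
        repeat {
          hold <- rlnorm(1, log(med[[percept]]), sdl)
          t <- t + hold
          if (t >= 60) break
          percept <- if (percept == "face") "vase" else "face"
          times <- c(times, t); percepts <- c(percepts, percept)
        }
        if (length(times) >= 4) # >= 3 switches
          return(data.frame(time = times, percept = percepts,
                            stringsAsFactors = FALSE))
      }
      stop_dim("could not generate a trial passing the switch filter")
    })
    percept_record(trials)
  })
}

# press streams -> press events on the session clock
press_events_from_record <- function(record, block_onsets, condition,
                                     press_duration = 0.1) {
  rows <- lapply(seq_along(record$trials), function(i) {
    tr <- record$trials[[i]]
    if (nrow(tr) == 0) return(NULL)
    data.frame(onset = block_onsets[i] + tr$time, percept = tr$percept,
               trial_index = i, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$onset), ]
  event_table(df$onset, press_duration, condition, percept = df$percept,
              trial_index = df$trial_index)
}

#' Assemble the full event table of one synthetic subject
#'
#' Session skeleton plus percept presses in blocks 1 and 3,
#' fixation-cross detection presses in block 2 (one per trial), and the
#' derived pre-switch / pre-press windows.
#'
#' @param rec1,rec3 [percept_record()]s for blocks 1 and 3.
#' @param seed seed for the block-2 press latencies.
#' @return an [event_table()] for the whole session.
#' @export
generate_subject_events <- function(rec1, rec3, seed) {
  skel <- generate_session_events()
  amb1 <- skel[skel$condition == "amb_block1", ]
  amb3 <- skel[skel$condition == "amb_block3", ]
  non2 <- skel[skel$condition == "nonamb_block2", ]
  p1 <- press_events_from_record(rec1, amb1$onset, "press_block1")
  p3 <- press_events_from_record(rec3, amb3$onset, "press_block3")
  p2 <- withr::with_seed(seed, {
    lat <- runif(nrow(non2), 3, 14)
    event_table(non2$onset + lat, 0.1, "press_block2", percept = "face",
                trial_index = non2$trial_index)
  })
  ps1 <- derive_preswitch_events(p1, amb1)
  ps3 <- derive_preswitch_events(p3, amb3)
  ps2 <- derive_preswitch_events(p2, non2)
  ev <- rbind(skel, p1, p2, p3, ps1, ps2, ps3)
  ev <- ev[order(ev$onset), ]
  class(ev) <- c("event_table", "data.frame")
  validate_events(ev)
  ev
}

#' Simulate one subject's region BOLD from the ground truth
#'
#' Builds the four stimulus functions from the subject's events and runs
#' the stochastic forward model under the cohort's model-1 truth.
#'
#' @param events subject [event_table()].
#' @param truth ground-truth [dcm_params()] (model-1 masks).
#' @param config a [cohort_config()].
#' @param seed integer seed for innovations and observation noise.
#' @return a [region_timeseries()] with attribute `inputs`.
#' @export
generate_subject_bold <- function(events, truth, config, seed) {
  inputs <- build_stimulus_functions(events,
                                     microtime_step = config$TR / config$microtime_bins,
                                     duration = session_duration())
  bold <- simulate_bold(truth, inputs, duration = session_duration(),
                        TR = config$TR, seed = seed,
                        microtime_bins = config$microtime_bins)
  attr(bold, "inputs") <- inputs
  bold
}

#' @rdname generate_session_events
#' @export
session_duration <- function() 6 * 66 + 16 * 20 + 6 * 66

#' Generate a voxel block around one region series
#'
#' Voxel v = loading_v x series + isotropic Gaussian noise, with positive
#' loadings and voxel offsets placed uniformly inside an 8-mm sphere.
#'
#' @param series the latent region series.
#' @param n_voxels number of voxels.
#' @param loading_spread loadings drawn from Uniform(1 - s, 1 + s).
#' @param noise_sd voxel noise sd (same units as the series).
#' @param seed integer seed.
#' @param radius sphere radius (mm).
#' @return a [voxel_block()].
#' @export
generate_roi_voxels <- function(series, n_voxels = 12, loading_spread = 0.4,
                                noise_sd = 0.15, seed = 1L, radius = 8) {
  stopifnot(n_voxels >= 1)
  withr::with_seed(seed, {
    loadings <- runif(n_voxels, 1 - loading_spread, 1 + loading_spread)
    Y <- outer(series, loadings) +
      matrix(rnorm(length(series) * n_voxels, sd = noise_sd),
             length(series), n_voxels)
    off <- matrix(runif(n_voxels * 3, -1, 1), n_voxels, 3)
    bad <- sqrt(rowSums(off^2)) > 1
    while (any(bad)) {
      off[bad, ] <- matrix(runif(sum(bad) * 3, -1, 1), sum(bad), 3)
      bad <- sqrt(rowSums(off^2)) > 1
    }
    voxel_block(Y, offsets = off * radius, radius = radius)
  })
}

#' Generate a complete synthetic subject
#'
#' @param id subject id.
#' @param cohort `"young"` or `"older"`.
#' @param config a [cohort_config()].
#' @param seed subject seed (all stage seeds derive from it).
#' @param voxels also generate per-ROI voxel blocks.
#' @return list of class `synthetic_subject`: events, percept records,
#'   region BOLD, stimulus functions, ground truth, seeds.
#' @export
generate_subject <- function(id, cohort, config, seed, voxels = FALSE) {
  seeds <- derive_seeds(seed, 6, stream = "subject")
  rec1 <- generate_press_streams(config, cohort, 1, seeds[1])
  rec3 <- generate_press_streams(config, cohort, 3, seeds[2])
  events <- generate_subject_events(rec1, rec3, seeds[3])
  truth <- ground_truth_params(cohort, config, subject_seed = seeds[6])
  bold <- generate_subject_bold(events, truth, config, seeds[4])
  vox <- NULL
  if (voxels) {
    vseeds <- derive_seeds(seeds[5], 4, stream = "voxels")
    vox <- lapply(seq_len(4), function(i)
      generate_roi_voxels(bold$Y[, i], n_voxels = config$n_voxels,
                          noise_sd = config$voxel_noise_sd, seed = vseeds[i]))
    names(vox) <- dcm_regions()
  }
  structure(list(id = id, cohort = cohort, events = events,
                 records = list(block1 = rec1, block3 = rec3),
                 bold = bold, inputs = attr(bold, "inputs"),
                 truth = truth, voxels = vox, seed = seed),
            class = "synthetic_subject")
}

#' Generate a full synthetic cohort
#'
#' @param config a [cohort_config()].
#' @param voxels also generate per-ROI voxel blocks per subject.
#' @return list of class `synthetic_cohort` with `subjects` (named list)
#'   and the `config`.
#' @export
generate_cohort <- function(config = cohort_config(), voxels = FALSE) {
  n <- config$n_young + config$n_older
  seeds <- derive_seeds(config$seed, n, stream = "cohort")
  cohorts <- c(rep("young", config$n_young), rep("older", config$n_older))
  ids <- sprintf("sub-%02d", seq_len(n))
  subjects <- lapply(seq_len(n), function(i)
    generate_subject(ids[i], cohorts[i], config, seeds[i], voxels = voxels))
  names(subjects) <- ids
  structure(list(subjects = subjects, config = config), class = "synthetic_cohort")
}
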