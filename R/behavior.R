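#' Percept record for one subject and block
#'
#' @param trials list of trials; each trial a data.frame with columns
#'   `time` (press time, s from trial onset, strictly increasing) and
#'   `percept` (`"face"` or `"vase"`).
#' @param trial_length trial duration (s), default 60.
#' @return object of class `percept_record`.
#' @export
percept_record <- function(trials, trial_length = 60) {
  for (tr in trials) {
    stopifnot(all(c("time", "percept") %in% names(tr)))
    if (nrow(tr) && any(diff(tr$time) <= 0))
      stop_dim("press times must be strictly increasing within a trial")
    if (nrow(tr) && any(tr$time > trial_length))
      stop_dim("press after trial end")
    if (nrow(tr) && any(!tr$percept %in% c("face", "vase")))
      stop_dim("percepts must be face or vase")
  }
  structure(list(trials = trials, trial_length = trial_length),
            class = "percept_record")
}

#' Percept durations within each trial
#'
#' Each reported percept holds from its button press until the next
#' press, or until the trial end for the final percept. The interval
#' before the first press carries no report and is left unassigned, so
#' per trial: sum of face durations + sum of vase durations + unassigned
#' time = trial length.
#'
#' @param record a [percept_record()].
#' @return list with per-trial data.frames (`percept`, `duration` in s)
#'   and the per-trial `unassigned` head interval.
#' @export
percept_durations <- function(record) {
  lapply(record$trials, function(tr) {
    if (nrow(tr) == 0)
      return(list(durations = data.frame(percept = character(0), duration = numeric(0)),
                  unassigned = record$trial_length))
    ends <- c(tr$time[-1], record$trial_length)
    list(durations = data.frame(percept = tr$percept, duration = ends - tr$time,
                                stringsAsFactors = FALSE),
         unassigned = tr$time[1])
  })
}

#' Per-block behavioral summary
#'
#' Pools all percepts across the block's trials (regardless of switch
#' count or initial percept) into mean face and vase durations, and
#' counts switches (presses after the first) per trial.
#'
#' @param record a [percept_record()].
#' @return list with `mean_face_ms`, `mean_vase_ms`, `total_face_s`,
#'   `total_vase_s`, `switches` per trial, `n_face`, `n_vase`.
#' @export
behavior_summary <- function(record) {
  pd <- percept_durations(record)
  all_d <- do.call(rbind, lapply(pd, `[[`, "durations"))
  face <- all_d$duration[all_d$percept == "face"]
  vase <- all_d$duration[all_d$percept == "vase"]
  list(mean_face_ms = mean(face) * 1000, mean_vase_ms = mean(vase) * 1000,
       total_face_s = sum(face), total_vase_s = sum(vase),
       n_face = length(face), n_vase = length(vase),
       switches = vapply(record$trials, function(tr) max(nrow(tr) - 1L, 0L), integer(1)))
}

#' Switch-count inclusion filter
#'
#' A subject is included when every analyzed trial contains at least
#' `min_switches` perceptual switches (presses after the first). Set
#' `per_trial = FALSE` to relax to "at least one such trial".
#'
#' @param records named list of subjects; each subject a list of
#'   [percept_record()]s (one per analyzed block).
#' @param min_switches minimum switches per trial (default 3).
#' @param per_trial require the criterion in every trial (default) or in
#'   at least one.
#' @return character vector of included subject names.
#' @export
filter_subjects <- function(records, min_switches = 3L, per_trial = TRUE) {
  if (length(records) == 0) return(character(0))
  ok <- vapply(records, function(blocks) {
    sw <- unlist(lapply(blocks, function(rec)
      vapply(rec$trials, function(tr) max(nrow(tr) - 1L, 0L), integer(1))))
    if (per_trial) all(sw >= min_switches) else any(sw >= min_switches)
  }, logical(1))
  names(records)[ok]
}

#' Perceptual bias ratio
#'
#' Ratio of the mean duration of the trained ("faces") percept after
#' training (block 3) to before training (block 1); values above 1
#' indicate susceptibility to the experimenter-induced bias.
#'
#' @param block1,block3 [percept_record()]s or [behavior_summary()]s.
#' @return dimensionless ratio.
#' @export
bias_ratio <- function(block1, block3) {
  s1 <- if (inherits(block1, "percept_record")) behavior_summary(block1) else block1
  s3 <- if (inherits(block3, "percept_record")) behavior_summary(block3) else block3
  if (!is.finite(s1$mean_face_ms) || s1$mean_face_ms <= 0)
    stop_dim("block-1 mean face duration must be positive")
  s3$mean_face_ms / s1$mean_face_ms
}

#' Two-cohort comparison of a per-subject statistic
#'
#' Welch two-sample t-test (two-sided) plus Cohen's d with the pooled
#' standard deviation.
#'
#' @param values numeric vector, one value per subject.
#' @param cohorts cohort label per subject (two levels).
#' @return list with `t`, `p`, `d`, cohort means, `n` per cohort, and a
#'   `degenerate` flag when both cohorts have zero variance.
#' @export
cohort_compare <- function(values, cohorts) {
  lv <- unique(cohorts)
  if (length(lv) != 2) stop_dim("exactly two cohorts required")
  a <- values[cohorts == lv[1]]; b <- values[cohorts == lv[2]]
  if (length(a) < 2 || length(b) < 2) stop_dim("each cohort needs at least two subjects")
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
             (length(a) + length(b) - 2))
  if (sp == 0) {
    eq <- mean(a) == mean(b)
    return(list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                p = if (eq) 1 else 0, d = if (eq) 0 else Inf,
                mean_1 = mean(a), mean_2 = mean(b),
                n = c(length(a), length(b)), degenerate = TRUE))
  }
  tt <- t.test(a, b)
  list(t = unname(tt$statistic), p = tt$p.value, d = (mean(a) - mean(b)) / sp,
       mean_1 = mean(a), mean_2 = mean(b),
       n = setNames(c(length(a), length(b)), lv), degenerate = FALSE)
}

#' Association tests on the initial percept
#'
#' Chi-square tests (without continuity correction) of the first-press
#' percept against cohort and against block, as two separate 2x2
#' contingency tests. When any expected cell count falls below 1 the
#' test falls back to Fisher's exact test, flagged in the result.
#'
#' @param initial data.frame with columns `percept`, `cohort`, `block`
#'   (one row per trial).
#' @return list of two tests (`by_cohort`, `by_block`), each with
#'   `statistic`, `p`, `table`, `exact` flag.
#' @export
initial_percept_test <- function(initial) {
  one <- function(fac) {
    tab <- table(initial$percept, fac)
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expd < 1)) {
      ft <- fisher.test(tab)
      list(statistic = NA_real_, p = ft$p.value, table = tab, exact = TRUE)
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      list(statistic = unname(ct$statistic), p = ct$p.value, table = tab, exact = FALSE)
    }
  }
  list(by_cohort = one(initial$cohort), by_block = one(initial$block))
}
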