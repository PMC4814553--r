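#' Event-table conditions
#'
#' The session has three blocks: ambiguous block 1, non-ambiguous
#' "biasing" block 2, and ambiguous block 3. Conditions cover stimulus
#' presentations, button presses, the derived 2-s pre-switch (block 2:
#' pre-press) windows, and fixation.
#' @return character vector of valid condition labels.
#' @export
event_conditions <- function() {
  c("amb_block1", "amb_block3", "nonamb_block2",
    "press_block1", "press_block2", "press_block3",
    "preswitch_block1", "preswitch_block2", "preswitch_block3",
    "fixation")
}

# task regressor order used in the design matrix: ambiguous blocks,
# training block, then presses and pre-switch windows per block
task_conditions <- function() {
  c("amb_block1", "amb_block3", "nonamb_block2",
    "press_block1", "preswitch_block1",
    "press_block3", "preswitch_block3",
    "press_block2", "preswitch_block2")
}

#' Construct and validate an event table
#'
#' @param onset event onsets (s from session start).
#' @param duration event durations (s, > 0).
#' @param condition condition label per event, see [event_conditions()].
#' @param percept for press events, `"face"` or `"vase"`; `NA` otherwise.
#' @param trial_index integer trial number within the block.
#' @return data.frame of class `event_table`.
#' @export
event_table <- function(onset, duration, condition,
                        percept = NA_character_, trial_index = NA_integer_) {
  ev <- data.frame(onset = as.numeric(onset), duration = as.numeric(duration),
                   condition = as.character(condition),
                   percept = rep_len(as.character(percept), length(onset)),
                   trial_index = rep_len(as.integer(trial_index), length(onset)),
                   stringsAsFactors = FALSE)
  class(ev) <- c("event_table", "data.frame")
  validate_events(ev)
}

#' @rdname event_table
#' @param ev an event table to validate.
#' @export
validate_events <- function(ev) {
  if (nrow(ev) == 0) return(invisible(ev))
  bad <- setdiff(unique(ev$condition), event_conditions())
  if (length(bad)) stop_dim(paste("unknown condition(s):", paste(bad, collapse = ", ")))
  if (any(ev$onset < 0)) stop_dim("onsets must be nonnegative")
  if (any(ev$duration <= 0)) stop_dim("durations must be positive")
  is_press <- grepl("^press_", ev$condition)
  if (any(is_press & (is.na(ev$percept) | !ev$percept %in% c("face", "vase"))))
    stop_dim("press events must carry a percept (face or vase)")
  if (any(!is_press & !is.na(ev$percept)))
    stop_dim("percept must be absent on non-press events")
  for (cond in unique(ev$condition)) {
    o <- ev$onset[ev$condition == cond]
    if (is.unsorted(o)) stop_dim(paste("onsets must be nondecreasing within", cond))
  }
  invisible(ev)
}

#' Derive pre-switch events from button presses
#'
#' Each percept-switch button press contributes one modulatory event
#' covering the 2000 ms immediately before the press; presses occurring
#' less than 2 s into their trial yield a window truncated at the trial
#' onset. Press conditions map to the matching pre-switch condition
#' (`press_block1` to `preswitch_block1`, etc.).
#'
#' @param presses event table of press events.
#' @param trial_windows data.frame with columns `onset`, `duration`
#'   giving the stimulus-presentation windows the presses belong to.
#' @param window length of the pre-switch period (s, default 2).
#' @return event table of pre-switch events (empty if no presses).
#' @export
derive_preswitch_events <- function(presses, trial_windows, window = 2.0) {
  if (nrow(presses) == 0)
    return(event_table(numeric(0), numeric(0), character(0)))
  if (!all(grepl("^press_", presses$condition)))
    stop_dim("derive_preswitch_events expects press events only")
  t_press <- presses$onset
  idx <- vapply(t_press, function(t) {
    w <- which(trial_windows$onset <= t &
               t <= trial_windows$onset + trial_windows$duration)
    if (length(w) == 0) NA_integer_ else w[1]
  }, integer(1))
  if (anyNA(idx))
    stop_dim(sprintf("press at t = %.3f s lies outside every trial window",
                     t_press[which(is.na(idx))[1]]))
  start <- pmax(t_press - window, trial_windows$onset[idx])
  event_table(onset = start, duration = t_press - start,
              condition = sub("^press_", "preswitch_", presses$condition),
              trial_index = presses$trial_index)
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak at about 5 s,
#' undershoot around 16 s, peak-to-undershoot ratio 6) sampled on the
#' microtime grid over a 32-s support and scaled to unit sum.
#'
#' @param TR repetition time (s); sets the default microtime step.
#' @param microtime_step grid step (s), default `TR / 16`.
#' @param peak_delay,undershoot_delay gamma shape parameters (s).
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param length_s kernel support (s).
#' @return numeric kernel with attribute `dt`.
#' @export
canonical_hrf <- function(TR = 2, microtime_step = TR / 16,
                          peak_delay = 6, undershoot_delay = 16,
                          ratio = 6, length_s = 32) {
  if (TR <= 0 || microtime_step <= 0) stop_dim("TR and microtime_step must be positive")
  t <- seq(0, length_s, by = microtime_step)
  h <- dgamma(t, shape = peak_delay, rate = 1) -
       dgamma(t, shape = undershoot_delay, rate = 1) / ratio
  h <- h / sum(h)
  attr(h, "dt") <- microtime_step
  h
}

# coverage-fraction boxcar of a set of events on the microtime grid
boxcar_fraction <- function(onset, duration, n_micro, dt) {
  x <- numeric(n_micro)
  for (k in seq_along(onset)) {
    a <- onset[k]; b <- onset[k] + duration[k]
    i0 <- max(0L, floor(a / dt)); i1 <- min(n_micro - 1L, ceiling(b / dt) - 1L)
    if (i1 < i0) next
    i <- i0:i1
    x[i + 1L] <- x[i + 1L] + (pmin(b, (i + 1) * dt) - pmax(a, i * dt)) / dt
  }
  pmin(x, 1)
}

#' Build the first-level design matrix
#'
#' Renders condition boxcars on a microtime grid, convolves them with the
#' canonical HRF, and samples the result at the scan times. Task columns
#' appear in the fixed nine-condition order (ambiguous block 1, ambiguous
#' block 3, non-ambiguous block 2, then presses and pre-switch windows
#' per block), followed by any motion nuisance columns and a constant.
#' A condition without events yields an all-zero column and a warning, so
#' the column count is stable across subjects.
#'
#' @param events validated event table (fixation rows are ignored; they
#'   form the implicit baseline).
#' @param motion optional T x m matrix of motion parameters.
#' @param T_scans number of BOLD samples.
#' @param TR repetition time (s).
#' @param microtime_bins microtime bins per TR (default 16).
#' @return object of class `design_matrix`: list with matrix `X`
#'   (T x K), `labels`, `task_labels`, `TR`.
#' @export
build_design_matrix <- function(events, motion = NULL, T_scans, TR = 2,
                                microtime_bins = 16L) {
  validate_events(events)
  dt <- TR / microtime_bins
  n_micro <- T_scans * microtime_bins
  last <- if (nrow(events)) max(events$onset + events$duration) else 0
  if (T_scans * TR < last - 1e-9)
    stop_dim("T_scans * TR does not cover the last event")
  hrf <- canonical_hrf(TR, dt)
  idx <- (seq_len(T_scans) - 1L) * microtime_bins + 1L
  cols <- lapply(task_conditions(), function(cond) {
    sel <- events$condition == cond
    if (!any(sel)) {
      warning(sprintf("no events for condition '%s'; zero column kept", cond),
              call. = FALSE)
      return(numeric(T_scans))
    }
    bc <- boxcar_fraction(events$onset[sel], events$duration[sel], n_micro, dt)
    conv <- convolve_causal(bc, hrf)
    conv[idx]
  })
  X <- do.call(cbind, cols)
  labels <- task_conditions()
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != T_scans) stop_dim("motion rows must equal T_scans")
    X <- cbind(X, motion)
    labels <- c(labels, colnames(motion) %||% paste0("motion", seq_len(ncol(motion))))
  }
  X <- cbind(X, 1)
  labels <- c(labels, "constant")
  colnames(X) <- labels
  structure(list(X = X, labels = labels, task_labels = task_conditions(),
                 TR = TR, microtime_bins = microtime_bins),
            class = "design_matrix")
}

convolve_causal <- function(x, kernel) {
  n <- length(x)
  as.numeric(stats::convolve(x, rev(kernel), type = "open"))[seq_len(n)]
}

#' Build DCM stimulus functions from events
#'
#' Renders the four unconvolved inputs of the DCM as step functions with
#' values in \{0, 1\} on a shared microtime grid: the two driving inputs
#' (ambiguous-stimulus presentation in blocks 1 and 3, 60-s boxcars) and
#' the two modulatory inputs (2-s pre-switch windows in blocks 1 and 3).
#' Overlapping events within one input are merged with a warning.
#'
#' @param events validated event table containing `amb_block1`,
#'   `amb_block3` and (optionally) `preswitch_block1`, `preswitch_block3`
#'   rows.
#' @param microtime_step grid step (s); must divide the TR used
#'   downstream evenly.
#' @param duration grid length (s); defaults to the end of the last
#'   event, rounded up to the grid.
#' @return object of class `stimulus_functions`: list with matrix `U`
#'   (grid x 4, named), `dt`, `duration`, and the merged `intervals`
#'   per input.
#' @export
build_stimulus_functions <- function(events, microtime_step = 0.125,
                                     duration = NULL) {
  validate_events(events)
  input_names <- c(dcm_driving_inputs(), dcm_modulatory_inputs())
  intervals <- lapply(input_names, function(nm) {
    sel <- events$condition == nm
    merge_intervals(events$onset[sel], events$onset[sel] + events$duration[sel], nm)
  })
  names(intervals) <- input_names
  if (is.null(duration)) {
    ends <- unlist(lapply(intervals, function(iv) iv[, 2]))
    duration <- if (length(ends)) max(ends) else 0
  }
  render_stimulus(intervals, microtime_step, duration)
}

merge_intervals <- function(start, end, label) {
  if (length(start) == 0) return(matrix(numeric(0), 0, 2))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out <- NULL; merged <- FALSE
  for (k in seq_along(start)[-1]) {
    if (start[k] < me - 1e-12) {
      merged <- TRUE
      me <- max(me, end[k])
    } else if (start[k] <= me + 1e-12) {
      me <- max(me, end[k]) # abutting, silent join
    } else {
      out <- rbind(out, c(ms, me)); ms <- start[k]; me <- end[k]
    }
  }
  out <- rbind(out, c(ms, me))
  if (merged)
    warning(sprintf("overlapping events within input '%s' merged", label),
            call. = FALSE)
  out
}

render_stimulus <- function(intervals, dt, duration) {
  n_micro <- as.integer(ceiling(duration / dt - 1e-9))
  grid_start <- (seq_len(n_micro) - 1) * dt
  U <- vapply(intervals, function(iv) {
    u <- numeric(n_micro)
    for (k in seq_len(nrow(iv)))
      u[grid_start >= iv[k, 1] - 1e-12 & grid_start < iv[k, 2] - 1e-12] <- 1
    u
  }, numeric(n_micro))
  structure(list(U = U, dt = dt, duration = n_micro * dt, intervals = intervals),
            class = "stimulus_functions")
}

# re-render stored intervals on a new grid (used when a simulation asks
# for a different microtime step than the one the inputs were built at)
resample_stimulus <- function(inputs, dt) {
  render_stimulus(inputs$intervals, dt, inputs$duration)
}
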