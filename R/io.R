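#' Read and write event tables (BIDS-dialect TSV)
#'
#' Tab-delimited with `.` decimal and `n/a` for missing values; columns
#' `onset`, `duration`, `trial_type`, plus extras `percept` and
#' `trial_index`. Round-trips losslessly.
#'
#' @param path file path.
#' @return [read_events()]: a validated [event_table()].
#' @export
read_events <- function(path) {
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", na.strings = "n/a",
               colClasses = c(onset = "numeric", duration = "numeric",
                              trial_type = "character", percept = "character",
                              trial_index = "integer"),
               stringsAsFactors = FALSE),
    error = function(e) stop("malformed events file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(df)))
    stop_dim(paste("events file must have columns:", paste(need, collapse = ", ")))
  bad <- which(df$duration <= 0 | is.na(df$duration) | is.na(df$onset))
  if (length(bad))
    stop(sprintf("invalid onset/duration in '%s' at data line(s) %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  event_table(df$onset, df$duration, df$trial_type,
              percept = df$percept %||% NA_character_,
              trial_index = df$trial_index %||% NA_integer_)
}

#' @rdname read_events
#' @param ev event table to write.
#' @export
write_events <- function(ev, path) {
  validate_events(ev)
  out <- data.frame(onset = num12(ev$onset), duration = num12(ev$duration),
                    trial_type = ev$condition,
                    percept = ifelse(is.na(ev$percept), "n/a", ev$percept),
                    trial_index = ifelse(is.na(ev$trial_index), "n/a",
                                         as.character(ev$trial_index)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

num12 <- function(x) formatC(x, digits = 12, format = "g")

#' Read and write region time series as TSV
#'
#' Wide layout: a `time` column then one column per region, 12
#' significant digits.
#'
#' @param path file path.
#' @param TR repetition time when reading (inferred from the time column
#'   if `NULL`).
#' @return [read_timeseries()]: a [region_timeseries()].
#' @export
read_timeseries <- function(path, TR = NULL) {
  df <- tryCatch(read.table(path, header = TRUE, sep = "\t"),
                 error = function(e) stop("malformed time-series file '", path,
                                          "': ", conditionMessage(e), call. = FALSE))
  if (!"time" %in% names(df)) stop_dim("time-series file needs a 'time' column")
  if (is.null(TR)) TR <- if (nrow(df) > 1) df$time[2] - df$time[1] else 1
  region_timeseries(as.matrix(df[setdiff(names(df), "time")]), TR)
}

#' @rdname read_timeseries
#' @param ts a [region_timeseries()] to write.
#' @export
write_timeseries <- function(ts, path) {
  df <- data.frame(time = num12(ts$time))
  for (nm in ts$region_names) df[[nm]] <- num12(ts$Y[, nm])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write DCM model specifications as JSON
#'
#' Serializes region names, input names, the 0/1 A/B/C masks and the
#' prior hyperparameters.
#'
#' @param path file path.
#' @return [read_model()]: a [dcm_spec()].
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  priors <- lapply(j$priors, function(x) c(mean = x[["mean"]], var = x[["var"]]))
  B <- lapply(j$B_masks, function(m) matrix(as.logical(m), 4, 4))
  dcm_spec(j$name, B_masks = B, priors = priors)
}

#' @rdname read_model
#' @param spec a [dcm_spec()] to write.
#' @export
write_model <- function(spec, path) {
  j <- list(name = spec$name,
            region_names = spec$region_names,
            input_names = spec$input_names,
            A_mask = unclass(spec$A_mask * 1L),
            B_masks = lapply(spec$B_masks, function(m) unclass(m * 1L)),
            C_mask = unclass(spec$C_mask * 1L),
            priors = lapply(spec$priors, function(x)
              list(mean = unname(x[["mean"]]), var = unname(x[["var"]]))))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Serialize a posterior to JSON
#'
#' Means, covariance, free energy, per-region R-squared and convergence
#' flags, one file per subject and model.
#'
#' @param posterior a [variational_laplace()] result.
#' @param path file path.
#' @export
write_posterior <- function(posterior, path) {
  j <- list(spec_name = posterior$spec_name,
            mean = as.list(posterior$mean),
            cov = unclass(posterior$cov),
            F = posterior$F, lambda = posterior$lambda,
            R2 = as.list(posterior$R2),
            converged = posterior$converged,
            iterations = posterior$iterations)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_posterior
#' @param spec the [dcm_spec()] the posterior was fitted under (used to
#'   rebuild the prior packing and posterior-mean parameters).
#' @export
read_posterior <- function(path, spec) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mean <- unlist(j$mean)
  priors <- pack_priors(spec)
  structure(list(spec_name = j$spec_name, mean = mean,
                 cov = as.matrix(j$cov), F = j$F, lambda = j$lambda,
                 R2 = unlist(j$R2), converged = j$converged,
                 iterations = j$iterations, priors = priors,
                 params = theta_to_params(spec, mean[priors$labels], priors)),
            class = "dcm_posterior")
}

#' Write an evidence table as TSV (subject, cohort, model, F)
#'
#' @param ev an [evidence_table()].
#' @param path file path.
#' @export
write_evidence <- function(ev, path) {
  long <- do.call(rbind, lapply(seq_along(ev$subject), function(i)
    data.frame(subject = ev$subject[i], cohort = ev$cohort[i],
               model = ev$models, F = num12(ev$F[i, ]))))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
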