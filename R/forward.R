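#' Bilinear neuronal drift
#'
#' Rate of change of the neuronal states,
#' `dz/dt = (A + sum_j u_j B_j) z + C u_driving`: intrinsic coupling `A`,
#' input-dependent modulation `B`, direct driving influence `C`. Exactly
#' bilinear in the pair (z, u).
#'
#' @param state list with element `z` (length-n neuronal activity), e.g.
#'   from [rest_state()].
#' @param u named numeric vector of input values, one per input of the
#'   spec (driving then modulatory).
#' @param params a [dcm_params()].
#' @return length-n vector dz/dt (Hz).
#' @export
neuronal_drift <- function(state, u, params) {
  spec <- params$spec
  if (length(u) != length(spec$input_names))
    stop_dim("u must have one value per model input")
  u <- setNames(as.numeric(u), spec$input_names)
  Aeff <- params$A
  for (m in spec$modulatory_inputs) Aeff <- Aeff + u[[m]] * params$B[[m]]
  drop(Aeff %*% state$z + params$C %*% u[spec$driving_inputs])
}

#' Balloon-Windkessel hemodynamic drift
#'
#' Per region: vasodilatory signal `ds/dt = z - kappa s - gamma (f - 1)`,
#' inflow `df/dt = s`, venous volume `tau dv/dt = f - v^(1/alpha)`,
#' deoxyhemoglobin `tau dq/dt = f E(f, rho)/rho - v^(1/alpha) q / v`
#' with oxygen extraction `E(f, rho) = 1 - (1 - rho)^(1/f)`.
#' The rest point (z = 0, s = 0, f = v = q = 1) is an exact fixed point.
#'
#' @param state list with `z`, `s`, `f`, `v`, `q` (see [rest_state()]).
#' @param params a [dcm_params()].
#' @return list of vectors `ds`, `df`, `dv`, `dq`.
#' @export
hemodynamic_drift <- function(state, params) {
  if (any(state$f <= 0) || any(state$v <= 0) || any(state$q <= 0))
    stop_dim("hemodynamic states f, v, q must stay positive")
  ooa <- 1 / params$alpha
  fv <- state$v^ooa
  E <- 1 - (1 - params$rho)^(1 / state$f)
  list(
    ds = state$z - params$kappa * state$s - params$gamma * (state$f - 1),
    df = state$s,
    dv = (state$f - fv) / params$tau,
    dq = (state$f * E / params$rho - fv * state$q / state$v) / params$tau
  )
}

#' Nonlinear BOLD readout
#'
#' `y = 100 V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))` with
#' `k1 = 7 rho`, `k2 = 2`, `k3 = 2 rho - 0.2`, in percent signal change;
#' zero at rest.
#'
#' @inheritParams hemodynamic_drift
#' @return length-n vector of BOLD amplitudes (percent signal change).
#' @export
bold_observation <- function(state, params) {
  k1 <- 7 * params$rho; k2 <- 2; k3 <- 2 * params$rho - 0.2
  100 * params$V0 * (k1 * (1 - state$q) + k2 * (1 - state$q / state$v) + k3 * (1 - state$v))
}

#' Simulate region BOLD series from a DCM
#'
#' Integrates the coupled neuronal and hemodynamic dynamics on a
#' microtime grid of `TR / microtime_bins` using a Heun (explicit
#' trapezoid) step for the drift, with additive Gaussian innovations on
#' the neuronal states at scale `innovation_sd` per sqrt(s) and additive
#' observation noise at scale `obs_noise_sd` on the sampled BOLD.
#' Deterministic simulation is the `innovation_sd = 0` limit of the same
#' scheme. Identical seed and inputs give bit-identical output.
#'
#' @param params a [dcm_params()] (its spec defines masks and inputs).
#' @param inputs a `stimulus_functions` object, see
#'   [build_stimulus_functions()].
#' @param duration total simulated time (s); must cover all input events.
#' @param TR sampling interval of the BOLD series (s).
#' @param seed integer seed for innovations and observation noise;
#'   required when either noise scale is positive.
#' @param microtime_bins integration steps per TR (default 16).
#' @param return_states also return the neuronal trajectory on the
#'   microtime grid (for diagnostics and closed-form checks).
#' @return object of class `region_timeseries`: list with matrix `Y`
#'   (T x n, percent signal change), `TR`, `time`, `region_names`;
#'   if requested, attribute `states` with the microtime trajectories.
#' @export
simulate_bold <- function(params, inputs, duration, TR = 2, seed = NULL,
                          microtime_bins = 16L, return_states = FALSE) {
  validate_dcm_params(params)
  spec <- params$spec
  if (TR <= 0) stop_dim("TR must be positive")
  dt <- TR / microtime_bins
  if (abs(dt - inputs$dt) > 1e-12)
    inputs <- resample_stimulus(inputs, dt)
  n_micro <- as.integer(round(duration / dt))
  if (inputs$duration > duration + 1e-9)
    stop_dim("duration does not cover all input events")
  U <- matrix(0, n_micro, length(spec$input_names),
              dimnames = list(NULL, spec$input_names))
  take <- min(nrow(inputs$U), n_micro)
  for (nm in spec$input_names)
    if (nm %in% colnames(inputs$U)) U[seq_len(take), nm] <- inputs$U[seq_len(take), nm]

  T_out <- as.integer(floor(duration / TR))
  sample_idx <- (seq_len(T_out) - 1L) * as.integer(microtime_bins) + 1L

  noisy <- params$innovation_sd > 0 || params$obs_noise_sd > 0
  if (noisy && is.null(seed)) stop_dim("seed required for stochastic simulation")
  draw <- function() {
    innov <- if (params$innovation_sd > 0)
      matrix(rnorm(n_micro * 4), n_micro, 4) else matrix(0, 0, 0)
    obs <- if (params$obs_noise_sd > 0)
      matrix(rnorm(T_out * 4), T_out, 4) else matrix(0, 0, 0)
    list(innov = innov, obs = obs)
  }
  noise <- if (!noisy) list(innov = matrix(0, 0, 0), obs = matrix(0, 0, 0))
           else withr::with_seed(seed, draw())

  out <- dcm_integrate_cpp(params$A, params$B, params$C,
                           params$kappa, params$gamma, params$tau,
                           params$alpha, params$rho, params$V0,
                           U[, spec$driving_inputs, drop = FALSE],
                           U[, spec$modulatory_inputs, drop = FALSE],
                           dt, sample_idx, noise$innov, params$innovation_sd,
                           return_states)
  if (!out$ok)
    stop(sprintf("simulation diverged at t = %.2f s (states non-finite or f/v/q <= 0); offending parameters: %s",
                 out$t_fail, diverging_summary(params)), call. = FALSE)
  Y <- out$Y
  if (params$obs_noise_sd > 0) Y <- Y + params$obs_noise_sd * noise$obs
  dimnames(Y) <- list(NULL, spec$region_names)
  ts <- region_timeseries(Y, TR)
  if (return_states) attr(ts, "states") <- out$states
  ts
}

diverging_summary <- function(params) {
  sprintf("max|A| = %.3g, max|B| = %.3g, max|C| = %.3g, kappa in [%.3g, %.3g], tau in [%.3g, %.3g]",
          max(abs(params$A)), max(vapply(params$B, function(b) max(abs(b)), 0)),
          max(abs(params$C)), min(params$kappa), max(params$kappa),
          min(params$tau), max(params$tau))
}

#' Container for sampled region BOLD series
#'
#' @param Y T x n numeric matrix, one column per region.
#' @param TR repetition time (s).
#' @param region_names optional column labels.
#' @return object of class `region_timeseries`.
#' @export
region_timeseries <- function(Y, TR, region_names = colnames(Y)) {
  Y <- as.matrix(Y)
  if (is.null(region_names)) region_names <- paste0("R", seq_len(ncol(Y)))
  colnames(Y) <- region_names
  structure(list(Y = Y, TR = TR, time = (seq_len(nrow(Y)) - 1) * TR,
                 region_names = region_names),
            class = "region_timeseries")
}

#' @export
print.region_timeseries <- function(x, ...) {
  cat("<region_timeseries>", nrow(x$Y), "samples x", ncol(x$Y),
      "regions, TR =", x$TR, "s\n")
  invisible(x)
}
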