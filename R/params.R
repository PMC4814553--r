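#' Construct a full set of DCM parameters
#'
#' Holds the numeric connectivity matrices and the per-region
#' balloon-Windkessel hemodynamic parameters. Entries outside the masks
#' of the accompanying [dcm_spec()] must be exactly zero; the diagonal of
#' `A` must be strictly negative so the neuronal dynamics are stable.
#'
#' Hemodynamic defaults (classical values for a canonical BOLD response):
#' signal decay kappa = 0.64 1/s, flow feedback gamma = 0.32 1/s, mean
#' transit time tau = 2 s, vessel stiffness alpha = 0.32, resting oxygen
#' extraction rho = 0.32, resting venous volume fraction V0 = 0.04. The
#' BOLD readout uses k1 = 7 rho, k2 = 2, k3 = 2 rho - 0.2 and reports
#' percent signal change.
#'
#' @param spec a [dcm_spec()].
#' @param A 4x4 intrinsic coupling matrix (Hz).
#' @param B named list of 4x4 modulation matrices (Hz), one per
#'   modulatory input.
#' @param C 4x2 driving-input matrix (Hz per unit input).
#' @param kappa,gamma,tau,alpha,rho,V0 per-region hemodynamic parameters
#'   (scalars are recycled to the 4 regions).
#' @param innovation_sd scale of the stochastic neuronal innovations
#'   (Hz^0.5); 0 gives deterministic dynamics.
#' @param obs_noise_sd additive BOLD observation noise (percent signal
#'   change units).
#' @return object of class `dcm_params`.
#' @export
dcm_params <- function(spec, A = NULL, B = NULL, C = NULL,
                       kappa = 0.64, gamma = 0.32, tau = 2.0,
                       alpha = 0.32, rho = 0.32, V0 = 0.04,
                       innovation_sd = 0, obs_noise_sd = 0) {
  rg <- spec$region_names
  n <- length(rg)
  if (is.null(A)) { A <- matrix(0, n, n); diag(A) <- -0.5 }
  if (is.null(C)) C <- matrix(0, n, length(spec$driving_inputs))
  if (is.null(B)) B <- lapply(spec$B_masks, function(m) matrix(0, n, n))
  dimnames(A) <- list(rg, rg)
  dimnames(C) <- list(rg, spec$driving_inputs)
  names(B) <- spec$modulatory_inputs
  for (m in spec$modulatory_inputs) dimnames(B[[m]]) <- list(rg, rg)

  rec <- function(x) { x <- rep_len(x, n); names(x) <- rg; x }
  p <- structure(list(
    spec = spec, A = A, B = B, C = C,
    kappa = rec(kappa), gamma = rec(gamma), tau = rec(tau),
    alpha = rec(alpha), rho = rec(rho), V0 = rec(V0),
    innovation_sd = innovation_sd, obs_noise_sd = obs_noise_sd
  ), class = "dcm_params")
  validate_dcm_params(p)
  p
}

#' Validate DCM parameters against their specification
#'
#' Checks stability of the self-connections, positivity and range of the
#' hemodynamic parameters, and that every entry outside the spec masks is
#' exactly zero.
#' @param p a [dcm_params()] object.
#' @return `p`, invisibly; stops on violation.
#' @export
validate_dcm_params <- function(p) {
  spec <- p$spec
  if (any(diag(p$A) >= 0)) stop_dim("diagonal of A must be strictly negative")
  if (any(p$A[!spec$A_mask] != 0)) stop_dim("A has nonzero entries outside the intrinsic mask")
  for (m in spec$modulatory_inputs)
    if (any(p$B[[m]][!spec$B_masks[[m]]] != 0))
      stop_dim(sprintf("B[%s] has nonzero entries outside its mask", m))
  if (any(p$C[!spec$C_mask] != 0)) stop_dim("C has nonzero entries outside its mask")
  if (any(c(p$kappa, p$gamma, p$tau, p$V0) <= 0))
    stop_dim("kappa, gamma, tau, V0 must be positive")
  if (any(p$alpha <= 0 | p$alpha >= 1)) stop_dim("alpha must lie in (0,1)")
  if (any(p$rho <= 0 | p$rho >= 1)) stop_dim("rho must lie in (0,1)")
  if (p$innovation_sd < 0 || p$obs_noise_sd < 0) stop_dim("noise scales must be nonnegative")
  invisible(p)
}

#' Resting state of the neuronal-hemodynamic system
#'
#' Neuronal activity and vasodilatory signal zero; inflow, volume and
#' deoxyhemoglobin at their resting values of one.
#' @param n number of regions.
#' @return named list with elements `z`, `s`, `f`, `v`, `q`.
#' @export
rest_state <- function(n = 4) {
  list(z = numeric(n), s = numeric(n), f = rep(1, n), v = rep(1, n), q = rep(1, n))
}
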