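#' Region and input labels for the bistable-perception network
#'
#' The network has four regions: lingual gyrus (LIN), precuneus (PRE),
#' middle temporal gyrus (MTG) and inferior orbitofrontal cortex (IOF).
#' LIN and PRE are the posterior ("early") visual sources, MTG and IOF
#' the anterior ("higher") sources, so bottom-up means LIN/PRE -> MTG/IOF
#' and top-down the reverse. Ambiguous-stimulus onsets in the two
#' ambiguous blocks act as driving inputs; the 2-s pre-switch windows
#' before each percept-switch button press act as modulatory inputs.
#' @name network-labels
#' @keywords internal
NULL

dcm_regions <- function() c("LIN", "PRE", "MTG", "IOF")

dcm_region_mni <- function() {
  m <- rbind(LIN = c(-6, -68, -2), PRE = c(-12, -70, 36),
             MTG = c(50, 30, -6),  IOF = c(62, -22, -6))
  colnames(m) <- c("x", "y", "z")
  m
}

dcm_driving_inputs <- function() c("amb_block1", "amb_block3")
dcm_modulatory_inputs <- function() c("preswitch_block1", "preswitch_block3")

# directed edge masks; convention A[i, j] = influence of region j on region i
edge_mask <- function(targets, sources) {
  rg <- dcm_regions()
  m <- matrix(FALSE, 4, 4, dimnames = list(rg, rg))
  for (s in sources) for (t in targets) m[t, s] <- TRUE
  m
}

bottom_up_mask <- function() edge_mask(targets = c("MTG", "IOF"), sources = c("LIN", "PRE"))
top_down_mask  <- function() edge_mask(targets = c("LIN", "PRE"), sources = c("MTG", "IOF"))

#' Construct a DCM model specification
#'
#' A `dcm_spec` holds the region and input labels, the boolean sparsity
#' masks of the intrinsic (A), modulatory (B) and driving (C) parameter
#' matrices, and the prior moments used by [pack_priors()]. The intrinsic
#' mask is fixed across the model space: self-connections everywhere,
#' reciprocal connections between all region pairs except MTG and IOF.
#'
#' @param name model label.
#' @param B_masks named list (one 4x4 logical matrix per modulatory
#'   input) of allowed pre-switch modulations.
#' @param priors optional list overriding prior hyperparameters, see
#'   [dcm_prior_defaults()].
#' @return object of class `dcm_spec`.
#' @export
dcm_spec <- function(name, B_masks, priors = dcm_prior_defaults()) {
  rg <- dcm_regions()
  A <- matrix(TRUE, 4, 4, dimnames = list(rg, rg))
  A["MTG", "IOF"] <- FALSE
  A["IOF", "MTG"] <- FALSE
  Cm <- matrix(TRUE, 4, 2, dimnames = list(rg, dcm_driving_inputs()))
  mods <- dcm_modulatory_inputs()
  stopifnot(is.list(B_masks), identical(sort(names(B_masks)), sort(mods)))
  B_masks <- B_masks[mods]
  for (m in mods) {
    bm <- B_masks[[m]]
    stopifnot(is.logical(bm), identical(dim(bm), c(4L, 4L)))
    if (any(bm & !A)) stop_dim("B mask allows a modulation outside the intrinsic mask")
    if (any(diag(bm))) stop_dim("B mask must be off-diagonal")
    dimnames(bm) <- list(rg, rg)
    B_masks[[m]] <- bm
  }
  structure(list(
    name = name,
    region_names = rg,
    region_mni = dcm_region_mni(),
    input_names = c(dcm_driving_inputs(), mods),
    driving_inputs = dcm_driving_inputs(),
    modulatory_inputs = mods,
    A_mask = A, B_masks = B_masks, C_mask = Cm,
    priors = priors
  ), class = "dcm_spec")
}

#' Prior hyperparameters for the free parameters
#'
#' Variances are on the native scale of each parameter block:
#' off-diagonal intrinsic rates, modulatory and driving rates in Hz;
#' self-connections, signal-decay and transit-time parameters as
#' log-scalings of their nominal values; observation noise as a log
#' precision on the AR(1)-whitened residuals.
#' @return named list of prior means and variances per block.
#' @export
dcm_prior_defaults <- function() {
  list(A_offdiag = c(mean = 0, var = 1 / 16),
       A_self    = c(mean = 0, var = 1 / 16),
       B         = c(mean = 0, var = 1 / 4),
       C         = c(mean = 0, var = 1),
       log_kappa = c(mean = 0, var = 1 / 64),
       log_tau   = c(mean = 0, var = 1 / 64),
       log_prec  = c(mean = 4, var = 1 / 2))
}

#' Build the four-model space of pre-switch modulations
#'
#' All four models share the intrinsic and driving structure; they differ
#' only in which connections the pre-switch events may modulate:
#' \describe{
#'   \item{model 1}{bottom-up modulation before training (block 1),
#'     top-down modulation after training (block 3);}
#'   \item{model 2}{both directions in both blocks;}
#'   \item{model 3}{bottom-up only, in both blocks;}
#'   \item{model 4}{top-down only, in both blocks.}
#' }
#' @param priors prior hyperparameters shared by all models.
#' @return list of four [dcm_spec()] objects named `model1` .. `model4`.
#' @export
build_model_space <- function(priors = dcm_prior_defaults()) {
  bu <- bottom_up_mask(); td <- top_down_mask()
  both <- bu | td
  list(
    model1 = dcm_spec("model1", list(preswitch_block1 = bu,   preswitch_block3 = td),   priors),
    model2 = dcm_spec("model2", list(preswitch_block1 = both, preswitch_block3 = both), priors),
    model3 = dcm_spec("model3", list(preswitch_block1 = bu,   preswitch_block3 = bu),   priors),
    model4 = dcm_spec("model4", list(preswitch_block1 = td,   preswitch_block3 = td),   priors)
  )
}

#' @export
print.dcm_spec <- function(x, ...) {
  cat("<dcm_spec>", x$name, "\n")
  cat("  regions:", paste(x$region_names, collapse = ", "), "\n")
  cat("  A edges:", sum(x$A_mask), " (incl.", sum(diag(x$A_mask)), "self)\n")
  for (m in x$modulatory_inputs)
    cat("  B[", m, "]:", sum(x$B_masks[[m]]), "modulated edges\n")
  cat("  C entries:", sum(x$C_mask), "\n")
  invisible(x)
}
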