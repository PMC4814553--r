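#' Fit a general linear model to one or more series
#'
#' Ordinary least squares via a rank-revealing QR decomposition. A
#' rank-deficient design falls back to the pseudo-inverse solution with a
#' warning.
#'
#' @param Y T x V matrix of series (a vector is treated as one column).
#' @param design a [build_design_matrix()] object, or a plain numeric
#'   matrix (labels taken from its column names).
#' @return object of class `glm_fit`: coefficients (K x V), residuals,
#'   residual variance per series, degrees of freedom, design.
#' @export
fit_glm <- function(Y, design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  labels <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) stop_dim("Y and design row counts differ")
  qrx <- qr(X)
  rk <- qrx$rank
  if (rk < ncol(X)) {
    warning("rank-deficient design; using pseudo-inverse solution", call. = FALSE)
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) %*% Y / sv$d[pos])
  } else {
    beta <- qr.coef(qrx, Y)
  }
  beta[is.na(beta)] <- 0
  fitted <- X %*% beta
  res <- Y - fitted
  dof <- nrow(Y) - rk
  if (dof <= 0) stop_dim("no residual degrees of freedom")
  rownames(beta) <- labels
  structure(list(coefficients = beta, residuals = res, fitted = fitted,
                 sigma2 = colSums(res^2) / dof, dof = dof, rank = rk,
                 X = X, labels = labels, design = design),
            class = "glm_fit")
}

#' F-contrast on a fitted GLM
#'
#' Extra-sum-of-squares F test comparing the full model with the model
#' constrained to satisfy `contrast %*% beta = 0`, per series.
#'
#' @param fit a [fit_glm()] object.
#' @param contrast numeric matrix with one row per constrained
#'   combination and K columns, or a character vector of column labels
#'   (testing those effects jointly).
#' @return list with vectors `F`, `p`, and scalars `df1`, `df2`.
#' @export
f_contrast <- function(fit, contrast) {
  K <- ncol(fit$X)
  if (is.character(contrast)) {
    unknown <- setdiff(contrast, fit$labels)
    if (length(unknown)) stop_dim(paste("unknown labels:", paste(unknown, collapse = ", ")))
    contrast <- diag(K)[match(contrast, fit$labels), , drop = FALSE]
  }
  contrast <- matrix(as.numeric(contrast), ncol = K)
  if (all(contrast == 0)) stop_dim("contrast must be nonzero")
  r <- qr(t(contrast))$rank
  # reduced design: columns of X restricted to the null space of the contrast
  nullsp <- null_space(contrast)
  X0 <- fit$X %*% nullsp
  Y <- fit$fitted + fit$residuals
  rss1 <- colSums(fit$residuals^2)
  rss0 <- if (ncol(X0) == 0) colSums(Y^2) else {
    q0 <- qr(X0)
    colSums(qr.resid(q0, Y)^2)
  }
  Fstat <- pmax(0, (rss0 - rss1) / r) / (rss1 / fit$dof)
  list(F = Fstat, p = pf(Fstat, r, fit$dof, lower.tail = FALSE),
       df1 = r, df2 = fit$dof)
}

null_space <- function(M) {
  sv <- svd(M, nu = 0, nv = ncol(M))
  rk <- sum(sv$d > max(sv$d, 0) * 1e-10)
  if (rk == ncol(M)) matrix(numeric(0), ncol(M), 0)
  else sv$v[, (rk + 1):ncol(M), drop = FALSE]
}

#' Adjust series for effects of interest
#'
#' Removes the fitted contribution of every regressor *not* in `keep`
#' (motion, button presses, the constant, block-2 regressors) by
#' residual-forming projection on those columns, retaining the effects of
#' interest and the residuals. For the DCM extraction the kept effects
#' are the two ambiguous-block and two pre-switch regressors.
#'
#' @param Y T x V matrix of series.
#' @param fit the [fit_glm()] whose design defines the columns.
#' @param keep character vector of regressor labels to retain.
#' @return adjusted T x V matrix, orthogonal to every removed column.
#' @export
adjust_effects_of_interest <- function(Y, fit,
                                       keep = c("amb_block1", "amb_block3",
                                                "preswitch_block1", "preswitch_block3")) {
  unknown <- setdiff(keep, fit$labels)
  if (length(unknown)) stop_dim(paste("unknown labels:", paste(unknown, collapse = ", ")))
  Y <- as.matrix(Y)
  drop_cols <- setdiff(fit$labels, keep)
  if (length(drop_cols) == 0) return(Y)
  X0 <- fit$X[, match(drop_cols, fit$labels), drop = FALSE]
  # residual-forming projection; robust to zero/collinear nuisance columns
  qr.resid(qr(X0), Y)
}

#' Container for the voxel series of one spherical ROI
#'
#' @param Y T x V matrix of voxel series.
#' @param offsets V x 3 matrix of voxel offsets from the sphere center (mm).
#' @param radius sphere radius (mm), default 8.
#' @return object of class `voxel_block`.
#' @export
voxel_block <- function(Y, offsets = NULL, radius = 8) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 1) stop_dim("voxel block needs at least one voxel")
  if (is.null(offsets)) offsets <- matrix(0, ncol(Y), 3)
  offsets <- as.matrix(offsets)
  if (nrow(offsets) != ncol(Y)) stop_dim("one offset row per voxel required")
  if (any(sqrt(rowSums(offsets^2)) > radius + 1e-9))
    stop_dim("voxel offsets must lie within the sphere radius")
  structure(list(Y = Y, offsets = offsets, radius = radius), class = "voxel_block")
}

#' Principal eigenvariate of an ROI
#'
#' First singular component of the (per-voxel mean-centered) T x V voxel
#' matrix, scaled so that with V identical voxels the eigenvariate equals
#' the common series, and signed to correlate positively with the voxel
#' mean. The explained-variance fraction is the first squared singular
#' value over the total.
#'
#' @param block a [voxel_block()] or plain T x V matrix.
#' @param center per-voxel mean centering before the decomposition
#'   (default TRUE).
#' @return list with `series` (length T), `explained` (fraction in
#'   (0, 1]), and `loadings` (length V).
#' @export
principal_eigenvariate <- function(block, center = TRUE) {
  Y <- if (inherits(block, "voxel_block")) block$Y else as.matrix(block)
  if (all(Y == 0)) stop_dim("all-zero voxel block")
  if (center) Y <- sweep(Y, 2, colMeans(Y))
  if (all(abs(Y) < 1e-300)) stop_dim("voxel block has no variance")
  sv <- svd(Y, nu = 1, nv = 1)
  series <- sv$u[, 1] * sv$d[1] / sqrt(ncol(Y))
  m <- rowMeans(Y)
  if (sum(series * m) < 0) series <- -series
  list(series = series,
       explained = sv$d[1]^2 / sum(sv$d^2),
       loadings = drop(sv$v[, 1]) * sign(sum(sv$u[, 1] * m)))
}

#' Extract an adjusted ROI eigenvariate
#'
#' Convenience chain used before model inversion: adjust the voxel series
#' for effects of interest under the subject's GLM, optionally restrict
#' to voxels passing an F-test on the effects of interest, then take the
#' principal eigenvariate.
#'
#' @param block a [voxel_block()].
#' @param fit subject [fit_glm()] on the same time base.
#' @param keep effect-of-interest labels, as in
#'   [adjust_effects_of_interest()].
#' @param p_threshold optional uncorrected p threshold; voxels whose
#'   effects-of-interest F-test exceeds it are dropped (all kept when
#'   `NULL`, the default for synthetic data).
#' @return as [principal_eigenvariate()], plus `n_voxels` used.
#' @export
roi_eigenvariate <- function(block, fit,
                             keep = c("amb_block1", "amb_block3",
                                      "preswitch_block1", "preswitch_block3"),
                             p_threshold = NULL) {
  Y <- block$Y
  if (!is.null(p_threshold)) {
    vox_fit <- fit_glm(Y, fit$design)
    fc <- f_contrast(vox_fit, keep)
    sel <- fc$p < p_threshold
    if (!any(sel)) stop_dim("no voxels pass the inclusion threshold")
    Y <- Y[, sel, drop = FALSE]
  }
  adj <- adjust_effects_of_interest(Y, fit, keep)
  out <- principal_eigenvariate(adj)
  out$n_voxels <- ncol(Y)
  out
}
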