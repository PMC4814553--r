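make_design <- function(T_scans = 80, seed = 3, motion = TRUE) {
  withr::with_seed(seed, {
    ev <- rbind(
      event_table(c(0, 60), 30, "amb_block1"),
      event_table(c(100, 130), 20, "amb_block3"),
      event_table(90, 8, "nonamb_block2"),
      event_table(c(5, 65), 0.1, "press_block1",
                  percept = c("face", "vase")),
      event_table(c(3, 63), 2, "preswitch_block1"),
      event_table(c(105, 133), 0.1, "press_block3",
                  percept = c("face", "vase")),
      event_table(c(103, 131), 2, "preswitch_block3"),
      event_table(92, 0.1, "press_block2", percept = "face"),
      event_table(91, 1, "preswitch_block2")
    )
    m <- if (motion) matrix(cumsum(rnorm(T_scans * 6, 0, 0.1)), T_scans, 6)
    suppressWarnings(build_design_matrix(ev, motion = m, T_scans = T_scans, TR = 2))
  })
}

test_that("GLM coefficients match the normal-equations oracle", {
  X <- make_design()
  withr::with_seed(11, {
    beta_true <- rnorm(ncol(X$X))
    Y <- drop(X$X %*% beta_true) + matrix(rnorm(nrow(X$X) * 3, 0, 0.5), nrow(X$X), 3)
  })
  fit <- fit_glm(Y, X)
  expect_lt(max(abs(fit$coefficients - oracle_glm(Y, X$X))), 1e-8)
  expect_equal(fit$dof, nrow(Y) - qr(X$X)$rank)
  # exact fit of a single design column
  fit2 <- fit_glm(X$X[, "amb_block1"], X)
  expect_equal(unname(fit2$coefficients["amb_block1", 1]), 1, tolerance = 1e-8)
  expect_lt(fit2$sigma2[1], 1e-16)
  # identical row permutation leaves the fit unchanged
  perm <- withr::with_seed(5, sample(nrow(Y)))
  fit3 <- fit_glm(Y[perm, ], X$X[perm, ])
  expect_equal(fit3$coefficients, fit$coefficients, tolerance = 1e-9)
})

test_that("rank-deficient designs fall back to the pseudo-inverse with a warning", {
  X <- cbind(1, 1:10, 2 * (1:10))
  y <- rnorm(10)
  expect_warning(fit <- fit_glm(y, X), "rank-deficient")
  expect_equal(fit$dof, 10 - 2)
})

test_that("F-contrast equals the two-fit extra-sum-of-squares oracle", {
  X <- make_design()
  withr::with_seed(21, {
    Y <- drop(X$X %*% rnorm(ncol(X$X))) + matrix(rnorm(nrow(X$X) * 4), nrow(X$X), 4)
  })
  fit <- fit_glm(Y, X)
  keep <- c("amb_block1", "amb_block3")
  fc <- f_contrast(fit, keep)
  # oracle: explicit fits of the full and reduced models
  drop_idx <- match(keep, fit$labels)
  X0 <- X$X[, -drop_idx, drop = FALSE]
  rss1 <- colSums(qr.resid(qr(X$X), Y)^2)
  rss0 <- colSums(qr.resid(qr(X0), Y)^2)
  Foracle <- ((rss0 - rss1) / 2) / (rss1 / fit$dof)
  expect_lt(max(abs(fc$F - Foracle)), 1e-8)
  expect_equal(fc$df1, 2)
  # zero contrast rejected
  expect_error(f_contrast(fit, matrix(0, 1, ncol(X$X))), "nonzero")
  # noiseless data spanned by other columns -> F exactly 0
  y0 <- X$X[, "preswitch_block1"]
  fit0 <- fit_glm(y0, X)
  fc0 <- f_contrast(fit0, keep)
  expect_lt(fc0$F, 1e-8)
})

test_that("F-contrast type-I error is calibrated at the nominal level", {
  X <- make_design(T_scans = 80, motion = FALSE)
  n_sim <- 500
  withr::with_seed(99, {
    Y <- matrix(rnorm(80 * n_sim), 80, n_sim)
  })
  fit <- fit_glm(Y, X)
  fc <- f_contrast(fit, c("amb_block1", "amb_block3", "preswitch_block1",
                          "preswitch_block3"))
  rate <- mean(fc$p < 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / n_sim)
  expect_between(rate, ci[1], ci[2])
})

test_that("effects-of-interest adjustment removes exactly the nuisance space", {
  X <- make_design()
  withr::with_seed(31, {
    Y <- drop(X$X %*% rnorm(ncol(X$X))) + matrix(rnorm(nrow(X$X) * 3), nrow(X$X), 3)
  })
  fit <- fit_glm(Y, X)
  keep <- c("amb_block1", "amb_block3", "preswitch_block1", "preswitch_block3")
  adj <- adjust_effects_of_interest(Y, fit, keep)
  removed <- setdiff(fit$labels, keep)
  X0 <- X$X[, match(removed, fit$labels)]
  expect_lt(max(abs(t(X0) %*% adj)), 1e-8)
  # keep everything -> unchanged; keep nothing -> residuals
  expect_equal(adjust_effects_of_interest(Y, fit, fit$labels), Y)
  expect_equal(adjust_effects_of_interest(Y, fit, character(0)), fit$residuals,
               tolerance = 1e-9)
  expect_error(adjust_effects_of_interest(Y, fit, "no_such_column"), "unknown")
})

test_that("the principal eigenvariate recovers a rank-1 latent series", {
  withr::with_seed(41, {
    latent <- as.numeric(arima.sim(list(ar = 0.7), 120))
    loadings <- runif(15, 0.5, 1.5)
    Y <- outer(latent, loadings) + matrix(rnorm(120 * 15, 0, 0.3), 120, 15)
  })
  ev <- principal_eigenvariate(Y)
  expect_gte(abs(cor(ev$series, latent)), 0.99)
  expect_between(ev$explained, 0, 1)

  # identical copies: eigenvariate equals the common series, explained = 1
  yc <- latent - mean(latent)
  Yc <- matrix(rep(yc, 5), ncol = 5)
  evc <- principal_eigenvariate(Yc, center = FALSE)
  expect_equal(evc$series, yc, tolerance = 1e-10)
  expect_equal(evc$explained, 1)
  # sign convention follows the voxel mean
  evn <- principal_eigenvariate(-Yc, center = FALSE)
  expect_equal(evn$series, -yc, tolerance = 1e-10)
  expect_error(principal_eigenvariate(matrix(0, 10, 3)), "zero")
})

test_that("explained variance decreases with voxel noise", {
  withr::with_seed(52, latent <- as.numeric(arima.sim(list(ar = 0.8), 150)))
  expl <- vapply(c(0.1, 0.5, 1, 2), function(ns) {
    b <- generate_roi_voxels(latent, n_voxels = 10, noise_sd = ns, seed = 7)
    principal_eigenvariate(b)$explained
  }, numeric(1))
  expect_true(all(diff(expl) < 0))
})

test_that("the adjust-then-eigenvariate chain removes an injected motion artifact", {
  X <- make_design(T_scans = 100, seed = 61)
  T_scans <- 100
  withr::with_seed(62, {
    signal <- X$X[, "amb_block1"] * 2 + X$X[, "preswitch_block1"] * 1.5
    motion_reg <- X$X[, "motion1"]
    loadings <- runif(12, 0.6, 1.4)
    Y <- outer(signal + 3 * motion_reg, loadings) +
      matrix(rnorm(T_scans * 12, 0, 0.3), T_scans, 12)
  })
  fit <- fit_glm(Y, X)
  out <- roi_eigenvariate(voxel_block(Y), fit)
  expect_lt(abs(cor(out$series, motion_reg)), 0.1)
  expect_gt(abs(cor(out$series, adjust_effects_of_interest(signal, fit))), 0.9)
})

test_that("voxel inclusion by effects-of-interest F-test drops unresponsive voxels", {
  X <- make_design(T_scans = 100, seed = 71)
  withr::with_seed(72, {
    signal <- X$X[, "amb_block1"] * 3
    Yresp <- outer(signal, runif(8, 0.8, 1.2)) + matrix(rnorm(800, 0, 0.2), 100, 8)
    Ynull <- matrix(rnorm(400, 0, 0.2), 100, 4)
  })
  blk <- voxel_block(cbind(Yresp, Ynull))
  fit <- fit_glm(cbind(Yresp, Ynull), X)
  out <- roi_eigenvariate(blk, fit, p_threshold = 1e-4)
  expect_equal(out$n_voxels, 8)
})
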