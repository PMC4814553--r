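space <- build_model_space()

test_that("neuronal drift is the bilinear form, checked against a loop oracle", {
  p <- dcm_params(space$model1,
                  C = matrix(c(1, 0, 0, 0, 0, 0, 0, 0), 4, 2))
  # pure driving at rest
  d <- neuronal_drift(rest_state(), c(1, 0, 0, 0), p)
  expect_equal(unname(d), c(1, 0, 0, 0))
  # pure self-decay
  st <- rest_state(); st$z <- c(1, 0, 0, 0)
  p2 <- dcm_params(space$model1)
  expect_equal(unname(neuronal_drift(st, rep(0, 4), p2)), c(-0.5, 0, 0, 0))

  # random masked parameters against elementwise evaluation
  withr::with_seed(7, {
    for (rep in 1:10) {
      spec <- space$model2
      A <- matrix(rnorm(16, 0, 0.3), 4, 4) * spec$A_mask
      diag(A) <- -abs(rnorm(4, 0.5, 0.1))
      B <- lapply(spec$B_masks, function(m) matrix(rnorm(16, 0, 0.2), 4, 4) * m)
      C <- matrix(rnorm(8), 4, 2)
      pr <- dcm_params(spec, A = A, B = B, C = C)
      st <- rest_state(); st$z <- rnorm(4)
      u <- runif(4)
      expect_equal(unname(neuronal_drift(st, u, pr)),
                   oracle_neuronal_drift(A, B, C, st$z, u[3:4], u[1:2]),
                   tolerance = 1e-12)
    }
  })
  expect_error(neuronal_drift(rest_state(), c(1, 0), p), "one value per")
})

test_that("the rest point is an exact fixed point of the hemodynamics", {
  p <- dcm_params(space$model1, kappa = 0.8, tau = 1.5)
  d <- hemodynamic_drift(rest_state(), p)
  expect_equal(max(abs(unlist(d))), 0, tolerance = 1e-12)
  expect_equal(unname(bold_observation(rest_state(), p)), rep(0, 4))
  # positive activity raises the vasodilatory signal only
  st <- rest_state(); st$z <- c(0.5, 0, 0, 0)
  d2 <- hemodynamic_drift(st, p)
  expect_equal(unname(d2$ds), c(0.5, 0, 0, 0))
  expect_equal(unname(d2$df), rep(0, 4))
  expect_error(hemodynamic_drift(within(rest_state(), f[1] <- -0.1), p),
               "positive")
})

test_that("lower deoxyhemoglobin raises the BOLD signal", {
  st <- rest_state(); st$q <- rep(0.9, 4)
  p <- dcm_params(space$model1)
  expect_true(all(bold_observation(st, p) > 0))
})

test_that("impulse-response BOLD matches a fine-step reference integration", {
  skip_if_not_installed("deSolve")
  p <- dcm_params(space$model1, C = matrix(c(1, 0, 0, 0, 0, 0, 0, 0), 4, 2))
  ev <- event_table(0, 1, "amb_block1")
  inp <- build_stimulus_functions(ev, 2 / 2048, duration = 32)
  sim <- simulate_bold(p, inp, duration = 32, TR = 2, microtime_bins = 2048)
  u_drive <- function(t) c(if (t >= 0 && t < 1) 1 else 0, 0)
  u_mod <- function(t) c(0, 0)
  ref <- oracle_integrate_bold(p, u_drive, u_mod, duration = 32, TR = 2,
                               breaks = 1)
  expect_lt(max(abs(sim$Y - ref)), 1e-6)
})

test_that("impulse-response peak latency falls in the physiological window", {
  p <- dcm_params(space$model1, C = matrix(c(1, 0, 0, 0, 0, 0, 0, 0), 4, 2))
  ev <- event_table(0, 1, "amb_block1")
  inp <- build_stimulus_functions(ev, 0.125, duration = 40)
  sim <- simulate_bold(p, inp, duration = 40, TR = 0.5, microtime_bins = 4)
  latency <- sim$time[which.max(sim$Y[, 1])]
  expect_between(latency, 3, 7)
})

test_that("linear-regime neuronal trajectory matches the matrix-exponential closed form", {
  skip_if_not_installed("Matrix")
  spec <- space$model1
  A <- matrix(0, 4, 4); diag(A) <- -0.5
  A[2, 1] <- 0.2; A[1, 2] <- 0.1; A[3, 1] <- 0.15; A[4, 2] <- 0.1
  Cmat <- matrix(c(0.1, 0.05, 0, 0, 0, 0, 0, 0), 4, 2)
  p <- dcm_params(spec, A = A, C = Cmat)
  ev <- event_table(0, 30, "amb_block1")
  inp <- build_stimulus_functions(ev, 2 / 64, duration = 60)
  sim <- simulate_bold(p, inp, duration = 60, TR = 2, microtime_bins = 64,
                       return_states = TRUE)
  z <- attr(sim, "states")
  dt <- 2 / 64
  tgrid <- (seq_len(nrow(z)) - 1) * dt
  closed_form <- function(t) {
    # constant unit input until 30 s, then free decay
    b <- Cmat[, 1]
    if (t <= 30) {
      drop(solve(A) %*% (as.matrix(Matrix::expm(A * t)) - diag(4)) %*% b)
    } else {
      z30 <- closed_form(30)
      drop(as.matrix(Matrix::expm(A * (t - 30))) %*% z30)
    }
  }
  idx <- seq(1, nrow(z), by = 32)
  ref <- t(vapply(tgrid[idx], closed_form, numeric(4)))
  expect_lt(max(abs(z[idx, ] - ref)), 1e-4)
})

test_that("noiseless simulation with no input stays exactly at rest", {
  p <- dcm_params(space$model1, kappa = c(0.5, 0.64, 0.7, 0.6), tau = c(1.5, 2, 2.5, 2))
  ev <- event_table(0, 10, "amb_block1")
  inp <- build_stimulus_functions(ev, 0.125, duration = 20)
  p$C[] <- 0 # masked values allowed to be zero
  y <- simulate_bold(p, inp, duration = 20, TR = 2)
  expect_true(all(y$Y == 0))
})

test_that("stochastic simulation is seed-deterministic", {
  p <- dcm_params(space$model1, C = matrix(0.05, 4, 2),
                  innovation_sd = 0.05, obs_noise_sd = 0.2)
  ev <- event_table(0, 30, "amb_block1")
  inp <- build_stimulus_functions(ev, 0.125, duration = 60)
  y1 <- simulate_bold(p, inp, duration = 60, TR = 2, seed = 11)
  y2 <- simulate_bold(p, inp, duration = 60, TR = 2, seed = 11)
  y3 <- simulate_bold(p, inp, duration = 60, TR = 2, seed = 12)
  expect_identical(y1$Y, y2$Y)
  expect_false(identical(y1$Y, y3$Y))
  expect_error(simulate_bold(p, inp, duration = 60, TR = 2), "seed required")
})

test_that("masked-out parameters never influence the simulation", {
  spec <- space$model1
  priors <- pack_priors(spec)
  theta <- priors$mean
  theta["C[LIN,amb_block1]"] <- 0.4
  theta["B[preswitch_block3][LIN<-MTG]"] <- 0.3
  ev <- rbind(event_table(0, 30, "amb_block1"),
              event_table(c(5, 12), 2, "preswitch_block3"))
  inp <- build_stimulus_functions(ev, 0.125, duration = 60)
  sim <- function(th) simulate_bold(theta_to_params(spec, th, priors), inp,
                                    duration = 60, TR = 2)$Y
  y1 <- sim(theta)
  # perturbing structurally-masked entries leaves output bit-identical
  theta2 <- theta
  theta2["A[MTG<-IOF]"] <- 0.7
  theta2["B[preswitch_block1][LIN<-MTG]"] <- 0.9 # top-down, not in model-1 block-1 mask
  expect_identical(y1, sim(theta2))
  # and constructing parameters with nonzero masked entries is refused
  p <- dcm_params(spec, C = matrix(0.05, 4, 2))
  p$B$preswitch_block1["LIN", "PRE"] <- 0.9
  expect_error(validate_dcm_params(p), "outside its mask")
})

test_that("models 1 and 4 differ only while the block-1 pre-switch input is active", {
  shared_B3 <- matrix(0, 4, 4); shared_B3[1, 3] <- 0.3
  mk <- function(spec) {
    B <- lapply(spec$B_masks, function(m) matrix(0, 4, 4))
    B$preswitch_block3 <- shared_B3 * spec$B_masks$preswitch_block3
    Bm1 <- spec$B_masks$preswitch_block1
    B$preswitch_block1 <- matrix(0.4, 4, 4) * Bm1
    dcm_params(spec, C = matrix(0.05, 4, 2), B = B)
  }
  ev <- rbind(event_table(0, 60, "amb_block1"),
              event_table(70, 60, "amb_block3"),
              event_table(c(10, 30), 2, "preswitch_block1"),
              event_table(c(80, 100), 2, "preswitch_block3"))
  inp <- build_stimulus_functions(ev, 0.125, duration = 140)
  y1 <- simulate_bold(mk(space$model1), inp, duration = 140, TR = 2)
  y4 <- simulate_bold(mk(space$model4), inp, duration = 140, TR = 2)
  # identical until the first block-1 pre-switch window opens at 10 s
  pre <- y1$time < 10
  expect_equal(y1$Y[pre, ], y4$Y[pre, ])
  expect_false(isTRUE(all.equal(y1$Y, y4$Y)))
})

test_that("unstable parameters raise a diagnostic error", {
  A <- matrix(0, 4, 4); diag(A) <- -0.5
  A[2, 1] <- 3; A[1, 2] <- 3 # strongly unstable reciprocal coupling
  p <- dcm_params(space$model1, A = A, C = matrix(2, 4, 2))
  ev <- event_table(0, 60, "amb_block1")
  inp <- build_stimulus_functions(ev, 0.125, duration = 80)
  expect_error(simulate_bold(p, inp, duration = 80, TR = 2), "diverged")
})
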