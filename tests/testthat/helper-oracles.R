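# Independent reference implementations used as oracles. These are kept
# deliberately naive (elementwise loops, generic ODE solver) and separate
# from the package's own code paths.

# bilinear drift via explicit loops
oracle_neuronal_drift <- function(A, Blist, C, z, u_mod, u_drive) {
  n <- length(z)
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      aij <- A[i, j]
      for (m in seq_along(Blist)) aij <- aij + u_mod[m] * Blist[[m]][i, j]
      out[i] <- out[i] + aij * z[j]
    }
    for (d in seq_along(u_drive)) out[i] <- out[i] + C[i, d] * u_drive[d]
  }
  out
}

# full coupled system drift for deSolve, written directly from the model
# equations (plain states, not the package's integration coordinates)
oracle_system_drift <- function(t, x, parms) {
  n <- 4
  z <- x[1:n]; s <- x[n + 1:n]; f <- x[2 * n + 1:n]
  v <- x[3 * n + 1:n]; q <- x[4 * n + 1:n]
  u_drive <- parms$u_drive(t); u_mod <- parms$u_mod(t)
  Aeff <- parms$A
  for (m in seq_along(parms$B)) Aeff <- Aeff + u_mod[m] * parms$B[[m]]
  dz <- Aeff %*% z + parms$C %*% u_drive
  ds <- z - parms$kappa * s - parms$gamma * (f - 1)
  df <- s
  fv <- v^(1 / parms$alpha)
  E <- 1 - (1 - parms$rho)^(1 / f)
  dv <- (f - fv) / parms$tau
  dq <- (f * E / parms$rho - fv * q / v) / parms$tau
  list(c(dz, ds, df, dv, dq))
}

oracle_bold <- function(v, q, rho = 0.32, V0 = 0.04) {
  k1 <- 7 * rho; k2 <- 2; k3 <- 2 * rho - 0.2
  100 * V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}

# integrate the coupled system with deSolve from rest and return BOLD
# sampled at TR; `breaks` lists input discontinuity times so each segment
# is integrated with a smooth right-hand side
oracle_integrate_bold <- function(params, u_drive_fun, u_mod_fun, duration, TR,
                                  breaks = numeric(0)) {
  x0 <- c(rep(0, 8), rep(1, 12))
  parms <- list(A = params$A, B = params$B, C = params$C,
                kappa = params$kappa, gamma = params$gamma, tau = params$tau,
                alpha = params$alpha, rho = params$rho,
                u_drive = u_drive_fun, u_mod = u_mod_fun)
  sample_times <- seq(0, duration, by = TR)
  edges <- sort(unique(c(0, breaks, duration)))
  sol <- NULL
  state <- x0
  for (k in seq_len(length(edges) - 1)) {
    seg <- sort(unique(c(seq(edges[k], edges[k + 1], length.out = 17),
                         sample_times[sample_times >= edges[k] &
                                      sample_times <= edges[k + 1]])))
    # evaluate inputs just inside the segment so the RHS is smooth
    ek <- edges[k + 1] - 1e-9
    parms_k <- parms
    parms_k$u_drive <- local({ek <- ek; function(t) parms$u_drive(min(t, ek))})
    parms_k$u_mod <- local({ek <- ek; function(t) parms$u_mod(min(t, ek))})
    s <- deSolve::ode(state, seg, oracle_system_drift, parms_k,
                      method = "lsoda", rtol = 1e-11, atol = 1e-11)
    state <- as.numeric(s[nrow(s), -1])
    keep <- s[, 1] %in% sample_times
    if (!is.null(sol)) keep <- keep & !(s[, 1] %in% sol[, 1])
    sol <- rbind(sol, s[keep, , drop = FALSE])
  }
  sol <- sol[order(sol[, 1]), , drop = FALSE]
  v <- sol[, 1 + 12 + 1:4, drop = FALSE]
  q <- sol[, 1 + 16 + 1:4, drop = FALSE]
  y <- matrix(0, nrow(sol), 4)
  for (i in 1:4) y[, i] <- oracle_bold(v[, i], q[, i],
                                       rho = params$rho[i], V0 = params$V0[i])
  y[seq_len(floor(duration / TR)), , drop = FALSE]
}

# direct normal-equations GLM oracle
oracle_glm <- function(Y, X) solve(t(X) %*% X) %*% t(X) %*% Y

# short two-trial session used by design/forward tests (cheap)
short_session_events <- function() {
  rbind(
    event_table(c(0, 40), 30, "amb_block1", trial_index = c(1L, 2L)),
    event_table(c(80, 110), 20, "amb_block3", trial_index = c(1L, 2L)),
    event_table(c(10, 21, 45), 0.1, "press_block1",
                percept = c("face", "vase", "face"), trial_index = c(1L, 1L, 2L)),
    event_table(c(86, 95, 115), 0.1, "press_block3",
                percept = c("vase", "face", "vase"), trial_index = c(1L, 1L, 2L))
  )
}

short_session_inputs <- function(dt = 0.125, duration = 140) {
  ev <- short_session_events()
  presses1 <- ev[ev$condition == "press_block1", ]
  presses3 <- ev[ev$condition == "press_block3", ]
  amb1 <- ev[ev$condition == "amb_block1", ]
  amb3 <- ev[ev$condition == "amb_block3", ]
  ev2 <- rbind(ev, derive_preswitch_events(presses1, amb1),
               derive_preswitch_events(presses3, amb3))
  build_stimulus_functions(ev2, dt, duration = duration)
}

# a cheap synthetic subject on the short two-trial session (T = 70)
make_test_subject <- function(cohort = "young", seed = 1) {
  inp <- short_session_inputs(duration = 140)
  cc <- cohort_config(seed = seed)
  truth <- ground_truth_params(cohort, cc, subject_seed = seed)
  y <- simulate_bold(truth, inp, duration = 140, TR = 2, seed = seed)
  list(bold = y, inputs = inp, truth = truth)
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
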