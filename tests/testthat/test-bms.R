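test_that("random-effects BMS is symmetric under identical evidence", {
  F <- matrix(rep(c(-100, -100), each = 8), 8, 2)
  res <- suppressWarnings(rfx_bms(F, seed = 3)) # per-subject ties expected
  expect_equal(unname(res$exceedance), c(0.5, 0.5), tolerance = 0.01)
  expect_equal(unname(res$expected), c(0.5, 0.5), tolerance = 1e-6)
  expect_error(rfx_bms(matrix(0, 4, 1)), "two models")
})

test_that("Dirichlet exceedance matches the Beta closed form and is seed-stable", {
  # alpha = (2, 1): P(Beta(2,1) > 0.5) = 1 - 0.5^2 = 0.75
  xp <- dirichlet_exceedance(c(2, 1), n_draws = 1e6, seed = 11)
  expect_equal(xp[1], 0.75, tolerance = 0.01)
  expect_equal(sum(xp), 1)
  expect_identical(dirichlet_exceedance(c(2, 1), n_draws = 1e5, seed = 4),
                   dirichlet_exceedance(c(2, 1), n_draws = 1e5, seed = 4))
  # a second closed form: alpha = (1, 1) is uniform
  xp2 <- dirichlet_exceedance(c(1, 1), n_draws = 1e6, seed = 5)
  expect_equal(xp2[1], 0.5, tolerance = 0.01)
})

test_that("variational responsibilities agree with a naive fixed-point oracle", {
  F <- matrix(c(-10, -12, -11, -10.5, -9, -14), 3, 2, byrow = TRUE)
  res <- rfx_bms(F, alpha0 = 1, seed = 2)
  # naive oracle: iterate the published update equations directly
  alpha <- c(1, 1)
  for (i in 1:5000) {
    u <- exp(sweep(F, 2, digamma(alpha) - digamma(sum(alpha)), `+`))
    u <- u / rowSums(u)
    alpha <- 1 + colSums(u)
  }
  expect_lt(max(abs(res$responsibilities - u)), 1e-6)
  expect_lt(max(abs(res$alpha - alpha)), 1e-5)
  expect_true(all(res$alpha >= 1))
})

test_that("uninformative evidence yields a uniform Dirichlet and bounded exceedance", {
  F <- matrix(-50, 10, 4)
  res <- suppressWarnings(rfx_bms(F, seed = 9)) # all-way ties expected
  expect_equal(unname(res$alpha), rep(1 + 10 / 4, 4), tolerance = 1e-6)
  mc_err <- 3 * sqrt(0.25 * 0.75 / res$n_draws)
  expect_lte(max(res$exceedance), 1 / 4 + 3 * 0.01 + mc_err)
})

test_that("raising one model's evidence weakly raises its exceedance", {
  withr::with_seed(17, F0 <- matrix(rnorm(8 * 3, -100, 2), 8, 3))
  xps <- vapply(c(0, 1, 2, 4), function(boost) {
    F <- F0; F[, 2] <- F[, 2] + boost
    rfx_bms(F, seed = 21)$exceedance[2]
  }, numeric(1))
  expect_true(all(diff(xps) >= -0.01))
})

test_that("fixed-effects BMS sums evidence and softmaxes", {
  withr::with_seed(23, F <- matrix(rnorm(12, -200, 5), 3, 4))
  res <- ffx_bms(F)
  expect_equal(unname(res$group_logev), colSums(F))
  # high-precision softmax oracle via log-sum-exp
  le <- colSums(F)
  expect_equal(unname(res$posterior), exp(le - max(le)) / sum(exp(le - max(le))),
               tolerance = 1e-12)
  expect_equal(sum(res$posterior), 1)
  # single subject: softmax of that row
  r1 <- ffx_bms(F[1, , drop = FALSE])
  z <- F[1, ] - max(F[1, ])
  expect_equal(unname(r1$posterior), exp(z) / sum(exp(z)), tolerance = 1e-12)
  # shifting one subject's row leaves posteriors unchanged
  F2 <- F; F2[2, ] <- F2[2, ] + 123
  expect_equal(ffx_bms(F2)$posterior, res$posterior, tolerance = 1e-9)
})

test_that("winning counts tally argmax responsibilities with tie-break warnings", {
  F <- rbind(c(0, -5, -5, -5), c(-5, 0, -5, -5), c(0, -5, -5, -5))
  ev <- evidence_table(F, cohort = c("young", "young", "older"))
  res <- suppressWarnings(rfx_bms(ev, seed = 2)) # ties among losing models
  counts <- subject_winning_counts(res)
  expect_equal(sum(counts), 3)
  expect_equal(unname(counts[1]), 2)
  expect_equal(unname(subject_winning_counts(res, cohort = "older")[1]), 1)
  # exact tie breaks to the lowest index with a warning
  expect_warning(res_tie <- rfx_bms(matrix(-10, 2, 2), seed = 3), "tie")
  expect_equal(unname(res_tie$winner), c(1, 1))
})

test_that("group parameter test matches the textbook one-sample t", {
  space <- build_model_space()
  priors <- pack_priors(space$model1)
  fake_post <- function(b) {
    m <- priors$mean
    m["B[preswitch_block3][LIN<-MTG]"] <- b
    structure(list(mean = m, priors = priors, spec_name = "model1"),
              class = "dcm_posterior")
  }
  withr::with_seed(29, vals <- rnorm(12, 0.3, 0.2))
  posts <- lapply(vals, fake_post)
  res <- group_parameter_test(posts, "B[preswitch_block3][LIN<-MTG]")
  t_direct <- mean(vals) / (sd(vals) / sqrt(12))
  expect_equal(res$t, t_direct, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_direct), 11), tolerance = 1e-12)
  expect_equal(res$d, mean(vals) / sd(vals), tolerance = 1e-12)
  # symmetric values -> t = 0, p = 1
  sym <- lapply(c(-0.2, 0.2, -0.1, 0.1), fake_post)
  res_sym <- group_parameter_test(sym, "B[preswitch_block3][LIN<-MTG]")
  expect_equal(res_sym$t, 0)
  expect_equal(res_sym$p, 1)
  # degenerate zero-variance input flagged
  res_deg <- group_parameter_test(lapply(c(0.3, 0.3, 0.3), fake_post),
                                  "B[preswitch_block3][LIN<-MTG]")
  expect_true(res_deg$degenerate)
  expect_equal(res_deg$p, 0)
  # masked address rejected
  expect_error(group_parameter_test(posts, "B[preswitch_block1][LIN<-MTG]"),
               "not free")
  expect_error(group_parameter_test(posts, "nonsense"), "unknown parameter")
})

test_that("hemodynamic group comparison reports 8 Welch tests", {
  space <- build_model_space()
  mk <- function(kappa, tau) structure(
    list(params = list(kappa = setNames(kappa, c("LIN", "PRE", "MTG", "IOF")),
                       tau = setNames(tau, c("LIN", "PRE", "MTG", "IOF")))),
    class = "dcm_posterior")
  withr::with_seed(31, {
    posts <- c(lapply(1:5, function(i) mk(rnorm(4, 0.64, 0.05), rnorm(4, 2, 0.2))),
               lapply(1:5, function(i) mk(rnorm(4, 0.64, 0.05), rnorm(4, 2, 0.2))))
  })
  cohorts <- rep(c("young", "older"), each = 5)
  res <- hemodynamic_group_compare(posts, cohorts)
  expect_equal(nrow(res), 8)
  expect_setequal(unique(res$parameter), c("kappa", "tau"))
  # Welch statistic oracle for one row
  kap_y <- vapply(posts[1:5], function(p) p$params$kappa[["LIN"]], numeric(1))
  kap_o <- vapply(posts[6:10], function(p) p$params$kappa[["LIN"]], numeric(1))
  t_direct <- (mean(kap_y) - mean(kap_o)) / sqrt(var(kap_y) / 5 + var(kap_o) / 5)
  row <- res[res$parameter == "kappa" & res$region == "LIN", ]
  expect_equal(row$t, t_direct, tolerance = 1e-12)
  # identical cohorts -> all p = 1
  res_same <- hemodynamic_group_compare(c(posts[1:5], posts[1:5]),
                                        rep(c("young", "older"), each = 5))
  expect_true(all(res_same$p == 1))
})
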