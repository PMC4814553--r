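#' Assemble an evidence table
#'
#' @param F N x M matrix of free energies (nats), one row per subject,
#'   one column per model.
#' @param subject subject ids (default `s1..sN`).
#' @param cohort cohort label per subject (e.g. `young` / `older`).
#' @param models model ids (default column names of `F`).
#' @return object of class `evidence_table`.
#' @export
evidence_table <- function(F, subject = NULL, cohort = NULL, models = NULL) {
  F <- as.matrix(F)
  if (any(!is.finite(F))) stop_dim("evidence entries must be finite")
  subject <- subject %||% paste0("s", seq_len(nrow(F)))
  cohort <- cohort %||% rep("all", nrow(F))
  models <- models %||% (colnames(F) %||% paste0("model", seq_len(ncol(F))))
  dimnames(F) <- list(subject, models)
  structure(list(F = F, subject = subject, cohort = cohort, models = models),
            class = "evidence_table")
}

#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet scheme over subjects: model frequencies carry a
#' Dirichlet prior with concentration `alpha0` per model; subject
#' responsibilities are `u_nk proportional to exp(F_nk + psi(alpha_k) -
#' psi(sum alpha))` and the concentrations update to `alpha0 + sum_n
#' u_nk`, iterated to convergence. Exceedance probabilities — the
#' posterior probability that each model is the most frequent in the
#' population — are estimated by Monte-Carlo sampling from the Dirichlet
#' posterior.
#'
#' @param evidence an [evidence_table()] (or plain N x M matrix).
#' @param alpha0 prior concentration per model (default 1, uniform).
#' @param seed seed for the exceedance Monte-Carlo draws.
#' @param n_draws Monte-Carlo sample size (default 1e6; tolerance about
#'   0.01 on the exceedance probabilities).
#' @param tol convergence tolerance on `|delta alpha|`.
#' @return object of class `bms_result`: Dirichlet `alpha`, `expected`
#'   model frequencies, `exceedance` probabilities, per-subject
#'   `responsibilities` and `winner`.
#' @export
rfx_bms <- function(evidence, alpha0 = 1, seed = 1L, n_draws = 1e6, tol = 1e-6) {
  ev <- if (inherits(evidence, "evidence_table")) evidence
        else evidence_table(evidence)
  F <- ev$F
  M <- ncol(F)
  if (M < 2) stop_dim("model comparison needs at least two models")
  Fc <- sweep(F, 1, apply(F, 1, max)) # row-shift for numerical stability
  alpha <- rep(alpha0, M)
  for (it in 1:2000) {
    lw <- sweep(Fc, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    u <- exp(sweep(lw, 1, apply(lw, 1, max)))
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  exceedance <- dirichlet_exceedance(alpha, n_draws = n_draws, seed = seed)
  winner <- apply(u, 1, function(x) {
    w <- which(x == max(x))
    if (length(w) > 1) warning("tie in subject model probabilities; lowest index kept",
                               call. = FALSE)
    w[1]
  })
  structure(list(alpha = setNames(alpha, ev$models),
                 expected = setNames(alpha / sum(alpha), ev$models),
                 exceedance = setNames(exceedance, ev$models),
                 responsibilities = u, winner = winner,
                 subject = ev$subject, cohort = ev$cohort, models = ev$models,
                 alpha0 = alpha0, n_draws = n_draws),
            class = "bms_result")
}

#' Dirichlet exceedance probabilities by Monte Carlo
#'
#' @param alpha Dirichlet concentration vector.
#' @param n_draws number of draws.
#' @param seed integer seed.
#' @return probability per component of being the largest frequency.
#' @export
dirichlet_exceedance <- function(alpha, n_draws = 1e6, seed = 1L) {
  M <- length(alpha)
  withr::with_seed(seed, {
    counts <- integer(M)
    block <- 2e5
    done <- 0
    while (done < n_draws) {
      b <- min(block, n_draws - done)
      G <- matrix(rgamma(b * M, shape = rep(alpha, each = b)), b, M)
      mx <- max.col(G, ties.method = "first")
      counts <- counts + tabulate(mx, M)
      done <- done + b
    }
    counts / n_draws
  })
}

#' Fixed-effects Bayesian model selection
#'
#' Group log-evidence per model is the column sum of subject free
#' energies; posterior model probabilities follow by softmax under a
#' uniform model prior.
#'
#' @param evidence an [evidence_table()] or N x M matrix.
#' @return list with `group_logev` and `posterior` per model.
#' @export
ffx_bms <- function(evidence) {
  ev <- if (inherits(evidence, "evidence_table")) evidence
        else evidence_table(evidence)
  le <- colSums(ev$F)
  z <- le - max(le)
  p <- exp(z) / sum(exp(z))
  list(group_logev = setNames(le, ev$models), posterior = setNames(p, ev$models))
}

#' Count winning models per cohort
#'
#' Tallies the argmax of per-subject posterior model probabilities; exact
#' ties break to the lowest model index (with a warning emitted by
#' [rfx_bms()]).
#'
#' @param result a [rfx_bms()] result.
#' @param cohort optional cohort label to filter on.
#' @return named integer vector of counts per model.
#' @export
subject_winning_counts <- function(result, cohort = NULL) {
  sel <- if (is.null(cohort)) rep(TRUE, length(result$winner))
         else result$cohort == cohort
  setNames(tabulate(result$winner[sel], length(result$models)), result$models)
}

#' One-sample test of a DCM parameter across subjects
#'
#' Classical summary-statistic approach: the per-subject posterior means
#' of one addressed parameter (e.g. `B[preswitch_block3][LIN<-MTG]`) are
#' tested against zero with a two-sided one-sample t-test; Cohen's d is
#' mean / sd.
#'
#' @param posteriors list of [variational_laplace()] results.
#' @param parameter label of the parameter in the packed vector (see
#'   [pack_priors()]).
#' @param cohort,cohorts optional filter: `cohorts` gives the label per
#'   posterior, `cohort` the level to keep.
#' @return list with `t`, `p`, `mean`, `sd`, `d`, `n`, `values` and a
#'   `degenerate` flag for zero-variance input.
#' @export
group_parameter_test <- function(posteriors, parameter, cohort = NULL, cohorts = NULL) {
  if (!is.null(cohort)) {
    if (is.null(cohorts)) stop_dim("cohorts labels required to filter by cohort")
    posteriors <- posteriors[cohorts == cohort]
  }
  if (length(posteriors) < 2) stop_dim("need at least two subjects")
  vals <- vapply(posteriors, function(p) {
    if (!parameter %in% names(p$mean)) stop_dim(paste("unknown parameter:", parameter))
    if (!p$priors$free[[parameter]])
      stop_dim(paste("parameter not free in model", p$spec_name, ":", parameter))
    p$mean[[parameter]]
  }, numeric(1))
  n <- length(vals); m <- mean(vals); s <- sd(vals)
  if (s == 0) {
    return(list(t = if (m == 0) 0 else sign(m) * Inf, p = if (m == 0) 1 else 0,
                mean = m, sd = 0, d = if (m == 0) 0 else sign(m) * Inf,
                n = n, values = vals, degenerate = TRUE))
  }
  tt <- t.test(vals, mu = 0)
  list(t = unname(tt$statistic), p = tt$p.value, mean = m, sd = s,
       d = m / s, n = n, values = vals, degenerate = FALSE)
}

#' Age-group comparison of hemodynamic parameters
#'
#' Welch two-sample t-tests on the per-subject posterior means of signal
#' decay (kappa) and transit time (tau), per region: 2 parameters x 4
#' regions = 8 tests, reported with uncorrected p-values.
#'
#' @param posteriors list of [variational_laplace()] results.
#' @param cohorts cohort label per posterior (exactly two levels).
#' @return data.frame with one row per region x parameter.
#' @export
hemodynamic_group_compare <- function(posteriors, cohorts) {
  lv <- unique(cohorts)
  if (length(lv) != 2) stop_dim("exactly two cohorts required")
  if (min(table(cohorts)) < 2) stop_dim("each cohort needs at least two subjects")
  rows <- list()
  for (par in c("kappa", "tau")) for (rg in dcm_regions()) {
    vals <- vapply(posteriors, function(p) p$params[[par]][[rg]], numeric(1))
    a <- vals[cohorts == lv[1]]; b <- vals[cohorts == lv[2]]
    if (sd(a) == 0 && sd(b) == 0) {
      t <- 0; p <- 1
    } else {
      tt <- t.test(a, b)
      t <- unname(tt$statistic); p <- tt$p.value
    }
    rows[[length(rows) + 1]] <- data.frame(
      parameter = par, region = rg,
      mean_1 = mean(a), mean_2 = mean(b), t = t, p = p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "cohorts") <- lv
  out
}
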