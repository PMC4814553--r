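trial <- function(times, percepts) data.frame(time = times, percept = percepts,
                                              stringsAsFactors = FALSE)

test_that("percept durations partition the trial after the first press", {
  rec <- percept_record(list(
    trial(c(0, 20, 50), c("face", "vase", "face")),
    trial(5, "face")
  ))
  pd <- percept_durations(rec)
  expect_equal(pd[[1]]$durations$duration, c(20, 30, 10))
  expect_equal(pd[[1]]$durations$percept, c("face", "vase", "face"))
  expect_equal(pd[[1]]$unassigned, 0)
  expect_equal(pd[[2]]$durations$duration, 55)
  expect_equal(pd[[2]]$unassigned, 5)
  # partition property: durations + unassigned head = 60 exactly
  for (tr in pd)
    expect_equal(sum(tr$durations$duration) + tr$unassigned, 60)
  # validation
  expect_error(percept_record(list(trial(c(10, 5), c("face", "vase")))),
               "strictly increasing")
  expect_error(percept_record(list(trial(65, "face"))), "after trial end")
})

test_that("percepts never merge across trials", {
  rec <- percept_record(list(trial(c(1, 59), c("face", "vase")),
                             trial(c(1, 30), c("vase", "face"))))
  s <- behavior_summary(rec)
  # trial 1 vase runs to 60 only within its own trial
  expect_equal(s$total_vase_s, (60 - 59) + (30 - 1))
  expect_equal(s$n_face, 2)
})

test_that("the switch-count filter includes exactly the compliant subjects", {
  three_switches <- percept_record(list(trial(c(1, 10, 20, 30),
                                              c("face", "vase", "face", "vase"))))
  two_presses <- percept_record(list(trial(c(1, 10), c("face", "vase"))))
  records <- list(
    good = list(three_switches, three_switches),
    bad = list(three_switches, two_presses)
  )
  expect_equal(filter_subjects(records), "good")
  expect_setequal(filter_subjects(records, per_trial = FALSE), c("good", "bad"))
  expect_equal(filter_subjects(list()), character(0))
})

test_that("the bias ratio is the block-3 / block-1 mean face duration", {
  b1 <- list(mean_face_ms = 5000)
  b3 <- list(mean_face_ms = 7500)
  expect_equal(bias_ratio(b1, b3), 1.5)
  expect_equal(bias_ratio(b1, b1), 1.0)
  expect_error(bias_ratio(list(mean_face_ms = 0), b3), "positive")
  # ratio from raw streams equals ratio from precomputed summaries
  rec1 <- percept_record(list(trial(c(0, 10, 30, 45), c("face", "vase", "face", "vase"))))
  rec3 <- percept_record(list(trial(c(0, 15, 45, 50), c("face", "vase", "face", "vase"))))
  expect_equal(bias_ratio(rec1, rec3),
               bias_ratio(behavior_summary(rec1), behavior_summary(rec3)))
  # scale invariance: scaling all durations leaves the ratio unchanged
  scale_rec <- function(rec, c) percept_record(
    lapply(rec$trials, function(tr) trial(tr$time * c, tr$percept)),
    trial_length = rec$trial_length * c)
  expect_equal(bias_ratio(scale_rec(rec1, 0.5), scale_rec(rec3, 0.5)),
               bias_ratio(rec1, rec3))
})

test_that("cohort comparison matches the direct Welch and pooled-d formulas", {
  withr::with_seed(8, {
    a <- rnorm(14, 1, 1); b <- rnorm(16, 0, 1.3)
  })
  res <- cohort_compare(c(a, b), rep(c("young", "older"), c(14, 16)))
  # direct formulas
  se <- sqrt(var(a) / 14 + var(b) / 16)
  t_direct <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / 14)^2 / 13 + (var(b) / 16)^2 / 15)
  expect_equal(res$t, t_direct, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_direct), df), tolerance = 1e-9)
  sp <- sqrt((13 * var(a) + 15 * var(b)) / 28)
  expect_equal(res$d, (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  # identical cohorts -> no effect
  same <- cohort_compare(c(a, a), rep(c("young", "older"), each = 14))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$d, 0)
})

test_that("initial-percept association uses chi-square with exact fallback", {
  # perfectly balanced table -> statistic 0, p = 1
  balanced <- data.frame(
    percept = rep(c("face", "vase"), 40),
    cohort = rep(c("young", "older"), each = 40),
    block = rep(rep(c(1, 3), each = 20), 2)
  )
  res <- initial_percept_test(balanced)
  expect_equal(res$by_cohort$statistic, 0, tolerance = 1e-12)
  expect_equal(res$by_cohort$p, 1, tolerance = 1e-12)
  # statistic matches the direct sum((O-E)^2/E) formula on a random table
  withr::with_seed(13, {
    init <- data.frame(
      percept = sample(c("face", "vase"), 120, TRUE, prob = c(0.6, 0.4)),
      cohort = sample(c("young", "older"), 120, TRUE),
      block = sample(c(1, 3), 120, TRUE)
    )
  })
  res2 <- initial_percept_test(init)
  tab <- table(init$percept, init$cohort)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res2$by_cohort$statistic, sum((tab - expd)^2 / expd),
               tolerance = 1e-12)
  # transposition invariance
  tab_t <- t(tab)
  expd_t <- outer(rowSums(tab_t), colSums(tab_t)) / sum(tab_t)
  expect_equal(sum((tab_t - expd_t)^2 / expd_t), res2$by_cohort$statistic,
               tolerance = 1e-12)
  # tiny counts trigger the exact test
  tiny <- data.frame(percept = c("face", "vase", "face"),
                     cohort = c("young", "older", "older"),
                     block = c(1, 1, 3))
  expect_true(initial_percept_test(tiny)$by_cohort$exact)
})

test_that("generated press streams honor the bias targets and the filter", {
  cc <- cohort_config(seed = 7)
  # same seed reproduces; different seeds differ
  r1 <- generate_press_streams(cc, "young", 1, seed = 5)
  r2 <- generate_press_streams(cc, "young", 1, seed = 5)
  expect_identical(r1, r2)
  r3 <- generate_press_streams(cc, "young", 1, seed = 6)
  expect_false(identical(r1, r3))
  # every generated subject passes the inclusion filter
  recs <- lapply(1:10, function(i) list(
    generate_press_streams(cc, "older", 1, seed = 100 + i),
    generate_press_streams(cc, "older", 3, seed = 200 + i)))
  names(recs) <- paste0("s", 1:10)
  expect_equal(filter_subjects(recs), names(recs))
  # infeasible configuration rejected
  cc_bad <- cohort_config(face_median_ms = 40000, vase_median_ms = 40000)
  expect_error(generate_press_streams(cc_bad, "young", 1, seed = 1),
               "three switches")
})

test_that("large-sample mean bias ratios bracket 1 by cohort", {
  cc <- cohort_config(seed = 15)
  ratio_of <- function(ch, i) {
    b1 <- generate_press_streams(cc, ch, 1, seed = 1000 + i)
    b3 <- generate_press_streams(cc, ch, 3, seed = 5000 + i)
    bias_ratio(b1, b3)
  }
  young <- vapply(1:60, function(i) ratio_of("young", i), numeric(1))
  older <- vapply(1:60, function(i) ratio_of("older", i), numeric(1))
  expect_gt(mean(young), 1)
  expect_lt(mean(older), 1)
  expect_gt(mean(young), mean(older))
})
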