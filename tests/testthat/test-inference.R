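test_that("aggregate pooling concatenates participants and rejects key clashes", {
  per_part <- lapply(1:6, function(p)
    build_design(design_spec(), seed = p, participant = sprintf("P%02d", p)))
  pooled <- pool_aggregate(per_part)
  expect_equal(nrow(pooled), 35640L)
  expect_equal(pool_aggregate(per_part[[1L]]), per_part[[1L]])
  expect_error(pool_aggregate(list(per_part[[1L]], per_part[[1L]])),
               "duplicate")
})

test_that("the congruency effect is negative under the default generator and near the analytic value", {
  tr <- default_pooled()
  eff <- congruency_effect(tr)
  cfg <- generator_config()
  # the pooled incongruent curve mixes previous-trial depths ~half/half, and
  # the law is linear in depth, so the mixture equals the mean-depth law
  analytic_incong <- dense_law_min(cfg, "incongruent", "undefined")$value
  analytic_cong <- 0.5  # monotone law sits at chance at the window edge
  expect_lt(eff, 0)
  expect_lt(abs(eff - (analytic_incong - analytic_cong)), 0.05)
  all_cong <- tr[tr$congruency == "congruent", ]
  expect_error(congruency_effect(all_cong), "incongruent")
})

test_that("the congruency effect vanishes on null-generator data", {
  pooled <- pool_aggregate(lapply(1:10, function(p) {
    d <- build_design(design_spec(blocks_per_session = 38L, sessions = 1L),
                      seed = 200 + p, participant = sprintf("N%02d", p))
    simulate_trials(d, null_generator(), seed = 300 + p)
  }))  # 50,160 trials
  expect_lt(abs(congruency_effect(pooled)), 0.02)
  # with equal dip depths the sequence effect is null by construction
  eqcfg <- generator_config(dip_depth_prev_congruent = 0.2,
                            dip_depth_prev_incongruent = 0.2)
  pooled_eq <- pool_aggregate(lapply(1:10, function(p) {
    d <- build_design(design_spec(blocks_per_session = 38L, sessions = 1L),
                      seed = 400 + p, participant = sprintf("E%02d", p))
    simulate_trials(d, eqcfg, seed = 500 + p)
  }))
  expect_lt(abs(as.numeric(sequence_effect(pooled_eq))), 0.03)
})

test_that("the sequence effect matches the analytic depth difference", {
  pooled <- pool_aggregate(lapply(1:7, function(p) {
    d <- build_design(design_spec(), seed = 600 + p,
                      participant = sprintf("S%02d", p))
    simulate_trials(d, generator_config(), seed = 700 + p)
  }))  # 41,580 trials
  eff <- sequence_effect(pooled)
  expect_gt(attr(eff, "n_undefined_excluded"), 0)
  cfg <- generator_config()
  analytic <- dense_law_min(cfg, "incongruent", "congruent")$value -
    dense_law_min(cfg, "incongruent", "incongruent")$value
  expect_lt(as.numeric(eff), 0)
  expect_lt(abs(as.numeric(eff) - analytic), 0.05)
})

test_that("permutation p-values follow the add-one convention in the edge cases", {
  tr <- null_dataset(901)
  constant_fn <- function(trials) 1
  res <- permutation_test(tr, constant_fn, "congruency",
                          n_permutations = 50, seed = 1)
  expect_equal(res$p_value, 1)
  expect_length(res$null_effects, 50)
  # an observed effect beyond every null effect attains the smallest p
  orig <- tr$congruency
  match_fn <- function(trials) mean(trials$congruency == orig)
  res2 <- permutation_test(tr, match_fn, "congruency",
                           n_permutations = 200, seed = 2)
  expect_equal(res2$p_value, 1 / 201)
  expect_error(permutation_test(tr, constant_fn, "congruency",
                                n_permutations = 0), "n_permutations")
  tr$congruency <- "congruent"
  expect_error(permutation_test(tr, constant_fn, "congruency",
                                n_permutations = 10), "constant")
})

test_that("label shuffling preserves per-participant label counts and is seed-stable", {
  tr <- default_pooled()[seq(1, 23760, by = 8), ]
  counts <- table(tr$participant, tr$congruency)
  seen <- list()
  probe <- function(trials) {
    seen[[length(seen) + 1L]] <<- table(trials$participant, trials$congruency)
    stats::runif(1)  # effect value irrelevant, must just vary
  }
  res <- permutation_test(tr, probe, "congruency", n_permutations = 5,
                          seed = 3)
  for (tab in seen[-1L]) expect_equal(tab, counts)
  res2 <- permutation_test(tr, function(t) mean(t$congruency == "congruent"),
                           "congruency", n_permutations = 20, seed = 9)
  res3 <- permutation_test(tr, function(t) mean(t$congruency == "congruent"),
                           "congruency", n_permutations = 20, seed = 9)
  expect_identical(res2$null_effects, res3$null_effects)
})

test_that("permutation p-values are approximately uniform under the null", {
  p <- null_calibration_pvalues()
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("the congruency test has high power at the default dip size", {
  rejections <- vapply(1:10, function(i) {
    pooled <- pool_aggregate(lapply(1:4, function(p) {
      d <- build_design(design_spec(), seed = 1000 + 10 * i + p,
                        participant = sprintf("P%02d", p))
      simulate_trials(d, generator_config(), seed = 2000 + 10 * i + p)
    }))
    permutation_test(pooled, congruency_effect, "congruency",
                     n_permutations = 1999, seed = 3000 + i)$p_value
  }, numeric(1L))
  expect_gte(mean(rejections <= 0.001), 0.9)
})

test_that("bootstrap standard errors match the binomial closed form", {
  res_const <- bootstrap_se(toy_trials(runif(100, 0, 500)),
                            function(trials) 1, n_replicates = 50, seed = 1)
  expect_equal(res_const$se, 0)
  set.seed(10)
  n <- 2000
  tr <- toy_trials(runif(n, 0, 500), correct = runif(n) < 0.8)
  res <- bootstrap_se(tr, function(trials) mean(trials$correct),
                      n_replicates = 500, seed = 2, strata_field = NULL)
  closed_form <- sqrt(mean(tr$correct) * (1 - mean(tr$correct)) / n)
  expect_lt(abs(res$se - closed_form) / closed_form, 0.15)
  res_again <- bootstrap_se(tr, function(trials) mean(trials$correct),
                            n_replicates = 500, seed = 2, strata_field = NULL)
  expect_identical(res, res_again)
})

test_that("undefined bootstrap replicates are redrawn with a warning", {
  set.seed(11)
  tr <- toy_trials(runif(200, 0, 500), correct = runif(200) < 0.7)
  flaky <- function(trials) {
    m <- mean(trials$correct)
    if (m > 0.72) NA_real_ else m
  }
  expect_warning(res <- bootstrap_se(tr, flaky, n_replicates = 100, seed = 3,
                                     strata_field = NULL),
                 "redrawn")
  expect_true(is.finite(res$se))
  # valid on the original trials, undefined on (essentially) every resample
  fails_on_resamples <- function(trials) {
    if (anyDuplicated(trials$trial_in_block) > 0L) stop("tied resample")
    mean(trials$correct)
  }
  expect_error(suppressWarnings(
    bootstrap_se(tr, fails_on_resamples, n_replicates = 10, seed = 4,
                 strata_field = NULL)), "replicates")
})
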