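test_that("RPT is reaction time minus gap duration", {
  tr <- data.frame(participant = "P01", session = 1L, block = 1L,
                   trial_in_block = 1:3, fixation_ms = 400L,
                   gap_ms = c(200L, 950L, 100L),
                   congruency = "congruent", target_direction = "left",
                   response = c("left", "left", "none"),
                   rt_ms = c(600, 300, NA), correct = c(TRUE, TRUE, NA),
                   rpt_ms = NA_real_, prev_congruency = "undefined")
  out <- compute_rpt(tr)
  expect_equal(out$rpt_ms, c(400, -650, NA))
})

test_that("RPT filtering uses a closed interval and counts all exclusions", {
  tr <- toy_trials(c(-650, 0, 400, 1000))
  flt <- filter_rpt(tr)
  expect_equal(flt$trials$rpt_ms, c(0, 400, 1000))
  expect_equal(flt$exclusion_fraction, 0.25)
  # boundary values are kept
  expect_equal(filter_rpt(toy_trials(c(-200, 1000)))$exclusion_fraction, 0)
  # no-response trials count as excluded
  tr2 <- toy_trials(c(100, 200))
  tr2$response[1L] <- "none"
  tr2 <- compute_rpt(tr2)
  expect_equal(filter_rpt(tr2)$exclusion_fraction, 0.5)
  expect_error(filter_rpt(tr, lo = 100, hi = 100), "lo")
})

test_that("binned accuracy averages correctness per 1-ms grid point", {
  tr <- toy_trials(rep(250, 3), correct = c(TRUE, FALSE, TRUE))
  bp <- binned_performance(tr)
  at <- which(bp$grid_ms == 250)
  expect_equal(bp$raw_mean[at], 2 / 3)
  expect_equal(bp$raw_n[at], 3)
  # empty grid points are undefined and carry no weight
  expect_true(is.nan(bp$raw_mean[bp$grid_ms == 600]))
  expect_equal(bp$raw_n[bp$grid_ms == 600], 0)
  expect_error(binned_performance(tr[0L, ]), "no trials")
})

test_that("binned means conserve the overall proportion correct", {
  tr <- default_pooled()
  tr <- compute_rpt(tr)
  flt <- filter_rpt(tr)$trials
  bp <- binned_performance(flt)
  pop <- bp$raw_n > 0
  expect_equal(sum(bp$raw_mean[pop] * bp$raw_n[pop]) / sum(bp$raw_n),
               mean(flt$correct))
  expect_equal(sum(bp$raw_n), nrow(flt))
})

test_that("fitted curves have the shapes the generator builds in", {
  cv <- default_curves()
  dip <- min_drop(cv$incongruent)
  # incongruent: transient drop below chance
  expect_lt(dip$min_value, 0.5)
  expect_gt(dip$drop_below_chance, 0)
  # congruent: any non-monotone wiggle is small against the incongruent dip
  win <- cv$congruent$grid_ms >= 0 & cv$congruent$grid_ms <= 600
  s <- cv$congruent$smooth[win]
  expect_lt(max(cummax(s) - s), dip$drop_below_chance / 3)
  # smooth stays within [0, 1]
  for (cu in cv) expect_true(all(cu$smooth >= 0 & cu$smooth <= 1))
})

test_that("all-correct toy data fit at the upper clip", {
  set.seed(2)
  tr <- toy_trials(runif(500, -200, 1000), correct = TRUE)
  fit <- tachometric(tr, min_trials = 100)
  expect_true(all(fit$smooth > 0.999))
})

test_that("a too-small condition is refused with its label", {
  tr <- toy_trials(runif(50, 0, 500))
  expect_error(tachometric(tr, condition_label = "tiny"), "tiny")
})

test_that("the dip statistic locates the curve minimum", {
  grid <- seq(-200, 1000)
  flat <- curve_from_values(grid, rep(0.5, length(grid)))
  d <- min_drop(flat)
  expect_equal(d$min_value, 0.5)
  expect_equal(d$drop_below_chance, 0)
  rising <- curve_from_values(grid, seq(0.4, 0.9, length.out = length(grid)),
                              window = c(0, 600))
  expect_equal(min_drop(rising)$min_rpt_ms, 0)
  expect_error(min_drop(rising, window = c(2000, 3000)), "window")
})

test_that("the dip of the analytic law is found within 5 ms of brute force", {
  cfg <- generator_config()
  grid <- seq(-200, 1000)
  law <- curve_from_values(grid,
                           true_accuracy(grid, "incongruent", "congruent", cfg))
  d <- min_drop(law)
  oracle <- dense_law_min(cfg, "incongruent", "congruent")
  expect_lte(abs(d$min_rpt_ms - oracle$rpt), 5)
  expect_equal(d$min_value, oracle$value, tolerance = 1e-4)
})

test_that("the shift estimate recovers exact translations", {
  cfg <- generator_config()
  grid <- seq(-200, 1000)
  base <- true_accuracy(grid, "congruent", "congruent", cfg)
  shifted <- true_accuracy(grid - 100, "congruent", "congruent", cfg)
  a <- curve_from_values(grid, base)
  b <- curve_from_values(grid, shifted)
  expect_equal(shift_estimate(a, b), 100, tolerance = 1e-8)
  expect_equal(shift_estimate(a, a), 0)
  flat <- curve_from_values(grid, rep(0.5, length(grid)))
  expect_error(shift_estimate(flat, flat), "level")
})

test_that("the shift of the analytic laws matches a dense crossing oracle", {
  cfg <- generator_config()
  grid <- seq(-200, 1000)
  cong <- curve_from_values(grid,
                            true_accuracy(grid, "congruent", "undefined", cfg))
  incong <- curve_from_values(grid,
                              true_accuracy(grid, "incongruent", "undefined", cfg))
  est <- shift_estimate(cong, incong)
  dense <- seq(-200, 1000, by = 0.05)
  vc <- true_accuracy(dense, "congruent", "undefined", cfg)
  vi <- true_accuracy(dense, "incongruent", "undefined", cfg)
  oracle <- median(vapply(c(0.6, 0.7, 0.8, 0.9), function(p)
    dense_last_upcross(dense, vi, p) - dense_last_upcross(dense, vc, p),
    numeric(1L)))
  expect_equal(est, oracle, tolerance = 0.5)
})

test_that("tachometric fits expose standard model-object methods", {
  cv <- default_curves()$incongruent
  expect_s3_class(cv, "tachometric")
  expect_length(fitted(cv), length(cv$grid_ms))
  expect_equal(predict(cv, newdata = cv$grid_ms), cv$smooth)
  r <- residuals(cv)
  expect_length(r, sum(cv$raw_n > 0))
  expect_lt(mean(abs(r)), 0.5)
  s <- summary(cv)
  expect_s3_class(s, "summary.tachometric")
  expect_output(print(s), "minimum")
  expect_output(print(cv), "Tachometric")
  tmp <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tmp)
  expect_silent(plot(cv))
  grDevices::dev.off()
  expect_true(file.exists(tmp))
})
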