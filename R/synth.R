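#' Parameters of the synthetic accuracy law and reaction-time model
#'
#' The generator emulates an urgent two-alternative task. Accuracy as a
#' function of raw processing time (RPT) follows a logistic rise from chance
#' to an asymptote; in the incongruent condition a Gaussian-shaped transient
#' dip is subtracted, pulling accuracy below chance in a window around
#' `dip_center_ms`, deeper when the previous trial was congruent than when
#' it was incongruent (conflict adaptation), and the rise is delayed by
#' `incong_shift_ms`. Reaction time is the minimum of a deadline-driven
#' urgent process (truncated normal, triggered by the go-signal) and a
#' target-driven visual process (gamma, starting at target onset), which
#' reproduces the key feature of the urgency manipulation: the longer the
#' gap, the shorter the realized RPT.
#'
#' @param asymptote Upper asymptote of accuracy (default 0.98).
#' @param chance Guessing accuracy (0.5 for two alternatives).
#' @param rise_center_ms,rise_slope_ms Midpoint and slope scale of the
#'   logistic rise (ms).
#' @param incong_shift_ms Rightward shift of the rise in the incongruent
#'   condition (ms, >= 0).
#' @param dip_center_ms,dip_width_ms Center and standard-deviation width of
#'   the Gaussian dip (ms).
#' @param dip_depth_prev_congruent,dip_depth_prev_incongruent Dip depth after
#'   a congruent / incongruent predecessor, in `[0, 1)`, with
#'   `dip_depth_prev_congruent >= dip_depth_prev_incongruent`. Trials with
#'   undefined predecessor (first of a block) use the mean of the two.
#' @param urgent_mean_ms,urgent_sd_ms Mean and sd of the urgent process
#'   (truncated at 0).
#' @param visual_rt_shape,visual_rt_scale_ms Gamma shape and scale of the
#'   visual process.
#' @param miss_rate Probability of not responding at all.
#' @param clip_eps Accuracy is clipped to `[clip_eps, 1 - clip_eps]`.
#' @param seed Default seed used by [simulate_trials()].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(asymptote = 0.98,
                             chance = 0.5,
                             rise_center_ms = 300,
                             rise_slope_ms = 60,
                             incong_shift_ms = 80,
                             dip_center_ms = 250,
                             dip_width_ms = 50,
                             dip_depth_prev_congruent = 0.25,
                             dip_depth_prev_incongruent = 0.12,
                             urgent_mean_ms = 900,
                             urgent_sd_ms = 120,
                             visual_rt_shape = 9,
                             visual_rt_scale_ms = 40,
                             miss_rate = 0.02,
                             clip_eps = 0.01,
                             seed = 1L) {
  cfg <- list(asymptote = asymptote, chance = chance,
              rise_center_ms = rise_center_ms, rise_slope_ms = rise_slope_ms,
              incong_shift_ms = incong_shift_ms,
              dip_center_ms = dip_center_ms, dip_width_ms = dip_width_ms,
              dip_depth_prev_congruent = dip_depth_prev_congruent,
              dip_depth_prev_incongruent = dip_depth_prev_incongruent,
              urgent_mean_ms = urgent_mean_ms, urgent_sd_ms = urgent_sd_ms,
              visual_rt_shape = visual_rt_shape,
              visual_rt_scale_ms = visual_rt_scale_ms,
              miss_rate = miss_rate, clip_eps = clip_eps,
              seed = as.integer(seed))
  if (!(cfg$clip_eps > 0 && cfg$clip_eps < 0.5))
    stopf("clip_eps must be in (0, 0.5)")
  if (!(cfg$chance > 0 && cfg$chance < cfg$asymptote &&
        cfg$asymptote <= 1 - cfg$clip_eps))
    stopf("need 0 < chance < asymptote <= 1 - clip_eps")
  if (!(cfg$dip_depth_prev_congruent >= cfg$dip_depth_prev_incongruent &&
        cfg$dip_depth_prev_incongruent >= 0 &&
        cfg$dip_depth_prev_congruent < 1))
    stopf("dip depths must satisfy 0 <= prev_incongruent <= prev_congruent < 1")
  if (cfg$incong_shift_ms < 0) stopf("incong_shift_ms must be >= 0")
  positive <- c("rise_slope_ms", "dip_width_ms", "urgent_mean_ms",
                "urgent_sd_ms", "visual_rt_shape", "visual_rt_scale_ms")
  for (p in positive)
    if (!(is.finite(cfg[[p]]) && cfg[[p]] > 0)) stopf("%s must be > 0", p)
  if (!(cfg$miss_rate >= 0 && cfg$miss_rate <= 1))
    stopf("miss_rate must be a probability")
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic accuracy-law / RT-model configuration\n")
  cat(sprintf("  rise: chance %.2f -> asymptote %.2f, center %g ms, slope %g ms, incongruent shift +%g ms\n",
              x$chance, x$asymptote, x$rise_center_ms, x$rise_slope_ms,
              x$incong_shift_ms))
  cat(sprintf("  dip (incongruent only): center %g ms, width %g ms, depth %g (prev congruent) / %g (prev incongruent)\n",
              x$dip_center_ms, x$dip_width_ms, x$dip_depth_prev_congruent,
              x$dip_depth_prev_incongruent))
  cat(sprintf("  RT: min(N(%g, %g) urgent, gap + Gamma(%g, %g) visual), miss rate %g\n",
              x$urgent_mean_ms, x$urgent_sd_ms, x$visual_rt_shape,
              x$visual_rt_scale_ms, x$miss_rate))
  invisible(x)
}

#' True accuracy of the synthetic generator
#'
#' Evaluates the generator's accuracy law: a logistic rise from `chance` to
#' `asymptote`, shifted right by `incong_shift_ms` for incongruent trials,
#' minus (incongruent trials only) a Gaussian dip whose depth depends on the
#' previous trial's congruency. The result is clipped to
#' `[clip_eps, 1 - clip_eps]`. All arguments are vectorized over trials.
#'
#' @param rpt_ms Raw processing time(s) in ms.
#' @param congruency `"congruent"` or `"incongruent"`.
#' @param prev_congruency `"congruent"`, `"incongruent"` or `"undefined"`.
#' @param cfg A [generator_config()].
#' @return Probability of a correct response, same length as the longest
#'   argument.
#' @export
true_accuracy <- function(rpt_ms, congruency, prev_congruency, cfg) {
  if (!inherits(cfg, "generator_config")) stopf("cfg must be a generator_config")
  n <- max(length(rpt_ms), length(congruency), length(prev_congruency))
  rpt_ms <- rep_len(rpt_ms, n)
  congruency <- rep_len(congruency, n)
  prev_congruency <- rep_len(prev_congruency, n)
  incong <- congruency == "incongruent"
  center <- cfg$rise_center_ms + cfg$incong_shift_ms * incong
  base <- cfg$chance + (cfg$asymptote - cfg$chance) *
    plogis((rpt_ms - center) / cfg$rise_slope_ms)
  depth <- ifelse(prev_congruency == "congruent", cfg$dip_depth_prev_congruent,
           ifelse(prev_congruency == "incongruent",
                  cfg$dip_depth_prev_incongruent,
                  (cfg$dip_depth_prev_congruent +
                     cfg$dip_depth_prev_incongruent) / 2))
  dip <- ifelse(incong,
                depth * exp(-(rpt_ms - cfg$dip_center_ms)^2 /
                              (2 * cfg$dip_width_ms^2)),
                0)
  clamp(base - dip, cfg$clip_eps, 1 - cfg$clip_eps)
}

#' Simulate trial outcomes for a designed experiment
#'
#' Fills in `response`, `rt_ms`, `correct` and `rpt_ms` for a trial table
#' from [build_design()]. Reaction time is
#' `min(T_urgent, gap + T_visual)` with `T_urgent ~ Normal(urgent_mean_ms,
#' urgent_sd_ms)` truncated at 0 and `T_visual ~ Gamma(visual_rt_shape,
#' scale = visual_rt_scale_ms)`. With probability `miss_rate` the trial is a
#' miss (`response = "none"`, other outcome fields missing); otherwise the
#' response is correct with probability [true_accuracy()] at the realized
#' RPT, using the designed previous-trial congruency, and the button pressed
#' follows from correctness and the target direction. The simulation is
#' seed-deterministic.
#'
#' @param trials Trial table with unset responses.
#' @param cfg A [generator_config()].
#' @param seed Seed; defaults to `cfg$seed`.
#' @return The completed trial table.
#' @export
simulate_trials <- function(trials, cfg = generator_config(), seed = cfg$seed) {
  if (!inherits(cfg, "generator_config")) stopf("cfg must be a generator_config")
  if (any(!is.na(trials$response)))
    stopf("trials already contain responses; pass an unsimulated design")
  n <- nrow(trials)
  with_seed(seed, {
    t_urgent <- rnorm(n, cfg$urgent_mean_ms, cfg$urgent_sd_ms)
    while (any(neg <- t_urgent <= 0))  # truncate at 0 by redrawing
      t_urgent[neg] <- rnorm(sum(neg), cfg$urgent_mean_ms, cfg$urgent_sd_ms)
    t_visual <- rgamma(n, shape = cfg$visual_rt_shape,
                       scale = cfg$visual_rt_scale_ms)
    rt <- pmin(t_urgent, trials$gap_ms + t_visual)
    rpt <- rt - trials$gap_ms
    p_correct <- true_accuracy(rpt, trials$congruency, trials$prev_congruency,
                               cfg)
    correct <- runif(n) < p_correct
    miss <- runif(n) < cfg$miss_rate
  })
  other <- ifelse(trials$target_direction == "left", "right", "left")
  trials$response <- ifelse(miss, "none",
                            ifelse(correct, trials$target_direction, other))
  trials$rt_ms <- ifelse(miss, NA_real_, rt)
  trials$correct <- ifelse(miss, NA, correct)
  trials$rpt_ms <- ifelse(miss, NA_real_, rpt)
  trials
}
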