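#' Compute raw processing time (RPT)
#'
#' RPT is the reaction time from the go-signal minus the gap duration: the
#' time the target stimulus was visible before the response. Trials without
#' a response get a missing RPT.
#'
#' @param trials Trial table with `rt_ms` and `gap_ms`.
#' @return The trial table with `rpt_ms` set.
#' @export
compute_rpt <- function(trials) {
  rpt <- trials$rt_ms - trials$gap_ms
  rpt[is.na(trials$response) | trials$response == "none"] <- NA_real_
  trials$rpt_ms <- rpt
  trials
}

#' Filter trials to the analysable RPT range
#'
#' Keeps trials with `lo <= rpt_ms <= hi` (closed interval). Trials outside
#' the range — including no-response trials, whose RPT is undefined — are
#' excluded and counted in the exclusion fraction.
#'
#' @param trials Trial table with `rpt_ms` computed.
#' @param lo,hi Range bounds in ms (defaults −200 and 1000).
#' @return A list with `trials` (kept rows), `exclusion_fraction`,
#'   `n_excluded` and `n_total`.
#' @export
filter_rpt <- function(trials, lo = -200, hi = 1000) {
  if (lo >= hi) stopf("lo must be < hi")
  keep <- !is.na(trials$rpt_ms) & trials$rpt_ms >= lo & trials$rpt_ms <= hi
  list(trials = trials[keep, , drop = FALSE],
       exclusion_fraction = sum(!keep) / nrow(trials),
       n_excluded = sum(!keep),
       n_total = nrow(trials))
}

#' Bin accuracy on a millisecond RPT grid
#'
#' Assigns each trial to the grid point nearest its RPT (1-ms-wide bins on a
#' 1-ms grid by default) and averages correctness per bin. `bin_width` (an
#' odd number of grid steps) widens each bin symmetrically so that
#' neighbouring bins overlap, i.e. a sliding window.
#'
#' @param trials Filtered trial table (all rows responded, RPT in range).
#' @param step Grid step in ms.
#' @param range RPT range, default `c(-200, 1000)`.
#' @param bin_width Bin width in grid steps (odd integer, default 1).
#' @return A list with `grid_ms`, `raw_mean` (`NaN` at empty bins) and
#'   `raw_n`.
#' @export
binned_performance <- function(trials, step = 1, range = c(-200, 1000),
                               bin_width = 1) {
  if (nrow(trials) == 0L) stopf("no trials to bin")
  bp <- binned_core(trials$rpt_ms, trials$correct, step = step, range = range,
                    bin_width = bin_width)
  list(grid_ms = bp$grid, raw_mean = bp$hits / bp$n, raw_n = bp$n)
}

binned_core <- function(rpt, correct, step = 1, range = c(-200, 1000),
                        bin_width = 1) {
  grid <- seq(range[1L], range[2L], by = step)
  idx <- as.integer(round((rpt - range[1L]) / step)) + 1L
  n <- tabulate(idx, length(grid))
  hits <- tabulate(idx[correct], length(grid))
  if (bin_width > 1) {
    if (bin_width %% 2 == 0) stopf("bin_width must be odd")
    k <- rep(1, bin_width)
    pad <- (bin_width - 1) / 2
    run <- function(v) {
      s <- as.numeric(stats::filter(c(rep(0, pad), v, rep(0, pad)), k,
                                    sides = 2))
      s[(pad + 1L):(pad + length(v))]
    }
    n <- run(n)
    hits <- run(hits)
  }
  list(grid = grid, n = n, hits = hits)
}

#' Locally weighted polynomial regression
#'
#' For each evaluation point, the `ceiling(span * N)` nearest predictor
#' values are selected, weighted by a tricube kernel of their scaled
#' distance multiplied by the supplied weights, and a polynomial of the
#' given degree is fitted by weighted least squares; its value at the
#' evaluation point is returned. This is the classical loess smoother with
#' explicit case weights and direct (non-interpolated) evaluation.
#'
#' @param x,y Predictor and response, equal length.
#' @param weights Case weights (e.g. per-bin trial counts); default 1.
#' @param span Fraction of points in each local window, in (0, 1].
#' @param eval_points Where to evaluate the fit; defaults to `x`.
#' @param degree Polynomial degree, 1 or 2 (default 2).
#' @return Fitted values at `eval_points`.
#' @export
local_regression <- function(x, y, weights = NULL, span = 0.2,
                             eval_points = x, degree = 2) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) != length(x)) stopf("weights must match x")
  if (!(span > 0 && span <= 1)) stopf("span must be in (0, 1]")
  if (anyNA(x) || anyNA(y) || anyNA(weights)) stopf("missing values in input")
  ord <- order(x)
  cpp_local_regression(as.numeric(x[ord]), as.numeric(y[ord]),
                       as.numeric(weights[ord]), span,
                       as.numeric(eval_points), as.integer(degree))
}

# Fast internal path: filtered rpt/correct vectors -> smoothed curve on the
# full grid, plus the populated-bin summaries. Used by tachometric() and the
# resampling loops, which refit thousands of curves.
tach_core <- function(rpt, correct, span = 0.2, range = c(-200, 1000),
                      step = 1, bin_width = 1, degree = 2) {
  bp <- binned_core(rpt, correct, step = step, range = range,
                    bin_width = bin_width)
  pop <- bp$n > 0
  x <- bp$grid[pop]
  w <- bp$n[pop]
  y <- bp$hits[pop] / w
  q <- ceiling(span * length(x))
  if (q < degree + 1)
    stopf("only %d populated bins; local window too small for a degree-%d fit, increase the span",
          length(x), degree)
  smooth <- cpp_local_regression(x, y, as.numeric(w), span,
                                 as.numeric(bp$grid), as.integer(degree))
  list(grid = bp$grid, n = bp$n, hits = bp$hits,
       smooth = clamp(smooth, 0, 1))
}

#' Fit a tachometric function
#'
#' Estimates proportion correct as a function of raw processing time for one
#' condition: trials are restricted to `subset`, RPTs are computed and
#' filtered to `rpt_range`, accuracy is binned on a 1-ms grid
#' ([binned_performance()]) and the populated bins are smoothed by locally
#' weighted quadratic regression ([local_regression()]) weighted by the
#' per-bin trial counts, so the smoother is consistent with trial-level
#' averaging. The smooth is evaluated on the full grid and clipped to
#' `[0, 1]`.
#'
#' @param trials Trial table.
#' @param subset Optional logical vector (length `nrow(trials)`) selecting
#'   the condition, e.g. `trials$congruency == "incongruent"`.
#' @param condition_label Label stored in the fit (used in messages and
#'   printing).
#' @param span Loess span, fraction of populated bins per local window.
#' @param chance Chance accuracy level (0.5 for two alternatives).
#' @param rpt_range Analysis range in ms, default `c(-200, 1000)`.
#' @param bin_step,bin_width Grid step and bin width in ms (see
#'   [binned_performance()]).
#' @param min_trials Minimum number of analysable trials required.
#' @param degree Local polynomial degree (2, or 1).
#' @return An object of class `tachometric` with components `grid_ms`,
#'   `raw_mean`, `raw_n`, `smooth`, `condition_label`, `span`, `chance`,
#'   `n_trials`, `exclusion_fraction`, `rpt_window` (central 95% range of
#'   the observed RPTs, the default dip-search window).
#' @examples
#' trials <- simulate_trials(build_design(design_spec(sessions = 1L)))
#' fit <- tachometric(trials, trials$congruency == "congruent",
#'                    condition_label = "congruent")
#' print(fit)
#' @export
tachometric <- function(trials, subset = NULL, condition_label = "all",
                        span = 0.2, chance = 0.5, rpt_range = c(-200, 1000),
                        bin_step = 1, bin_width = 1, min_trials = 200,
                        degree = 2) {
  if (!is.null(subset)) {
    if (!is.logical(subset) || length(subset) != nrow(trials))
      stopf("subset must be a logical vector with one entry per trial")
    trials <- trials[subset & !is.na(subset), , drop = FALSE]
  }
  trials <- compute_rpt(trials)
  flt <- filter_rpt(trials, rpt_range[1L], rpt_range[2L])
  n <- nrow(flt$trials)
  if (n < min_trials)
    stopf("condition '%s' has %d analysable trials, fewer than min_trials = %d",
          condition_label, n, min_trials)
  rpt <- flt$trials$rpt_ms
  core <- tach_core(rpt, flt$trials$correct, span = span, range = rpt_range,
                    step = bin_step, bin_width = bin_width, degree = degree)
  structure(
    list(grid_ms = core$grid,
         raw_mean = core$hits / core$n,
         raw_n = core$n,
         smooth = core$smooth,
         condition_label = condition_label,
         span = span,
         chance = chance,
         degree = degree,
         n_trials = n,
         exclusion_fraction = flt$exclusion_fraction,
         rpt_window = unname(quantile(rpt, c(0.025, 0.975), names = FALSE))),
    class = "tachometric")
}

#' @export
print.tachometric <- function(x, ...) {
  cat(sprintf("Tachometric function '%s': %d trials, span %.2f, degree %d\n",
              x$condition_label, x$n_trials, x$span, x$degree))
  dip <- min_drop(x)
  cat(sprintf("  minimum %.3f at RPT %d ms (drop below chance %.3f)\n",
              dip$min_value, dip$min_rpt_ms, dip$drop_below_chance))
  invisible(x)
}

#' @export
summary.tachometric <- function(object, ...) {
  dip <- min_drop(object)
  out <- list(condition_label = object$condition_label,
              n_trials = object$n_trials,
              span = object$span,
              chance = object$chance,
              exclusion_fraction = object$exclusion_fraction,
              dip = dip,
              max_value = max(object$smooth),
              rpt_window = object$rpt_window)
  class(out) <- "summary.tachometric"
  out
}

#' @export
print.summary.tachometric <- function(x, ...) {
  cat(sprintf("Tachometric function '%s'\n", x$condition_label))
  cat(sprintf("  trials analysed: %d (%.2f%% of input excluded)\n",
              x$n_trials, 100 * x$exclusion_fraction))
  cat(sprintf("  smoother: loess span %.2f, count-weighted, clipped to [0, 1]\n",
              x$span))
  cat(sprintf("  minimum %.3f at %d ms in window [%.0f, %.0f] ms; drop below chance (%.2f): %.3f\n",
              x$dip$min_value, x$dip$min_rpt_ms, x$rpt_window[1L],
              x$rpt_window[2L], x$chance, x$dip$drop_below_chance))
  cat(sprintf("  maximum smoothed accuracy: %.3f\n", x$max_value))
  invisible(x)
}

#' @export
fitted.tachometric <- function(object, ...) object$smooth

#' @rdname predict.tachometric
#' @export
residuals.tachometric <- function(object, ...) {
  pop <- object$raw_n > 0
  object$raw_mean[pop] - object$smooth[pop]
}

#' Evaluate a fitted tachometric function
#'
#' `predict` evaluates the smoothed curve at arbitrary RPTs by linear
#' interpolation of the fitted grid; `residuals` returns raw binned accuracy
#' minus the smooth at the populated grid points.
#'
#' @param object A [tachometric()] fit.
#' @param newdata Numeric RPTs (ms); defaults to the fitted grid.
#' @param ... Unused.
#' @return Numeric vector of accuracies.
#' @export
predict.tachometric <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$smooth)
  approx(object$grid_ms, object$smooth, xout = newdata, rule = 2)$y
}

#' Plot a tachometric function
#'
#' Raw binned accuracy (point size proportional to trial count) with the
#' smoothed curve and the chance line.
#'
#' @param x A [tachometric()] fit.
#' @param add Add to an existing plot.
#' @param col Curve colour.
#' @param show_raw Draw the raw bin means.
#' @param main Plot title; defaults to the condition label.
#' @param ... Passed to `plot`.
#' @export
plot.tachometric <- function(x, add = FALSE, col = "black", show_raw = TRUE,
                             main = x$condition_label, ...) {
  if (!add) {
    plot(NA, xlim = range(x$grid_ms), ylim = c(0, 1),
         xlab = "raw processing time (ms)", ylab = "proportion correct",
         main = main, ...)
    graphics::abline(h = x$chance, lty = 3, col = "grey40")
  }
  if (show_raw) {
    pop <- x$raw_n > 0
    cex <- 0.2 + sqrt(x$raw_n[pop] / max(x$raw_n))
    graphics::points(x$grid_ms[pop], x$raw_mean[pop], pch = 16, cex = cex,
                     col = grDevices::adjustcolor(col, alpha.f = 0.25))
  }
  graphics::lines(x$grid_ms, x$smooth, col = col, lwd = 2)
  invisible(x)
}

# minimum of a smooth curve over a window; shared by min_drop() and the
# fast resampling paths
min_on_window <- function(grid, smooth, window) {
  in_win <- grid >= window[1L] & grid <= window[2L]
  if (!any(in_win)) stopf("empty dip-search window [%g, %g]", window[1L], window[2L])
  i <- which(in_win)[which.min(smooth[in_win])]
  list(min_value = smooth[i], min_rpt_ms = grid[i])
}

#' Maximum drop below chance of a tachometric function
#'
#' Locates the minimum of the smoothed curve inside the search window and
#' reports its depth below chance. The default window is the central 95%
#' quantile range of the observed RPTs, which keeps the edge regions of the
#' local regression (where few trials constrain the fit) out of the search.
#'
#' @param curve A [tachometric()] fit.
#' @param chance Chance level; defaults to the value stored in the fit.
#' @param window Numeric `c(lo, hi)` search window in ms, or `NULL` for the
#'   default.
#' @return An object of class `dip_statistic`: `min_value`, `min_rpt_ms`,
#'   `drop_below_chance` (`chance - min_value`; negative if the curve never
#'   falls below chance), `chance`, `search_window_ms`.
#' @export
min_drop <- function(curve, chance = NULL, window = NULL) {
  if (!inherits(curve, "tachometric")) stopf("curve must be a tachometric fit")
  chance <- chance %||% curve$chance
  window <- window %||% curve$rpt_window
  m <- min_on_window(curve$grid_ms, curve$smooth, window)
  structure(list(min_value = m$min_value,
                 min_rpt_ms = m$min_rpt_ms,
                 drop_below_chance = chance - m$min_value,
                 chance = chance,
                 search_window_ms = window),
            class = "dip_statistic")
}

#' @export
print.dip_statistic <- function(x, ...) {
  cat(sprintf("Dip: minimum %.4f at RPT %d ms; drop below chance (%.2f) = %.4f\n",
              x$min_value, x$min_rpt_ms, x$chance, x$drop_below_chance))
  cat(sprintf("  search window: [%.0f, %.0f] ms\n",
              x$search_window_ms[1L], x$search_window_ms[2L]))
  invisible(x)
}

# last upward crossing of level p by the piecewise-linear curve (grid, s)
last_upcross <- function(grid, s, p) {
  below <- s < p
  i <- which(below[-length(s)] & !below[-1L])
  if (length(i) == 0L) return(NA_real_)
  i <- max(i)
  grid[i] + (p - s[i]) / (s[i + 1L] - s[i]) * (grid[i + 1L] - grid[i])
}

#' Rightward shift between two tachometric functions
#'
#' Measures how much later the incongruent curve reaches fixed performance
#' levels on its final rising limb: for each level the last upward crossing
#' of both smoothed curves is located (linear interpolation between grid
#' points) and the median over levels of the incongruent-minus-congruent
#' crossing times is returned. Levels never crossed by one of the curves
#' are skipped; if no level is crossed by both, an error is raised.
#'
#' @param curve_congruent,curve_incongruent [tachometric()] fits.
#' @param levels Performance levels on the rising limb.
#' @return Shift in ms (positive = incongruent delayed).
#' @export
shift_estimate <- function(curve_congruent, curve_incongruent,
                           levels = c(0.6, 0.7, 0.8, 0.9)) {
  if (!inherits(curve_congruent, "tachometric") ||
      !inherits(curve_incongruent, "tachometric"))
    stopf("both curves must be tachometric fits")
  shifts <- vapply(levels, function(p) {
    a <- last_upcross(curve_congruent$grid_ms, curve_congruent$smooth, p)
    b <- last_upcross(curve_incongruent$grid_ms, curve_incongruent$smooth, p)
    b - a
  }, numeric(1L))
  shifts <- shifts[!is.na(shifts)]
  if (length(shifts) == 0L)
    stopf("no performance level was crossed by both curves")
  median(shifts)
}
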