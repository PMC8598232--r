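# Independent oracles, implemented with plain base-R linear algebra so they
# share no code with the package's smoothing path.

# brute-force locally weighted least squares: for each evaluation point,
# select the ceiling(span*n) nearest x, tricube-weight them, and solve the
# weighted normal equations with lm.wfit
oracle_lwr <- function(x, y, w, span, eval_points, degree = 2) {
  n <- length(x)
  q <- ceiling(span * n)
  vapply(eval_points, function(x0) {
    d <- abs(x - x0)
    sel <- order(d)[seq_len(q)]
    dmax <- max(d[sel])
    tric <- if (dmax == 0) rep(1, q) else (1 - pmin(d[sel] / dmax, 1)^3)^3
    X <- outer(x[sel] - x0, 0:degree, "^")
    fit <- stats::lm.wfit(X, y[sel], tric * w[sel])
    unname(fit$coefficients[1L])
  }, numeric(1L))
}

# a tachometric object whose smooth is an arbitrary function of the grid;
# used to test the dip and shift statistics against analytic curves
curve_from_values <- function(grid, values, chance = 0.5,
                              window = range(grid)) {
  structure(list(grid_ms = grid, raw_mean = values,
                 raw_n = rep(1L, length(grid)), smooth = values,
                 condition_label = "analytic", span = 0.2, chance = chance,
                 degree = 2, n_trials = length(grid), exclusion_fraction = 0,
                 rpt_window = window),
            class = "tachometric")
}

# dense brute-force minimizer of the generator accuracy law
dense_law_min <- function(cfg, congruency, prev, lo = -200, hi = 1000,
                          by = 0.01) {
  g <- seq(lo, hi, by = by)
  v <- true_accuracy(g, congruency, prev, cfg)
  i <- which.min(v)
  list(rpt = g[i], value = v[i])
}

# independent last-upward-crossing locator on a dense grid: walks the curve
# from the right and finds the first point below the level
dense_last_upcross <- function(g, v, p) {
  below <- which(v < p)
  if (length(below) == 0L || max(below) == length(v)) return(NA_real_)
  i <- max(below)
  g[i] + (p - v[i]) / (v[i + 1L] - v[i]) * (g[i + 1L] - g[i])
}
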