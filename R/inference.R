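cond_min_value <- function(rpt, correct, span, rpt_range, bin_step, bin_width,
                           degree, window) {
  core <- tach_core(rpt, correct, span = span, range = rpt_range,
                    step = bin_step, bin_width = bin_width, degree = degree)
  win <- window %||% unname(quantile(rpt, c(0.025, 0.975), names = FALSE))
  min_on_window(core$grid, core$smooth, win)$min_value
}

#' Congruency effect on the tachometric minimum
#'
#' Difference between the minima of the incongruent and congruent smoothed
#' tachometric functions (incongruent minus congruent): negative when the
#' incongruent curve dips lower, as when urgency drives responses toward the
#' task-irrelevant stimulus attribute.
#'
#' @param trials Pooled trial table.
#' @param span,chance,rpt_range,bin_step,bin_width,min_trials,degree,window
#'   Curve-fitting options, as in [tachometric()] and [min_drop()].
#' @return The effect (a single number).
#' @seealso [permutation_test()], [sequence_effect()]
#' @export
congruency_effect <- function(trials, span = 0.2, chance = 0.5,
                              rpt_range = c(-200, 1000), bin_step = 1,
                              bin_width = 1, min_trials = 200, degree = 2,
                              window = NULL) {
  trials <- compute_rpt(trials)
  flt <- filter_rpt(trials, rpt_range[1L], rpt_range[2L])$trials
  mins <- vapply(c("congruent", "incongruent"), function(lab) {
    sel <- flt$congruency == lab
    if (sum(sel) < min_trials)
      stopf("condition '%s' has %d analysable trials, fewer than min_trials = %d",
            lab, sum(sel), min_trials)
    cond_min_value(flt$rpt_ms[sel], flt$correct[sel], span, rpt_range,
                   bin_step, bin_width, degree, window)
  }, numeric(1L))
  unname(mins["incongruent"] - mins["congruent"])
}

#' Trial-sequence (conflict-adaptation) effect on the incongruent minimum
#'
#' Among incongruent trials with a defined predecessor, fits separate
#' tachometric functions for trials preceded by a congruent vs. an
#' incongruent trial and returns the difference of their minima
#' (previous-congruent minus previous-incongruent): negative when the
#' below-chance dip is deeper after congruent trials, the classic
#' conflict-adaptation pattern. First-of-block trials (undefined
#' predecessor) are excluded; their count is attached as attribute
#' `n_undefined_excluded`.
#'
#' @inheritParams congruency_effect
#' @return The effect (a single number) with attribute
#'   `n_undefined_excluded`.
#' @export
sequence_effect <- function(trials, span = 0.2, chance = 0.5,
                            rpt_range = c(-200, 1000), bin_step = 1,
                            bin_width = 1, min_trials = 200, degree = 2,
                            window = NULL) {
  trials <- compute_rpt(trials)
  flt <- filter_rpt(trials, rpt_range[1L], rpt_range[2L])$trials
  incong <- flt[flt$congruency == "incongruent", , drop = FALSE]
  n_undef <- sum(incong$prev_congruency == "undefined")
  incong <- incong[incong$prev_congruency != "undefined", , drop = FALSE]
  mins <- vapply(c("congruent", "incongruent"), function(lab) {
    sel <- incong$prev_congruency == lab
    if (sum(sel) < min_trials)
      stopf("previous-%s group has %d analysable trials, fewer than min_trials = %d",
            lab, sum(sel), min_trials)
    cond_min_value(incong$rpt_ms[sel], incong$correct[sel], span, rpt_range,
                   bin_step, bin_width, degree, window)
  }, numeric(1L))
  structure(unname(mins["congruent"] - mins["incongruent"]),
            n_undefined_excluded = n_undef)
}

#' Permutation test by label shuffling
#'
#' Builds the null distribution of an effect by repeatedly shuffling a
#' condition label column and recomputing the effect on the relabeled
#' trials. Labels are shuffled within participant, preserving each
#' participant's label counts, which respects the participant structure of
#' pooled data. The two-sided p-value uses add-one smoothing:
#' `(1 + #\{|null| >= |observed|\}) / (n_permutations + 1)`.
#'
#' @param trials Trial table.
#' @param effect_fn Function `trials -> number`, e.g.
#'   `congruency_effect`.
#' @param label_field Name of the label column to shuffle (two-valued on the
#'   shuffled subset; `NA` and `"undefined"` rows are left in place).
#' @param n_permutations Number of relabelings (the study-scale choice is
#'   2000).
#' @param seed Integer seed.
#' @param subset Optional logical vector restricting which rows are
#'   shuffled (e.g. only incongruent trials when testing the sequence
#'   effect).
#' @param effect_name Label stored in the result.
#' @return An object of class `permutation_result`: `observed_effect`,
#'   `null_effects`, `n_permutations`, `p_value`, `seed`, `effect_name`.
#' @export
permutation_test <- function(trials, effect_fn, label_field,
                             n_permutations = 2000, seed = 1L,
                             subset = NULL, effect_name = label_field) {
  if (!is_count(n_permutations)) stopf("n_permutations must be >= 1")
  if (!label_field %in% names(trials)) stopf("no column '%s'", label_field)
  labs <- trials[[label_field]]
  elig <- !is.na(labs) & labs != "undefined"
  if (!is.null(subset)) elig <- elig & subset & !is.na(subset)
  if (length(unique(labs[elig])) < 2L)
    stopf("column '%s' is constant on the shuffled subset", label_field)
  observed <- effect_fn(trials)
  idx_by_part <- split(which(elig), trials$participant[elig])
  null_effects <- numeric(n_permutations)
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      newl <- labs
      for (ix in idx_by_part) newl[ix] <- labs[ix][sample.int(length(ix))]
      relabeled <- trials
      relabeled[[label_field]] <- newl
      null_effects[b] <- effect_fn(relabeled)
    }
  })
  p <- (1 + sum(abs(null_effects) >= abs(observed))) / (n_permutations + 1)
  structure(list(observed_effect = as.numeric(observed),
                 null_effects = null_effects,
                 n_permutations = as.integer(n_permutations),
                 p_value = p,
                 seed = as.integer(seed),
                 effect_name = effect_name),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test of '%s'\n", x$effect_name))
  cat(sprintf("  observed effect: %.4f\n", x$observed_effect))
  cat(sprintf("  null distribution: %d relabelings, mean %.4f, sd %.4f\n",
              x$n_permutations, mean(x$null_effects), sd(x$null_effects)))
  cat(sprintf("  two-sided p (add-one): %.4g\n", x$p_value))
  invisible(x)
}

#' Bootstrap standard error of a trial-level statistic
#'
#' Resamples trials with replacement (same size, stratified by a condition
#' label so each condition keeps its trial count), recomputes the statistic
#' on each replicate and returns the standard deviation of the replicates
#' as the standard error. Replicates on which the statistic fails or is not
#' finite are redrawn, up to `max_redraws` times each, with a warning.
#'
#' @param trials Trial table.
#' @param statistic_fn Function `trials -> number`.
#' @param n_replicates Number of bootstrap replicates (the study-scale
#'   choice is 1000).
#' @param seed Integer seed.
#' @param strata_field Column to stratify resampling by; `NULL` for
#'   unstratified.
#' @param max_redraws Redraw cap per replicate.
#' @return An object of class `bootstrap_result`: `estimate` (statistic on
#'   the original trials), `se`, `n_replicates`, `seed`.
#' @export
bootstrap_se <- function(trials, statistic_fn, n_replicates = 1000,
                         seed = 1L, strata_field = "congruency",
                         max_redraws = 20L) {
  if (nrow(trials) == 0L) stopf("trials must be non-empty")
  if (!is_count(n_replicates)) stopf("n_replicates must be >= 1")
  if (!is.null(strata_field) && strata_field %in% names(trials)) {
    idx_by_s <- split(seq_len(nrow(trials)), trials[[strata_field]])
  } else {
    idx_by_s <- list(seq_len(nrow(trials)))
  }
  estimate <- as.numeric(statistic_fn(trials))
  replicates <- numeric(n_replicates)
  total_redraws <- 0L
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      tries <- 0L
      repeat {
        idx <- unlist(lapply(idx_by_s, function(ix)
          ix[sample.int(length(ix), replace = TRUE)]), use.names = FALSE)
        val <- tryCatch(as.numeric(statistic_fn(trials[idx, , drop = FALSE])),
                        error = function(e) NA_real_)
        if (is.finite(val)) break
        tries <- tries + 1L
        if (tries > max_redraws)
          stopf("statistic failed on %d consecutive bootstrap replicates", tries)
      }
      total_redraws <- total_redraws + tries
      replicates[r] <- val
    }
  })
  if (total_redraws > 0L)
    warnf("%d bootstrap replicate(s) were redrawn because the statistic was undefined",
          total_redraws)
  structure(list(estimate = estimate,
                 se = sd(replicates),
                 replicates = replicates,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap: estimate %.4f, SE %.4f (%d replicates)\n",
              x$estimate, x$se, x$n_replicates))
  invisible(x)
}

#' Pool participants into one aggregate dataset
#'
#' Concatenates per-participant trial tables, preserving within-participant
#' trial order and keeping the participant column so that permutation
#' resampling can respect the participant structure. Duplicate
#' (participant, session, block, trial) keys are an error.
#'
#' @param per_participant_trials A list of trial tables (or a single one).
#' @return The pooled trial table.
#' @export
pool_aggregate <- function(per_participant_trials) {
  if (is.data.frame(per_participant_trials))
    per_participant_trials <- list(per_participant_trials)
  pooled <- do.call(rbind, c(per_participant_trials,
                             list(make.row.names = FALSE)))
  key <- paste(pooled$participant, pooled$session, pooled$block,
               pooled$trial_in_block, sep = "\r")
  if (anyDuplicated(key) > 0L)
    stopf("duplicate (participant, session, block, trial) keys in pooled data")
  pooled
}
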