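#' Specify a balanced factorial gap-paradigm design
#'
#' Describes one experiment of the urgent-response gap paradigm: every block
#' crosses fixation duration, gap duration, target direction and congruency,
#' and each session contains `blocks_per_session` such blocks. The defaults
#' reproduce the spatial-Stroop / flanker design: 3 fixation durations x 11
#' gap durations x 2 directions x 2 congruency levels = 132 trials per block,
#' 9 blocks per session (1188 trials), 5 sessions (5940 trials per
#' participant).
#'
#' @param fixation_durations_ms Integer vector of fixation durations (ms),
#'   strictly increasing, values >= 0.
#' @param gap_durations_ms Integer vector of gap durations between go-signal
#'   and target onset (ms), strictly increasing, values >= 0.
#' @param target_directions Character vector, a subset of
#'   `c("left", "right")`.
#' @param congruency_levels Character vector, a subset of
#'   `c("congruent", "incongruent")`.
#' @param blocks_per_session,sessions Positive integers.
#' @param task `"spatial_stroop"` or `"flanker"`; a label only, the analysis
#'   is identical for both conflict types.
#' @return An object of class `design_spec`.
#' @seealso [build_design()]
#' @export
design_spec <- function(fixation_durations_ms = c(350L, 400L, 500L),
                        gap_durations_ms = c(0L, seq(100L, 900L, by = 100L), 950L),
                        target_directions = c("left", "right"),
                        congruency_levels = c("congruent", "incongruent"),
                        blocks_per_session = 9L,
                        sessions = 5L,
                        task = c("spatial_stroop", "flanker")) {
  task <- match.arg(task)
  check_durations <- function(x, name) {
    if (length(x) == 0L) stopf("%s must be non-empty", name)
    if (any(!is.finite(x)) || any(x < 0)) stopf("%s must be finite and >= 0", name)
    if (length(x) > 1L && any(diff(x) <= 0)) stopf("%s must be strictly increasing", name)
  }
  check_durations(fixation_durations_ms, "fixation_durations_ms")
  check_durations(gap_durations_ms, "gap_durations_ms")
  if (length(target_directions) == 0L ||
      !all(target_directions %in% c("left", "right")))
    stopf("target_directions must be a non-empty subset of {left, right}")
  if (length(congruency_levels) == 0L ||
      !all(congruency_levels %in% c("congruent", "incongruent")))
    stopf("congruency_levels must be a non-empty subset of {congruent, incongruent}")
  if (!is_count(blocks_per_session)) stopf("blocks_per_session must be a positive integer")
  if (!is_count(sessions)) stopf("sessions must be a positive integer")
  structure(
    list(fixation_durations_ms = as.integer(fixation_durations_ms),
         gap_durations_ms = as.integer(gap_durations_ms),
         target_directions = unique(target_directions),
         congruency_levels = unique(congruency_levels),
         blocks_per_session = as.integer(blocks_per_session),
         sessions = as.integer(sessions),
         task = task),
    class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  n_comb <- length(x$fixation_durations_ms) * length(x$gap_durations_ms) *
    length(x$target_directions) * length(x$congruency_levels)
  cat(sprintf("Gap-paradigm design (%s)\n", x$task))
  cat(sprintf("  fixation: %s ms\n", paste(x$fixation_durations_ms, collapse = ", ")))
  cat(sprintf("  gaps:     %s ms\n", paste(x$gap_durations_ms, collapse = ", ")))
  cat(sprintf("  %d factor combinations x %d blocks x %d sessions = %d trials\n",
              n_comb, x$blocks_per_session, x$sessions,
              n_comb * x$blocks_per_session * x$sessions))
  invisible(x)
}

design_crossing <- function(spec) {
  expand.grid(fixation_ms = spec$fixation_durations_ms,
              gap_ms = spec$gap_durations_ms,
              target_direction = spec$target_directions,
              congruency = spec$congruency_levels,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Build the randomized trial sequence of a factorial design
#'
#' Expands a [design_spec()] into an ordered trial table. By default each
#' block holds exactly one full crossing of the four factors in
#' seeded-random order, so every combination occurs `blocks_per_session`
#' times per session. With `randomize = "session"` the
#' `blocks_per_session` crossings of a session are shuffled jointly and cut
#' into equally sized blocks, balancing the session but not each block.
#'
#' Response fields (`response`, `rt_ms`, `correct`, `rpt_ms`) are `NA`;
#' [simulate_trials()] fills them in. `prev_congruency` is the congruency of
#' the immediately preceding trial of the same block, `"undefined"` for the
#' first trial of a block (blocks are separated by pauses, so sequence
#' effects are not carried across them).
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed for the trial-order randomization.
#' @param participant Participant identifier stored in every row.
#' @param randomize `"block"` (default) or `"session"` randomization
#'   granularity.
#' @return A `data.frame` with one row per trial and columns `participant`,
#'   `session`, `block`, `trial_in_block`, `fixation_ms`, `gap_ms`,
#'   `congruency`, `target_direction`, `response`, `rt_ms`, `correct`,
#'   `rpt_ms`, `prev_congruency`.
#' @examples
#' d <- build_design(design_spec(sessions = 1L), seed = 1)
#' nrow(d)  # 1188
#' @export
build_design <- function(spec, seed = 1L, participant = "P01",
                         randomize = c("block", "session")) {
  if (!inherits(spec, "design_spec")) stopf("spec must be a design_spec")
  randomize <- match.arg(randomize)
  crossing <- design_crossing(spec)
  n_comb <- nrow(crossing)
  n_block <- spec$blocks_per_session
  with_seed(seed, {
    per_session <- lapply(seq_len(spec$sessions), function(s) {
      if (randomize == "block") {
        rows <- unlist(lapply(seq_len(n_block), function(b)
          sample.int(n_comb)), use.names = FALSE)
      } else {
        rows <- rep(seq_len(n_comb), n_block)
        rows <- rows[sample.int(length(rows))]
      }
      out <- crossing[rows, , drop = FALSE]
      out$session <- s
      out$block <- rep(seq_len(n_block), each = n_comb)
      out$trial_in_block <- rep(seq_len(n_comb), times = n_block)
      out
    })
    trials <- do.call(rbind, per_session)
  })
  rownames(trials) <- NULL
  trials$participant <- participant
  trials$response <- NA_character_
  trials$rt_ms <- NA_real_
  trials$correct <- NA
  trials$rpt_ms <- NA_real_
  trials$prev_congruency <- ifelse(
    trials$trial_in_block == 1L, "undefined",
    c("undefined", trials$congruency[-nrow(trials)]))
  trials[, c("participant", "session", "block", "trial_in_block",
             "fixation_ms", "gap_ms", "congruency", "target_direction",
             "response", "rt_ms", "correct", "rpt_ms", "prev_congruency")]
}

#' Check factorial balance of a trial table
#'
#' Counts every combination of fixation duration, gap duration, target
#' direction and congruency within each block and session and flags
#' imbalance (unequal counts within a block, or counts differing between
#' sessions).
#'
#' @param trials A trial table as returned by [build_design()].
#' @return A `balance_report` list with elements `per_block` (count table),
#'   `per_session`, `block_balanced`, `session_balanced`, `balanced`.
#' @export
validate_balance <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    stopf("trials must be a non-empty data.frame")
  combo <- interaction(trials$fixation_ms, trials$gap_ms,
                       trials$target_direction, trials$congruency,
                       drop = FALSE, sep = "/")
  per_block <- table(combo,
                     block = interaction(trials$participant, trials$session,
                                         trials$block, sep = "/"))
  per_session <- table(combo,
                       session = interaction(trials$participant,
                                             trials$session, sep = "/"))
  block_balanced <- all(apply(per_block, 2L, function(x) length(unique(x)) == 1L))
  session_balanced <- ncol(per_session) < 2L ||
    all(apply(per_session, 1L, function(x) length(unique(x)) == 1L))
  structure(list(per_block = per_block,
                 per_session = per_session,
                 block_balanced = block_balanced,
                 session_balanced = session_balanced,
                 balanced = block_balanced && session_balanced),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("Balance report: %s\n",
              if (x$balanced) "balanced" else "IMBALANCED"))
  cat(sprintf("  within blocks:   %s\n",
              if (x$block_balanced) "equal counts" else "unequal counts"))
  cat(sprintf("  across sessions: %s\n",
              if (x$session_balanced) "equal counts" else "unequal counts"))
  invisible(x)
}
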