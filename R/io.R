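trial_columns <- c("participant", "session", "block", "trial_in_block",
                   "fixation_ms", "gap_ms", "congruency", "target_direction",
                   "response", "rt_ms", "correct", "rpt_ms", "prev_congruency")

#' Write a trial table to CSV
#'
#' Comma-separated, UTF-8, header row, `.` decimal separator, empty string
#' for missing values. Real-valued columns are written with 17 significant
#' digits so that `read_trials(write_trials(x))` restores them exactly.
#'
#' @param trials Trial table (see [build_design()] for the schema).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols) > 0L)
    stopf("trials is missing column(s): %s", paste(missing_cols, collapse = ", "))
  out <- trials[, trial_columns]
  for (col in c("rt_ms", "rpt_ms")) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
  }
  out$correct <- ifelse(is.na(out$correct), "",
                        ifelse(out$correct, "TRUE", "FALSE"))
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Reads a CSV in the schema written by [write_trials()] and validates it:
#' all required columns must be present, enumerated columns must only hold
#' their documented levels, gap durations must be non-negative, and the
#' derived columns are recomputed and checked. `rpt_ms` must equal
#' `rt_ms - gap_ms`; with `strict = TRUE` a mismatch is an error, otherwise
#' a warning is raised and the recomputed value is used. A missing `rpt_ms`
#' or `prev_congruency` column is filled in silently.
#'
#' @param path CSV file path.
#' @param strict Error (default) or warn-and-recompute on inconsistent
#'   derived fields.
#' @return A trial table `data.frame`.
#' @export
read_trials <- function(path, strict = TRUE) {
  if (!file.exists(path)) stopf("trial table '%s' does not exist", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  fileEncoding = "UTF-8")
  required <- setdiff(trial_columns, c("rpt_ms", "prev_congruency"))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L)
    stopf("%s: missing required column(s): %s", path,
          paste(missing_cols, collapse = ", "))

  check_enum <- function(col, levels, allow_na = FALSE) {
    v <- raw[[col]]
    bad <- which(!(v %in% levels) & !(allow_na & is.na(v)))
    if (length(bad) > 0L)
      stopf("%s: row %d, column %s: unparsable value '%s'", path, bad[1L],
            col, as.character(v[bad[1L]]))
  }
  check_enum("congruency", c("congruent", "incongruent"))
  check_enum("target_direction", c("left", "right"))
  check_enum("response", c("left", "right", "none"), allow_na = TRUE)
  if ("prev_congruency" %in% names(raw))
    check_enum("prev_congruency", c("congruent", "incongruent", "undefined"))

  for (col in c("session", "block", "trial_in_block", "fixation_ms", "gap_ms"))
    if (!is.numeric(raw[[col]]))
      stopf("%s: column %s is not numeric", path, col)
  bad_gap <- which(raw$gap_ms < 0)
  if (length(bad_gap) > 0L)
    stopf("%s: row %d, column gap_ms: negative gap duration", path, bad_gap[1L])

  raw$rt_ms <- as.numeric(raw$rt_ms)
  raw$correct <- as.logical(raw$correct)

  # derived: rpt_ms
  rpt_new <- ifelse(is.na(raw$response) | raw$response == "none",
                    NA_real_, raw$rt_ms - raw$gap_ms)
  if ("rpt_ms" %in% names(raw)) {
    raw$rpt_ms <- as.numeric(raw$rpt_ms)
    mism <- which(xor(is.na(raw$rpt_ms), is.na(rpt_new)) |
                    (!is.na(raw$rpt_ms) & !is.na(rpt_new) &
                       raw$rpt_ms != rpt_new))
    if (length(mism) > 0L) {
      msg <- sprintf("%s: row %d, column rpt_ms: stored value inconsistent with rt_ms - gap_ms",
                     path, mism[1L])
      if (strict) stop(msg, call. = FALSE)
      warning(paste0(msg, "; recomputed"), call. = FALSE)
    }
  }
  raw$rpt_ms <- rpt_new

  # derived: correct consistency with response/target
  responded <- !is.na(raw$response) & raw$response != "none"
  corr_new <- ifelse(responded, raw$response == raw$target_direction, NA)
  mism <- which(responded & (is.na(raw$correct) | raw$correct != corr_new))
  if (length(mism) > 0L) {
    msg <- sprintf("%s: row %d, column correct: inconsistent with response and target_direction",
                   path, mism[1L])
    if (strict) stop(msg, call. = FALSE)
    warning(paste0(msg, "; recomputed"), call. = FALSE)
  }
  raw$correct <- corr_new

  if (!("prev_congruency" %in% names(raw)))
    raw$prev_congruency <- ifelse(
      raw$trial_in_block == 1L, "undefined",
      c("undefined", raw$congruency[-nrow(raw)]))

  raw[, trial_columns]
}
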