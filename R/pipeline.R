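#' Configure an end-to-end analysis run
#'
#' Bundles every choice of a full analysis: where trials come from
#' (simulated from a design + generator, or ingested from a CSV), the
#' tachometric estimation options, and the resampling effort. All random
#' seeds are derived from `seed`, so a run is reproducible from its config
#' alone.
#'
#' @param mode `"simulate"` or `"ingest"`.
#' @param design A [design_spec()] (simulate mode).
#' @param generator A [generator_config()] (simulate mode).
#' @param input_path Trial-table CSV (ingest mode).
#' @param n_participants Number of simulated participants pooled into the
#'   aggregate dataset (simulate mode).
#' @param span,chance,rpt_range,bin_step,bin_width,min_trials,degree,window
#'   Tachometric options, see [tachometric()] and [min_drop()].
#' @param shift_levels Performance levels for [shift_estimate()].
#' @param n_permutations,n_bootstrap Resampling effort. Defaults (500 / 200)
#'   are scaled for routine runs; the study-scale analysis uses 2000 / 1000.
#' @param seed Master seed.
#' @param out_dir Output directory for the report bundle, or `NULL` to run
#'   in memory only.
#' @param write_plots Also write a tachometric-curve PNG (requires
#'   `out_dir`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "ingest"),
                       design = design_spec(),
                       generator = generator_config(),
                       input_path = NULL,
                       n_participants = 6L,
                       span = 0.2, chance = 0.5, rpt_range = c(-200, 1000),
                       bin_step = 1, bin_width = 1, min_trials = 200,
                       degree = 2, window = NULL,
                       shift_levels = c(0.6, 0.7, 0.8, 0.9),
                       n_permutations = 500L, n_bootstrap = 200L,
                       seed = 1L, out_dir = NULL, write_plots = FALSE) {
  mode <- match.arg(mode)
  if (mode == "simulate") {
    if (!inherits(design, "design_spec")) stopf("design must be a design_spec")
    if (!inherits(generator, "generator_config"))
      stopf("generator must be a generator_config")
    if (!is_count(n_participants)) stopf("n_participants must be >= 1")
  } else {
    if (is.null(input_path)) stopf("ingest mode requires input_path")
  }
  if (!is_count(n_permutations) || !is_count(n_bootstrap))
    stopf("n_permutations and n_bootstrap must be positive integers")
  structure(list(mode = mode, design = design, generator = generator,
                 input_path = input_path,
                 n_participants = as.integer(n_participants),
                 span = span, chance = chance, rpt_range = rpt_range,
                 bin_step = bin_step, bin_width = bin_width,
                 min_trials = min_trials, degree = degree, window = window,
                 shift_levels = shift_levels,
                 n_permutations = as.integer(n_permutations),
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed), out_dir = out_dir,
                 write_plots = isTRUE(write_plots)),
            class = "run_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full tachometric analysis pipeline
#'
#' Simulates (or ingests) the pooled trial table, estimates the congruent
#' and incongruent tachometric functions, extracts the maximum drops below
#' chance and the rightward shift, runs the congruency and trial-sequence
#' permutation tests, attaches bootstrap standard errors, and (when
#' `out_dir` is set) writes a reproducible report bundle: `trials.csv`,
#' `curve_congruent.csv`, `curve_incongruent.csv`, `statistics.json`
#' (versioned schema) and `run_log.txt` with versions, seeds and the full
#' config echo. With the same config and seed the statistics JSON is
#' byte-identical across runs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `trials`, `curves` (congruent,
#'   incongruent), `statistics` (the JSON content as a list), `tests`
#'   (permutation_result objects) and `paths` (written files, if any).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stopf("config must be a run_config")
  base_seed <- config$seed

  trials <- pipeline_stage("data", {
    if (config$mode == "simulate") {
      per_part <- lapply(seq_len(config$n_participants), function(p) {
        d <- build_design(config$design, seed = base_seed + 1000L + p,
                          participant = sprintf("P%02d", p))
        simulate_trials(d, config$generator, seed = base_seed + 2000L + p)
      })
      pool_aggregate(per_part)
    } else {
      read_trials(config$input_path)
    }
  })

  trials <- compute_rpt(trials)
  flt <- pipeline_stage("rpt_filter",
                        filter_rpt(trials, config$rpt_range[1L],
                                   config$rpt_range[2L]))

  tach_opts <- function(label, subset)
    tachometric(trials, subset = subset, condition_label = label,
                span = config$span, chance = config$chance,
                rpt_range = config$rpt_range, bin_step = config$bin_step,
                bin_width = config$bin_width, min_trials = config$min_trials,
                degree = config$degree)
  curves <- pipeline_stage("tachometric", list(
    congruent = tach_opts("congruent", trials$congruency == "congruent"),
    incongruent = tach_opts("incongruent",
                            trials$congruency == "incongruent")))

  dips <- lapply(curves, min_drop, chance = config$chance,
                 window = config$window)
  shift_ms <- pipeline_stage("shift",
                             shift_estimate(curves$congruent,
                                            curves$incongruent,
                                            levels = config$shift_levels))

  eff_opts <- list(span = config$span, chance = config$chance,
                   rpt_range = config$rpt_range, bin_step = config$bin_step,
                   bin_width = config$bin_width,
                   min_trials = config$min_trials, degree = config$degree,
                   window = config$window)
  cong_fn <- function(tr) do.call(congruency_effect, c(list(tr), eff_opts))
  seq_fn <- function(tr) do.call(sequence_effect, c(list(tr), eff_opts))

  tests <- pipeline_stage("permutation", list(
    congruency = permutation_test(trials, cong_fn, "congruency",
                                  n_permutations = config$n_permutations,
                                  seed = base_seed + 11L,
                                  effect_name = "congruency effect"),
    sequence = permutation_test(
      trials, seq_fn, "prev_congruency",
      n_permutations = config$n_permutations, seed = base_seed + 12L,
      subset = trials$congruency == "incongruent",
      effect_name = "sequence effect")))

  boot <- pipeline_stage("bootstrap", {
    min_stat <- function(lab) function(tr) {
      tr <- compute_rpt(tr)
      f <- filter_rpt(tr, config$rpt_range[1L], config$rpt_range[2L])$trials
      sel <- f$congruency == lab
      config$chance - cond_min_value(f$rpt_ms[sel], f$correct[sel],
                                     config$span, config$rpt_range,
                                     config$bin_step, config$bin_width,
                                     config$degree, config$window)
    }
    list(drop_congruent = bootstrap_se(trials, min_stat("congruent"),
                                       n_replicates = config$n_bootstrap,
                                       seed = base_seed + 21L),
         drop_incongruent = bootstrap_se(trials, min_stat("incongruent"),
                                         n_replicates = config$n_bootstrap,
                                         seed = base_seed + 22L),
         congruency_effect = bootstrap_se(trials, cong_fn,
                                          n_replicates = config$n_bootstrap,
                                          seed = base_seed + 23L))
  })

  statistics <- list(
    schema_version = "1.0",
    n_trials_total = flt$n_total,
    n_trials_analysed = flt$n_total - flt$n_excluded,
    exclusion_fraction = flt$exclusion_fraction,
    chance = config$chance,
    min_drop = lapply(dips, function(d)
      list(min_value = d$min_value, min_rpt_ms = d$min_rpt_ms,
           drop_below_chance = d$drop_below_chance,
           search_window_ms = d$search_window_ms)),
    congruency = list(observed_effect = tests$congruency$observed_effect,
                      p_value = tests$congruency$p_value,
                      n_permutations = tests$congruency$n_permutations,
                      seed = tests$congruency$seed),
    sequence = list(observed_effect = tests$sequence$observed_effect,
                    p_value = tests$sequence$p_value,
                    n_permutations = tests$sequence$n_permutations,
                    seed = tests$sequence$seed),
    shift_ms = shift_ms,
    bootstrap = list(
      drop_congruent_se = boot$drop_congruent$se,
      drop_incongruent_se = boot$drop_incongruent$se,
      congruency_effect_se = boot$congruency_effect$se,
      n_replicates = config$n_bootstrap,
      seeds = c(base_seed + 21L, base_seed + 22L, base_seed + 23L)),
    master_seed = base_seed)

  paths <- list()
  if (!is.null(config$out_dir)) {
    paths <- pipeline_stage("report", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      p <- list(trials = file.path(config$out_dir, "trials.csv"),
                statistics = file.path(config$out_dir, "statistics.json"),
                log = file.path(config$out_dir, "run_log.txt"))
      write_trials(trials, p$trials)
      for (lab in names(curves)) {
        cp <- file.path(config$out_dir, sprintf("curve_%s.csv", lab))
        cv <- curves[[lab]]
        utils::write.csv(data.frame(grid_ms = cv$grid_ms,
                                    raw_mean = cv$raw_mean,
                                    raw_n = cv$raw_n,
                                    smooth = cv$smooth),
                         cp, row.names = FALSE, na = "")
        p[[paste0("curve_", lab)]] <- cp
      }
      jsonlite::write_json(statistics, p$statistics, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      log_lines <- c(
        sprintf("urgetach %s | R %s.%s | run at %s",
                as.character(utils::packageVersion("urgetach")),
                R.version$major, R.version$minor,
                format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
        sprintf("mode: %s", config$mode),
        sprintf("master seed: %d", base_seed),
        sprintf("derived seeds: permutation %d/%d, bootstrap %d/%d/%d",
                base_seed + 11L, base_seed + 12L, base_seed + 21L,
                base_seed + 22L, base_seed + 23L),
        "config echo:",
        utils::capture.output(utils::str(unclass(config))))
      writeLines(log_lines, p$log)
      if (config$write_plots) {
        p$plot <- file.path(config$out_dir, "curves.png")
        grDevices::png(p$plot, width = 900, height = 600)
        plot(curves$congruent, col = "forestgreen",
             main = "Tachometric functions")
        plot(curves$incongruent, add = TRUE, col = "firebrick")
        graphics::legend("bottomright", legend = names(curves),
                         col = c("forestgreen", "firebrick"), lwd = 2)
        grDevices::dev.off()
      }
      p
    })
  }

  invisible(list(trials = trials, curves = curves, statistics = statistics,
                 tests = tests, bootstrap = boot, paths = paths))
}
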