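# Shared simulated datasets, built once per test run and cached. Sizes are
# chosen so the whole suite stays well inside a routine run while the
# resampling checks keep enough resolution to be meaningful.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

# ~23,760 pooled trials (4 simulated participants x 5,940), default generator
default_pooled <- function() cached("pooled_default", {
  pool_aggregate(lapply(1:4, function(p)
    simulate_trials(build_design(design_spec(), seed = p,
                                 participant = sprintf("P%02d", p)),
                    generator_config(), seed = 100 + p)))
})

default_curves <- function() cached("curves_default", {
  tr <- default_pooled()
  list(congruent = tachometric(tr, tr$congruency == "congruent",
                               condition_label = "congruent"),
       incongruent = tachometric(tr, tr$congruency == "incongruent",
                                 condition_label = "incongruent"))
})

# generator with no congruency structure at all (no shift, no dip)
null_generator <- function(seed = 1L)
  generator_config(incong_shift_ms = 0, dip_depth_prev_congruent = 0,
                   dip_depth_prev_incongruent = 0, seed = seed)

# one ~5,016-trial null dataset (38 blocks of the full factorial crossing)
null_dataset <- function(seed) {
  spec <- design_spec(blocks_per_session = 38L, sessions = 1L)
  simulate_trials(build_design(spec, seed = 3000 + seed),
                  null_generator(), seed = 5000 + seed)
}

# minimal hand-built trial table for unit-level checks
toy_trials <- function(rpt, correct = TRUE, congruency = "congruent") {
  n <- length(rpt)
  data.frame(participant = "P01", session = 1L, block = 1L,
             trial_in_block = seq_len(n), fixation_ms = 400L,
             gap_ms = 0L, congruency = rep_len(congruency, n),
             target_direction = "left",
             response = ifelse(rep_len(correct, n), "left", "right"),
             rt_ms = rpt, correct = rep_len(correct, n), rpt_ms = rpt,
             prev_congruency = "undefined")
}

# p-values of the congruency permutation test on 200 independent null
# datasets, 500 permutations each; feeds both the type-I calibration and the
# uniformity check
null_calibration_pvalues <- function() cached("null_pvalues", {
  vapply(1:200, function(i)
    permutation_test(null_dataset(i), congruency_effect, "congruency",
                     n_permutations = 500, seed = 7000 + i)$p_value,
    numeric(1L))
})
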