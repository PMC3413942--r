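# Shared fixture builders (all in code; nothing on disk).

# Observed RRD trial in one call.
sim_rrd_trial <- function(params, n_subjects, n_periods, seed,
                          scheme = "constrained") {
  po <- simulate_potential_outcomes(params, n_subjects, n_periods, seed = seed)
  sch <- suppressMessages(build_schedule("rrd", n_subjects, n_periods,
                                         scheme = scheme, seed = seed + 1L))
  observe(po, sch)
}

# Hand-built trial from explicit records.
trial_from <- function(subject_id, period, arm, outcome) {
  as_rrd_trial(data.frame(subject_id = subject_id, period = period,
                          arm = arm, outcome = outcome))
}

# The worked example: one subject who shows 0 kg change on treatment while
# their control periods show +0.5 kg gain.
worked_example_trial <- function() {
  trial_from(subject_id = rep(1L, 4), period = 1:4,
             arm = c("T", "C", "T", "C"),
             outcome = c(0, 0.5, 0, 0.5))
}
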