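#' Build an allocation schedule for a trial design
#'
#' Constructs the per-subject, per-period treatment indicators for four
#' designs:
#'
#' * `"pgd"` — parallel groups: one baseline randomization, each subject
#'   stays on the same arm for all `p` periods (balanced across arms).
#' * `"crossover2"` — two-period crossover: sequences TC and CT, balanced;
#'   requires `n_periods = 2`.
#' * `"balaam"` — Balaam design: sequences TT, TC, CT, CC, balanced;
#'   requires `n_periods = 2`.
#' * `"rrd"` — repeated randomizations: every subject is re-randomized at
#'   every period. With `scheme = "unconstrained"` each cell is an
#'   independent fair coin flip; with `scheme = "constrained"` each subject
#'   receives exactly `p/2` treatment periods in uniformly random order
#'   (requires even `p`).
#'
#' The Balaam design is exactly the unconstrained RRD with `p = 2`.
#' "Balanced" sequence assignment for pgd/crossover2/balaam fills equal
#' blocks of each sequence and assigns any remainder at random.
#'
#' Constrained schedules carry a practical caveat: in an unblinded study a
#' subject who has used up one arm's allocation can predict the remaining
#' periods. The builder signals this once per call as a message of class
#' `rrd_predictability_note` (it never refuses to build the schedule).
#'
#' @param design_kind One of `"pgd"`, `"crossover2"`, `"balaam"`, `"rrd"`.
#' @param n_subjects Number of subjects (>= 1).
#' @param n_periods Number of periods (2 for crossover2/balaam).
#' @param scheme `"unconstrained"` (default) or `"constrained"`; only
#'   meaningful for `"rrd"`.
#' @param seed Integer seed.
#' @return A tibble of class `rrd_schedule` with columns `subject_id`,
#'   `period` and `treated` (0/1), plus design metadata in attributes.
#' @examples
#' # every subject guaranteed treatment in exactly 12 of 24 periods:
#' sch <- suppressMessages(
#'   build_schedule("rrd", 10, 24, scheme = "constrained", seed = 1)
#' )
#' schedule_counts(sch)
#' @export
build_schedule <- function(design_kind = c("pgd", "crossover2", "balaam", "rrd"),
                           n_subjects, n_periods,
                           scheme = c("unconstrained", "constrained"),
                           seed = 1L) {
  design_kind <- match.arg(design_kind)
  scheme <- match.arg(scheme)
  stopifnot(n_subjects >= 1, n_periods >= 1)
  if (design_kind %in% c("crossover2", "balaam") && n_periods != 2) {
    rlang::abort(sprintf("%s requires n_periods = 2", design_kind),
                 class = "rrd_config_error")
  }
  if (design_kind == "rrd" && scheme == "constrained" && n_periods %% 2 != 0) {
    rlang::abort("constrained allocation requires an even number of periods",
                 class = "rrd_config_error")
  }
  set.seed(as.integer(seed))

  x <- switch(
    design_kind,
    pgd = {
      arms <- balanced_sequences(n_subjects, list(1L, 0L))
      matrix(rep(arms, n_periods), nrow = n_subjects)
    },
    crossover2 = {
      seqs <- balanced_sequences(n_subjects, list(c(1L, 0L), c(0L, 1L)))
      do.call(rbind, seqs)
    },
    balaam = {
      seqs <- balanced_sequences(
        n_subjects, list(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L)))
      do.call(rbind, seqs)
    },
    rrd = {
      if (scheme == "unconstrained") {
        matrix(sample(0:1, n_subjects * n_periods, replace = TRUE),
               nrow = n_subjects)
      } else {
        rlang::inform(
          "constrained allocation: late-trial assignments become predictable if blinding fails",
          class = "rrd_predictability_note")
        base <- rep(c(1L, 0L), each = n_periods / 2)
        t(vapply(seq_len(n_subjects), function(i) sample(base),
                 integer(n_periods)))
      }
    }
  )

  sch <- tidyr::expand_grid(subject_id = seq_len(n_subjects),
                            period = seq_len(n_periods)) |>
    dplyr::mutate(treated = as.integer(x[cbind(.data$subject_id, .data$period)]))

  structure(
    sch,
    design_kind = design_kind,
    scheme = scheme,
    seed = as.integer(seed),
    n_subjects = as.integer(n_subjects),
    n_periods = as.integer(n_periods),
    class = c("rrd_schedule", class(sch))
  )
}

# assign each subject one of `choices` (sequences), equal blocks, remainder
# assigned at random; order of subjects then shuffled
balanced_sequences <- function(n_subjects, choices) {
  k <- length(choices)
  idx <- rep(seq_len(k), length.out = k * ceiling(n_subjects / k))
  idx <- sample(idx)[seq_len(n_subjects)]
  lapply(idx, function(i) choices[[i]])
}

#' Per-subject treatment and control period counts
#'
#' @param schedule A [build_schedule()] result.
#' @return A tibble with columns `subject_id`, `n_treat`, `n_control`;
#'   `n_treat + n_control = p` for every subject.
#' @export
schedule_counts <- function(schedule) {
  stopifnot(inherits(schedule, "rrd_schedule"))
  tibble::as_tibble(schedule) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_treat = sum(.data$treated),
                     n_control = sum(1L - .data$treated),
                     .groups = "drop")
}

#' Probability of a single-arm sequence
#'
#' Probability that one subject receives only one arm for the whole trial.
#' Under the unconstrained RRD each of the `p` randomizations is a fair coin,
#' so
#' \deqn{P = (1/2)^p + (1/2)^p = (1/2)^{p-1},}
#' which vanishes as `p` grows — the property that motivates the design from
#' the participant's point of view. Constrained allocation makes it exactly 0
#' for `p >= 2`. In a parallel-groups design every subject is single-arm by
#' construction (probability 1), and the chance of the *control-only*
#' sequence specifically is 1/2. The two-period crossover always delivers
#' both arms.
#'
#' @param design_kind One of `"pgd"`, `"crossover2"`, `"balaam"`, `"rrd"`.
#' @param n_periods Number of periods (>= 1).
#' @param scheme `"unconstrained"` or `"constrained"` (rrd only).
#' @param arm `"either"` (default): only-treatment or only-control;
#'   `"control"` / `"treatment"`: that single-arm sequence alone.
#' @return A probability.
#' @examples
#' prob_single_arm("rrd", 10)           # (1/2)^9
#' prob_single_arm("pgd", 24, arm = "control")  # 0.5
#' @export
prob_single_arm <- function(design_kind = c("pgd", "crossover2", "balaam", "rrd"),
                            n_periods,
                            scheme = c("unconstrained", "constrained"),
                            arm = c("either", "control", "treatment")) {
  design_kind <- match.arg(design_kind)
  scheme <- match.arg(scheme)
  arm <- match.arg(arm)
  stopifnot(n_periods >= 1)
  p_one_arm <- switch(
    design_kind,
    pgd = 0.5,
    crossover2 = 0,
    balaam = 0.25,
    rrd = if (scheme == "constrained" && n_periods >= 2) 0
          else 0.5^n_periods
  )
  if (arm == "either") 2 * p_one_arm else p_one_arm
}
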