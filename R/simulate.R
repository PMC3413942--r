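#' Simulate counterfactual (potential) outcomes for every subject and period
#'
#' Generates both counterfactual weight changes for each subject-period cell:
#' the outcome had the subject been treated that period and the outcome had
#' they been on control, under the linear mixed model described in
#' [trial_params()]. Because the residual \eqn{e_{ij}} is shared by the two
#' counterfactuals of a cell, the per-period causal difference is exactly
#' \eqn{D_i = \tau + b_i} for every period: the treatment response is a
#' subject-level quantity, which is what makes its variance (the TRH) a single
#' identified variance component.
#'
#' The stored counterfactual tables exclude carryover; [observe()] adds the
#' \eqn{\gamma} term from the *realized* treatment sequence, since carryover
#' depends on which arm was actually experienced in the previous period.
#'
#' @param params A [trial_params()] object.
#' @param n_subjects Number of subjects \eqn{N} (>= 1).
#' @param n_periods Number of treatment periods \eqn{p} (>= 1).
#' @param seed Integer seed; every random draw flows from it.
#'
#' @return A tibble of class `rrd_potential_outcomes` with one row per
#'   subject-period and columns `subject_id`, `period`, `y_control`, `y_treat`
#'   (kg) and `d_true` (the subject's causal response \eqn{D_i}, constant
#'   across that subject's rows). The generating `params` are kept in an
#'   attribute.
#' @examples
#' po <- simulate_potential_outcomes(
#'   trial_params(mu = -1, tau = -0.5, sigma2_trh = 0.25, sigma2_resid = 1),
#'   n_subjects = 4, n_periods = 6, seed = 1
#' )
#' po
#' @seealso [observe()], [true_effects()], [build_schedule()]
#' @export
simulate_potential_outcomes <- function(params, n_subjects, n_periods, seed) {
  stopifnot(inherits(params, "trial_params"),
            n_subjects >= 1, n_periods >= 1)
  pe <- period_effects_for(params, n_periods)
  set.seed(as.integer(seed))

  a <- stats::rnorm(n_subjects, 0, sqrt(params$sigma2_subject))
  b <- stats::rnorm(n_subjects, 0, sqrt(params$sigma2_trh))
  e <- matrix(stats::rnorm(n_subjects * n_periods, 0, sqrt(params$sigma2_resid)),
              nrow = n_subjects, ncol = n_periods)
  d_i <- params$tau + b

  po <- tidyr::expand_grid(subject_id = seq_len(n_subjects),
                           period = seq_len(n_periods)) |>
    dplyr::mutate(
      y_control = params$mu + pe[.data$period] + a[.data$subject_id] +
        e[cbind(.data$subject_id, .data$period)],
      y_treat = .data$y_control + d_i[.data$subject_id],
      d_true = d_i[.data$subject_id]
    )

  structure(
    po,
    params = params,
    n_subjects = as.integer(n_subjects),
    n_periods = as.integer(n_periods),
    seed = as.integer(seed),
    class = c("rrd_potential_outcomes", class(po))
  )
}

#' True individual treatment responses of a simulated cohort
#'
#' Returns each subject's causal response \eqn{D_i}: the difference between
#' the change they would show under treatment and the change the *same*
#' subject would show under control in the same period. The mean of this
#' column is the realized sample \eqn{\mu_D}. These are the unobservable
#' quantities the estimators target; a real trial never sees them.
#'
#' @param po A [simulate_potential_outcomes()] result.
#' @return A tibble with columns `subject_id` and `d_true` (kg), one row per
#'   subject.
#' @export
true_effects <- function(po) {
  stopifnot(inherits(po, "rrd_potential_outcomes"))
  dplyr::distinct(tibble::as_tibble(po), .data$subject_id, .data$d_true)
}

#' Observe one arm per subject-period according to an allocation schedule
#'
#' Realizes the fundamental problem of causal inference: for each
#' subject-period cell exactly one of the two counterfactual outcomes is
#' recorded, chosen by the schedule's treatment indicator. First-order
#' carryover is recomputed from the realized sequence: \eqn{\gamma} is added
#' to a period's outcome whenever the subject was treated in the previous
#' period.
#'
#' @param po A [simulate_potential_outcomes()] result.
#' @param schedule A [build_schedule()] result with matching dimensions.
#' @return A tibble of class `rrd_trial` with columns `subject_id`, `period`,
#'   `arm` (`"T"` or `"C"`) and `outcome` (kg).
#' @examples
#' po <- simulate_potential_outcomes(trial_params(tau = -0.5), 6, 4, seed = 2)
#' sch <- build_schedule("rrd", 6, 4, scheme = "constrained", seed = 3)
#' observe(po, sch)
#' @export
observe <- function(po, schedule) {
  stopifnot(inherits(po, "rrd_potential_outcomes"),
            inherits(schedule, "rrd_schedule"))
  if (attr(po, "n_subjects") != attr(schedule, "n_subjects") ||
      attr(po, "n_periods") != attr(schedule, "n_periods")) {
    rlang::abort("schedule dimensions do not match the potential outcomes",
                 class = "rrd_dimension_error")
  }
  gamma <- attr(po, "params")$carryover

  trial <- tibble::as_tibble(po) |>
    dplyr::inner_join(tibble::as_tibble(schedule),
                      by = c("subject_id", "period")) |>
    dplyr::arrange(.data$subject_id, .data$period) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(
      prev_treated = dplyr::lag(.data$treated, default = 0L),
      outcome = ifelse(.data$treated == 1L, .data$y_treat, .data$y_control) +
        gamma * .data$prev_treated,
      arm = ifelse(.data$treated == 1L, "T", "C")
    ) |>
    dplyr::ungroup() |>
    dplyr::select("subject_id", "period", "arm", "outcome")

  new_rrd_trial(trial,
                n_subjects = attr(po, "n_subjects"),
                n_periods = attr(po, "n_periods"),
                design_kind = attr(schedule, "design_kind"))
}

new_rrd_trial <- function(df, n_subjects = NULL, n_periods = NULL,
                          design_kind = NA_character_) {
  df <- tibble::as_tibble(df)
  structure(
    df,
    n_subjects = n_subjects %||% length(unique(df$subject_id)),
    n_periods = n_periods %||% max(df$period),
    design_kind = design_kind,
    class = unique(c("rrd_trial", class(df)))
  )
}

#' Coerce a long-format data frame to an observed-trial table
#'
#' @param x A data frame with columns `subject_id`, `period`, `arm`
#'   (`"T"`/`"C"`) and `outcome`.
#' @return The same data as a validated `rrd_trial` tibble.
#' @export
as_rrd_trial <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("subject_id", "period", "arm", "outcome")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    rlang::abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")),
                 class = "rrd_parse_error")
  }
  if (!all(x$arm %in% c("T", "C"))) {
    rlang::abort("`arm` must be 'T' or 'C'", class = "rrd_parse_error")
  }
  dup <- duplicated(x[c("subject_id", "period")])
  if (any(dup)) {
    k <- x[which(dup)[1L], ]
    rlang::abort(sprintf("duplicate record for subject '%s', period %s",
                         k$subject_id, k$period),
                 class = "rrd_parse_error")
  }
  new_rrd_trial(x[need])
}
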