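#' Estimate each subject's individual mean treatment effect
#'
#' For every subject observed under *both* arms, computes
#' \eqn{\hat d_i = \bar Y_i(T) - \bar Y_i(C)}: the mean of their treated
#' outcomes minus the mean of their control outcomes. This is the quantity a
#' repeated-randomizations trial makes estimable and a parallel-groups trial
#' cannot touch — a PGD subject is only ever observed under one arm, so their
#' individual response has no sample analogue.
#'
#' With `period_adjust = TRUE` (recommended for RRD data) each outcome is
#' first centered by its period's cross-subject mean, removing fixed period
#' effects that randomization balances only in expectation.
#'
#' @param trial An `rrd_trial` tibble (from [observe()], [read_trial_csv()]
#'   or [as_rrd_trial()]).
#' @param period_adjust Subtract per-period cross-subject means first?
#'   Default `TRUE`.
#' @return A tibble with one row per estimable subject: `subject_id`, `d_hat`
#'   (kg), `n_treat`, `n_control`, `std_error` (NA when no within-condition
#'   replication exists). Subjects observed under a single condition are
#'   skipped; their count is in attribute `n_skipped`.
#' @examples
#' trial <- as_rrd_trial(data.frame(
#'   subject_id = 1, period = 1:4,
#'   arm = c("T", "C", "T", "C"),
#'   outcome = c(0, 0.5, 0, 0.5)
#' ))
#' individual_effects(trial, period_adjust = FALSE)  # d_hat = -0.5
#' @export
individual_effects <- function(trial, period_adjust = TRUE) {
  stopifnot(inherits(trial, "rrd_trial"))
  dat <- tibble::as_tibble(trial) |> dplyr::filter(!is.na(.data$outcome))
  if (nrow(dat) == 0L) {
    rlang::abort("trial has no non-missing outcomes", class = "rrd_data_error")
  }
  if (period_adjust) {
    dat <- dat |>
      dplyr::group_by(.data$period) |>
      dplyr::mutate(outcome = .data$outcome - mean(.data$outcome)) |>
      dplyr::ungroup()
  }
  per <- dat |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_treat = sum(.data$arm == "T"),
      n_control = sum(.data$arm == "C"),
      mean_t = mean(.data$outcome[.data$arm == "T"]),
      mean_c = mean(.data$outcome[.data$arm == "C"]),
      var_t = stats::var(.data$outcome[.data$arm == "T"]),
      var_c = stats::var(.data$outcome[.data$arm == "C"]),
      .groups = "drop"
    )
  est <- per |>
    dplyr::filter(.data$n_treat >= 1, .data$n_control >= 1) |>
    dplyr::mutate(
      d_hat = .data$mean_t - .data$mean_c,
      std_error = sqrt(.data$var_t / .data$n_treat +
                         .data$var_c / .data$n_control)
    ) |>
    dplyr::select("subject_id", "d_hat", "n_treat", "n_control", "std_error")
  n_skipped <- nrow(per) - nrow(est)
  if (nrow(est) == 0L) {
    rlang::abort(
      paste("no subject was observed under both conditions;",
            "individual effects are not estimable in this design",
            "(the parallel-groups degenerate case)"),
      class = "rrd_identifiability_error"
    )
  }
  attr(est, "n_skipped") <- n_skipped
  est
}

#' Pooled within-subject, within-condition residual variance
#'
#' Pools the sample variances of each subject's repeated outcomes under a
#' fixed condition, weighting by degrees of freedom
#' \eqn{\sum_i (p_{T,i} - 1) + \sum_i (p_{C,i} - 1)}. This is what separates
#' residual noise from genuine response heterogeneity.
#'
#' Only subjects observed under *both* conditions contribute: the estimate
#' exists to de-noise those subjects' individual effects, and using the
#' single-arm subjects a Balaam design provides (its TT and CC sequences)
#' would lean on the cross-period homogeneity assumptions the repeated
#' design is meant to avoid. Under this contract the estimate exists only
#' when some dual-condition subject sees the same condition twice — which
#' two-period crossover and Balaam trials never deliver, so for them the
#' TRH cannot be separated from noise.
#'
#' @inheritParams individual_effects
#' @return The pooled variance (kg^2), with the pooled degrees of freedom in
#'   attribute `df`.
#' @export
pooled_residual_variance <- function(trial, period_adjust = TRUE) {
  stopifnot(inherits(trial, "rrd_trial"))
  dat <- tibble::as_tibble(trial) |> dplyr::filter(!is.na(.data$outcome))
  if (period_adjust && nrow(dat) > 0L) {
    dat <- dat |>
      dplyr::group_by(.data$period) |>
      dplyr::mutate(outcome = .data$outcome - mean(.data$outcome)) |>
      dplyr::ungroup()
  }
  cells <- dat |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::filter(dplyr::n_distinct(.data$arm) == 2L) |>
    dplyr::group_by(.data$subject_id, .data$arm) |>
    dplyr::summarise(n = dplyr::n(), v = stats::var(.data$outcome),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= 2L)
  df <- sum(cells$n - 1L)
  if (df == 0L) {
    rlang::abort(
      paste("no subject has repeated observations within one condition, so",
            "residual variance cannot be separated from response",
            "heterogeneity (the two-period crossover / Balaam limitation)"),
      class = "rrd_identifiability_error"
    )
  }
  out <- sum((cells$n - 1L) * cells$v) / df
  attr(out, "df") <- df
  out
}

#' Moment estimator of treatment response heterogeneity
#'
#' Method-of-moments estimator of the TRH variance \eqn{\sigma^2_D}. The
#' between-subject variance of the individual estimates \eqn{\hat d_i}
#' overstates the heterogeneity because each \eqn{\hat d_i} carries sampling
#' noise \eqn{\sigma^2_e (1/p_{T,i} + 1/p_{C,i})}; the estimator removes that
#' mean noise contribution and truncates at zero:
#' \deqn{\hat\sigma^2_D = \max\{0,\; \mathrm{Var}_i(\hat d_i) -
#'   \hat\sigma^2_e \cdot \mathrm{mean}_i(1/p_{T,i} + 1/p_{C,i})\}.}
#'
#' @inheritParams individual_effects
#' @return An object of class `rrd_trh` with elements `mu_d_hat`,
#'   `sigma2_trh_hat` (truncated at 0), `sigma2_trh_raw` (untruncated),
#'   `sigma2_resid_hat`, `method = "moment"`, `n_subjects_used`. Has
#'   [tidy()][generics::tidy] and [glance()][generics::glance] methods.
#' @examples
#' po <- simulate_potential_outcomes(
#'   trial_params(tau = -0.5, sigma2_trh = 4, sigma2_resid = 1),
#'   n_subjects = 200, n_periods = 8, seed = 1
#' )
#' sch <- suppressMessages(
#'   build_schedule("rrd", 200, 8, scheme = "constrained", seed = 2))
#' trh_moment(observe(po, sch))
#' @export
trh_moment <- function(trial, period_adjust = TRUE) {
  eff <- individual_effects(trial, period_adjust = period_adjust)
  if (nrow(eff) < 2L) {
    rlang::abort("need at least two subjects with both conditions",
                 class = "rrd_identifiability_error")
  }
  s2e <- pooled_residual_variance(trial, period_adjust = period_adjust)
  noise <- s2e * mean(1 / eff$n_treat + 1 / eff$n_control)
  raw <- stats::var(eff$d_hat) - noise
  new_rrd_trh(
    mu_d_hat = mean(eff$d_hat),
    sigma2_trh_hat = max(0, raw),
    sigma2_trh_raw = raw,
    sigma2_resid_hat = as.numeric(s2e),
    method = "moment",
    n_subjects_used = nrow(eff)
  )
}

#' Mixed-model (REML) estimator of treatment response heterogeneity
#'
#' Fits a linear mixed model with a random intercept and an independent
#' random treatment slope per subject,
#' `outcome ~ treated + (1 | subject) + (0 + treated | subject)`
#' (plus fixed period effects when `period_adjust = TRUE`), by REML via
#' [lme4::lmer()]. The slope variance is the TRH estimate; the `treated`
#' fixed effect is \eqn{\hat\mu_D}. The intercept-slope correlation is fixed
#' at zero because it is weakly identified at small numbers of periods.
#'
#' @inheritParams individual_effects
#' @return An `rrd_trh` object with `method = "mixed"` and the fitted
#'   [lme4::lmer] model in element `fit`.
#' @export
trh_mixed <- function(trial, period_adjust = TRUE) {
  stopifnot(inherits(trial, "rrd_trial"))
  dat <- tibble::as_tibble(trial) |>
    dplyr::filter(!is.na(.data$outcome)) |>
    dplyr::mutate(treated = as.numeric(.data$arm == "T"),
                  period = factor(.data$period))
  form <- if (period_adjust && nlevels(dat$period) > 1L) {
    outcome ~ treated + period + (1 | subject_id) + (0 + treated | subject_id)
  } else {
    outcome ~ treated + (1 | subject_id) + (0 + treated | subject_id)
  }
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(form, data = dat, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    )),
    error = function(e) {
      rlang::abort(paste0("mixed-model fit failed: ", conditionMessage(e)),
                   class = "rrd_fit_error", parent = e)
    }
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  slope_var <- vc$vcov[vc$grp == "subject_id.1" & vc$var1 == "treated"]
  if (length(slope_var) != 1L) {  # single grouping row naming differs if intercept term dropped
    slope_var <- vc$vcov[vc$var1 == "treated" & !is.na(vc$var1)][1L]
  }
  new_rrd_trh(
    mu_d_hat = unname(lme4::fixef(fit)["treated"]),
    sigma2_trh_hat = slope_var,
    sigma2_trh_raw = slope_var,
    sigma2_resid_hat = vc$vcov[vc$grp == "Residual"],
    method = "mixed",
    n_subjects_used = length(unique(dat$subject_id)),
    fit = fit
  )
}

new_rrd_trh <- function(mu_d_hat, sigma2_trh_hat, sigma2_trh_raw,
                        sigma2_resid_hat, method, n_subjects_used,
                        fit = NULL) {
  structure(
    list(mu_d_hat = mu_d_hat,
         sigma2_trh_hat = sigma2_trh_hat,
         sigma2_trh_raw = sigma2_trh_raw,
         sigma2_resid_hat = sigma2_resid_hat,
         method = method,
         n_subjects_used = n_subjects_used,
         fit = fit),
    class = "rrd_trh"
  )
}

#' @export
print.rrd_trh <- function(x, ...) {
  cat(sprintf("<rrd_trh: %s estimator, %d subjects>\n",
              x$method, x$n_subjects_used))
  cat(sprintf("  mu_D hat:        %8.4f kg\n", x$mu_d_hat))
  cat(sprintf("  TRH (sigma2_D):  %8.4f kg^2\n", x$sigma2_trh_hat))
  cat(sprintf("  residual var:    %8.4f kg^2\n", x$sigma2_resid_hat))
  invisible(x)
}

#' Population mean treatment effect
#'
#' Estimates \eqn{\mu_D}, the average effect of treatment on weight change.
#' When at least one subject is observed under both arms (RRD, crossover),
#' the within-subject route is used: the mean of the \eqn{\hat d_i} with its
#' empirical standard error. Otherwise (parallel groups) the between-arm
#' difference of per-subject mean changes is returned with a two-sample
#' standard error.
#'
#' @inheritParams individual_effects
#' @return A one-row tibble: `estimate` (kg), `std_error`, `method`
#'   (`"within_subject"` or `"between_arm"`), `n_subjects`.
#' @export
mean_effect <- function(trial, period_adjust = TRUE) {
  stopifnot(inherits(trial, "rrd_trial"))
  dat <- tibble::as_tibble(trial) |> dplyr::filter(!is.na(.data$outcome))
  arms_present <- unique(dat$arm)
  if (!all(c("T", "C") %in% arms_present)) {
    rlang::abort("both arms must be observed somewhere in the trial",
                 class = "rrd_data_error")
  }
  both <- dat |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(has_both = dplyr::n_distinct(.data$arm) == 2L,
                     .groups = "drop")
  if (any(both$has_both)) {
    eff <- individual_effects(trial, period_adjust = period_adjust)
    tibble::tibble(
      estimate = mean(eff$d_hat),
      std_error = if (nrow(eff) > 1L)
        stats::sd(eff$d_hat) / sqrt(nrow(eff)) else NA_real_,
      method = "within_subject",
      n_subjects = nrow(eff)
    )
  } else {
    per <- dat |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(arm = .data$arm[1L], m = mean(.data$outcome),
                       .groups = "drop")
    mt <- per$m[per$arm == "T"]; mc <- per$m[per$arm == "C"]
    se <- sqrt((if (length(mt) > 1L) stats::var(mt) / length(mt) else NA_real_) +
                 (if (length(mc) > 1L) stats::var(mc) / length(mc) else NA_real_))
    tibble::tibble(
      estimate = mean(mt) - mean(mc),
      std_error = se,
      method = "between_arm",
      n_subjects = nrow(per)
    )
  }
}

#' Responder proportions under a normal model for individual effects
#'
#' Given estimates of \eqn{\mu_D} and \eqn{\sigma^2_D}, treats the individual
#' response as \eqn{D \sim N(\hat\mu_D, \hat\sigma^2_D)} and reports:
#'
#' * `prop_treat_better` — \eqn{P(D < 0)}: treatment superior for weight loss;
#' * `prop_control_better` — \eqn{P(D > 0)}: the standard/control condition
#'   works better, even if treatment wins on average;
#' * `prop_nonresponder` — \eqn{P(|D| \le \delta)}: subjects whose causal
#'   effect lies within a tolerance band around zero. The half-width `delta`
#'   is an analysis choice with no default: "no response" is only meaningful
#'   relative to a stated equivalence margin.
#'
#' With \eqn{\hat\sigma_D = 0} the distribution is a point mass at
#' \eqn{\hat\mu_D} and indicator values are returned.
#'
#' @param est An `rrd_trh` object, or a list/one-row data frame with
#'   `mu_d_hat` and `sigma2_trh_hat`.
#' @param delta Non-response band half-width (kg), >= 0.
#' @return A one-row tibble of class `rrd_responders`: `delta`,
#'   `prop_nonresponder`, `prop_treat_better`, `prop_control_better`,
#'   `mu_d_hat`, `sigma_d_hat`.
#' @examples
#' responder_proportions(list(mu_d_hat = -1, sigma2_trh_hat = 1), delta = 0.25)
#' @export
responder_proportions <- function(est, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0) {
    rlang::abort("`delta` must be a single non-negative number",
                 class = "rrd_config_error")
  }
  mu <- est$mu_d_hat
  s2 <- est$sigma2_trh_hat
  stopifnot(is.numeric(mu), is.numeric(s2), s2 >= 0)
  if (s2 == 0) {
    out <- tibble::tibble(
      delta = delta,
      prop_nonresponder = as.numeric(abs(mu) <= delta),
      prop_treat_better = as.numeric(mu < 0),
      prop_control_better = as.numeric(mu > 0),
      mu_d_hat = mu, sigma_d_hat = 0
    )
  } else {
    s <- sqrt(s2)
    out <- tibble::tibble(
      delta = delta,
      prop_nonresponder = stats::pnorm((delta - mu) / s) -
        stats::pnorm((-delta - mu) / s),
      prop_treat_better = stats::pnorm(-mu / s),
      prop_control_better = 1 - stats::pnorm(-mu / s),
      mu_d_hat = mu, sigma_d_hat = s
    )
  }
  class(out) <- c("rrd_responders", class(out))
  out
}

#' Empirical (plug-in) responder proportions
#'
#' Same summaries as [responder_proportions()] but computed from the
#' empirical distribution of the individual estimates \eqn{\hat d_i} instead
#' of a fitted normal. Because each \eqn{\hat d_i} carries sampling noise of
#' order \eqn{\sigma^2_e(1/p_T + 1/p_C)}, these proportions are
#' *noise-inflated*: mass near zero leaks outward, so the band proportion is
#' biased downward and the tail proportions upward. Prefer the normal-model
#' version unless the normality assumption itself is in doubt.
#'
#' @param effects A tibble from [individual_effects()] (or any data frame
#'   with a `d_hat` column).
#' @param delta Non-response band half-width (kg), >= 0.
#' @return A one-row tibble like [responder_proportions()].
#' @export
responder_proportions_empirical <- function(effects, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0) {
    rlang::abort("`delta` must be a single non-negative number",
                 class = "rrd_config_error")
  }
  d <- effects$d_hat
  stopifnot(length(d) >= 1L)
  out <- tibble::tibble(
    delta = delta,
    prop_nonresponder = mean(abs(d) <= delta),
    prop_treat_better = mean(d < 0),
    prop_control_better = mean(d > 0),
    mu_d_hat = mean(d), sigma_d_hat = stats::sd(d)
  )
  class(out) <- c("rrd_responders", class(out))
  out
}
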