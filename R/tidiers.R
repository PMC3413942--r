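#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a TRH estimate
#'
#' @param x An `rrd_trh` object.
#' @param ... Unused.
#' @return A tibble with one row per estimated quantity: `term`, `estimate`.
#' @export
tidy.rrd_trh <- function(x, ...) {
  tibble::tibble(
    term = c("mu_d", "sigma2_trh", "sigma2_resid"),
    estimate = c(x$mu_d_hat, x$sigma2_trh_hat, x$sigma2_resid_hat)
  )
}

#' @rdname tidy.rrd_trh
#' @return `glance()`: a one-row tibble with the estimates, the method and
#'   the number of subjects used.
#' @export
glance.rrd_trh <- function(x, ...) {
  tibble::tibble(
    mu_d_hat = x$mu_d_hat,
    sigma2_trh_hat = x$sigma2_trh_hat,
    sigma2_trh_raw = x$sigma2_trh_raw,
    sigma2_resid_hat = x$sigma2_resid_hat,
    method = x$method,
    n_subjects_used = x$n_subjects_used
  )
}

#' Tidy an efficiency comparison
#'
#' @param x An `rrd_efficiency` tibble.
#' @param ... Unused.
#' @return The per-design results as a plain tibble.
#' @export
tidy.rrd_efficiency <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidy.rrd_efficiency
#' @return `glance()`: a one-row tibble with the comparison dimensions.
#' @export
glance.rrd_efficiency <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    n_subjects = cfg$n_subjects,
    n_periods = cfg$n_periods,
    n_replicates = cfg$n_replicates,
    n_designs = length(cfg$designs),
    covariate_effect = cfg$covariate_effect
  )
}

#' Tidy a survey summary
#'
#' @param x An `rrd_survey_summary` object.
#' @param ... Unused.
#' @return The per-item summary tibble.
#' @export
tidy.rrd_survey_summary <- function(x, ...) x$items

#' @rdname tidy.rrd_survey_summary
#' @export
glance.rrd_survey_summary <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    pct_prefer_rrd = x$preference$proportion,
    pct_lower = x$preference$lower,
    pct_upper = x$preference$upper,
    p_enroll = x$tests$p_value[x$tests$comparison == "enroll_B_vs_A"],
    p_complete = x$tests$p_value[x$tests$comparison == "complete_B_vs_A"]
  )
}
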