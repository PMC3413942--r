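#' Generative-model parameters for a weight-change trial
#'
#' Bundles the parameters of the linear mixed potential-outcomes model used
#' throughout the package:
#'
#' \deqn{Y_{ij}(x) = \mu + \pi_j + a_i + (\tau + b_i)\,x + \gamma\,x_{i,j-1} + e_{ij}}
#'
#' where \eqn{x \in \{0,1\}} is the treatment indicator, \eqn{a_i \sim
#' N(0,\sigma^2_a)} are subject intercepts, \eqn{b_i \sim N(0,\sigma^2_D)} are
#' subject-treatment interactions, and \eqn{e_{ij} \sim N(0,\sigma^2_e)} is
#' residual noise shared by the two counterfactual outcomes of a cell. The
#' individual treatment response is \eqn{D_i = \tau + b_i} (carryover excluded
#' by definition), so `sigma2_trh` is exactly the treatment response
#' heterogeneity (TRH): the variance of \eqn{D} across subjects, and `tau` is
#' its population mean \eqn{\mu_D}.
#'
#' The outcome is a within-period weight change in kg; negative values mean
#' weight lost, so \eqn{D_i < 0} means the treatment is superior for weight
#' loss.
#'
#' @param mu Mean per-period change under control (kg).
#' @param tau Population mean treatment effect \eqn{\mu_D} (kg).
#' @param sigma2_subject Variance of subject random intercepts (kg^2).
#' @param sigma2_trh Variance of subject-treatment interactions, the TRH
#'   (kg^2).
#' @param period_effects Numeric vector of fixed per-period shifts \eqn{\pi_j}
#'   (kg); the first entry must be 0 (the reference period). Length must equal
#'   the number of periods simulated. A single 0 is recycled to any number of
#'   periods (no period effects).
#' @param carryover First-order carryover coefficient \eqn{\gamma} (kg),
#'   added to an outcome when the *previous* period was treated. Defaults to 0.
#' @param sigma2_resid Residual variance \eqn{\sigma^2_e} (kg^2).
#'
#' @return An object of class `trial_params` (a named list).
#' @examples
#' trial_params(mu = -1, tau = -0.5, sigma2_trh = 0.25)
#' @export
trial_params <- function(mu = 0,
                         tau = 0,
                         sigma2_subject = 0,
                         sigma2_trh = 0,
                         period_effects = 0,
                         carryover = 0,
                         sigma2_resid = 0) {
  stopifnot(is.numeric(mu), length(mu) == 1L,
            is.numeric(tau), length(tau) == 1L,
            is.numeric(period_effects), length(period_effects) >= 1L,
            is.numeric(carryover), length(carryover) == 1L)
  for (v in c(sigma2_subject = sigma2_subject, sigma2_trh = sigma2_trh,
              sigma2_resid = sigma2_resid)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      rlang::abort("variance components must be single non-negative numbers",
                   class = "rrd_config_error")
    }
  }
  if (period_effects[1L] != 0) {
    rlang::abort("`period_effects[1]` must be 0 (first period is the reference)",
                 class = "rrd_config_error")
  }
  structure(
    list(mu = mu, tau = tau,
         sigma2_subject = sigma2_subject, sigma2_trh = sigma2_trh,
         period_effects = period_effects, carryover = carryover,
         sigma2_resid = sigma2_resid),
    class = "trial_params"
  )
}

#' @export
print.trial_params <- function(x, ...) {
  cat("<trial_params>\n")
  cat(sprintf("  mu (control change):      %g kg\n", x$mu))
  cat(sprintf("  tau (mean effect mu_D):   %g kg\n", x$tau))
  cat(sprintf("  sigma2_subject:           %g kg^2\n", x$sigma2_subject))
  cat(sprintf("  sigma2_trh (TRH):         %g kg^2\n", x$sigma2_trh))
  cat(sprintf("  sigma2_resid:             %g kg^2\n", x$sigma2_resid))
  cat(sprintf("  carryover gamma:          %g kg\n", x$carryover))
  cat(sprintf("  period effects:           %s\n",
              paste(signif(x$period_effects, 4), collapse = ", ")))
  invisible(x)
}

# expand period effects to p periods, validating length
period_effects_for <- function(params, n_periods) {
  pe <- params$period_effects
  if (length(pe) == 1L && pe == 0) pe <- rep(0, n_periods)
  if (length(pe) != n_periods) {
    rlang::abort(
      sprintf("`period_effects` has length %d but the trial has %d periods",
              length(pe), n_periods),
      class = "rrd_config_error"
    )
  }
  pe
}
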