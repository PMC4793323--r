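#' Akaike's information criterion
#'
#' @param loglik Maximized log-likelihood.
#' @param n_params Number of estimated parameters (the mixed model counts its
#'   random-intercept standard deviation as one).
#' @return `-2 * loglik + 2 * n_params`.
#' @export
aic <- function(loglik, n_params) {
  stopifnot(n_params >= 1)
  -2 * loglik + 2 * n_params
}

#' Odds ratio with a Wald confidence interval
#'
#' Exponentiates a log-odds coefficient and its `beta +/- z * se` Wald bounds.
#' The default level is 99%, the stringent level used in place of a
#' multiple-testing correction.
#'
#' @param beta_j Coefficient on the log-odds scale (scalar or vector).
#' @param se_j Standard error(s), `>= 0`.
#' @param level Two-sided confidence level in (0, 1).
#' @return A tibble with columns `or`, `ci_low`, `ci_high`, `level`.
#' @examples
#' or_with_ci(2.1576, 0.1577)
#' @export
or_with_ci <- function(beta_j, se_j, level = 0.99) {
  stopifnot(level > 0, level < 1, all(se_j >= 0 | is.na(se_j)))
  z <- qnorm((1 + level) / 2)
  tibble::tibble(
    or = exp(beta_j),
    ci_low = exp(beta_j - z * se_j),
    ci_high = exp(beta_j + z * se_j),
    level = level
  )
}

#' Compare the mixed and fixed fits by AIC
#'
#' `delta_aic = AIC(mixed) - AIC(fixed)`; the mixed model wins when the
#' difference is negative, and a tie goes to the simpler fixed model. If
#' either fit did not converge the preference is undetermined.
#'
#' @param fixed A `pv_fixed_fit`.
#' @param mixed A `pv_mixed_fit` on the same design.
#' @return A one-row tibble with `delta_aic` and `winner`
#'   (`"mixed"`, `"fixed"`, or `"undetermined"`).
#' @export
compare_models <- function(fixed, mixed) {
  if (!isTRUE(fixed$converged) || !isTRUE(mixed$converged)) {
    return(tibble::tibble(delta_aic = NA_real_, winner = "undetermined"))
  }
  delta <- mixed$aic - fixed$aic
  tibble::tibble(delta_aic = delta,
                 winner = if (delta < 0) "mixed" else "fixed")
}
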