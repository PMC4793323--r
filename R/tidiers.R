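#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fixed-effects logistic fit
#'
#' @param x A `pv_fixed_fit`.
#' @param conf.level Wald confidence level for the odds-ratio columns.
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate`, `std.error`,
#'   `or`, `ci_low`, `ci_high`.
#' @method tidy pv_fixed_fit
#' @export
tidy.pv_fixed_fit <- function(x, conf.level = 0.99, ...) {
  ci <- or_with_ci(x$beta, x$se, level = conf.level)
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta),
                 std.error = unname(x$se),
                 or = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high)
}

#' @rdname tidy.pv_fixed_fit
#' @method tidy pv_mixed_fit
#' @export
tidy.pv_mixed_fit <- function(x, conf.level = 0.99, ...) {
  tidy.pv_fixed_fit(x, conf.level = conf.level, ...)
}

#' One-row summary of a fixed-effects logistic fit
#'
#' @param x A `pv_fixed_fit` or `pv_mixed_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the log-likelihood, AIC, parameter count,
#'   convergence flag, and (for mixed fits) `sigma` and its standard error.
#' @method glance pv_fixed_fit
#' @export
glance.pv_fixed_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, aic = x$aic, n_params = x$n_params,
                 n = x$n, converged = x$converged)
}

#' @rdname glance.pv_fixed_fit
#' @method glance pv_mixed_fit
#' @export
glance.pv_mixed_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, aic = x$aic, n_params = x$n_params,
                 sigma = x$sigma, sigma_se = x$sigma_se,
                 n = x$n, n_clusters = x$n_clusters,
                 converged = x$converged, boundary = x$boundary)
}

#' @export
print.pv_fixed_fit <- function(x, ...) {
  cat("Fixed-effects logistic fit:", x$n, "cases,",
      x$n_params, "parameters\n")
  cat(sprintf("  logLik %.4f  AIC %.4f  converged: %s\n",
              x$loglik, x$aic, x$converged))
  print(tidy(x), ...)
  invisible(x)
}

#' @export
print.pv_mixed_fit <- function(x, ...) {
  cat("Mixed-effects logistic fit:", x$n, "cases in",
      x$n_clusters, "quarterly clusters\n")
  cat(sprintf("  sigma %.4f  logLik %.4f  AIC %.4f  converged: %s%s\n",
              x$sigma, x$loglik, x$aic, x$converged,
              if (isTRUE(x$boundary)) "  (sigma at boundary)" else ""))
  print(tidy(x), ...)
  invisible(x)
}
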