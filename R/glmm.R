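# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 18
  out[big] <- x[big] + log1p(exp(-x[big]))
  out[!big] <- log1p(exp(x[!big]))
  out
}

log_sum_exp_rows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Log-likelihood of the fixed-effects logistic model
#'
#' The ordinary Bernoulli log-likelihood
#' `sum_i [ y_i eta_i - log(1 + exp(eta_i)) ]` with `eta = X beta`. An empty
#' design contributes 0.
#'
#' @param beta Coefficient vector (intercept first, matching
#'   `design_matrix()` column order).
#' @param design A `pv_design` tibble (see [build_design()]; any tibble with
#'   a binary `y`, numeric covariates, and optionally `cluster` works).
#' @return The log-likelihood (a scalar).
#' @export
loglik_fixed <- function(beta, design) {
  if (nrow(design) == 0) return(0)
  X <- design_matrix(design)
  y <- design_response(design)
  eta <- drop(X %*% beta)
  sum(y * eta - log1pexp(eta))
}

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' For clusters (quarterly periods) `c`, the marginal likelihood integrates
#' the Bernoulli likelihood over the cluster's normal random intercept
#' `u ~ N(0, sigma^2)`:
#' `sum_c log integral prod_{i in c} p(y_i | x_i' beta + u) phi(u; 0, sigma^2) du`.
#' The integral is evaluated by Gauss-Hermite quadrature with the substitution
#' `u = sqrt(2) sigma x`, weights normalized by `sqrt(pi)`. At `sigma = 0` the
#' integral degenerates and the value equals [loglik_fixed()] exactly.
#'
#' @inheritParams loglik_fixed
#' @param sigma Random-intercept standard deviation, `>= 0`.
#' @param n_quad Number of quadrature nodes.
#' @return The marginal log-likelihood (a scalar).
#' @export
loglik_marginal <- function(beta, sigma, design, n_quad = 8) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(loglik_fixed(beta, design))
  if (nrow(design) == 0) return(0)
  parts <- marginal_parts(beta, log(sigma), design, n_quad)
  parts$loglik
}

# Shared workhorse: marginal log-likelihood and its analytic gradient in
# (beta, log sigma). Returns the pieces the optimizer and the SE step need.
marginal_parts <- function(beta, log_sigma, design, n_quad, want_grad = FALSE) {
  X <- design_matrix(design)
  y <- design_response(design)
  sigma <- exp(min(log_sigma, 5))   # clamp: line searches must not overflow
  rule <- gauss_hermite_rule(n_quad)
  u <- sqrt(2) * sigma * rule$nodes              # K random-intercept values
  lw <- log(rule$weights) - 0.5 * log(pi)        # normalized log-weights
  gid <- match(design$cluster, sort(unique(design$cluster)))
  eta0 <- drop(X %*% beta)
  ETA <- outer(eta0, u, `+`)                     # n x K
  LP <- y * ETA - log1pexp(ETA)                  # per-row Bernoulli log-probs
  S <- rowsum(LP, gid)                           # C x K cluster log-products
  logA <- sweep(S, 2, lw, `+`)
  logS_c <- log_sum_exp_rows(logA)
  out <- list(loglik = sum(logS_c), sigma = sigma)
  if (!want_grad) return(out)
  A <- exp(logA - logS_c)                        # posterior node weights, rows sum to 1
  R <- y - plogis(ETA)                           # n x K residuals at each node
  W <- A[gid, , drop = FALSE] * R
  rw <- rowSums(W)
  out$grad_beta <- drop(crossprod(X, rw))
  grad_sigma <- sum(W %*% (sqrt(2) * rule$nodes))
  out$grad_log_sigma <- sigma * grad_sigma
  out$grad_sigma <- grad_sigma
  out
}

#' Fit the fixed-effects logistic model by Newton-Raphson
#'
#' Maximum likelihood with the observed-information Newton update and step
#' halving; convergence when the largest absolute score component falls below
#' `tol`. Standard errors come from the inverse observed information. A
#' singular information matrix (e.g. under complete separation) yields a
#' flagged, still-returned result.
#'
#' @inheritParams loglik_fixed
#' @param tol Convergence tolerance on the score (default 1e-8).
#' @param max_iter Iteration cap.
#' @return A `pv_fixed_fit` list: `beta`, `se`, `loglik`, `aic`, `converged`,
#'   `n_iter`, `n`, plus the term names.
#' @examples
#' d <- tibble::tibble(y = rep(c(0, 1), c(40, 60)))
#' fit_fixed(d)$beta  # intercept = logit(0.6)
#' @export
fit_fixed <- function(design, tol = 1e-8, max_iter = 100) {
  X <- design_matrix(design)
  y <- design_response(design)
  if (nrow(X) == 0) abort("empty design is not estimable")
  p <- ncol(X)
  beta <- numeric(p)
  ll <- loglik_fixed(beta, design)
  converged <- FALSE
  singular <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    mu <- plogis(drop(X %*% beta))
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    w <- mu * (1 - mu)
    info <- crossprod(X, X * w)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) { singular <- TRUE; break }
    # step halving keeps the likelihood ascending
    for (h in 0:25) {
      cand <- beta + step / 2^h
      ll_new <- loglik_fixed(cand, design)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
    }
    beta <- cand
    ll <- ll_new
  }
  mu <- plogis(drop(X %*% beta))
  info <- crossprod(X, X * (mu * (1 - mu)))
  cov <- tryCatch(solve(info), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, p) else sqrt(pmax(diag(cov), 0))
  if (is.null(cov)) singular <- TRUE
  # coefficients running away on the logit scale indicate (quasi-)separation:
  # the score can still vanish, so flag rather than trust convergence
  if (max(abs(beta)) > 15) singular <- TRUE
  structure(list(
    beta = setNames(beta, colnames(X)),
    se = setNames(se, colnames(X)),
    loglik = loglik_fixed(beta, design),
    aic = aic(loglik_fixed(beta, design), p),
    converged = converged && !singular,
    singular = singular,
    n_iter = iter,
    n = nrow(X),
    n_params = p
  ), class = "pv_fixed_fit")
}

#' Fit the mixed-effects logistic model by maximum marginal likelihood
#'
#' Jointly maximizes the Gauss-Hermite marginal log-likelihood over the fixed
#' coefficients and `log(sigma)` (BFGS with analytic gradients, then Newton
#' polishing until the score tolerance is met). The positivity of `sigma` is
#' enforced by the log parameterization; an estimate below `1e-6` is snapped
#' to the `sigma = 0` boundary, where the model collapses to the fixed fit
#' and the fit is flagged `boundary`. Standard errors come from the inverse
#' observed information of the marginal log-likelihood, computed by central
#' differences of the analytic gradient in the `(beta, sigma)`
#' parameterization. The AIC counts `sigma` as one extra parameter.
#'
#' @inheritParams loglik_marginal
#' @param tol Convergence tolerance on the score (default 1e-8).
#' @param max_iter Iteration cap for the quasi-Newton stage.
#' @return A `pv_mixed_fit` list: `beta`, `se`, `sigma`, `sigma_se`,
#'   `loglik`, `aic`, `converged`, `boundary`, `n_iter`, `n_quad`, `n`,
#'   `n_clusters`.
#' @export
fit_mixed <- function(design, n_quad = 8, tol = 1e-8, max_iter = 100) {
  if (!"cluster" %in% names(design)) abort("design lacks a cluster column")
  n_clusters <- length(unique(design$cluster))
  if (n_clusters < 2) abort("mixed fit needs at least 2 clusters")
  fixed <- fit_fixed(design, tol = tol, max_iter = max_iter)
  p <- fixed$n_params

  negll <- function(theta) {
    if (any(!is.finite(theta))) return(1e10)
    v <- marginal_parts(theta[1:p], theta[p + 1], design, n_quad)$loglik
    if (!is.finite(v)) 1e10 else -v
  }
  neggrad <- function(theta) {
    if (any(!is.finite(theta))) return(rep(0, p + 1))
    parts <- marginal_parts(theta[1:p], theta[p + 1], design, n_quad,
                            want_grad = TRUE)
    g <- -c(parts$grad_beta, parts$grad_log_sigma)
    if (any(!is.finite(g))) rep(0, p + 1) else g
  }
  # a (quasi-)separated fixed fit gives runaway start values; rein them in
  theta <- c(pmin(pmax(fixed$beta, -10), 10), log(0.5))
  opt <- tryCatch(
    optim(theta, negll, neggrad, method = "BFGS",
          control = list(maxit = max_iter, reltol = 1e-14)),
    error = function(e) NULL
  )
  if (!is.null(opt)) theta <- opt$par

  # Newton polish on the full parameter vector in (beta, log sigma)
  converged <- FALSE
  polish <- 0
  ll <- -negll(theta)
  while (polish < 25) {
    g <- -neggrad(theta)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    if (exp(theta[p + 1]) < 1e-8) break   # boundary: log-sigma direction degenerates
    H <- grad_jacobian(function(th) -neggrad(th), theta)
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    improved <- FALSE
    for (h in 0:25) {
      cand <- theta + step / 2^h
      ll_new <- tryCatch(-negll(cand), error = function(e) -Inf)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) { improved <- TRUE; break }
    }
    if (!improved) break
    theta <- cand
    ll <- ll_new
    polish <- polish + 1
  }

  beta <- setNames(theta[1:p], names(fixed$beta))
  sigma <- unname(exp(theta[p + 1]))
  ll <- loglik_marginal(beta, sigma, design, n_quad)

  # boundary handling: a vanishing sigma, or an "optimum" that fails to reach
  # the nested fixed fit's likelihood, collapses to the sigma = 0 solution
  boundary <- sigma < 1e-6 || ll < fixed$loglik
  if (boundary) {
    beta <- fixed$beta
    sigma <- 0
    ll <- fixed$loglik
    se <- fixed$se
    sigma_se <- NA_real_
    converged <- fixed$converged
  } else {
    gfun <- function(th) {
      parts <- marginal_parts(th[1:p], log(th[p + 1]), design, n_quad,
                              want_grad = TRUE)
      c(parts$grad_beta, parts$grad_sigma)
    }
    hs <- pmax(abs(c(beta, sigma)), 1) * 1e-5
    hs[p + 1] <- min(hs[p + 1], sigma / 2)   # keep sigma positive in the stencil
    H <- grad_jacobian(gfun, c(beta, sigma), h = hs)
    cov <- tryCatch(solve(-H), error = function(e) NULL)
    if (is.null(cov) || any(diag(cov) < 0)) {
      se <- rep(NA_real_, p)
      sigma_se <- NA_real_
      converged <- FALSE
    } else {
      se <- setNames(sqrt(diag(cov)[1:p]), names(beta))
      sigma_se <- sqrt(diag(cov)[p + 1])
    }
  }
  structure(list(
    beta = beta, se = se, sigma = sigma, sigma_se = sigma_se,
    loglik = ll, aic = aic(ll, p + 1),
    converged = converged, boundary = boundary,
    n_iter = if (is.null(opt)) NA_integer_ else opt$counts[["function"]],
    n_quad = n_quad, n = nrow(design), n_clusters = n_clusters,
    n_params = p + 1
  ), class = "pv_mixed_fit")
}

# central-difference Jacobian of a gradient function (symmetrized)
grad_jacobian <- function(g, x, h = NULL) {
  k <- length(x)
  if (is.null(h)) h <- pmax(abs(x), 1) * 1e-5
  J <- matrix(0, k, k)
  for (j in seq_len(k)) {
    xp <- x; xp[j] <- xp[j] + h[j]
    xm <- x; xm[j] <- xm[j] - h[j]
    J[, j] <- (g(xp) - g(xm)) / (2 * h[j])
  }
  (J + t(J)) / 2
}
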