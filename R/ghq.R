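#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for integrals weighted by `exp(-x^2)` (physicists'
#' convention): the nodes are the roots of the degree-n Hermite polynomial
#' and the weights sum to `sqrt(pi)`. Computed by the Golub-Welsch method:
#' eigendecomposition of the symmetric tridiagonal Jacobi matrix with
#' off-diagonal `sqrt(k/2)`.
#'
#' @param n Number of nodes (1 to 100).
#' @return A list with numeric vectors `nodes` (increasing) and `weights`.
#' @examples
#' gauss_hermite_rule(2)  # nodes +/- 1/sqrt(2), weights sqrt(pi)/2
#' @export
gauss_hermite_rule <- function(n) {
  if (length(n) != 1 || is.na(n) || n < 1 || n != floor(n)) {
    abort("n must be a positive integer")
  }
  if (n > 100) abort("n must be at most 100")
  n <- as.integer(n)
  if (n == 1L) {
    return(list(nodes = 0, weights = sqrt(pi)))
  }
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  nodes <- sort(eigen(J, symmetric = TRUE, only.values = TRUE)$values)
  # symmetrize against rounding: the rule is exactly even
  nodes <- (nodes - rev(nodes)) / 2
  # Christoffel weights: 1 / sum_j p_j(x)^2 over the orthonormal Hermite
  # polynomials. Unlike squared first eigenvector components, these cannot
  # underflow at large n.
  p_prev <- rep(pi^(-1 / 4), n)
  ssq <- p_prev^2
  p_cur <- nodes * p_prev / off[1]
  if (n >= 2) ssq <- ssq + p_cur^2
  for (k in 2:max(n - 1, 2)) {
    if (k > n - 1) break
    p_next <- (nodes * p_cur - off[k - 1] * p_prev) / off[k]
    ssq <- ssq + p_next^2
    p_prev <- p_cur
    p_cur <- p_next
  }
  weights <- 1 / ssq
  weights <- (weights + rev(weights)) / 2
  list(nodes = nodes, weights = weights)
}
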