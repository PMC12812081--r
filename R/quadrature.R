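# Quadrature-node machinery shared by the encounter models and the
# trajectory integrator. Nodes are obtained by Golub-Welsch (eigenvalues of
# the symmetric Jacobi matrix of the orthogonal-polynomial recurrence) and
# cached per order.

.quad_cache <- new.env(parent = emptyenv())

#' Gauss-Legendre nodes and weights on [-1, 1]
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights`.
#' @keywords internal
#' @noRd
gauss_legendre <- function(n) {
  key <- paste0("gl", n)
  if (!is.null(.quad_cache[[key]])) return(.quad_cache[[key]])
  if (n == 1L) {
    out <- list(nodes = 0, weights = 2)
  } else {
    i <- seq_len(n - 1L)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- b
    J[cbind(i + 1L, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    out <- list(nodes = e$values, weights = 2 * e$vectors[1L, ]^2)
  }
  .quad_cache[[key]] <- out
  out
}

#' Gauss-Hermite nodes and weights (weight function exp(-x^2))
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights`; sum(weights) = sqrt(pi).
#' @keywords internal
#' @noRd
gauss_hermite <- function(n) {
  key <- paste0("gh", n)
  if (!is.null(.quad_cache[[key]])) return(.quad_cache[[key]])
  i <- seq_len(n - 1L)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  out <- list(nodes = e$values, weights = sqrt(pi) * e$vectors[1L, ]^2)
  .quad_cache[[key]] <- out
  out
}

# Evaluate int_lo^hi fn(s) ds for each row of subintervals, by fixed-order
# Gauss-Legendre. `fn` must be vectorized. Returns one value per subinterval.
gl_piecewise <- function(fn, lo, hi, order = 7L) {
  gl <- gauss_legendre(order)
  half <- (hi - lo) / 2
  mid <- (hi + lo) / 2
  # nodes matrix: length(lo) x order
  s <- outer(half, gl$nodes) + mid
  v <- matrix(fn(as.vector(s)), nrow = length(lo))
  as.vector(v %*% gl$weights) * half
}
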