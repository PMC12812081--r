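# Trajectory integration.
#
# Both model ODEs are linear, so instead of a generic stepper the package
# propagates exact integrating-factor solutions between grid points:
#   state    dN/dt      = h(t) - u N      (forward, N(0) = N0)
#   costate  dlambda/dt = -A(t) + u lambda, A = K n g / N^2 (backward, lambda(T) = 0)
# Within a subinterval, inhomogeneous terms are integrated by fixed-order
# Gauss-Legendre; for constant-h pieces the state update is exact. The grid
# always contains the control discontinuities as subinterval boundaries, and
# is refined geometrically near t = 0 where the fighting-cost integrand
# behaves like 1/(N0 + h t).

trajectory_quadrature <- function(pieces, problem, order = 7L) {
  Tmax <- problem$T
  if (abs(pieces[[1L]]$t0) > 1e-12 ||
      abs(pieces[[length(pieces)]]$t1 - Tmax) > 1e-9 * max(1, Tmax))
    stop("control pieces must cover [0, T]")
  if (problem$N0 <= 0)
    stop("fitness evaluation requires N0 > 0 (the fighting cost diverges at N = 0)")
  n_base <- problem$n_grid
  lo <- numeric(0); hi <- numeric(0); pidx <- integer(0)
  for (j in seq_along(pieces)) {
    p <- pieces[[j]]
    len <- p$t1 - p$t0
    if (len <= 0) next
    ns <- max(4L, ceiling(n_base * len / Tmax))
    br <- seq(p$t0, p$t1, length.out = ns + 1L)
    if (j == 1L && p$t0 == 0) {
      h0 <- if (p$type == "const") p$h else p$h(1e-12)
      scale <- problem$N0 / max(h0, problem$N0 * problem$cost$u)
      scale <- max(scale, 1e-13 * Tmax)
      if (scale < br[2L] / 4) {
        geo <- scale * 2^(0:ceiling(log2(br[2L] / scale)))
        br <- sort(unique(c(br, geo[geo < br[2L]])))
      }
    }
    lo <- c(lo, br[-length(br)])
    hi <- c(hi, br[-1L])
    pidx <- c(pidx, rep.int(j, length(br) - 1L))
  }
  M <- length(lo)
  gl <- gauss_legendre(order)
  half <- (hi - lo) / 2
  nodes <- outer(half, gl$nodes) + (hi + lo) / 2        # M x order
  w <- outer(half, gl$weights)                           # M x order

  u <- problem$cost$u
  N_lo <- numeric(M); N_hi <- numeric(M)
  N_nodes <- matrix(NA_real_, M, order)
  h_nodes <- matrix(NA_real_, M, order)

  gl3 <- gauss_legendre(3L)
  Ncur <- problem$N0
  for (j in seq_along(pieces)) {
    p <- pieces[[j]]
    idx <- which(pidx == j)
    if (!length(idx)) next
    if (p$type == "const") {
      # exact solution from the piece start for endpoints and nodes alike
      Nstar <- p$h / u
      t0 <- p$t0
      N_lo[idx] <- Nstar + (Ncur - Nstar) * exp(-u * (lo[idx] - t0))
      N_hi[idx] <- Nstar + (Ncur - Nstar) * exp(-u * (hi[idx] - t0))
      N_nodes[idx, ] <- Nstar + (Ncur - Nstar) * exp(-u * (nodes[idx, , drop = FALSE] - t0))
      h_nodes[idx, ] <- p$h
      Ncur <- N_hi[idx[length(idx)]]
    } else {
      # chain of exact-kernel updates through subinterval endpoints and nodes
      for (k in idx) {
        times <- c(lo[k], sort(nodes[k, ]), hi[k])
        Nt <- numeric(length(times))
        Nt[1L] <- Ncur
        for (q in 2L:length(times)) {
          d <- times[q] - times[q - 1L]
          s <- (times[q] + times[q - 1L]) / 2 + (d / 2) * gl3$nodes
          inc <- sum(gl3$weights * exp(-u * (times[q] - s)) * p$h(s)) * d / 2
          Nt[q] <- Nt[q - 1L] * exp(-u * d) + inc
        }
        N_lo[k] <- Nt[1L]
        N_hi[k] <- Nt[length(Nt)]
        ord <- order(nodes[k, ])
        N_nodes[k, ord] <- Nt[2L:(length(Nt) - 1L)]
        h_nodes[k, ] <- p$h(nodes[k, ])
        Ncur <- N_hi[k]
      }
    }
  }

  g_nodes <- matrix(novelty_intensity(problem$model, as.vector(nodes)), M, order)
  A_nodes <- problem$cost$K * problem$model$n * g_nodes / N_nodes^2
  labels <- vapply(pieces, `[[`, character(1), "label")[pidx]

  list(lo = lo, hi = hi, piece = pidx, label = labels,
       nodes = nodes, w = w,
       N_lo = N_lo, N_hi = N_hi, N_nodes = N_nodes,
       h_nodes = h_nodes, A_nodes = A_nodes, g_nodes = g_nodes)
}

# Backward costate pass: exact integrating factor per subinterval, with the
# inhomogeneous term from the stored Gauss-Legendre nodes.
costate_pass <- function(quad, problem) {
  u <- problem$cost$u
  M <- length(quad$lo)
  b <- rowSums(quad$w * exp(-u * (quad$nodes - quad$lo)) * quad$A_nodes)
  lam_hi <- numeric(M); lam_lo <- numeric(M)
  lam <- 0 # lambda(T) = 0
  for (k in M:1L) {
    lam_hi[k] <- lam
    lam <- exp(-u * (quad$hi[k] - quad$lo[k])) * lam + b[k]
    lam_lo[k] <- lam
  }
  list(lam_lo = lam_lo, lam_hi = lam_hi, intA = rowSums(quad$w * quad$A_nodes))
}

#' Integrate state, costate and cost along a control schedule
#'
#' Runs the clone-count ODE forward from `N(0) = N0` under the schedule's
#' production rule, the costate ODE backward from `lambda(T) = 0`, and
#' accumulates the instantaneous cost `Psi(t) = K n g(t) / N(t) + m h(t)`
#' and the fitness `phi = C - integral(Psi)`. Phase boundaries are exact
#' grid points; integration restarts at each boundary.
#'
#' @param schedule a [phase_schedule()][assemble_schedule()] or a
#'   [gridded_control()].
#' @param problem a [control_problem()].
#' @return an object of class `trajectory`: a list with co-indexed vectors
#'   `ages`, `N`, `lam`, `h`, `psi`, the phase `label` of the interval to the
#'   right of each age, and the scalar fitness `phi`.
#' @export
integrate_trajectory <- function(schedule, problem) {
  stopifnot(inherits(problem, "control_problem"))
  pieces <- control_pieces(schedule, problem)
  quad <- trajectory_quadrature(pieces, problem)
  cs <- costate_pass(quad, problem)
  m <- problem$cost$m
  M <- length(quad$lo)

  psi_nodes <- quad$A_nodes * quad$N_nodes + m * quad$h_nodes
  phi <- problem$C - sum(quad$w * psi_nodes)

  ages <- c(quad$lo, quad$hi[M])
  N <- c(quad$N_lo, quad$N_hi[M])
  lam <- c(cs$lam_lo, cs$lam_hi[M])
  h_at <- function(j, t) {
    p <- pieces[[j]]
    if (p$type == "const") p$h else p$h(t)
  }
  h <- c(vapply(seq_len(M), function(k) h_at(quad$piece[k], quad$lo[k]), numeric(1)),
         h_at(quad$piece[M], quad$hi[M]))
  g <- novelty_intensity(problem$model, ages)
  psi <- problem$cost$K * problem$model$n * g / N + m * h

  out <- list(ages = ages, N = N, lam = lam, h = h, psi = psi, phi = phi,
              label = c(quad$label, quad$label[M]))
  attr(out, "quad") <- quad
  attr(out, "costate") <- cs
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory on [0, ", max(x$ages), "]: ", length(x$ages),
      " grid points, phi = ", format(x$phi), "\n", sep = "")
  invisible(x)
}

#' Fitness of an integrated trajectory
#'
#' Evaluates `phi = C - integral(K n g / N + m h)` by quadrature on the
#' trajectory's stored Gauss-Legendre nodes.
#'
#' @param trajectory a [integrate_trajectory()] result.
#' @param problem the [control_problem()] it was integrated under.
#' @return scalar fitness.
#' @export
fitness <- function(trajectory, problem) {
  stopifnot(inherits(trajectory, "trajectory"), inherits(problem, "control_problem"))
  quad <- attr(trajectory, "quad")
  if (any(quad$N_nodes <= 0))
    stop("clone count reached zero while the fighting cost was evaluated")
  psi_nodes <- quad$A_nodes * quad$N_nodes + problem$cost$m * quad$h_nodes
  problem$C - sum(quad$w * psi_nodes)
}

# phi and its adjoint gradient for a piecewise-constant control; gradient
# component j is  integral over interval j of (lambda(t) - m) dt, evaluated
# exactly from the costate identity  integral(lambda) = (dlambda + integral(A)) / u.
control_fitness_gradient <- function(control, problem) {
  pieces <- control_pieces(control, problem)
  quad <- trajectory_quadrature(pieces, problem)
  cs <- costate_pass(quad, problem)
  m <- problem$cost$m
  u <- problem$cost$u
  psi_nodes <- quad$A_nodes * quad$N_nodes + m * quad$h_nodes
  phi <- problem$C - sum(quad$w * psi_nodes)
  int_lam_sub <- (cs$lam_hi - cs$lam_lo + cs$intA) / u
  fac <- factor(quad$piece, levels = seq_along(pieces))
  int_lam <- tapply(int_lam_sub, fac, sum, default = 0)
  len <- tapply(quad$hi - quad$lo, fac, sum, default = 0)
  grad <- as.numeric(int_lam) - m * as.numeric(len)
  list(phi = phi, gradient = grad)
}
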