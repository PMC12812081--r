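#' Direct numerical optimization of the production schedule
#'
#' Independent oracle for the Pontryagin construction: maximizes the fitness
#' functional over piecewise-constant controls on a grid, without using any
#' maximum-principle structure. The gradient of the fitness with respect to
#' each interval level is computed from the adjoint relation (the integral of
#' `lambda - m` over the interval) and fed to projected quasi-Newton ascent
#' (`L-BFGS-B` with box bounds `[0, h_max]`) from multiple random starts.
#'
#' @param problem a [control_problem()].
#' @param intervals number of equal control intervals on `[0, T]` (>= 10).
#' @param starts number of random multi-starts.
#' @param seed integer seed for the random starts (reproducible).
#' @param maxit maximum L-BFGS-B iterations per start.
#' @return a list with `control` (the best [gridded_control()]), `phi` (its
#'   fitness), `phi_starts` (best fitness per start), and `convergence`
#'   (per-start optim convergence codes).
#' @export
optimize_control <- function(problem, intervals = 200L, starts = 8L,
                             seed = 1L, maxit = 400L) {
  stopifnot(inherits(problem, "control_problem"))
  if (intervals < 10L) stop("'intervals' must be >= 10")
  breaks <- seq(0, problem$T, length.out = intervals + 1L)
  hmax <- problem$h_max

  if (hmax == 0) {
    ctl <- gridded_control(breaks, rep(0, intervals))
    fg <- control_fitness_gradient(ctl, problem)
    return(list(control = ctl, phi = fg$phi, phi_starts = fg$phi,
                convergence = 0L))
  }

  objective <- function(levels) {
    -control_fitness_gradient(gridded_control(breaks, levels), problem)$phi
  }
  gradient <- function(levels) {
    -control_fitness_gradient(gridded_control(breaks, levels), problem)$gradient
  }

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  best <- NULL
  phi_starts <- numeric(starts)
  conv <- integer(starts)
  for (s in seq_len(starts)) {
    start_levels <- if (s == 1L) rep(hmax / 2, intervals)
                    else stats::runif(intervals, 0, hmax)
    fit <- stats::optim(start_levels, objective, gradient, method = "L-BFGS-B",
                        lower = rep(0, intervals), upper = rep(hmax, intervals),
                        control = list(maxit = maxit, factr = 10))
    phi_starts[s] <- -fit$value
    conv[s] <- fit$convergence
    if (is.null(best) || -fit$value > best$phi)
      best <- list(phi = -fit$value, levels = pmin(pmax(fit$par, 0), hmax))
  }
  list(control = gridded_control(breaks, best$levels, hmax),
       phi = best$phi, phi_starts = phi_starts, convergence = conv)
}

#' Fitness scan over bang-bang switching ages
#'
#' Evaluates the fitness of every schedule that produces at `h_max` up to a
#' switch age `t3` and nothing afterwards, over a grid of switch ages; an
#' independent cross-check for the two-phase Pontryagin solution.
#'
#' @param problem a [control_problem()].
#' @param grid_size number of switch ages (>= 50).
#' @return a list with `t3_grid`, `phi` (the fitness curve), `best_t3` and
#'   `best_phi`.
#' @export
two_phase_scan <- function(problem, grid_size = 200L) {
  stopifnot(inherits(problem, "control_problem"))
  if (grid_size < 50L) stop("'grid_size' must be >= 50")
  Tmax <- problem$T
  t3_grid <- seq(Tmax * 1e-6, Tmax, length.out = grid_size)
  phi <- vapply(t3_grid, function(t3) {
    pieces <- if (t3 >= Tmax) list(control_piece(0, Tmax, problem$h_max, "max"))
              else list(control_piece(0, t3, problem$h_max, "max"),
                        control_piece(t3, Tmax, 0, "zero"))
    fg <- trajectory_quadrature(pieces, problem)
    psi <- fg$A_nodes * fg$N_nodes + problem$cost$m * fg$h_nodes
    problem$C - sum(fg$w * psi)
  }, numeric(1))
  i <- which.max(phi)
  list(t3_grid = t3_grid, phi = phi, best_t3 = t3_grid[i], best_phi = phi[i])
}
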