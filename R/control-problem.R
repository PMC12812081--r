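#' Dynamic control problem for the naive T cell production schedule
#'
#' Bundles the cost parameters, the encounter-rate model, the horizon and the
#' production cap for the full dynamic optimization: choose `h(t)` on
#' `[0, T]`, `0 <= h <= h_max`, to maximize
#' `phi = C - integral( K n g(t) / N(t) + m h(t) ) dt` subject to
#' `dN/dt = h - u N`.
#'
#' The model's own initial condition `N(0) = 0` makes the fighting-cost
#' integral formally divergent for any schedule with finite `h` near birth,
#' so fitness evaluation uses a small regularized initial clone count `N0`,
#' applied identically to every schedule that is compared. The default is
#' `1e-6` times the singular-arc clone count at age 0. Rankings of schedules
#' are insensitive to this choice; absolute fitness values are not.
#'
#' @param cost a [cost_params()].
#' @param model an [encounter_model()].
#' @param T maximum age (horizon), strictly positive.
#' @param h_max maximum production rate, strictly positive.
#' @param C baseline fitness in the absence of naive T cell costs (additive
#'   constant).
#' @param N0 initial clone-count regularization; `NULL` for the default.
#' @param rel_tol,abs_tol integration tolerances for adaptive quadrature.
#' @param n_grid base number of subintervals used by the trajectory
#'   integrator over `[0, T]`.
#' @return an object of class `control_problem`.
#' @export
control_problem <- function(cost, model, T, h_max, C = 0, N0 = NULL,
                            rel_tol = 1e-10, abs_tol = 1e-12, n_grid = 1200L) {
  stopifnot(inherits(cost, "cost_params"), inherits(model, "encounter_model"))
  if (length(T) != 1L || !is.finite(T) || T <= 0) stop("'T' must be a positive age")
  if (length(h_max) != 1L || !is.finite(h_max) || h_max <= 0)
    stop("'h_max' must be strictly positive")
  if (is.null(N0)) {
    N0 <- 1e-6 * sqrt(cost$K * model$n * novelty_intensity(model, 0) / (cost$u * cost$m))
  }
  if (N0 < 0) stop("'N0' must be >= 0")
  if (rel_tol <= 0 || abs_tol <= 0) stop("tolerances must be positive")
  structure(list(cost = cost, model = model, T = as.numeric(T),
                 h_max = as.numeric(h_max), C = as.numeric(C),
                 N0 = as.numeric(N0), rel_tol = rel_tol, abs_tol = abs_tol,
                 n_grid = as.integer(n_grid)),
            class = "control_problem")
}

#' @export
print.control_problem <- function(x, ...) {
  cat("Dynamic control problem on [0, ", x$T, "]: h in [0, ", x$h_max,
      "], C = ", x$C, ", N0 = ", format(x$N0), "\n", sep = "")
  print(x$cost)
  print(x$model)
  invisible(x)
}

# A control is represented internally as a list of pieces covering [0, T]:
# each piece has t0 < t1 and either a constant level (type "const") or a
# vectorized function of age (type "fun"), plus a label used by the
# certificate ("max", "singular", "zero", "custom").
control_piece <- function(t0, t1, h, label = "custom") {
  if (is.function(h)) list(t0 = t0, t1 = t1, type = "fun", h = h, label = label)
  else list(t0 = t0, t1 = t1, type = "const", h = as.numeric(h), label = label)
}

#' Piecewise description of a candidate optimal schedule
#'
#' Built by [assemble_schedule()]; a three-phase schedule runs at `h_max` on
#' `[0, t1)`, follows the singular control on `[t1, t2)` and produces nothing
#' on `[t2, T]`; a two-phase schedule switches once from `h_max` to zero at
#' `t3`.
#'
#' @name phase_schedule
#' @seealso [assemble_schedule()], [integrate_trajectory()]
NULL

new_phase_schedule <- function(structure, problem, t1 = NA_real_, t2 = NA_real_,
                               t3 = NA_real_, pieces) {
  structure(list(structure = structure, t1 = t1, t2 = t2, t3 = t3,
                 T = problem$T, h_max = problem$h_max, pieces = pieces),
            class = "phase_schedule")
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat("Candidate optimal schedule (", x$structure, ") on [0, ", x$T, "]\n", sep = "")
  for (p in x$pieces) {
    cat(sprintf("  [%-8s] %.6g .. %.6g : %s\n", p$label, p$t0, p$t1,
                if (p$type == "const") paste("h =", format(p$h)) else "h(t) (singular rule)"))
  }
  invisible(x)
}

#' Piecewise-constant control on a grid
#'
#' The discretized control space used by the direct optimizer: constant
#' levels on consecutive intervals spanning `[0, T]`.
#'
#' @param breakpoints strictly increasing ages starting at 0; length
#'   `length(levels) + 1`.
#' @param levels per-interval production rates.
#' @param h_max optional cap; if given, levels are validated against
#'   `[0, h_max]`.
#' @return an object of class `gridded_control`.
#' @export
gridded_control <- function(breakpoints, levels, h_max = NULL) {
  if (length(breakpoints) != length(levels) + 1L)
    stop("'breakpoints' must have length(levels) + 1 entries")
  if (any(diff(breakpoints) <= 0)) stop("'breakpoints' must be strictly increasing")
  if (abs(breakpoints[1L]) > 1e-12) stop("'breakpoints' must start at age 0")
  if (any(levels < 0)) stop("levels must be >= 0")
  if (!is.null(h_max) && any(levels > h_max + 1e-12))
    stop("levels must not exceed h_max")
  structure(list(breakpoints = as.numeric(breakpoints),
                 levels = as.numeric(levels)),
            class = "gridded_control")
}

#' @export
print.gridded_control <- function(x, ...) {
  cat("Piecewise-constant control:", length(x$levels), "intervals on [0,",
      x$breakpoints[length(x$breakpoints)], "]\n")
  invisible(x)
}

control_pieces <- function(x, problem) {
  if (inherits(x, "phase_schedule")) return(x$pieces)
  if (inherits(x, "gridded_control")) {
    k <- length(x$levels)
    return(lapply(seq_len(k), function(i)
      control_piece(x$breakpoints[i], x$breakpoints[i + 1L], x$levels[i])))
  }
  if (is.list(x) && all(vapply(x, is.list, logical(1)))) return(x)
  stop("unsupported control representation")
}
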