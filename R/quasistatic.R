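#' Cost parameters of the involution trade-off
#'
#' @param K strictly positive; magnitude of the fighting cost incurred per
#'   novel-pathogen infection (the cost of one infection is `K / N`, inversely
#'   proportional to the peripheral clone count `N`).
#' @param m strictly positive; maintenance cost per unit naive T cell output
#'   from the thymus.
#' @param u strictly positive; exponential decay rate of naive T cell clones
#'   in the periphery.
#' @return an object of class `cost_params`.
#' @export
cost_params <- function(K, m, u) {
  vals <- c(K = K, m = m, u = u)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("'K', 'm' and 'u' must all be strictly positive and finite")
  structure(list(K = as.numeric(K), m = as.numeric(m), u = as.numeric(u)),
            class = "cost_params")
}

#' @export
print.cost_params <- function(x, ...) {
  cat("Cost parameters: K =", x$K, "(fighting), m =", x$m,
      "(maintenance), u =", x$u, "(peripheral clone decay)\n")
  invisible(x)
}

#' Instantaneous cost rate under rapid peripheral turnover
#'
#' With rapid turnover the clone count sits at its quasi-stationary value
#' `N = h / u`, and the cost per unit time at age `t` under production rate
#' `h` is `n g(t) K u / h + m h`: a diverging fighting cost as `h` shrinks
#' against a linear maintenance cost as `h` grows.
#'
#' @param t age, `t >= 0` (vectorized jointly with `h`).
#' @param h production rate, strictly positive.
#' @param params a [cost_params()].
#' @param model an [encounter_model()].
#' @return cost per unit time.
#' @export
pointwise_cost <- function(t, h, params, model) {
  stopifnot(inherits(params, "cost_params"), inherits(model, "encounter_model"))
  check_age(t)
  if (any(!is.finite(h)) || any(h <= 0))
    stop("'h' must be strictly positive (the fighting cost diverges at h = 0)")
  g <- novelty_intensity(model, t)
  model$n * g * params$K * params$u / h + params$m * h
}

#' Optimal production rate under rapid peripheral turnover
#'
#' Minimizes the instantaneous cost at each age independently, giving
#' `h(t) = sqrt(K u n g(t) / m)`. With identical encounter rates this is an
#' exponential decline `sqrt(K u n fbar / m) exp(-fbar t / 2)`; with
#' Gamma-dispersed rates (shape `a`) it is
#' `sqrt(K u n fbar / m) (1 + fbar t / a)^-((a+1)/2)`, a power-law decline
#' when `a` is small.
#'
#' @inheritParams pointwise_cost
#' @return optimal production rate at each age in `t`.
#' @export
optimal_production <- function(t, params, model) {
  stopifnot(inherits(params, "cost_params"), inherits(model, "encounter_model"))
  check_age(t)
  sqrt(params$K * params$u * model$n * novelty_intensity(model, t) / params$m)
}

#' Quasi-stationary clone count under the optimal schedule
#'
#' `N(t) = h(t) / u` where `h` is [optimal_production()].
#'
#' @inheritParams pointwise_cost
#' @return clone count at each age in `t`.
#' @export
clone_count <- function(t, params, model) {
  optimal_production(t, params, model) / params$u
}

#' Total lifetime naive T cell production
#'
#' Integrates the quasi-static optimal schedule over age. With identical
#' encounter rates and an infinite horizon the closed form is
#' `2 sqrt(K u n / (m fbar))`: lifetime output rises with the fighting cost
#' and the number of strains, and falls with the maintenance cost and the
#' per-strain encounter rate. Heavy-tailed Gamma dispersion (`a <= 1`) makes
#' the infinite-horizon integral diverge (the schedule decays like
#' `t^-((a+1)/2)`), which is reported as an error rather than truncated.
#'
#' @inheritParams pointwise_cost
#' @param horizon upper limit of integration; `Inf` for the whole-life
#'   approximation.
#' @param rel_tol relative tolerance passed to the adaptive quadrature.
#' @return integrated production (clone count).
#' @export
lifetime_production <- function(params, model, horizon = Inf, rel_tol = 1e-10) {
  stopifnot(inherits(params, "cost_params"), inherits(model, "encounter_model"))
  if (length(horizon) != 1L || is.na(horizon) || horizon < 0)
    stop("'horizon' must be a single age >= 0, possibly Inf")
  if (horizon == 0) return(0)
  if (is.infinite(horizon) && model$kind == "gamma" && model$shape <= 1)
    stop("lifetime production diverges: the Gamma schedule with shape a <= 1 decays ",
         "like t^-((a+1)/2), which is not integrable on an infinite horizon")
  f <- function(t) optimal_production(t, params, model)
  stats::integrate(f, 0, horizon, rel.tol = rel_tol, subdivisions = 500L)$value
}

#' Log-schedule slope and curvature diagnostics
#'
#' Finite-difference first and second derivatives of `log h(t)` on a grid.
#' For any dispersion in encounter rates the log-schedule has negative slope
#' and nonnegative curvature (the decline decelerates with age); the
#' curvature is identically zero only when all strains share one rate, in
#' which case the log-schedule is the straight line of slope `-fbar / 2`.
#'
#' @inheritParams pointwise_cost
#' @param grid strictly increasing ages, length >= 3.
#' @param tol tolerance on log-values used when flagging violations
#'   (absorbs floating-point noise).
#' @return a list with `grid`, `slope` (forward differences at
#'   `grid[-length(grid)]`), `curvature` (second differences at interior
#'   points), and integer vectors `slope_violations`, `curvature_violations`
#'   indexing grid points where slope >= 0 or curvature < 0 beyond `tol`.
#' @export
log_schedule_diagnostics <- function(params, model, grid, tol = 1e-10) {
  if (length(grid) < 3L || any(diff(grid) <= 0))
    stop("'grid' must be strictly increasing with length >= 3")
  lh <- log(optimal_production(grid, params, model))
  dt <- diff(grid)
  slope <- diff(lh) / dt
  # second difference on a possibly non-uniform grid
  n <- length(grid)
  curvature <- 2 * (lh[-c(1L, 2L)] * dt[-(n - 1L)] -
                    lh[-c(1L, n)] * (dt[-1L] + dt[-(n - 1L)]) +
                    lh[-c(n - 1L, n)] * dt[-1L]) /
    (dt[-1L] * dt[-(n - 1L)] * (dt[-1L] + dt[-(n - 1L)]))
  list(grid = grid,
       slope = slope,
       curvature = curvature,
       slope_violations = which(slope >= tol),
       curvature_violations = which(curvature < -tol))
}

#' Tabulate the quasi-static optimal schedule
#'
#' Convenience wrapper producing the table emitted by the command-line
#' `quasistatic` subcommand.
#'
#' @inheritParams pointwise_cost
#' @param grid ages at which to evaluate the schedule.
#' @return a data.frame with columns `t`, `h`, `N`, `Psi`, `log_h`.
#' @export
quasistatic_schedule <- function(params, model, grid) {
  check_age(grid)
  h <- optimal_production(grid, params, model)
  data.frame(t = grid,
             h = h,
             N = h / params$u,
             Psi = pointwise_cost(grid, h, params, model),
             log_h = log(h))
}
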