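#' Monte Carlo simulation of pathogen-encounter life histories
#'
#' Validates the expectation structure of the deterministic cost model: each
#' strain's first encounter happens at an exponential time with its own rate
#' (strains whose time exceeds the horizon are never met); only first
#' encounters cost anything, because the host retains lifelong memory. Each
#' first encounter at age `t` costs `K / N(t)` with `N` the deterministic
#' clone-count trajectory under the schedule; the maintenance cost
#' `integral(m h)` is deterministic. The mean realized lifetime cost over
#' hosts converges to `integral(Psi)` at the usual `1/sqrt(hosts)` rate.
#'
#' @param schedule a [phase_schedule][assemble_schedule()] or
#'   [gridded_control()].
#' @param problem a [control_problem()].
#' @param hosts number of simulated hosts (>= 1).
#' @param seed integer seed; identical seeds give identical samples.
#' @param freeze_rates if `TRUE`, draw one per-strain rate vector and share
#'   it across hosts (the fixed-rate-list reading of the cost model); if
#'   `FALSE` (default), resample the rates for every host.
#' @return a list of class `lifetime_cost_sim` with `mean`, `se`,
#'   `per_host` (total realized cost per host), `fighting`, `production`
#'   (the deterministic maintenance cost), and `encounter_ages` (hosts x
#'   strains matrix of first-encounter ages, `NA` when never encountered).
#' @export
simulate_lifetime_cost <- function(schedule, problem, hosts, seed = NULL,
                                   freeze_rates = FALSE) {
  stopifnot(inherits(problem, "control_problem"))
  if (hosts < 1 || hosts != round(hosts)) stop("'hosts' must be a positive integer")
  hosts <- as.integer(hosts)
  n <- problem$model$n
  Tmax <- problem$T

  traj <- integrate_trajectory(schedule, problem)
  if (any(traj$N <= 0))
    stop("clone count reaches zero under this schedule; fighting cost undefined")
  # N on the trajectory grid: monotone-safe interpolation for encounter ages
  N_at <- stats::approxfun(traj$ages, traj$N, rule = 2)
  quad <- attr(traj, "quad")
  production_cost <- sum(quad$w * problem$cost$m * quad$h_nodes)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }

  if (freeze_rates || problem$model$kind %in% c("degenerate", "empirical")) {
    rates <- sample_rates(problem$model, n)
    rate_mat <- matrix(rates, hosts, n, byrow = TRUE)
  } else {
    rate_mat <- matrix(sample_rates(problem$model, hosts * n), hosts, n)
  }

  ages <- matrix(stats::rexp(hosts * n, rate = as.vector(rate_mat)), hosts, n)
  ages[ages > Tmax] <- NA_real_
  fighting <- vapply(seq_len(hosts), function(i) {
    a <- ages[i, ]
    a <- a[!is.na(a)]
    if (!length(a)) 0 else sum(problem$cost$K / N_at(a))
  }, numeric(1))

  per_host <- fighting + production_cost
  structure(list(mean = mean(per_host),
                 se = stats::sd(per_host) / sqrt(hosts),
                 per_host = per_host,
                 fighting = fighting,
                 production = production_cost,
                 encounter_ages = ages),
            class = "lifetime_cost_sim")
}

#' @export
print.lifetime_cost_sim <- function(x, ...) {
  cat("Simulated lifetime cost over", length(x$per_host), "hosts:",
      format(x$mean), "+/-", format(x$se), "(SE)\n")
  invisible(x)
}

#' Empirical novelty curve from simulated life histories
#'
#' The fraction of (host, strain) pairs not yet encountered by each grid
#' age: a Monte Carlo estimate of the per-strain novelty probability
#' `E[exp(-f t)]` returned by [novel_fraction()].
#'
#' @param sim a [simulate_lifetime_cost()] result (or a matrix of
#'   first-encounter ages with `NA` for never-encountered).
#' @param grid ages at which to evaluate the curve.
#' @return numeric vector of novel fractions, one per grid age.
#' @export
empirical_novelty_curve <- function(sim, grid) {
  ages <- if (inherits(sim, "lifetime_cost_sim")) sim$encounter_ages else sim
  if (!length(ages)) stop("no samples")
  check_age(grid)
  vapply(grid, function(t0) mean(is.na(ages) | ages > t0), numeric(1))
}
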