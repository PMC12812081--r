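#' Clone count along the singular arc
#'
#' On a singular segment the costate sits at `lambda = m` and the costate
#' ODE's stationarity pins the state to
#' `N*(t) = sqrt(K n g(t) / (u m))`, i.e. the residual
#' `-K n g(t) / N^2 + u m` vanishes identically. This is exactly the
#' quasi-static optimal clone count: the dynamic and rapid-turnover optima
#' agree on the arc. With identical encounter rates the closed form is
#' `sqrt(K n fbar / (m u)) exp(-fbar t / 2)`; with Gamma-dispersed rates it
#' is the same prefactor times `(1 + fbar t / a)^-((a+1)/2)`. For lognormal
#' and empirical models the identical stationarity solution is evaluated
#' through the numerically computed `g(t)`.
#'
#' @param t age (vectorized), `t >= 0`.
#' @param problem a [control_problem()].
#' @return singular-arc clone count at each age in `t`.
#' @export
singular_clone_count <- function(t, problem) {
  stopifnot(inherits(problem, "control_problem"))
  check_age(t)
  with(problem, sqrt(cost$K * model$n * novelty_intensity(model, t) / (cost$u * cost$m)))
}

#' Production rate along the singular arc
#'
#' The control that holds the state on the singular arc:
#' `h(t) = dN*/dt + u N* = N*(t) (u + g'(t) / (2 g(t)))`. With identical
#' encounter rates this is `(u - fbar/2) sqrt(K n fbar / (m u)) exp(-fbar t / 2)`
#' (strictly below the quasi-static production rate `u N*`); slow peripheral
#' decay `u <= fbar / 2` makes it negative, i.e. the singular arc is
#' infeasible and all production is concentrated early in life.
#'
#' @inheritParams singular_clone_count
#' @param check if `TRUE` (default), raise an error when the value falls
#'   outside `[0, h_max]` at any requested age.
#' @return singular production rate at each age in `t`.
#' @export
singular_control <- function(t, problem, check = TRUE) {
  stopifnot(inherits(problem, "control_problem"))
  check_age(t)
  g <- novelty_intensity(problem$model, t)
  gp <- novelty_intensity_deriv(problem$model, t)
  Nstar <- sqrt(problem$cost$K * problem$model$n * g / (problem$cost$u * problem$cost$m))
  h <- Nstar * (problem$cost$u + gp / (2 * g))
  if (check) {
    if (any(h < -1e-12 * problem$h_max))
      stop("singular arc infeasible at t = ",
           format(t[which(h < 0)[1L]]), ": singular control is negative")
    if (any(h > problem$h_max * (1 + 1e-12)))
      stop("singular control exceeds h_max at t = ",
           format(t[which(h > problem$h_max)[1L]]))
  }
  pmax(h, 0)
}

#' Age at which the maximum-rate trajectory reaches the singular arc
#'
#' Solves `N0 exp(-u t1) + (h_max / u)(1 - exp(-u t1)) = N*(t1)` by bracketed
#' root finding: the clone count grown from birth at the production cap
#' meets the singular-arc clone count at `t1`. (With the regularization
#' `N0 = 0` this is the textbook switching equation; the default `N0` is
#' small enough that the two agree to ~1e-6.)
#'
#' @param problem a [control_problem()].
#' @param tol root tolerance.
#' @return the switching age `t1`.
#' @export
solve_t1 <- function(problem, tol = 1e-12) {
  stopifnot(inherits(problem, "control_problem"))
  u <- problem$cost$u
  F <- function(t) problem$N0 * exp(-u * t) +
    (problem$h_max / u) * (1 - exp(-u * t)) - singular_clone_count(t, problem)
  grid <- seq(0, problem$T, length.out = 1001L)
  Fg <- F(grid)
  sc <- which(Fg[-1L] * Fg[-length(Fg)] <= 0)
  if (!length(sc)) {
    if (all(Fg < 0))
      stop("initial phase does not reach the singular arc within [0, T]; ",
           "h_max is too small for a three-phase solution")
    stop("maximum-rate trajectory starts above the singular arc; no initial phase")
  }
  i <- sc[1L]
  stats::uniroot(F, c(grid[i], grid[i + 1L]), tol = tol)$root
}

#' Onset age of the final no-production phase
#'
#' In the final phase production stops, the clone count decays from its
#' singular-arc value and the costate is integrated backward from
#' `lambda(T) = 0`; `t2` is the age at which `lambda` reaches `m`. With
#' identical encounter rates this has the closed form
#' `T - t2 = log(2 - fbar/u) / (u - fbar)` (with the removable singularity
#' `T - t2 -> 1/u` as `u -> fbar`), defined only for `u > fbar / 2`: slower
#' peripheral decay lengthens the final phase until the singular phase
#' disappears altogether. For dispersed encounter-rate models `t2` is found
#' by root-finding the same backward-costate condition numerically.
#'
#' @inheritParams solve_t1
#' @return the switching age `t2`.
#' @export
solve_t2 <- function(problem, tol = 1e-12) {
  stopifnot(inherits(problem, "control_problem"))
  u <- problem$cost$u
  Tmax <- problem$T
  if (problem$model$kind == "degenerate") {
    fb <- problem$model$mean_rate
    if (u <= fb / 2)
      stop("final-phase formula undefined: u <= fbar/2, no singular segment exists ",
           "(all production is concentrated at the beginning of life)")
    tau <- if (u == fb) 1 / u else log1p((u - fb) / u) / (u - fb)
    t2 <- Tmax - tau
    if (t2 < 0)
      stop("horizon too short for a final phase: T - t2 = ", format(tau), " exceeds T")
    return(t2)
  }
  # general backward-costate condition: u * int_{t2}^{T} (g(s)/g(t2)) e^{u(s-t2)} ds = 1
  F <- function(t2) {
    g2 <- novelty_intensity(problem$model, t2)
    val <- stats::integrate(function(s)
      novelty_intensity(problem$model, s) * exp(u * (s - t2)),
      t2, Tmax, rel.tol = 1e-11)$value
    u * val / g2 - 1
  }
  if (F(0) < 0)
    stop("horizon too short for a final phase: lambda never reaches m")
  grid <- seq(0, Tmax, length.out = 201L)
  Fg <- vapply(grid, F, numeric(1))
  i <- which(Fg[-1L] * Fg[-length(Fg)] <= 0)[1L]
  if (is.na(i)) stop("no onset of the final phase found in [0, T]")
  stats::uniroot(F, c(grid[i], grid[i + 1L]), tol = tol)$root
}

# Backward-costate value at the switch of a bang-bang (h_max then 0)
# schedule: lambda(t3) given the trajectory induced by switching at t3.
bang_bang_lambda_at_switch <- function(t3, problem) {
  u <- problem$cost$u
  Nb <- problem$N0 * exp(-u * t3) + (problem$h_max / u) * (1 - exp(-u * t3))
  val <- stats::integrate(function(s)
    novelty_intensity(problem$model, s) * exp(u * (s - t3)),
    t3, problem$T, rel.tol = 1e-11)$value
  problem$cost$K * problem$model$n * val / Nb^2
}

#' Assemble the candidate optimal schedule
#'
#' Builds the Pontryagin candidate: if the maximum-rate phase reaches the
#' singular arc before the final phase begins (`t1 < t2`), the schedule has
#' three phases (`h_max`, singular rule, zero). Otherwise the singular
#' segment disappears and the schedule is bang-bang with a single switch
#' `t3`, located by root-finding the switching condition `lambda(t3) = m`
#' on the self-consistent bang-bang trajectory (the same condition a dense
#' fitness scan over `t3` maximizes).
#'
#' @param problem a [control_problem()].
#' @return a `phase_schedule` object.
#' @export
assemble_schedule <- function(problem) {
  stopifnot(inherits(problem, "control_problem"))
  Tmax <- problem$T
  t1 <- tryCatch(solve_t1(problem), error = function(e) NA_real_)
  t2 <- tryCatch(solve_t2(problem), error = function(e) NA_real_)

  if (!is.na(t1) && !is.na(t2) && t1 < t2) {
    sing_ok <- tryCatch({
      singular_control(seq(t1, t2, length.out = 101L), problem, check = TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (sing_ok) {
      pieces <- list(
        control_piece(0, t1, problem$h_max, "max"),
        control_piece(t1, t2, function(t) singular_control(t, problem, check = FALSE),
                      "singular"),
        control_piece(t2, Tmax, 0, "zero"))
      return(new_phase_schedule("three_phase", problem, t1 = t1, t2 = t2,
                                pieces = pieces))
    }
  }

  # two-phase: single switch from h_max to 0 where lambda crosses m
  m <- problem$cost$m
  F <- function(t3) bang_bang_lambda_at_switch(t3, problem) - m
  eps <- Tmax * 1e-9
  FT <- F(Tmax - eps)
  if (FT >= 0) {
    warning("lambda exceeds m over the whole horizon; returning a single-phase ",
            "maximum-production schedule")
    return(new_phase_schedule("two_phase", problem, t3 = Tmax,
                              pieces = list(control_piece(0, Tmax, problem$h_max, "max"))))
  }
  F0 <- F(eps)
  if (F0 <= 0) {
    warning("lambda is below m from birth; returning a single-phase ",
            "zero-production schedule")
    return(new_phase_schedule("two_phase", problem, t3 = 0,
                              pieces = list(control_piece(0, Tmax, 0, "zero"))))
  }
  grid <- seq(eps, Tmax - eps, length.out = 201L)
  Fg <- vapply(grid, F, numeric(1))
  i <- which(Fg[-1L] * Fg[-length(Fg)] <= 0)[1L]
  t3 <- stats::uniroot(F, c(grid[i], grid[i + 1L]), tol = 1e-12)$root
  pieces <- list(control_piece(0, t3, problem$h_max, "max"),
                 control_piece(t3, Tmax, 0, "zero"))
  new_phase_schedule("two_phase", problem, t3 = t3, pieces = pieces)
}

#' Certify the Pontryagin conditions along a trajectory
#'
#' Numerical check of the maximum-principle conditions on an integrated
#' trajectory: (i) sign consistency between the costate and the control
#' (`lambda > m` only where `h = h_max`, `lambda < m` only where `h = 0`,
#' `lambda = m` within tolerance on singular segments); (ii) the terminal
#' condition `lambda(T) = 0`; (iii) a numerical generalized Legendre-Clebsch
#' sign check along the singular segment: the sensitivity of the second time
#' derivative of `dH/dh = lambda - m` with respect to the control, estimated
#' by central finite differences, must be positive (its analytic value is
#' `2 K n g / N^3`). Violations are reported, not raised.
#'
#' @param trajectory an [integrate_trajectory()] result.
#' @param problem the [control_problem()] it was integrated under.
#' @param sign_tol dead band around `lambda = m` for the bang-bang sign
#'   checks, as a fraction of `m`.
#' @param singular_tol allowed relative deviation `|lambda - m| / m` on
#'   singular segments.
#' @param terminal_tol allowed `|lambda(T)|` (absolute, relative to `m`).
#' @return an object of class `pmp_certificate`: a list of logical `passed`
#'   flags and maximum violation magnitudes.
#' @export
pmp_certificate <- function(trajectory, problem,
                            sign_tol = 1e-4, singular_tol = 1e-4,
                            terminal_tol = 1e-8) {
  stopifnot(inherits(trajectory, "trajectory"), inherits(problem, "control_problem"))
  m <- problem$cost$m
  u <- problem$cost$u
  K <- problem$cost$K
  n <- problem$model$n
  lam <- trajectory$lam
  h <- trajectory$h
  lab <- trajectory$label
  hmax <- problem$h_max

  # (i) sign consistency wherever lambda is clearly away from m
  above <- lam > m * (1 + sign_tol)
  below <- lam < m * (1 - sign_tol)
  viol_above <- if (any(above)) max(abs(h[above] - hmax)) else 0
  viol_below <- if (any(below)) max(abs(h[below])) else 0
  sing <- lab == "singular"
  sing_dev <- if (any(sing)) max(abs(lam[sing] - m)) / m else 0

  # (ii) terminal condition
  terminal_residual <- abs(lam[length(lam)])

  # (iii) generalized Legendre-Clebsch along the singular segment:
  # S(h) = d^2/dt^2 (dH/dh) as a function of the instantaneous control;
  # dS/dh estimated by central differences must be positive.
  glc_min <- NA_real_
  if (any(sing)) {
    idx <- which(sing)
    t_s <- trajectory$ages[idx]
    N_s <- trajectory$N[idx]
    lam_s <- lam[idx]
    g <- novelty_intensity(problem$model, t_s)
    gp <- novelty_intensity_deriv(problem$model, t_s)
    S <- function(hh) {
      Np <- hh - u * N_s
      -K * n * gp / N_s^2 + 2 * K * n * g * Np / N_s^3 +
        u * (-K * n * g / N_s^2 + u * lam_s)
    }
    delta <- max(1e-6 * hmax, 1e-9)
    dS <- (S(h[idx] + delta) - S(h[idx] - delta)) / (2 * delta)
    glc_min <- min(dS)
  }

  out <- list(
    sign_ok = viol_above <= sign_tol * hmax && viol_below <= sign_tol * hmax,
    terminal_ok = terminal_residual <= terminal_tol * m,
    singular_ok = sing_dev <= singular_tol,
    glc_ok = is.na(glc_min) || glc_min > 0,
    max_violation_hmax = viol_above,
    max_violation_zero = viol_below,
    max_singular_dev = sing_dev,
    terminal_residual = terminal_residual,
    glc_min_sensitivity = glc_min,
    has_singular = any(sing))
  out$passed <- out$sign_ok && out$terminal_ok && out$singular_ok && out$glc_ok
  class(out) <- "pmp_certificate"
  out
}

#' @export
print.pmp_certificate <- function(x, ...) {
  ok <- function(b) if (b) "ok" else "VIOLATED"
  cat("Pontryagin certificate:", if (x$passed) "PASSED" else "FAILED", "\n")
  cat("  sign consistency:  ", ok(x$sign_ok),
      " (max |h - h_max| where lambda > m: ", format(x$max_violation_hmax),
      ", max |h| where lambda < m: ", format(x$max_violation_zero), ")\n", sep = "")
  if (x$has_singular)
    cat("  singular segment:  ", ok(x$singular_ok),
        " (max |lambda - m| / m = ", format(x$max_singular_dev), ")\n", sep = "")
  cat("  terminal lambda(T):", ok(x$terminal_ok),
      " (|lambda(T)| = ", format(x$terminal_residual), ")\n", sep = "")
  if (x$has_singular)
    cat("  Legendre-Clebsch:  ", ok(x$glc_ok),
        " (min sensitivity = ", format(x$glc_min_sensitivity), ")\n", sep = "")
  invisible(x)
}
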