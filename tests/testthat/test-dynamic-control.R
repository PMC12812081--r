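test_that("the singular arc coincides with the quasi-static optimum", {
  for (make in list(
    function() fig4a_problem(),
    function() control_problem(cost_params(0.001, 1, 1),
                               encounter_model("gamma", n = 1000, shape = 5, rate_param = 20),
                               T = 10, h_max = 3),
    function() control_problem(cost_params(0.01, 1, 2),
                               encounter_model("empirical", n = 4,
                                               rates = c(0.1, 0.2, 0.3, 0.5)),
                               T = 10, h_max = 3))) {
    pr <- make()
    tt <- seq(0, pr$T, by = 0.5)
    expect_equal(singular_clone_count(tt, pr), clone_count(tt, pr$cost, pr$model),
                 tolerance = 1e-12)
    # stationarity residual -K n g / N^2 + u m = 0 to machine precision
    res <- -pr$cost$K * pr$model$n * novelty_intensity(pr$model, tt) /
      singular_clone_count(tt, pr)^2 + pr$cost$u * pr$cost$m
    expect_lt(max(abs(res)), 1e-10)
  }
})

test_that("the Gamma singular arc approaches the single-rate arc as shape grows", {
  pr_deg <- control_problem(cost_params(0.001, 1, 1),
                            encounter_model("degenerate", n = 1000, mean_rate = 0.275),
                            T = 10, h_max = 3)
  pr_gam <- control_problem(cost_params(0.001, 1, 1),
                            encounter_model("gamma", n = 1000, shape = 1e5,
                                            rate_param = 1e5 / 0.275),
                            T = 10, h_max = 3)
  tt <- seq(0, 10, by = 0.25)
  expect_equal(singular_clone_count(tt, pr_gam), singular_clone_count(tt, pr_deg),
               tolerance = 1e-3)
  expect_equal(singular_control(tt, pr_gam), singular_control(tt, pr_deg),
               tolerance = 1e-3)
})

test_that("singular control obeys its closed forms and feasibility limits", {
  pr <- fig4a_problem() # u = 1, fbar = 0.275
  tt <- seq(0, 10, by = 0.5)
  fb <- 0.275
  closed <- (1 - fb / 2) * sqrt(0.001 * 1000 * fb / 1) * exp(-fb * tt / 2)
  expect_equal(singular_control(tt, pr), closed, tolerance = 1e-12)
  # strictly below the quasi-static production rate at every age
  expect_true(all(singular_control(tt, pr) < optimal_production(tt, pr$cost, pr$model)))

  # u = fbar/2 makes the singular control vanish at all ages
  pr0 <- control_problem(cost_params(0.001, 1, u = 0.275 / 2),
                         encounter_model("degenerate", n = 1000, mean_rate = 0.275),
                         T = 10, h_max = 3)
  expect_equal(singular_control(tt, pr0), rep(0, length(tt)), tolerance = 1e-12)

  # u < fbar/2: infeasible (negative) singular control is rejected
  pr_neg <- control_problem(cost_params(0.001, 1, u = 0.1),
                            encounter_model("degenerate", n = 1000, mean_rate = 0.275),
                            T = 10, h_max = 3)
  expect_error(singular_control(5, pr_neg), "infeasible")

  # finite-difference dN*/dt + u N* recovers the closed form (gamma case too)
  prg <- control_problem(cost_params(0.001, 1, 1),
                         encounter_model("gamma", n = 1000, shape = 5, rate_param = 20),
                         T = 10, h_max = 3)
  eps <- 1e-6
  for (t0 in c(0.5, 3, 8)) {
    dN <- (singular_clone_count(t0 + eps, prg) - singular_clone_count(t0 - eps, prg)) /
      (2 * eps)
    expect_equal(singular_control(t0, prg),
                 dN + prg$cost$u * singular_clone_count(t0, prg), tolerance = 1e-6)
  }
  # and the printed Gamma closed form
  a <- 5; fb <- 0.25
  tt <- c(0.5, 3, 8)
  pref <- sqrt(0.001 * 1000 * fb / 1)
  closed_g <- pref * (1 - ((a + 1) / 2) * (fb / a) / (1 + fb * tt / a)) *
    (1 + fb * tt / a)^(-(a + 1) / 2)
  expect_equal(singular_control(tt, prg), closed_g, tolerance = 1e-12)
})

test_that("t1 matches an independent forward RK4 crossing of the singular arc", {
  pr <- fig4a_problem()
  t1 <- solve_t1(pr)
  # defining equation residual
  lhs <- pr$N0 * exp(-1 * t1) + (pr$h_max / 1) * (1 - exp(-t1))
  expect_equal(lhs, singular_clone_count(t1, pr), tolerance = 1e-10)

  # independent oracle: fixed-step RK4 of dN/dt = h_max - u N from N0
  times <- seq(0, 0.4, by = 1e-4)
  Nrk <- rk4_path(function(t, N) pr$h_max - pr$cost$u * N, pr$N0, times)
  gap <- splinefun(times, Nrk - singular_clone_count(times, pr))
  t1_oracle <- uniroot(gap, c(0.1, 0.3), tol = 1e-14)$root
  expect_lt(abs(t1 - t1_oracle), 1e-8)

  # a huge cap makes the initial phase vanish
  pr_big <- fig4a_problem(N0 = 1e-9)
  pr_big$h_max <- 1e6
  expect_lt(solve_t1(pr_big), 1e-3)

  # too small a cap: the max-rate trajectory never reaches the arc
  expect_error(solve_t1(fig4b_problem()), "does not reach")
})

test_that("t2 matches the closed form and a backward RK4 costate oracle", {
  pr <- control_problem(cost_params(K = 0.001, m = 1, u = 1),
                        encounter_model("degenerate", n = 1000, mean_rate = 0.5),
                        T = 10, h_max = 3)
  t2 <- solve_t2(pr)
  expect_equal(10 - t2, 2 * log(1.5), tolerance = 1e-12)

  # oracle: integrate the costate ODE backward from lambda(T) = 0 with h = 0
  # and N decaying from the singular-arc value at candidate t2; lambda(t2) = m
  lam_at <- function(t2c) {
    N2 <- singular_clone_count(t2c, pr)
    times <- seq(10, t2c, length.out = 4001)
    f <- function(t, lam) {
      N <- N2 * exp(-pr$cost$u * (t - t2c))
      -pr$cost$K * pr$model$n * novelty_intensity(pr$model, t) / N^2 + pr$cost$u * lam
    }
    rk4_path(f, 0, times)[4001]
  }
  t2_oracle <- uniroot(function(t) lam_at(t) - 1, c(8, 9.8), tol = 1e-10)$root
  expect_lt(abs(t2 - t2_oracle), 1e-6)

  # removable singularity u -> fbar: final phase length tends to 1/u
  pr_eq <- control_problem(cost_params(0.001, 1, u = 0.5),
                           encounter_model("degenerate", n = 1000, mean_rate = 0.5),
                           T = 10, h_max = 3)
  expect_equal(10 - solve_t2(pr_eq), 1 / 0.5, tolerance = 1e-12)
  pr_near <- control_problem(cost_params(0.001, 1, u = 0.5 + 1e-9),
                             encounter_model("degenerate", n = 1000, mean_rate = 0.5),
                             T = 10, h_max = 3)
  expect_equal(10 - solve_t2(pr_near), 2, tolerance = 1e-6)

  # slower peripheral decay lengthens the final phase
  u_grid <- c(2, 1, 0.6, 0.35)
  tails <- vapply(u_grid, function(u) {
    p <- control_problem(cost_params(0.001, 1, u),
                         encounter_model("degenerate", n = 1000, mean_rate = 0.5),
                         T = 30, h_max = 3)
    p$T - solve_t2(p)
  }, numeric(1))
  expect_true(all(diff(tails) > 0))

  expect_error(solve_t2(control_problem(cost_params(0.001, 1, u = 0.2),
                                        encounter_model("degenerate", n = 1000,
                                                        mean_rate = 0.5),
                                        T = 10, h_max = 3)),
               "undefined")

  # general (root-found) branch agrees with the closed form in the
  # near-degenerate Gamma limit
  prg <- control_problem(cost_params(0.001, 1, 1),
                         encounter_model("gamma", n = 1000, shape = 1e6,
                                         rate_param = 2e6),
                         T = 10, h_max = 3)
  expect_equal(solve_t2(prg), solve_t2(pr), tolerance = 1e-4)
})

test_that("schedule assembly picks the right structure", {
  sch_a <- assemble_schedule(fig4a_problem())
  expect_identical(sch_a$structure, "three_phase")
  expect_lt(sch_a$t1, sch_a$t2)

  sch_b <- assemble_schedule(fig4b_problem())
  expect_identical(sch_b$structure, "two_phase")
  expect_true(sch_b$t3 > 0 && sch_b$t3 < 10)

  # the lambda-crossing switch agrees with the argmax of a dense fitness scan
  scan <- two_phase_scan(fig4b_problem(), grid_size = 200)
  expect_lt(abs(sch_b$t3 - scan$best_t3), 10 / 200)

  # slow peripheral decay (u <= fbar/2): no singular segment survives
  pr_slow <- control_problem(cost_params(0.001, 1, u = 0.1),
                             encounter_model("degenerate", n = 1000, mean_rate = 0.275),
                             T = 10, h_max = 3)
  sch_slow <- assemble_schedule(pr_slow)
  expect_identical(sch_slow$structure, "two_phase")
  expect_false(any(vapply(sch_slow$pieces, `[[`, character(1), "label") == "singular"))
})

test_that("trajectory integration reproduces linear-ODE closed forms", {
  pr <- fig4a_problem(N0 = 0.05)
  # constant control: N(t) = N0 e^(-ut) + (h/u)(1 - e^(-ut))
  ctl <- gridded_control(c(0, 4, 10), c(1.2, 1.2))
  tr <- integrate_trajectory(ctl, pr)
  expect_equal(tr$N, 0.05 * exp(-tr$ages) + 1.2 * (1 - exp(-tr$ages)),
               tolerance = 1e-10)
  # zero control: pure fighting cost, exponential decay of N
  ctl0 <- gridded_control(c(0, 10), 0)
  tr0 <- integrate_trajectory(ctl0, pr)
  expect_equal(tr0$N, 0.05 * exp(-tr0$ages), tolerance = 1e-12)
  expect_equal(tr0$psi,
               pr$cost$K * pr$model$n * novelty_intensity(pr$model, tr0$ages) / tr0$N,
               tolerance = 1e-12)

  # closed-form fitness oracle for the no-production schedule:
  # phi = C - K n fbar (e^((u - fbar) T) - 1) / ((u - fbar) N0)
  fb <- 0.275
  phi_closed <- pr$C - pr$cost$K * pr$model$n * fb *
    (exp((1 - fb) * 10) - 1) / ((1 - fb) * 0.05)
  expect_equal(tr0$phi, phi_closed, tolerance = 1e-9)

  # an additive constant in C shifts phi by exactly that constant
  pr_C <- fig4a_problem(N0 = 0.05, C = 7.5)
  expect_equal(integrate_trajectory(ctl, pr_C)$phi, tr$phi + 7.5, tolerance = 1e-10)
})

test_that("the three-phase candidate satisfies the maximum-principle conditions", {
  pr <- fig4a_problem()
  sch <- assemble_schedule(pr)
  tr <- integrate_trajectory(sch, pr)
  # lambda = m on the singular segment, lambda(T) = 0, N continuous at switches
  sing <- tr$label == "singular"
  expect_lt(max(abs(tr$lam[sing] - 1)), 1e-4)
  expect_lt(abs(tr$lam[length(tr$lam)]), 1e-8)
  i1 <- which(tr$ages == sch$t1); i2 <- which(tr$ages == sch$t2)
  expect_equal(tr$N[i1], singular_clone_count(sch$t1, pr), tolerance = 1e-6)
  expect_equal(tr$N[i2], singular_clone_count(sch$t2, pr), tolerance = 1e-6)

  cert <- pmp_certificate(tr, pr)
  expect_true(cert$passed)
  expect_true(cert$glc_ok)
  expect_gt(cert$glc_min_sensitivity, 0)

  # perturbing t1 lowers fitness
  phi0 <- tr$phi
  for (fac in c(0.95, 1.05)) {
    t1p <- sch$t1 * fac
    pieces <- list(
      thymodel:::control_piece(0, t1p, pr$h_max, "max"),
      thymodel:::control_piece(t1p, sch$t2,
                               function(t) singular_control(t, pr, check = FALSE),
                               "singular"),
      thymodel:::control_piece(sch$t2, 10, 0, "zero"))
    expect_lt(integrate_trajectory(pieces, pr)$phi, phi0)
  }
})

test_that("the certificate flags deliberately wrong schedules", {
  pr <- fig4a_problem()
  sch <- assemble_schedule(pr)
  # swapped switch roles: produce nothing early, flat out late
  bad <- list(thymodel:::control_piece(0, sch$t1, 0, "zero"),
              thymodel:::control_piece(sch$t1, sch$t2, pr$h_max, "max"),
              thymodel:::control_piece(sch$t2, 10, 0, "zero"))
  cert_bad <- pmp_certificate(integrate_trajectory(bad, pr), pr)
  expect_false(cert_bad$passed)
  expect_false(cert_bad$sign_ok)

  # flat-out production violates the final-phase sign condition
  allmax <- gridded_control(c(0, 10), pr$h_max)
  cert_max <- pmp_certificate(integrate_trajectory(allmax, pr), pr)
  expect_false(cert_max$sign_ok)
  expect_gt(cert_max$max_violation_zero, 0)
})
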