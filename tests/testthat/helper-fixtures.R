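# Shared fixtures and independent numerical oracles. The oracles here must
# stay independent of the package's integration path: classic fixed-step RK4
# and brute-force summation/grid search only.

fig4a_problem <- function(u = 1, ...) {
  control_problem(cost_params(K = 0.001, m = 1, u = u),
                  encounter_model("degenerate", n = 1000, mean_rate = 0.275),
                  T = 10, h_max = 3, ...)
}

fig4b_problem <- function(u = 1, ...) {
  control_problem(cost_params(K = 0.001, m = 1, u = u),
                  encounter_model("degenerate", n = 1000, mean_rate = 0.2751),
                  T = 10, h_max = 0.1, ...)
}

# Kun/m = 1e4 decomposition used by the quasi-static worked examples
quasi_params <- function() cost_params(K = 10, m = 1, u = 1)

# classic fixed-step RK4 for dy/dt = f(t, y); returns y at all times
rk4_path <- function(f, y0, times) {
  y <- numeric(length(times))
  y[1] <- y0
  for (i in seq_len(length(times) - 1L)) {
    t <- times[i]; dt <- times[i + 1L] - t; yi <- y[i]
    k1 <- f(t, yi)
    k2 <- f(t + dt / 2, yi + dt * k1 / 2)
    k3 <- f(t + dt / 2, yi + dt * k2 / 2)
    k4 <- f(t + dt, yi + dt * k3)
    y[i + 1L] <- yi + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
  }
  y
}

# random encounter model of any kind, for property sweeps
random_model <- function(kind = NULL) {
  if (is.null(kind)) kind <- sample(c("degenerate", "gamma", "lognormal", "empirical"), 1)
  switch(kind,
    degenerate = encounter_model("degenerate", n = 500, mean_rate = runif(1, 0.02, 1)),
    gamma = encounter_model("gamma", n = 500, shape = runif(1, 0.5, 50),
                            rate_param = runif(1, 5, 200)),
    lognormal = encounter_model("lognormal", n = 500, log_mean = runif(1, -4, -1),
                                log_var = runif(1, 0.05, 1.5)),
    empirical = encounter_model("empirical", n = 20,
                                rates = runif(20, 0.01, 1))
  )
}
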