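#' Encounter-rate distribution across pathogen strains
#'
#' A host meets each of `n` pathogen strains as an independent Poisson process
#' with per-strain rate `f`. The distribution of `f` across strains determines
#' the shape of thymic involution: identical rates give an exponential decline
#' of the optimal naive T cell production rate, while dispersed rates (Gamma,
#' lognormal, or an explicit empirical list) flatten the decline toward a
#' power law.
#'
#' Parametrizations follow the shape-rate convention for the Gamma law
#' (density proportional to `f^(shape-1) * exp(-rate_param * f)`), with mean
#' `shape / rate_param`, and the log-scale mean/variance for the lognormal
#' law, with mean `exp(log_mean + log_var / 2)`.
#'
#' @param kind one of `"degenerate"`, `"gamma"`, `"lognormal"`, `"empirical"`.
#' @param n positive integer; number of pathogen strains a host may encounter
#'   over its lifetime.
#' @param mean_rate mean encounter rate per unit age (degenerate kind; for
#'   the other kinds it is derived from the shape parameters and must not be
#'   supplied).
#' @param shape,rate_param Gamma shape `a` and rate `b` (gamma kind only).
#' @param log_mean,log_var mean and variance of `log f` (lognormal kind only).
#' @param rates numeric vector of `n` strictly positive per-strain rates
#'   (empirical kind only).
#' @return an object of class `encounter_model`.
#' @examples
#' m <- encounter_model("gamma", n = 1000, shape = 1, rate_param = 10)
#' m$mean_rate             # 0.1
#' novelty_intensity(m, 5) # mean of f * exp(-f t) across strains
#' @export
encounter_model <- function(kind = c("degenerate", "gamma", "lognormal", "empirical"),
                            n,
                            mean_rate = NULL,
                            shape = NULL, rate_param = NULL,
                            log_mean = NULL, log_var = NULL,
                            rates = NULL) {
  kind <- match.arg(kind)
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("'n' must be a positive integer")
  n <- as.integer(n)

  has <- function(x) !is.null(x)
  model <- list(kind = kind, n = n)

  if (kind == "degenerate") {
    if (!has(mean_rate) || mean_rate <= 0)
      stop("degenerate model requires a strictly positive 'mean_rate'")
    if (has(shape) || has(rate_param) || has(log_mean) || has(log_var) || has(rates))
      stop("degenerate model takes only 'mean_rate'")
    model$mean_rate <- as.numeric(mean_rate)
  } else if (kind == "gamma") {
    if (!has(shape) || !has(rate_param) || shape <= 0 || rate_param <= 0)
      stop("gamma model requires strictly positive 'shape' and 'rate_param'")
    if (has(mean_rate))
      stop("gamma model derives 'mean_rate' = shape / rate_param; do not supply it")
    model$shape <- as.numeric(shape)
    model$rate_param <- as.numeric(rate_param)
    model$mean_rate <- model$shape / model$rate_param
  } else if (kind == "lognormal") {
    if (!has(log_mean) || !has(log_var) || log_var <= 0)
      stop("lognormal model requires 'log_mean' and strictly positive 'log_var'")
    if (has(mean_rate))
      stop("lognormal model derives 'mean_rate' = exp(log_mean + log_var/2); do not supply it")
    model$log_mean <- as.numeric(log_mean)
    model$log_var <- as.numeric(log_var)
    model$mean_rate <- exp(model$log_mean + model$log_var / 2)
  } else { # empirical
    if (!has(rates) || length(rates) != n)
      stop("empirical model requires 'rates' of length n")
    if (any(!is.finite(rates)) || any(rates <= 0))
      stop("all empirical rates must be strictly positive and finite")
    model$rates <- as.numeric(rates)
    model$mean_rate <- mean(model$rates)
  }

  if (kind %in% c("gamma", "lognormal") && n < 100L)
    warning("continuous-distribution approximation of the strain sum is intended for n >= 100; ",
            "consider an explicit empirical rate list for n = ", n)

  structure(model, class = "encounter_model")
}

#' @export
print.encounter_model <- function(x, ...) {
  cat("Encounter-rate model (", x$kind, "), n = ", x$n,
      " strains, mean rate = ", format(x$mean_rate), "\n", sep = "")
  if (x$kind == "gamma")
    cat("  Gamma shape a = ", x$shape, ", rate b = ", x$rate_param,
        " (variance/mean^2 = ", format(1 / x$shape), ")\n", sep = "")
  if (x$kind == "lognormal")
    cat("  log-mean mu = ", x$log_mean, ", log-variance sigma^2 = ", x$log_var, "\n", sep = "")
  invisible(x)
}

# Lognormal expectations E[fn(f)] with f = exp(mu + sigma Z) via Gauss-Hermite
# in z = log f; a doubling check guards against (unlikely) non-convergence of
# the spectral rule.
lognormal_expect <- function(fn, log_mean, log_var, nodes = 128L, tol = 1e-8) {
  ev <- function(k) {
    gh <- gauss_hermite(k)
    f <- exp(log_mean + sqrt(2 * log_var) * gh$nodes)
    vapply(seq_along(f), function(i) fn(f[i]), numeric(1)) %*% gh$weights / sqrt(pi)
  }
  v1 <- drop(ev(nodes))
  v2 <- drop(ev(2L * nodes))
  if (abs(v2 - v1) > tol * max(abs(v2), 1e-300))
    stop("lognormal quadrature did not converge at ", 2L * nodes,
         " Gauss-Hermite nodes (relative change ", format(abs(v2 - v1) / max(abs(v2), 1e-300)), ")")
  v2
}

check_age <- function(t) {
  if (any(!is.finite(t)) || any(t < 0)) stop("age 't' must be finite and >= 0")
  invisible(t)
}

#' Novelty-weighted encounter intensity g(t)
#'
#' The mean over strains of `f * exp(-f t)`: the rate at which a host of age
#' `t` meets strains it has never seen before, per strain. This quantity
#' drives every optimum in the model; it is strictly positive and strictly
#' decreasing in age. Closed forms: `fbar * exp(-fbar t)` (degenerate) and
#' `fbar * (1 + fbar t / a)^-(a+1)` (Gamma, shape `a`); the lognormal case is
#' evaluated by Gauss-Hermite quadrature and the empirical case by the exact
#' strain average.
#'
#' @param model an [encounter_model()].
#' @param t age (vectorized), `t >= 0`.
#' @return `g(t)`, same length as `t`.
#' @export
novelty_intensity <- function(model, t) {
  stopifnot(inherits(model, "encounter_model"))
  check_age(t)
  fb <- model$mean_rate
  switch(model$kind,
    degenerate = fb * exp(-fb * t),
    gamma = fb * (1 + fb * t / model$shape)^(-(model$shape + 1)),
    lognormal = vapply(t, function(ti)
      lognormal_expect(function(f) f * exp(-f * ti), model$log_mean, model$log_var),
      numeric(1)),
    empirical = vapply(t, function(ti) mean(model$rates * exp(-model$rates * ti)),
                       numeric(1))
  )
}

# d g / d t = -mean of f^2 exp(-f t); needed for the singular control rule.
novelty_intensity_deriv <- function(model, t) {
  stopifnot(inherits(model, "encounter_model"))
  check_age(t)
  fb <- model$mean_rate
  switch(model$kind,
    degenerate = -fb^2 * exp(-fb * t),
    gamma = {
      a <- model$shape
      -fb^2 * ((a + 1) / a) * (1 + fb * t / a)^(-(a + 2))
    },
    lognormal = vapply(t, function(ti)
      -lognormal_expect(function(f) f^2 * exp(-f * ti), model$log_mean, model$log_var),
      numeric(1)),
    empirical = vapply(t, function(ti) -mean(model$rates^2 * exp(-model$rates * ti)),
                       numeric(1))
  )
}

#' Probability that a strain is still novel at age t
#'
#' The per-strain probability of no prior encounter by age `t`, `E[exp(-f t)]`.
#' Equals 1 at `t = 0` and decreases monotonically; for the Gamma law it is
#' the moment generating function `(1 + fbar t / a)^-a`.
#'
#' @inheritParams novelty_intensity
#' @return probability vector, same length as `t`.
#' @export
novel_fraction <- function(model, t) {
  stopifnot(inherits(model, "encounter_model"))
  check_age(t)
  fb <- model$mean_rate
  switch(model$kind,
    degenerate = exp(-fb * t),
    gamma = (1 + fb * t / model$shape)^(-model$shape),
    lognormal = vapply(t, function(ti)
      lognormal_expect(function(f) exp(-f * ti), model$log_mean, model$log_var),
      numeric(1)),
    empirical = vapply(t, function(ti) mean(exp(-model$rates * ti)), numeric(1))
  )
}

#' Draw per-strain encounter rates from a model
#'
#' Reproducible sampling used to build empirical fixtures and per-host rate
#' vectors in the Monte Carlo simulator. The empirical kind returns its own
#' list (recycled or truncated to `count`).
#'
#' @param model an [encounter_model()].
#' @param count number of rates to draw.
#' @param seed integer seed; identical seeds give identical draws. `NULL`
#'   uses (and advances) the current RNG state.
#' @return numeric vector of `count` strictly positive rates.
#' @export
sample_rates <- function(model, count, seed = NULL) {
  stopifnot(inherits(model, "encounter_model"))
  if (length(count) != 1L || count < 1 || count != round(count))
    stop("'count' must be a positive integer")
  count <- as.integer(count)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  switch(model$kind,
    degenerate = rep(model$mean_rate, count),
    gamma = stats::rgamma(count, shape = model$shape, rate = model$rate_param),
    lognormal = stats::rlnorm(count, meanlog = model$log_mean, sdlog = sqrt(model$log_var)),
    empirical = rep_len(model$rates, count)
  )
}

#' Serialize an encounter model to a plain configuration list
#'
#' @param model an [encounter_model()].
#' @return a named list with keys `kind`, `n` and the kind-specific
#'   parameters, suitable for JSON round-tripping.
#' @seealso [encounter_model_from_config()]
#' @export
encounter_model_config <- function(model) {
  stopifnot(inherits(model, "encounter_model"))
  out <- list(kind = model$kind, n = model$n)
  out <- switch(model$kind,
    degenerate = c(out, list(mean_rate = model$mean_rate)),
    gamma = c(out, list(shape = model$shape, rate_param = model$rate_param)),
    lognormal = c(out, list(log_mean = model$log_mean, log_var = model$log_var)),
    empirical = c(out, list(rates = model$rates))
  )
  out
}

#' Rebuild an encounter model from a configuration list
#'
#' @param config a list as produced by [encounter_model_config()].
#' @return an [encounter_model()].
#' @export
encounter_model_from_config <- function(config) {
  allowed <- c("kind", "n", "mean_rate", "shape", "rate_param",
               "log_mean", "log_var", "rates")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown encounter-model config keys: ", paste(unknown, collapse = ", "))
  do.call(encounter_model, config)
}

#' Read or write an empirical rate list as single-column CSV
#'
#' The file has a single column with header `f`, one strictly positive rate
#' per row.
#'
#' @param path file path.
#' @param n strain count for the resulting model (defaults to the number of
#'   rows).
#' @return `read_rates_csv`: an empirical [encounter_model()];
#'   `write_rates_csv`: `path`, invisibly.
#' @export
read_rates_csv <- function(path, n = NULL) {
  df <- utils::read.csv(path)
  if (!identical(names(df), "f"))
    stop("rate CSV must have the single column 'f'")
  rates <- df$f
  if (is.null(n)) n <- length(rates)
  encounter_model("empirical", n = n, rates = rates)
}

#' @rdname read_rates_csv
#' @param model an empirical [encounter_model()].
#' @export
write_rates_csv <- function(model, path) {
  stopifnot(inherits(model, "encounter_model"))
  if (model$kind != "empirical") stop("only empirical models are written as rate CSVs")
  utils::write.csv(data.frame(f = model$rates), path, row.names = FALSE)
  invisible(path)
}
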