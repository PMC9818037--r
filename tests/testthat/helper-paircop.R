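# shared helpers: oracles and small simulation fixtures

# asymptotic (null) standard error of the empirical Kendall tau
tau_se <- function(n) sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))

# central finite difference of C in u
fd_partial_u <- function(spec, u, v, h = 1e-6) {
  (copula_cdf(spec, u + h, v) - copula_cdf(spec, u - h, v)) / (2 * h)
}

# mixed second finite difference of C
fd_density <- function(spec, u, v, h = 1e-5) {
  (copula_cdf(spec, u + h, v + h) - copula_cdf(spec, u + h, v - h) -
   copula_cdf(spec, u - h, v + h) + copula_cdf(spec, u - h, v - h)) /
    (4 * h^2)
}

# brute-force product-limit estimator over distinct event times
km_bruteforce <- function(times, indicators) {
  tt <- sort(unique(times[indicators == 1]))
  surv <- numeric(length(tt))
  s <- 1
  for (i in seq_along(tt)) {
    n_risk <- sum(times >= tt[i])
    d <- sum(times == tt[i] & indicators == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = tt, surv = surv)
}

# small bivariate dataset from the default generating process
sim_small <- function(n, seed, tau = 0.41) {
  cfg <- default_config(n = n, seed = seed, tau = tau)
  generate_cohort(cfg)$data
}

# cohort whose only nonzero coefficients are `active`, so that fitting
# exactly those covariates is a correctly specified model (fitting a
# subset of truly active covariates would let the omitted shared
# covariates masquerade as extra copula dependence)
sim_active <- function(n, seed, active, tau = 0.41) {
  cfg <- default_config(n = n, seed = seed, tau = tau)
  keep <- cfg$beta[active]
  cfg$beta[] <- 0
  cfg$beta[active] <- keep
  list(cfg = cfg, data = generate_cohort(cfg)$data)
}

# km_est container built from an exact survival curve (for transform checks)
km_from_curve <- function(t, S) {
  structure(list(time = t, surv = S, n.risk = rev(seq_along(t)),
                 n.event = rep(1, length(t)), times = t,
                 indicators = rep(1, length(t))), class = "km_est")
}

PUBLISHED_FIT <- data.frame(
  term = c("male", "age36_55", "age56plus", "famhist", "hypertension",
           "diabetes", "anemia", "obesity"),
  estimate = c(0.37, 0.04, 0.65, 0.42, 0.75, 0.43, 0.18, 0.41),
  se = c(0.18, 0.22, 0.27, 0.19, 0.22, 0.14, 0.19, 0.20),
  OR = c(1.45, 1.04, 1.91, 1.53, 2.11, 1.53, 1.20, 1.50))
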