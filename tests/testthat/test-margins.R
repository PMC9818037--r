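test_that("baseline survival takes its closed forms and boundary values", {
  for (fam in c("weibull", "gompertz", "loglogistic")) {
    m <- margin_spec(fam, 1.5, if (fam == "loglogistic") 500 else 0.001)
    expect_equal(baseline_survival(m, 0), 1)
    tt <- seq(10, 2000, by = 10)
    expect_true(all(diff(baseline_survival(m, tt)) <= 0))
    expect_error(baseline_survival(m, -1), "nonnegative")
  }
  expect_equal(baseline_survival(margin_spec("weibull", 1, 0.01), 100),
               exp(-1), tolerance = 1e-12)
  expect_equal(baseline_survival(margin_spec("loglogistic", 2, 500), 500),
               0.5, tolerance = 1e-12)
  # Gompertz near-zero shape falls back to the exponential limit
  expect_equal(baseline_survival(margin_spec("gompertz", 1e-12, 0.01), 100),
               exp(-1), tolerance = 1e-9)
})

test_that("covariate links obey the PH power and PO odds identities", {
  w <- margin_spec("weibull", 1.3, 2e-4)
  t0 <- invert_survival(w, numeric(0), NULL, 0.9)
  expect_equal(survival_given_covariates(w, log(2), matrix(1), t0),
               0.81, tolerance = 1e-9)
  ll <- margin_spec("loglogistic", 2, 500)
  # at the baseline median, an odds ratio of 1.45 gives S = 1/(1 + 1.45)
  expect_equal(survival_given_covariates(ll, log(1.45), matrix(1), 500),
               1 / 2.45, tolerance = 1e-12)
  # zero linear predictor recovers the baseline
  for (fam in c("weibull", "gompertz", "loglogistic")) {
    m <- margin_spec(fam, 2, if (fam == "loglogistic") 800 else 1e-6)
    expect_equal(survival_given_covariates(m, c(0.5, -0.2),
                                           matrix(0, 1, 2), 321),
                 baseline_survival(m, 321), tolerance = 1e-12)
  }
  expect_error(survival_given_covariates(ll, c(1, 2), matrix(1), 100),
               "dimension")
})

test_that("PH margins have multiplicative hazards and the PO margin shifts log-odds", {
  set.seed(3)
  z <- matrix(rbinom(10, 1, 0.5))
  beta <- 0.6
  for (fam in c("weibull", "gompertz")) {
    m <- margin_spec(fam, if (fam == "gompertz") 0.002 else 1.4,
                     if (fam == "gompertz") 5e-4 else 1e-4)
    t <- runif(10, 50, 900)
    h <- margin_density(m, beta, z, t) /
      survival_given_covariates(m, beta, z, t)
    h0 <- margin_density(m, beta, matrix(0, 10, 1), t) /
      survival_given_covariates(m, beta, matrix(0, 10, 1), t)
    expect_equal(h, h0 * exp(beta * z[, 1]), tolerance = 1e-9)
  }
  ll <- margin_spec("loglogistic", 2.5, 600)
  t <- runif(10, 50, 900)
  S1 <- survival_given_covariates(ll, beta, z, t)
  S0 <- baseline_survival(ll, t)
  expect_equal(log((1 - S1) / S1) - log((1 - S0) / S0), beta * z[, 1],
               tolerance = 1e-9)
})

test_that("densities match finite differences and integrate to one", {
  set.seed(9)
  for (fam in c("weibull", "gompertz", "loglogistic")) {
    m <- margin_spec(fam, if (fam == "gompertz") 0.001 else 1.7,
                     if (fam == "loglogistic") 700 else 2e-4)
    z <- matrix(1); beta <- 0.3
    for (t in c(50, 400, 1100)) {
      fd <- -(survival_given_covariates(m, beta, z, t + 1e-3) -
                survival_given_covariates(m, beta, z, t - 1e-3)) / 2e-3
      expect_equal(margin_density(m, beta, z, t), fd, tolerance = 1e-6)
    }
  }
  for (fam in c("weibull", "loglogistic")) {
    m <- margin_spec(fam, 1.7, if (fam == "loglogistic") 700 else 2e-4)
    I <- integrate(function(t) margin_density(m, 0.3, matrix(1, length(t), 1), t),
                   0, Inf, rel.tol = 1e-9)$value
    expect_equal(I, 1, tolerance = 1e-5)
  }
  expect_equal(margin_density(margin_spec("weibull", 1, 0.01),
                              numeric(0), NULL, 100),
               0.01 * exp(-1), tolerance = 1e-12)
})

test_that("invert_survival round-trips through the conditional survival", {
  set.seed(21)
  for (fam in c("weibull", "gompertz", "loglogistic")) {
    m <- margin_spec(fam, if (fam == "gompertz") 8e-4 else 2.1,
                     if (fam == "loglogistic") 650 else 1.5e-4)
    z <- matrix(rbinom(100, 1, 0.4))
    u <- runif(100, 0.01, 0.99)
    t <- invert_survival(m, 0.5, z, u)
    expect_equal(survival_given_covariates(m, 0.5, z, t), u,
                 tolerance = 1e-8)
  }
  ll <- margin_spec("loglogistic", 3, 777)
  expect_equal(invert_survival(ll, numeric(0), NULL, 0.5), 777,
               tolerance = 1e-9)
  # closed form against a numeric root
  w <- margin_spec("weibull", 1.4, 3e-4)
  t <- invert_survival(w, 0.3, matrix(1), 0.42)
  root <- uniroot(function(tt)
    survival_given_covariates(w, 0.3, matrix(1), tt) - 0.42,
    c(1, 1e5), tol = 1e-10)$root
  expect_equal(t, root, tolerance = 1e-6)
})

test_that("censored log-likelihood adds the expected record contributions", {
  m <- margin_spec("weibull", 1, 0.002)  # exponential
  # single censored record contributes log S
  expect_equal(margin_loglik(m, numeric(0), 400, 0), -0.002 * 400,
               tolerance = 1e-10)
  # 5-record hand-computed closed form: sum(d) log(lambda) - lambda sum(t)
  t <- c(100, 250, 30, 700, 410); d <- c(1, 0, 1, 1, 0)
  expect_equal(margin_loglik(m, numeric(0), t, d),
               sum(d) * log(0.002) - 0.002 * sum(t), tolerance = 1e-10)
  # duplicating a record doubles its contribution
  base <- margin_loglik(m, numeric(0), t, d)
  dup <- margin_loglik(m, numeric(0), c(t, 100), c(d, 1))
  expect_equal(dup - base, 1 * log(0.002) - 0.002 * 100, tolerance = 1e-10)
  expect_error(margin_loglik(m, numeric(0), c(1, -5), c(1, 0)), "record 2")
})

test_that("fit_margin reaches the exponential closed-form MLE", {
  set.seed(14)
  t <- rexp(500, 0.004)
  cens <- runif(500, 0, 500)
  y <- pmin(t, cens); d <- as.integer(t <= cens)
  fit <- fit_margin("weibull", y, d, fix_shape = 1)
  expect_equal(fit$margin$scale, sum(d) / sum(y), tolerance = 1e-6)
  expect_equal(fit$margin$shape, 1)
})

test_that("fit_margin recovers simulated Weibull parameters and matches flexsurv", {
  skip_if_not_installed("flexsurv")
  set.seed(25)
  n <- 2000
  z <- matrix(rbinom(n, 1, 0.5), dimnames = list(NULL, "x"))
  m <- margin_spec("weibull", 1.5, 0.002)
  t <- invert_survival(m, 0.4, z, runif(n))
  cens <- runif(n, 0, quantile(t, 0.9))
  y <- pmin(t, cens); d <- as.integer(t <= cens)
  expect_gt(mean(d), 0.5)
  fit <- fit_margin("weibull", y, d, z)
  # 3-SE recovery (SEs approximated by the flexsurv fit below)
  fs <- flexsurv::flexsurvreg(survival::Surv(y, d) ~ x,
                              data = data.frame(y = y, d = d, x = z[, 1]),
                              dist = "weibullPH")
  se <- fs$res["x", "se"]
  expect_lt(abs(fit$coef[["x"]] - 0.4), 3 * se)
  # same likelihood optimum as the independent implementation
  expect_equal(fit$loglik, fs$loglik, tolerance = 1e-4)
  expect_equal(fit$margin$shape, fs$res["shape", "est"], tolerance = 1e-3)
  expect_equal(unname(fit$coef), fs$res["x", "est"], tolerance = 1e-3)
})

test_that("fitted optimum is a local maximum and is order-invariant", {
  dat <- sim_small(400, seed = 8)
  fit <- fit_margin("loglogistic", dat$y1, dat$d1,
                    as.matrix(dat[c("male", "hypertension")]))
  z <- as.matrix(dat[c("male", "hypertension")])
  ll0 <- margin_loglik(fit$margin, fit$coef, dat$y1, dat$d1, z)
  for (k in 1:2) for (eps in c(-0.02, 0.02)) {
    cf <- fit$coef; cf[k] <- cf[k] + eps
    expect_lt(margin_loglik(fit$margin, cf, dat$y1, dat$d1, z), ll0)
  }
  m2 <- margin_spec("loglogistic", fit$margin$shape * 1.02, fit$margin$scale)
  expect_lt(margin_loglik(m2, fit$coef, dat$y1, dat$d1, z), ll0)
  set.seed(99)
  perm <- sample(nrow(dat))
  fit2 <- fit_margin("loglogistic", dat$y1[perm], dat$d1[perm], z[perm, ])
  expect_equal(fit2$coef, fit$coef, tolerance = 1e-8)
  expect_equal(fit2$margin$scale, fit$margin$scale, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(fit_margin("weibull", c(10, 20), c(0, 0)), "no events")
  dat <- data.frame(y = c(10, 20, 30, 40), d = c(1, 0, 1, 1),
                    a = c(1, 1, 1, 1), b = c(1, 1, 1, 1))
  expect_error(fit_margin("weibull", dat$y, dat$d, as.matrix(dat[c("a", "b")])),
               "rank")
})
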