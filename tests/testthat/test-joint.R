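test_that("joint specification enforces matching margin families", {
  cop <- copula_spec("clayton", 1.4)
  m1 <- margin_spec("loglogistic", 2, 500)
  m2 <- margin_spec("weibull", 2, 1e-5)
  expect_error(joint_spec(cop, m1, m2), "same parametric family")
})

test_that("joint likelihood factorizes at near-independence", {
  dat <- sim_small(200, seed = 2)
  covs <- c("male", "hypertension", "diabetes")
  z <- as.matrix(dat[covs])
  m1 <- margin_spec("loglogistic", 2.5, 2000)
  m2 <- margin_spec("loglogistic", 2.5, 2200)
  beta <- c(0.4, 0.7, 0.3)
  spec <- joint_spec(copula_spec("clayton", 1e-8), m1, m2, beta)
  jl <- joint_loglik(spec, dat, covs)
  ml <- margin_loglik(m1, beta, dat$y1, dat$d1, z) +
    margin_loglik(m2, beta, dat$y2, dat$d2, z)
  expect_equal(jl, ml, tolerance = 1e-4)
})

test_that("single-record contributions match their defining derivatives", {
  m1 <- margin_spec("weibull", 1, 0.002)  # exponential margins
  m2 <- margin_spec("weibull", 1, 0.003)
  spec <- joint_spec(copula_spec("clayton", 2), m1, m2, numeric(0))
  rec <- data.frame(y1 = 300, y2 = 450, d1 = 0, d2 = 0)
  # doubly censored record is exactly log C(S1, S2)
  expect_equal(joint_loglik(spec, rec),
               log(copula_cdf(spec$copula,
                              baseline_survival(m1, 300),
                              baseline_survival(m2, 450))),
               tolerance = 1e-12)
  # doubly observed record equals the mixed t-derivative of C(S1(t1), S2(t2))
  rec11 <- data.frame(y1 = 300, y2 = 450, d1 = 1, d2 = 1)
  h <- 0.05
  Cst <- function(t1, t2) copula_cdf(spec$copula,
                                     baseline_survival(m1, t1),
                                     baseline_survival(m2, t2))
  fd <- (Cst(300 + h, 450 + h) - Cst(300 + h, 450 - h) -
           Cst(300 - h, 450 + h) + Cst(300 - h, 450 - h)) / (4 * h^2)
  expect_equal(exp(joint_loglik(spec, rec11)), fd, tolerance = 1e-5)
  # singly observed record: dC/du times the margin density
  rec10 <- data.frame(y1 = 300, y2 = 450, d1 = 1, d2 = 0)
  u <- baseline_survival(m1, 300); v <- baseline_survival(m2, 450)
  expect_equal(exp(joint_loglik(spec, rec10)),
               copula_partial_u(spec$copula, u, v) *
                 margin_density(m1, numeric(0), NULL, 300),
               tolerance = 1e-10)
})

test_that("joint likelihood is exchangeable under mirroring margins", {
  dat <- sim_small(150, seed = 6)
  m <- margin_spec("loglogistic", 2.5, 2000)
  spec <- joint_spec(copula_spec("gumbel", 1.8), m, m, c(0.4))
  mirrored <- dat
  mirrored[c("y1", "y2", "d1", "d2")] <- dat[c("y2", "y1", "d2", "d1")]
  expect_equal(joint_loglik(spec, dat, "male"),
               joint_loglik(spec, mirrored, "male"), tolerance = 1e-10)
})

test_that("the generating model beats perturbed models on large data", {
  dat <- sim_small(5000, seed = 17)
  cfg <- default_config()
  truth <- joint_spec(copula_spec("clayton", cfg$eta),
                      margin_spec("loglogistic", cfg$shape, cfg$scale1),
                      margin_spec("loglogistic", cfg$shape, cfg$scale2),
                      unname(cfg$beta))
  covs <- names(cfg$beta)
  ll_true <- joint_loglik(truth, dat, covs)
  alt <- function(...) {
    sp <- truth
    for (nm in names(list(...))) sp[[nm]] <- list(...)[[nm]]
    sp
  }
  perturb <- list(
    alt(copula = copula_spec("clayton", cfg$eta * 2)),
    alt(coef = truth$coef + 0.3),
    alt(margin1 = margin_spec("loglogistic", cfg$shape * 1.3, cfg$scale1)))
  for (sp in perturb)
    expect_lt(joint_loglik(sp, dat, covs), ll_true)
})

test_that("two-stage fit recovers the generating parameters within 3 SE", {
  covs <- c("male", "hypertension", "obesity")
  sa <- sim_active(2000, seed = 43, active = covs)
  cfg <- sa$cfg; dat <- sa$data
  fit <- two_step_fit(dat, covs, "loglogistic", "clayton", se = TRUE)
  expect_equal(fit$convergence, 0)
  truth <- cfg$beta[covs]
  for (k in seq_along(covs))
    expect_lt(abs(fit$coefficients[k] - truth[k]), 3 * fit$se_coef[k])
  expect_lt(abs(fit$eta - cfg$eta), 3 * fit$se_eta)
  expect_equal(fit$tau, fit$eta / (fit$eta + 2), tolerance = 1e-12)
  # refinement can only improve on the stage-2 likelihood
  expect_gte(fit$loglik, fit$loglik_stage2 - 1e-6)
  # AIC/BIC consistent with the stored likelihood
  expect_equal(fit$AIC, -2 * fit$loglik + 2 * fit$K, tolerance = 1e-9)
  expect_equal(fit$BIC, -2 * fit$loglik + fit$K * log(fit$n), tolerance = 1e-9)
})

test_that("estimated tau tracks the generating tau across the family grid", {
  for (cop in c("clayton", "gumbel", "joe")) {
    cfg <- sim_active(2000, seed = 53, active = c("male", "hypertension"))$cfg
    cfg$copula_family <- cop
    cfg$eta <- eta_from_tau(cop, 0.41)
    dat <- generate_cohort(cfg)$data
    fit <- two_step_fit(dat, c("male", "hypertension"), "loglogistic", cop,
                        se = TRUE)
    dtau <- switch(cop, clayton = 2 / (fit$eta + 2)^2,
                   gumbel = 1 / fit$eta^2,
                   (tau_from_eta(copula_spec("joe", fit$eta + 1e-4)) -
                      fit$tau) / 1e-4)
    se_tau <- fit$se_eta * dtau
    expect_lt(abs(fit$tau - 0.41), 3 * se_tau)
  }
})

test_that("refitting permuted data reproduces the estimates", {
  dat <- sim_small(400, seed = 29)
  covs <- c("male", "diabetes")
  fit1 <- two_step_fit(dat, covs, "weibull", "gumbel", se = FALSE)
  set.seed(1)
  fit2 <- two_step_fit(dat[sample(nrow(dat)), ], covs, "weibull", "gumbel",
                       se = FALSE)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-8)
  expect_equal(fit1$eta, fit2$eta, tolerance = 1e-8)
})

test_that("confidence intervals for eta achieve nominal coverage", {
  hits <- 0; reps <- 200
  for (r in seq_len(reps)) {
    sa <- sim_active(400, seed = 1000 + r, active = "hypertension")
    cfg <- sa$cfg; dat <- sa$data
    fit <- tryCatch(
      two_step_fit(dat, "hypertension", "loglogistic", "clayton", se = TRUE),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$se_theta)) { reps <- reps - 1; next }
    # CI built on the unconstrained log-eta scale, then mapped back
    theta <- log(fit$eta)
    ci <- exp(theta + c(-1.96, 1.96) * fit$se_theta)
    if (cfg$eta >= ci[1] && cfg$eta <= ci[2]) hits <- hits + 1
  }
  coverage <- hits / reps
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.99)
})

test_that("Wald report reproduces the published odds-ratio arithmetic", {
  fake <- structure(list(
    coefficients = setNames(PUBLISHED_FIT$estimate, PUBLISHED_FIT$term),
    se_coef = setNames(PUBLISHED_FIT$se, PUBLISHED_FIT$term),
    eta = 1.40, se_eta = 0.27, copula_family = "clayton"),
    class = "copula_survfit")
  w <- wald_inference(fake)
  rows <- match(PUBLISHED_FIT$term, w$term)
  expect_equal(round(w$OR[rows][PUBLISHED_FIT$term == "male"], 2), 1.45)
  expect_equal(round(w$OR[rows][PUBLISHED_FIT$term == "anemia"], 2), 1.20)
  expect_equal(round(w$OR[rows][PUBLISHED_FIT$term == "age36_55"], 2), 1.04)
  expect_true(all(abs(w$OR[rows] - PUBLISHED_FIT$OR) <= 0.01))
  expect_true(all(w$ci_lo[rows] < w$OR[rows] & w$OR[rows] < w$ci_hi[rows]))
  # published P value for the male coefficient: 0.37/0.18 -> 0.038 (2 dp)
  expect_equal(round(w$p_value[w$term == "male"], 3), 0.04, tolerance = 2e-3)
  # a zero coefficient gives OR 1 with a log-symmetric interval
  fake0 <- structure(list(coefficients = c(x = 0), se_coef = c(x = 0.2),
                          eta = 1.4, se_eta = 0.3,
                          copula_family = "clayton"),
                     class = "copula_survfit")
  w0 <- wald_inference(fake0)
  expect_equal(w0$OR[1], 1)
  expect_equal(w0$ci_lo[1] * w0$ci_hi[1], 1, tolerance = 1e-12)
})
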