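# Parametric marginal survival regressions.
#
# Parameterizations (stated here once and used everywhere):
#   weibull      PH: baseline cumulative hazard H0(t) = lambda * t^a
#   gompertz     PH: baseline hazard h0(t) = lambda * exp(gamma * t)
#   loglogistic  PO: baseline survival S0(t) = 1 / (1 + (t/b)^a)
# PH margins: S(t|z) = S0(t)^exp(b'z).  PO margin: covariates multiply the
# failure odds, S(t|z) = S0 / (S0 + (1 - S0) * exp(b'z)).  Time unit: days.

.MARGIN_FAMILIES <- c("weibull", "gompertz", "loglogistic")

#' Marginal survival model specification
#'
#' @param family `"weibull"`, `"gompertz"` or `"loglogistic"`.  The
#'   covariate link is forced by the family: proportional hazards for
#'   Weibull/Gompertz, proportional odds for log-logistic.
#' @param shape shape parameter: Weibull `a > 0`, Gompertz `gamma` (any
#'   real; values within 1e-8 of zero are evaluated by the exponential
#'   limit), log-logistic `a > 0`.
#' @param scale rate `lambda > 0` for Weibull/Gompertz; scale `b > 0`
#'   (the baseline median) for log-logistic.
#' @return an object of class `margin_spec`.
#' @export
#' @examples
#' margin_spec("loglogistic", shape = 2, scale = 500)
margin_spec <- function(family = c("weibull", "gompertz", "loglogistic"),
                        shape, scale) {
  family <- match.arg(family)
  stopifnot(is.numeric(shape), length(shape) == 1L, is.finite(shape),
            is.numeric(scale), length(scale) == 1L, is.finite(scale))
  if (scale <= 0) stop("scale/rate parameter must be positive")
  if (family != "gompertz" && shape <= 0)
    stop(sprintf("%s shape must be positive", family))
  structure(list(family = family, shape = shape, scale = scale,
                 link = if (family == "loglogistic") "PO" else "PH"),
            class = "margin_spec")
}

#' @export
print.margin_spec <- function(x, ...) {
  cat(sprintf("%s margin (%s link): shape = %.4g, %s = %.4g\n",
              x$family, x$link, x$shape,
              if (x$family == "loglogistic") "scale" else "rate", x$scale))
  invisible(x)
}

.lp <- function(coef, z) {
  if (is.null(coef) || length(coef) == 0) return(0)
  if (is.null(z)) stop("covariates required when coefficients are present")
  z <- as.matrix(z)
  if (ncol(z) != length(coef))
    stop(sprintf("covariate dimension (%d) does not match coefficients (%d)",
                 ncol(z), length(coef)))
  drop(z %*% coef)
}

# baseline log survival
.base_logS <- function(margin, t) {
  switch(margin$family,
    weibull = -margin$scale * t^margin$shape,
    gompertz = {
      g <- margin$shape
      if (abs(g) < 1e-8) -margin$scale * t
      else -margin$scale * expm1(g * t) / g
    },
    loglogistic = -log1p((t / margin$scale)^margin$shape))
}

# baseline log hazard
.base_logh <- function(margin, t) {
  switch(margin$family,
    weibull = log(margin$scale) + log(margin$shape) +
      (margin$shape - 1) * log(t),
    gompertz = log(margin$scale) + margin$shape * t,
    loglogistic = {
      # h0 = f0/S0 = (a/b) (t/b)^(a-1) / (1 + (t/b)^a)
      a <- margin$shape; b <- margin$scale
      log(a) - log(b) + (a - 1) * (log(t) - log(b)) - log1p((t / b)^a)
    })
}

# log S(t|z) and log f(t|z) for a margin + shared coefficients
.margin_logS <- function(margin, coef, z, t) {
  bz <- .lp(coef, z)
  if (margin$link == "PH") {
    exp(bz) * .base_logS(margin, t)
  } else {
    # S = 1 / (1 + e^bz * (t/b)^a)
    q <- exp(bz + margin$shape * (log(t) - log(margin$scale)))
    -log1p(q)
  }
}

.margin_logf <- function(margin, coef, z, t) {
  bz <- .lp(coef, z)
  if (margin$link == "PH") {
    bz + .base_logh(margin, t) + exp(bz) * .base_logS(margin, t)
  } else {
    a <- margin$shape; b <- margin$scale
    lq <- bz + a * (log(t) - log(b))
    bz + log(a) - log(b) + (a - 1) * (log(t) - log(b)) - 2 * log1p(exp(lq))
  }
}

#' Baseline survival function
#'
#' @param margin a [margin_spec()].
#' @param t times in days, `t >= 0` (vectorised).
#' @return \eqn{S_0(t)}.
#' @export
baseline_survival <- function(margin, t) {
  stopifnot(inherits(margin, "margin_spec"))
  if (any(t < 0)) stop("t must be nonnegative")
  exp(.base_logS(margin, t))
}

#' Covariate-conditional survival function
#'
#' PH margins: \eqn{S(t|z) = S_0(t)^{\exp(\beta'z)}}.  PO margin: the
#' failure odds are multiplied, \eqn{S(t|z) = S_0 / (S_0 + (1 - S_0)
#' e^{\beta'z})}.  A zero linear predictor recovers the baseline.
#'
#' @param margin a [margin_spec()].
#' @param coef numeric coefficient vector (possibly length 0).
#' @param z covariate matrix/vector matching `coef`.
#' @param t times in days.
#' @return survival probabilities.
#' @export
survival_given_covariates <- function(margin, coef, z, t) {
  stopifnot(inherits(margin, "margin_spec"))
  if (any(t < 0)) stop("t must be nonnegative")
  exp(.margin_logS(margin, coef, z, t))
}

#' Event-time density given covariates
#'
#' \eqn{f(t|z) = -dS(t|z)/dt}, per day.
#'
#' @inheritParams survival_given_covariates
#' @export
margin_density <- function(margin, coef, z, t) {
  stopifnot(inherits(margin, "margin_spec"))
  if (any(t <= 0)) stop("t must be positive")
  exp(.margin_logf(margin, coef, z, t))
}

#' Invert the conditional survival function
#'
#' Returns the time `t` with `survival_given_covariates(...) == u`
#' (closed form for every family/link); the workhorse of the synthetic
#' cohort generator.
#'
#' @inheritParams survival_given_covariates
#' @param u survival probabilities strictly inside (0, 1).
#' @export
invert_survival <- function(margin, coef, z, u) {
  stopifnot(inherits(margin, "margin_spec"))
  .check_unit(u, FALSE, "u")
  bz <- .lp(coef, z)
  switch(margin$family,
    weibull = (-log(u) / (margin$scale * exp(bz)))^(1 / margin$shape),
    gompertz = {
      g <- margin$shape
      x <- -log(u) / (margin$scale * exp(bz))
      if (abs(g) < 1e-8) x else {
        arg <- g * x
        if (any(arg <= -1))
          stop("survival level unreachable: Gompertz with negative shape plateaus above u")
        log1p(arg) / g
      }
    },
    loglogistic =
      margin$scale * exp((log1p(-u) - log(u) - bz) / margin$shape))
}

#' Right-censored marginal log-likelihood
#'
#' \eqn{\sum_i d_i \log f(t_i|z_i) + (1 - d_i) \log S(t_i|z_i)}.
#'
#' @param margin a [margin_spec()].
#' @param coef coefficient vector.
#' @param t observed times (days), positive.
#' @param d event indicators in \{0, 1\}.
#' @param z covariate matrix (or NULL if `coef` empty).
#' @export
margin_loglik <- function(margin, coef, t, d, z = NULL) {
  stopifnot(inherits(margin, "margin_spec"))
  if (any(t <= 0)) {
    bad <- which(t <= 0)[1]
    stop(sprintf("nonpositive time at record %d", bad))
  }
  if (!all(d %in% c(0, 1))) stop("event indicators must be 0/1")
  lf <- .margin_logf(margin, coef, z, t)
  lS <- .margin_logS(margin, coef, z, t)
  sum(ifelse(d == 1, lf, lS))
}

# --- fitting ---------------------------------------------------------------

# unconstrained parameterization of the baseline: weibull (log a, log lambda),
# gompertz (gamma, log lambda), loglogistic (log a, log b)
.margin_from_par <- function(family, p) {
  if (family == "gompertz") margin_spec(family, p[1], exp(p[2]))
  else margin_spec(family, exp(p[1]), exp(p[2]))
}

.margin_to_par <- function(margin) {
  if (margin$family == "gompertz") c(margin$shape, log(margin$scale))
  else c(log(margin$shape), log(margin$scale))
}

.margin_start <- function(family, t, d, fix_shape = NULL) {
  rate <- max(sum(d), 0.5) / sum(t)
  base <- switch(family,
    weibull = c(0, log(rate)),
    gompertz = c(1e-4, log(rate)),
    loglogistic = c(0, log(stats::median(t))))
  if (!is.null(fix_shape))
    base[1] <- if (family == "gompertz") fix_shape else log(fix_shape)
  base
}

#' Fit one marginal survival regression by maximum likelihood
#'
#' Quasi-Newton (BFGS) maximization of [margin_loglik()] on the
#' unconstrained scale (log shape -- except the Gompertz shape, which is
#' free -- log rate/scale, free coefficients), with jittered restarts if
#' the first run fails to converge.
#'
#' @param family marginal family name.
#' @param t,d,z observed times, 0/1 event indicators, covariate matrix
#'   (or NULL for no covariates).
#' @param fix_shape optionally pin the shape parameter (e.g. `1` with
#'   `family = "weibull"` fits the exponential submodel).
#' @param start optional starting values on the working scale.
#' @return a list with `margin` ([margin_spec()]), `coef`, `loglik`,
#'   `convergence` (0 = converged).
#' @export
fit_margin <- function(family = c("weibull", "gompertz", "loglogistic"),
                       t, d, z = NULL, fix_shape = NULL, start = NULL) {
  family <- match.arg(family)
  if (sum(d) < 1) stop("no events: marginal model unidentifiable")
  if (!is.null(z)) {
    z <- as.matrix(z)
    if (qr(cbind(1, z))$rank < ncol(z) + 1)
      stop("design matrix (with intercept) is rank deficient")
  }
  p <- if (is.null(z)) 0L else ncol(z)
  fixed <- !is.null(fix_shape)

  nll <- function(par) {
    if (fixed) {
      shp <- if (family == "gompertz") fix_shape else log(fix_shape)
      full <- c(shp, par)
    } else full <- par
    m <- tryCatch(.margin_from_par(family, full[1:2]), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    cf <- if (p > 0) full[2 + seq_len(p)] else numeric(0)
    ll <- margin_loglik(m, cf, t, d, z)
    if (!is.finite(ll)) 1e10 else -ll
  }

  s0 <- if (!is.null(start)) start else {
    full <- c(.margin_start(family, t, d, fix_shape), rep(0, p))
    if (fixed) full[-1] else full
  }
  best <- NULL
  for (try in 0:3) {
    s <- if (try == 0) s0 else s0 + stats::rnorm(length(s0), 0, 0.3)
    fit <- tryCatch(
      optim(s, nll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value - 1e-9))
      best <- fit
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best)) stop("marginal fit failed to converge after restarts")
  par <- best$par
  full <- if (fixed)
    c(if (family == "gompertz") fix_shape else log(fix_shape), par) else par
  list(margin = .margin_from_par(family, full[1:2]),
       coef = if (p > 0) setNames(full[2 + seq_len(p)], colnames(z))
              else numeric(0),
       loglik = -best$value,
       convergence = best$convergence)
}
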