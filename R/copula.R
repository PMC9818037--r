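# Archimedean copula families (Clayton, Gumbel, Joe) on the unit square.
# All kernels work on the log scale so that likelihood evaluations stay
# finite deep into the corners of [0,1]^2.

.COPULA_FAMILIES <- c("clayton", "gumbel", "joe")

#' Archimedean copula specification
#'
#' A copula family together with its dependence parameter \eqn{\eta}.
#' Clayton requires \eqn{\eta > 0}; Gumbel and Joe require
#' \eqn{\eta \ge 1}.  All three cover positive dependence only, with
#' independence reached at \eqn{\eta \to 0^+} (Clayton) or \eqn{\eta = 1}
#' (Gumbel, Joe).
#'
#' @param family one of `"clayton"`, `"gumbel"`, `"joe"`.
#' @param eta dependence parameter (scalar).
#' @return an object of class `copula_spec`.
#' @export
#' @examples
#' copula_spec("clayton", 1.4)
copula_spec <- function(family = c("clayton", "gumbel", "joe"), eta) {
  family <- match.arg(family)
  stopifnot(is.numeric(eta), length(eta) == 1L, is.finite(eta))
  if (family == "clayton") {
    if (eta <= 0)
      stop("Clayton copula requires eta > 0 (independence is the limit eta -> 0+)")
  } else if (eta < 1) {
    stop(sprintf("%s copula requires eta >= 1 (eta = 1 is independence)",
                 family))
  }
  structure(list(family = family, eta = eta), class = "copula_spec")
}

#' @export
print.copula_spec <- function(x, ...) {
  cat(sprintf("Archimedean copula: %s, eta = %.4g (Kendall's tau = %.3f)\n",
              x$family, x$eta, tau_from_eta(x)))
  invisible(x)
}

.check_unit <- function(u, closed = TRUE, name = "u") {
  if (closed) {
    if (any(u < 0 | u > 1)) stop(sprintf("%s must lie in [0, 1]", name))
  } else {
    if (any(u <= 0 | u >= 1))
      stop(sprintf("%s must lie strictly inside (0, 1); clamp before calling", name))
  }
  invisible(NULL)
}

# log T for the Joe generator composition: T = x + y - x*y with
# x = (1-u)^eta, y = (1-v)^eta.  T in (0, 1] for u, v in [0, 1).
.joe_logT <- function(eta, u, v) {
  x <- exp(eta * log1p(-u))
  y <- exp(eta * log1p(-v))
  log(x + y - x * y)
}

.cop_logcdf <- function(family, eta, u, v) {
  switch(family,
    clayton = {
      s <- expm1(-eta * log(u)) + expm1(-eta * log(v))
      -log1p(s) / eta
    },
    gumbel = {
      -((-log(u))^eta + (-log(v))^eta)^(1 / eta)
    },
    joe = {
      lT <- .joe_logT(eta, u, v)
      out <- log(-expm1(lT / eta))
      out[lT == 0] <- -Inf      # T = 1 <=> C = 0
      out
    })
}

.cop_logpdf <- function(family, eta, u, v) {
  switch(family,
    clayton = {
      s <- expm1(-eta * log(u)) + expm1(-eta * log(v))
      log1p(eta) - (eta + 1) * (log(u) + log(v)) - (1 / eta + 2) * log1p(s)
    },
    gumbel = {
      lS <- log((-log(u))^eta + (-log(v))^eta)
      A <- exp(lS / eta)
      -A + (1 / eta - 2) * lS + (eta - 1) * (log(-log(u)) + log(-log(v))) -
        log(u) - log(v) + log(A + eta - 1)
    },
    joe = {
      lT <- .joe_logT(eta, u, v)
      (1 / eta - 2) * lT + (eta - 1) * (log1p(-u) + log1p(-v)) +
        log(eta - 1 + exp(lT))
    })
}

# d C / d u, the conditional distribution of V given U = u, on the log scale.
.cop_logpartial <- function(family, eta, u, v) {
  switch(family,
    clayton = {
      s <- expm1(-eta * log(u)) + expm1(-eta * log(v))
      -(eta + 1) * log(u) - (1 / eta + 1) * log1p(s)
    },
    gumbel = {
      lS <- log((-log(u))^eta + (-log(v))^eta)
      -exp(lS / eta) + (1 / eta - 1) * lS + (eta - 1) * log(-log(u)) - log(u)
    },
    joe = {
      lT <- .joe_logT(eta, u, v)
      (1 / eta - 1) * lT + (eta - 1) * log1p(-u) +
        log(-expm1(eta * log1p(-v)))
    })
}

#' Copula distribution function
#'
#' Evaluates \eqn{C_\eta(u, v)}.  Grounded at the boundaries:
#' \eqn{C(u, 0) = 0}, \eqn{C(u, 1) = u}.
#'
#' @param spec a [copula_spec()].
#' @param u,v probabilities in \[0, 1\] (vectorised, recycled).
#' @return \eqn{C_\eta(u, v)}.
#' @export
#' @examples
#' copula_cdf(copula_spec("clayton", 2), 0.5, 0.5)  # 7^(-1/2)
copula_cdf <- function(spec, u, v) {
  stopifnot(inherits(spec, "copula_spec"))
  .check_unit(u, TRUE, "u"); .check_unit(v, TRUE, "v")
  exp(.cop_logcdf(spec$family, spec$eta, u, v))
}

#' Copula density
#'
#' The mixed second partial \eqn{c(u, v) = \partial^2 C / \partial u
#' \partial v}, symmetric in its arguments for all three families.
#' Arguments must lie strictly inside the unit square; callers working at
#' observed survival probabilities should clamp to
#' `[1e-12, 1 - 1e-12]` first.
#'
#' @inheritParams copula_cdf
#' @return nonnegative density values.
#' @export
copula_density <- function(spec, u, v) {
  stopifnot(inherits(spec, "copula_spec"))
  .check_unit(u, FALSE, "u"); .check_unit(v, FALSE, "v")
  exp(.cop_logpdf(spec$family, spec$eta, u, v))
}

#' Copula partial derivative in the first argument
#'
#' \eqn{\partial C(u, v) / \partial u}, i.e. the conditional distribution
#' function of \eqn{V} given \eqn{U = u}.  Used by the likelihood
#' contribution of a pair where only the first event is observed, and by
#' conditional-inversion sampling.
#'
#' @param spec a [copula_spec()].
#' @param u probability strictly inside (0, 1).
#' @param v probability in \[0, 1\].
#' @return values in \[0, 1\], nondecreasing in `v`.
#' @export
copula_partial_u <- function(spec, u, v) {
  stopifnot(inherits(spec, "copula_spec"))
  .check_unit(u, FALSE, "u"); .check_unit(v, TRUE, "v")
  out <- numeric(length(u + v))  # recycled length
  uu <- rep_len(u, length(out)); vv <- rep_len(v, length(out))
  inner <- vv > 0 & vv < 1
  out[vv == 0] <- 0
  out[vv == 1] <- 1
  if (any(inner))
    out[inner] <- exp(.cop_logpartial(spec$family, spec$eta, uu[inner], vv[inner]))
  out
}

#' @rdname copula_partial_u
#' @export
copula_partial_v <- function(spec, u, v) {
  # all three families are exchangeable
  copula_partial_u(spec, v, u)
}

#' Kendall's tau from the dependence parameter
#'
#' Closed forms \eqn{\tau = \eta / (\eta + 2)} (Clayton) and
#' \eqn{\tau = (\eta - 1) / \eta} (Gumbel); for Joe the series
#' \eqn{\tau = 1 - 4 \sum_{k \ge 1} 1 / [k (\eta k + 2)(\eta (k-1) + 2)]},
#' truncated when a term falls below 1e-12.
#'
#' @param spec a [copula_spec()].
#' @return tau in \[0, 1).
#' @export
#' @examples
#' tau_from_eta(copula_spec("clayton", 1.40))  # 0.41 to 2 dp
tau_from_eta <- function(spec) {
  stopifnot(inherits(spec, "copula_spec"))
  eta <- spec$eta
  switch(spec$family,
    clayton = eta / (eta + 2),
    gumbel  = (eta - 1) / eta,
    joe     = {
      total <- 0
      k0 <- 1
      repeat {
        k <- k0:(k0 + 9999)
        term <- 1 / (k * (eta * k + 2) * (eta * (k - 1) + 2))
        total <- total + sum(term)
        if (term[length(term)] < 1e-12) break
        k0 <- k0 + 10000
        if (k0 > 1e7) break  # terms decay like k^-3; never reached in practice
      }
      1 - 4 * total
    })
}

#' Dependence parameter from Kendall's tau
#'
#' Inverse of [tau_from_eta()]: algebraic for Clayton
#' (\eqn{\eta = 2\tau/(1-\tau)}) and Gumbel (\eqn{\eta = 1/(1-\tau)}),
#' numerical bisection for Joe.
#'
#' @param family copula family name.
#' @param tau Kendall's tau; in (0, 1) for Clayton, \[0, 1) for
#'   Gumbel/Joe.
#' @return the dependence parameter eta.
#' @export
#' @examples
#' eta_from_tau("clayton", 0.41)  # 1.3898...
eta_from_tau <- function(family = c("clayton", "gumbel", "joe"), tau) {
  family <- match.arg(family)
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau))
  if (tau >= 1) stop("tau must be below 1")
  if (family == "clayton") {
    if (tau <= 0) stop("Clayton covers tau in (0, 1) only")
    return(2 * tau / (1 - tau))
  }
  if (tau < 0) stop(sprintf("%s covers tau in [0, 1) only", family))
  if (family == "gumbel") return(1 / (1 - tau))
  if (tau == 0) return(1)
  f <- function(e) tau_from_eta(copula_spec("joe", e)) - tau
  hi <- 2
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(1, hi), tol = 1e-12)$root
}

#' Conditional-inversion sampling of the second coordinate
#'
#' Solves \eqn{\partial C(u, v)/\partial u = w} for `v`.  With `u, w`
#' independent uniforms the pairs `(u, v)` have copula \eqn{C_\eta}.
#' Closed form for Clayton; monotone bisection (tolerance below 1e-10)
#' for Gumbel and Joe.
#'
#' @param spec a [copula_spec()].
#' @param u,w probabilities strictly inside (0, 1) (vectorised).
#' @return v with `copula_partial_u(spec, u, v) == w`.
#' @export
conditional_sample <- function(spec, u, w) {
  stopifnot(inherits(spec, "copula_spec"))
  .check_unit(u, FALSE, "u"); .check_unit(w, FALSE, "w")
  n <- max(length(u), length(w))
  u <- rep_len(u, n); w <- rep_len(w, n)
  eta <- spec$eta
  if (spec$family == "clayton") {
    t1 <- expm1(-eta / (1 + eta) * log(w)) * exp(-eta * log(u))
    return(exp(-log1p(t1) / eta))
  }
  # Gumbel / Joe: h(v) = dC/du is continuous and strictly increasing in v.
  lw <- log(w)
  lo <- rep(1e-14, n); hi <- rep(1 - 1e-14, n)
  for (it in 1:64) {
    mid <- (lo + hi) / 2
    below <- .cop_logpartial(spec$family, eta, u, mid) < lw
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Draw pairs from an Archimedean copula
#'
#' @param spec a [copula_spec()].
#' @param n number of pairs.
#' @return an `n x 2` matrix of (u, v) pairs with copula `spec`.
#' @export
copula_sample <- function(spec, n) {
  u <- runif(n)
  v <- conditional_sample(spec, u, runif(n))
  cbind(u = u, v = v)
}
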