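# Graphical adequacy diagnostics: marginal linearization coordinates and
# the copula scatter comparison.

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator via [survival::survfit()], returned in a small
#' container that keeps the raw times and indicators (the Gompertz
#' life-table hazard needs them).
#'
#' @param times positive observed times.
#' @param indicators 0/1 event indicators.
#' @return object of class `km_est` with `time`, `surv`, `n.risk`,
#'   `n.event` at the distinct observed times.
#' @export
km_survival <- function(times, indicators) {
  if (any(times <= 0)) stop("times must be positive")
  if (!all(indicators %in% c(0, 1))) stop("indicators must be 0/1")
  if (sum(indicators) == 0)
    warning("no events: survival estimate is flat at 1")
  sf <- survival::survfit(survival::Surv(times, indicators) ~ 1)
  structure(list(time = sf$time, surv = sf$surv, n.risk = sf$n.risk,
                 n.event = sf$n.event, times = times,
                 indicators = indicators), class = "km_est")
}

#' @export
print.km_est <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: %d subjects, %d events, %d time points\n",
              length(x$times), sum(x$indicators), length(x$time)))
  invisible(x)
}

# discrete life-table hazard on nbins equal-width intervals: d / (n * width)
.lifetable_hazard <- function(times, indicators, nbins = 10) {
  edges <- seq(0, max(times), length.out = nbins + 1)
  mid <- (edges[-1] + edges[-(nbins + 1)]) / 2
  width <- diff(edges)
  h <- numeric(nbins)
  for (i in seq_len(nbins)) {
    at_risk <- sum(times > edges[i])
    ev <- sum(indicators == 1 & times > edges[i] & times <= edges[i + 1])
    h[i] <- if (at_risk > 0) ev / (at_risk * width[i]) else NA_real_
  }
  data.frame(t = mid, hazard = h)
}

#' Linearization coordinates for marginal adequacy plots
#'
#' Transforms a nonparametric survival estimate so that the candidate
#' baseline family maps to a straight line:
#' Weibull `(log t, log(-log S))` (slope = shape), Gompertz
#' `(t, log hazard)` with a life-table hazard estimate (slope = shape),
#' log-logistic `(log t, log((1-S)/S))` (slope = shape).  The returned
#' `straightness` is the squared Pearson correlation of the coordinates.
#'
#' @param family candidate marginal family.
#' @param km a [km_survival()] estimate.
#' @param nbins intervals for the Gompertz life-table hazard.
#' @return a data frame (`x`, `y`) of class `diagnostic_series` with
#'   attributes `label`, `straightness`, `n_dropped`.
#' @export
linearization_coords <- function(family = c("weibull", "gompertz", "loglogistic"),
                                 km, nbins = 10) {
  family <- match.arg(family)
  stopifnot(inherits(km, "km_est"))
  if (family == "gompertz") {
    lt <- .lifetable_hazard(km$times, km$indicators, nbins)
    x <- lt$t; y <- log(lt$hazard)
    label <- "log hazard vs time"
  } else {
    keep <- km$n.event > 0 & km$surv > 0 & km$surv < 1
    t <- km$time[keep]; S <- km$surv[keep]
    if (family == "weibull") {
      x <- log(t); y <- log(-log(S)); label <- "log cumulative hazard vs log time"
    } else {
      x <- log(t); y <- log((1 - S) / S); label <- "log failure odds vs log time"
    }
  }
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop("fewer than 3 usable points for the ", family, " linearization")
  structure(data.frame(x = x, y = y),
            label = label, family = family,
            straightness = stats::cor(x, y)^2,
            slope = stats::coef(stats::lm(y ~ x))[2],
            n_dropped = n_dropped,
            class = c("diagnostic_series", "data.frame"))
}

#' Copula adequacy scatter diagnostic
#'
#' Simulates pairs from the fitted copula (conditional inversion at the
#' estimated dependence parameter) and computes the observed
#' pseudo-observations (the fitted marginal survival probabilities at
#' each subject's observed times).  Overlaying the two clouds -- and
#' comparing their empirical Kendall's tau values -- shows whether the
#' chosen Archimedean family reproduces the observed dependence shape.
#'
#' @param fit a [two_step_fit()] result.
#' @param n_sim number of simulated pairs.
#' @param seed RNG seed (simulation is bitwise reproducible given the
#'   seed).
#' @return list with `simulated` and `observed` data frames of (u, v)
#'   pairs, plus `tau_sim`, `tau_obs` and the model `tau`.
#' @export
copula_scatter <- function(fit, n_sim = 5000, seed = 1) {
  stopifnot(inherits(fit, "copula_survfit"))
  set.seed(seed)
  sim <- copula_sample(fit$spec$copula, n_sim)
  obs <- fit$pseudo
  list(simulated = as.data.frame(sim),
       observed = obs,
       tau_sim = kendall_tau(sim[, 1], sim[, 2]),
       tau_obs = kendall_tau(obs$u, obs$v),
       tau_model = fit$tau)
}
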