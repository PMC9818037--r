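# Model selection: information criteria, the margin-by-copula comparison
# grid, and the 25%-rule univariable covariate screen.

#' Akaike and Bayesian information criteria
#'
#' `AIC = -2 llk + 2K`, `BIC = -2 llk + K log(n)`.
#'
#' @param llk maximized log-likelihood.
#' @param K number of estimated parameters counted by the criterion.
#' @param n number of subjects.
#' @return list with `AIC` and `BIC`.
#' @export
#' @examples
#' information_criteria(-2121.48, K = 9, n = 431)
information_criteria <- function(llk, K, n) {
  stopifnot(is.numeric(llk), length(llk) == 1L)
  if (!(K >= 1) || !(n >= 1)) stop("K and n must be positive counts")
  list(AIC = -2 * llk + 2 * K, BIC = -2 * llk + K * log(n))
}

#' Fit the full margin-by-copula comparison grid
#'
#' Fits every combination of marginal family and copula family with
#' [two_step_fit()] and tabulates AIC, BIC, final joint log-likelihood
#' and Kendall's tau.  Stage-1 margin fits are shared across the copula
#' families within each marginal family.  The selected model is the
#' AIC minimizer, with ties broken by BIC and then by log-likelihood;
#' single-model failures are recorded in-row and the rest of the grid is
#' still returned.
#'
#' @inheritParams two_step_fit
#' @param margin_families,copula_families families to cross.
#' @param se compute standard errors for each fit (not needed for the
#'   criteria themselves; default off for speed).
#' @return a data frame of class `comparison_grid` with attributes
#'   `selected` (the winning row index) and `fits` (the fit objects).
#' @export
compare_grid <- function(data, covariates = character(0),
                         margin_families = c("weibull", "gompertz", "loglogistic"),
                         copula_families = c("clayton", "gumbel", "joe"),
                         se = FALSE,
                         ic_param_count = c("regression_plus_copula", "all")) {
  ic_param_count <- match.arg(ic_param_count)
  rows <- list(); fits <- list()
  for (mf in margin_families) {
    step1 <- tryCatch(.fit_margins_indep(mf, data, covariates),
                      error = function(e) NULL)
    for (cf in copula_families) {
      key <- paste(mf, cf, sep = "-")
      fit <- if (is.null(step1)) NULL else tryCatch(
        two_step_fit(data, covariates, mf, cf, se = se,
                     ic_param_count = ic_param_count, step1 = step1),
        error = function(e) NULL)
      fits[[key]] <- fit
      rows[[key]] <- if (is.null(fit)) {
        data.frame(margin = mf, copula = cf, AIC = NA_real_, BIC = NA_real_,
                   final_llk = NA_real_, tau = NA_real_, K = NA_integer_,
                   n = nrow(data), converged = FALSE)
      } else {
        data.frame(margin = mf, copula = cf, AIC = fit$AIC, BIC = fit$BIC,
                   final_llk = fit$loglik, tau = fit$tau, K = fit$K,
                   n = fit$n, converged = fit$convergence == 0)
      }
    }
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  ord <- order(grid$AIC, grid$BIC, -grid$final_llk, na.last = TRUE)
  sel <- ord[1]
  structure(grid, selected = sel, fits = fits, class = c("comparison_grid",
                                                         "data.frame"))
}

#' @export
print.comparison_grid <- function(x, ...) {
  df <- as.data.frame(x)
  df[c("AIC", "BIC", "final_llk")] <- round(df[c("AIC", "BIC", "final_llk")], 2)
  df$tau <- round(df$tau, 2)
  print(df)
  sel <- attr(x, "selected")
  cat(sprintf("Selected (min AIC): %s-%s\n", df$margin[sel], df$copula[sel]))
  invisible(x)
}

#' Which grid cell was selected
#'
#' @param grid a [compare_grid()] result.
#' @return list with `margin`, `copula` and the fitted model.
#' @export
selected_model <- function(grid) {
  sel <- attr(grid, "selected")
  key <- paste(grid$margin[sel], grid$copula[sel], sep = "-")
  list(margin = grid$margin[sel], copula = grid$copula[sel],
       fit = attr(grid, "fits")[[key]])
}

#' Univariable covariate screen at the 25% rule
#'
#' Fits the joint model once per covariate (that covariate alone) and
#' retains those whose Wald P value falls below `alpha` (default 0.25) as
#' candidates for the multivariable model.  Covariates constant in the
#' data are excluded with a warning rather than aborting the screen.
#'
#' @inheritParams two_step_fit
#' @param all_covariates covariate column names to screen.
#' @param alpha retention threshold on the Wald P value.
#' @return a data frame (one row per screened covariate: estimate, SE,
#'   P, retained) with attribute `retained` (character vector).
#' @export
screen_univariable <- function(data, all_covariates,
                               margin_family = "loglogistic",
                               copula_family = "clayton", alpha = 0.25) {
  stopifnot(length(all_covariates) >= 1, alpha > 0, alpha <= 1)
  rows <- list()
  for (cv in all_covariates) {
    vals <- data[[cv]]
    if (is.null(vals)) stop("covariate column not found: ", cv)
    if (length(unique(vals)) < 2) {
      warning("covariate '", cv, "' is constant; excluded from the screen")
      rows[[cv]] <- data.frame(covariate = cv, estimate = NA_real_,
                               se = NA_real_, p_value = NA_real_,
                               retained = FALSE)
      next
    }
    fit <- two_step_fit(data, cv, margin_family, copula_family, se = TRUE)
    w <- wald_inference(fit)
    rows[[cv]] <- data.frame(covariate = cv, estimate = w$estimate[1],
                             se = w$se[1], p_value = w$p_value[1],
                             retained = is.finite(w$p_value[1]) &&
                               w$p_value[1] < alpha)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, retained = out$covariate[which(out$retained)],
            alpha = alpha)
}
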