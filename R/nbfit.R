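# Negative binomial log-linear trend fit for short monthly count histories.
# Time is coded t = -w..-1 with the monitored month at t = 0, so the
# forecast linear predictor is the intercept and its standard error falls
# straight out of the parameter covariance. The dispersion is profiled:
# for fixed alpha the regression is an ordinary GLM (IRLS), and a 1-D
# search over log(alpha) yields the joint maximum likelihood. Variance
# parameterisation is mu + alpha * mu^2 (NB2); alpha at the zero boundary
# collapses to Poisson, which is also the fallback when the NB fit fails.

ALPHA_MIN <- 1e-6
ALPHA_MAX <- 50

#' Is a history too sparse for the trend regression?
#'
#' With mostly-null histories the trend regression is unreliable, so
#' detection falls back to a threshold-only heuristic. A history of length
#' `window` is "null" when it has `window - 2` or more zeros — for the
#' default 6-month window, 4 or more zeros — i.e. fewer than 3 non-zero
#' points, too few to support a two-parameter trend fit.
#'
#' @param history integer vector of monthly counts, oldest first.
#' @param window expected history length (defaults to `length(history)`).
#' @return `TRUE` if the heuristic branch applies.
#' @export
is_null_history <- function(history, window = length(history)) {
  if (length(history) != window) {
    stop("history has length ", length(history), ", expected ", window,
         call. = FALSE)
  }
  sum(history == 0) >= window - 2L
}

check_history <- function(history) {
  if (length(history) < 3L) {
    stop("history must have at least 3 observations", call. = FALSE)
  }
  if (anyNA(history) || any(history < 0) ||
      any(abs(history - round(history)) > 1e-8)) {
    stop("history must be non-negative integer counts", call. = FALSE)
  }
  as.integer(round(history))
}

# expected-information covariance of (beta0, beta1) at fixed dispersion;
# working weights mu / (1 + alpha * mu), the GLM convention
beta_covariance <- function(X, mu, alpha) {
  W <- mu / (1 + alpha * mu)
  solve(crossprod(X, X * W))
}

#' Fit the negative binomial trend to a count history
#'
#' Maximum-likelihood fit of `count_t ~ NB(mu_t, alpha)` with
#' `log mu_t = beta0 + beta1 * t`, `t = -w, ..., -1`, so that `exp(beta0)`
#' is the forecast mean for the monitored month `t = 0`. The dispersion
#' `alpha` (variance `mu + alpha * mu^2`) is estimated by profile
#' likelihood; when its estimate sits at the zero boundary, or the NB fit
#' does not converge, the model is refit as a Poisson GLM
#' (`family_used = "poisson"`).
#'
#' @param history integer vector of monthly counts, oldest first; must not
#'   satisfy [is_null_history()].
#' @return object of class `nb_fit`: list with `beta0`, `beta1`, `alpha`,
#'   `se_eta0` (standard error of the linear predictor at `t = 0`),
#'   `loglik`, `converged`, `family_used`, `window`.
#' @export
fit_nb_trend <- function(history) {
  y <- check_history(history)
  w <- length(y)
  if (is_null_history(y, w)) {
    stop("history is mostly null (", sum(y == 0), " zeros of ", w,
         "); the heuristic branch applies, not the regression", call. = FALSE)
  }
  tt <- seq.int(-w, -1L)
  X <- cbind(`(Intercept)` = 1, t = tt)

  pois <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
  ll_pois <- sum(stats::dpois(y, pois$fitted.values, log = TRUE))

  profile_ll <- function(log_alpha) {
    alpha <- exp(log_alpha)
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(
        X, y, family = MASS::negative.binomial(theta = 1 / alpha),
        control = stats::glm.control(maxit = 50))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) {
      # finite penalty keeps optimize() quiet on non-convergent dispersions
      return(list(ll = -1e10, fit = NULL))
    }
    mu <- fit$fitted.values
    list(ll = sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE)),
         fit = fit)
  }

  opt <- tryCatch(
    stats::optimize(function(la) profile_ll(la)$ll,
                    interval = log(c(ALPHA_MIN, ALPHA_MAX)),
                    maximum = TRUE, tol = 1e-8),
    error = function(e) NULL)

  use_poisson <- TRUE
  if (!is.null(opt) && is.finite(opt$objective) &&
      opt$objective > ll_pois + 1e-7) {
    alpha_hat <- exp(opt$maximum)
    if (alpha_hat > ALPHA_MIN * 1.5) {
      nb <- profile_ll(opt$maximum)
      if (!is.null(nb$fit)) {
        cov_beta <- beta_covariance(X, nb$fit$fitted.values, alpha_hat)
        out <- list(beta0 = unname(nb$fit$coefficients[1L]),
                    beta1 = unname(nb$fit$coefficients[2L]),
                    alpha = alpha_hat,
                    se_eta0 = sqrt(cov_beta[1L, 1L]),
                    loglik = nb$ll,
                    converged = TRUE,
                    family_used = "negbin",
                    window = w)
        use_poisson <- FALSE
      }
    }
  }
  if (use_poisson) {
    cov_beta <- beta_covariance(X, pois$fitted.values, 0)
    out <- list(beta0 = unname(pois$coefficients[1L]),
                beta1 = unname(pois$coefficients[2L]),
                alpha = 0,
                se_eta0 = sqrt(cov_beta[1L, 1L]),
                loglik = ll_pois,
                converged = pois$converged,
                family_used = "poisson",
                window = w)
  }
  structure(out, class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf(
    "nb_fit (%s): beta0 = %.4f, beta1 = %.4f, alpha = %.4g, se(eta0) = %.4f, logLik = %.4f\n",
    x$family_used, x$beta0, x$beta1, x$alpha, x$se_eta0, x$loglik))
  invisible(x)
}

#' Forecast the monitored month from a fitted trend
#'
#' The point forecast is `exp(beta0)`. Two upper bounds are offered:
#' `"ci_mean"`, the upper limit of the Wald confidence interval of the
#' forecast mean, `exp(beta0 + z * se_eta0)` — the default decision rule —
#' and `"prediction"`, the smallest integer count `q` whose NB (or Poisson)
#' CDF at mean `exp(beta0 + z * se_eta0)` reaches `level`, a conservative
#' count-scale bound that also carries outcome-level variability.
#'
#' @param fit an `nb_fit`.
#' @param level bound level in (0, 1); default 0.95.
#' @param bound_type `"ci_mean"` or `"prediction"`.
#' @return object of class `uif_forecast`: list with `y_hat`,
#'   `upper_bound`, `level`, `bound_type`, `fit`.
#' @export
forecast_t0 <- function(fit, level = 0.95,
                        bound_type = c("ci_mean", "prediction")) {
  stopifnot(inherits(fit, "nb_fit"))
  bound_type <- match.arg(bound_type)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!isTRUE(fit$converged)) {
    stop("cannot forecast from a non-converged fit", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  y_hat <- exp(fit$beta0)
  mu_upper <- exp(fit$beta0 + z * fit$se_eta0)
  upper_bound <- if (bound_type == "ci_mean") {
    mu_upper
  } else if (fit$alpha > 0) {
    stats::qnbinom(level, size = 1 / fit$alpha, mu = mu_upper)
  } else {
    stats::qpois(level, mu_upper)
  }
  # count-scale quantile can fall below a sub-unit mean; keep the bound
  # above the point forecast
  upper_bound <- max(upper_bound, y_hat)
  structure(list(y_hat = y_hat, upper_bound = as.numeric(upper_bound),
                 level = level, bound_type = bound_type, fit = fit),
            class = "uif_forecast")
}

#' @export
print.uif_forecast <- function(x, ...) {
  cat(sprintf("forecast: y_hat = %.3f, upper bound (%s, %.0f%%) = %.3f\n",
              x$y_hat, x$bound_type, 100 * x$level, x$upper_bound))
  invisible(x)
}
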