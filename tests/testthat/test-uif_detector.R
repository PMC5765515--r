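test_that("the null-history rule needs window - 2 zeros", {
  expect_true(is_null_history(c(0, 0, 0, 0, 2, 1), 6))
  expect_false(is_null_history(c(0, 0, 0, 1, 2, 1), 6))
  expect_true(is_null_history(c(0, 0, 3), 3))
  expect_false(is_null_history(c(2, 1, 3), 3))
  expect_error(is_null_history(c(0, 0, 1), 6), "length")
})

test_that("a constant history fits a flat Poisson trend at the sample mean", {
  fit <- fit_nb_trend(c(5, 5, 5, 5, 5, 5))
  expect_equal(fit$beta1, 0, tolerance = 1e-8)
  expect_equal(exp(fit$beta0), 5, tolerance = 1e-8)
  expect_equal(fit$family_used, "poisson")
  expect_equal(fit$alpha, 0)
})

test_that("geometric growth recovers a log-slope of ln 2 per month", {
  fit <- fit_nb_trend(c(1, 2, 4, 8, 16, 32))
  expect_equal(fit$beta1, log(2), tolerance = 0.05)
  expect_equal(exp(fit$beta0), 64, tolerance = 0.05)
})

test_that("the trend fit agrees with an independent NB GLM", {
  y <- c(12, 3, 25, 2, 18, 7)
  fit <- fit_nb_trend(y)
  expect_equal(fit$family_used, "negbin")
  tt <- seq.int(-6, -1)
  ref <- suppressWarnings(MASS::glm.nb(y ~ tt))
  expect_equal(fit$beta0, unname(coef(ref)[1]), tolerance = 1e-3)
  expect_equal(fit$beta1, unname(coef(ref)[2]), tolerance = 1e-3)
  expect_equal(fit$alpha, 1 / ref$theta, tolerance = 1e-2)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-4)
})

test_that("histories no more dispersed than Poisson use the Poisson family", {
  set.seed(7)
  n_checked <- 0
  for (i in 1:50) {
    y <- random_history()
    if (var(y) > mean(y)) next
    n_checked <- n_checked + 1
    fit <- fit_nb_trend(y)
    expect_equal(fit$family_used, "poisson")
    tt <- seq.int(-6, -1)
    ref <- glm(y ~ tt, family = poisson)
    expect_equal(exp(fit$beta0),
                 unname(exp(coef(ref)[1])), tolerance = 1e-6)
  }
  expect_gt(n_checked, 3)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_nb_trend(c(0, 0, 0, 0, 2, 1)), "mostly null")
  expect_error(fit_nb_trend(c(1.5, 2, 3, 4, 5, 6)), "integer")
  expect_error(fit_nb_trend(c(-1, 2, 3, 4, 5, 6)), "non-negative")
})

test_that("a zero-variance linear predictor degenerates to y_hat", {
  fit <- structure(list(beta0 = log(5), beta1 = 0, alpha = 0, se_eta0 = 0,
                        loglik = NA_real_, converged = TRUE,
                        family_used = "poisson", window = 6),
                   class = "nb_fit")
  fc <- forecast_t0(fit, level = 0.95, bound_type = "ci_mean")
  expect_equal(fc$y_hat, 5)
  expect_equal(fc$upper_bound, 5)
})

test_that("the prediction bound is the smallest count quantile at the level", {
  fit <- structure(list(beta0 = log(5), beta1 = 0, alpha = 0, se_eta0 = 0,
                        loglik = NA_real_, converged = TRUE,
                        family_used = "poisson", window = 6),
                   class = "nb_fit")
  fc <- forecast_t0(fit, level = 0.95, bound_type = "prediction")
  # independent oracle: direct CDF summation for Poisson(5)
  q <- min(which(cumsum(dpois(0:100, 5)) >= 0.95)) - 1L
  expect_equal(q, 9L)
  expect_equal(fc$upper_bound, 9)
})

test_that("the upper bound never falls below the point forecast", {
  set.seed(19)
  for (i in 1:30) {
    fit <- fit_nb_trend(random_history())
    for (bt in c("ci_mean", "prediction")) {
      fc <- forecast_t0(fit, level = 0.95, bound_type = bt)
      expect_gte(fc$upper_bound, fc$y_hat)
      expect_gte(fc$y_hat, 0)
    }
  }
})

test_that("the decision rule fires per branch and short-circuits below tau", {
  cfg5 <- screen_config(threshold_tau = 5)
  det <- detect(c(0, 0, 0, 0, 2, 1), 5, cfg5)
  expect_equal(det$branch, "heuristic")
  expect_null(det$forecast)
  cfg3 <- screen_config(threshold_tau = 3)
  expect_null(detect(c(5, 5, 5, 5, 5, 5), 4, cfg3))
  expect_null(detect(c(2, 1, 3, 2, 2, 1), 2, cfg3))
})

test_that("detection is monotone in the observed count", {
  set.seed(23)
  cfg <- screen_config(threshold_tau = 3)
  for (i in 1:20) {
    y <- random_history()
    fired_at <- NA
    for (y0 in 0:40) {
      fired <- !is.null(detect(y, y0, cfg))
      if (fired && is.na(fired_at)) fired_at <- y0
      if (!is.na(fired_at)) expect_true(fired)
    }
  }
})

test_that("exactly one branch is evaluated, chosen by the null-history rule", {
  set.seed(29)
  cfg <- screen_config(threshold_tau = 3)
  for (i in 1:40) {
    y <- as.integer(rnbinom(6, size = 2, mu = runif(1, 0.2, 6)))
    y0 <- 3L + as.integer(rpois(1, 8))
    det <- detect(y, y0, cfg)
    if (!is.null(det)) {
      expect_equal(det$branch,
                   if (is_null_history(y, 6)) "heuristic" else "regression")
    } else {
      # a non-firing candidate must have gone down the regression branch
      expect_false(is_null_history(y, 6))
    }
  }
})

test_that("screen flags only eligible series and is deterministic", {
  months <- month_seq("2010-01", "2010-07")
  mk <- function(drug, event, counts) {
    data.frame(drug_level = "substance", drug_id = drug,
               event_level = "pt", event_id = event,
               month = months, count = counts)
  }
  counts <- rbind(mk("drug x", "a1", c(0, 0, 0, 0, 2, 1, 6)),
                  mk("drug x", "b1", c(2, 1, 3, 2, 2, 1, 2)))
  cfg <- screen_config(threshold_tau = 5)
  out <- screen(counts, "2010-07", cfg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$event_id, "a1")
  expect_equal(out$branch, "heuristic")
  log <- attr(out, "run_log")
  expect_equal(log$n_universe, 2L)
  expect_equal(log$n_candidates, 1L)
  # determinism
  again <- screen(counts, "2010-07", cfg)
  expect_identical(as.data.frame(out), as.data.frame(again))
  # empty universe
  none <- screen(counts[0, ], "2010-07", cfg)
  expect_equal(nrow(none), 0L)
})
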