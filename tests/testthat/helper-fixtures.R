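# Shared in-code fixtures: a 10-PT toy hierarchy, report-table builders,
# and independent likelihood oracles for the trend fit.

toy_hierarchy <- function() {
  pt <- data.frame(
    pt = c("a1", "a2", "a3", "b1", "b2", "b3", "c1", "c2", "c3", "c4"),
    hlt = c("ha", "ha", "ha", "hb", "hb", "hb", "hc", "hc", "hc", "hc"),
    hlgt = c(rep("gab", 6), rep("gc", 4)),
    soc = c(rep("s1", 6), rep("s2", 4)),
    ime = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
            TRUE, FALSE, FALSE, FALSE),
    dme = c(TRUE, rep(FALSE, 9)),
    quality_issue = c(rep(FALSE, 9), TRUE),
    stringsAsFactors = FALSE)
  smq <- data.frame(
    smq_id = c("smq1", "smq1", "smq1", "smq1", "smq2", "smq2"),
    pt = c("a2", "b1", "b2", "c1", "c2", "c3"),
    scope = c("narrow", "narrow", "broad", "broad", "narrow", "narrow"),
    stringsAsFactors = FALSE)
  term_hierarchy(pt, smq)
}

report_row <- function(case_id, date, substance = "drug x",
                       product = "brand x", pt = "a1",
                       literature = FALSE, module = "post_marketing") {
  data.frame(case_id = case_id, receive_date = date, substance = substance,
             product_name = product, event_pt = pt,
             literature = literature, module = module,
             stringsAsFactors = FALSE)
}

# a random valid report table over the toy hierarchy (caller sets the seed)
random_reports <- function(h, n = 60, months = c("2010-01", "2010-12")) {
  mseq <- month_seq(months[1], months[2])
  m <- sample(mseq, n, replace = TRUE)
  day <- sample(28, n, replace = TRUE)
  data.frame(
    case_id = sprintf("R%05d", seq_len(n)),
    receive_date = sprintf("%s-%02d", m, day),
    substance = sample(c("drug x", "drug y"), n, replace = TRUE),
    product_name = ifelse(runif(n) < 0.7, "brand x", NA_character_),
    event_pt = sample(all_pts_of(h), n, replace = TRUE),
    literature = runif(n) < 0.25,
    module = "post_marketing",
    stringsAsFactors = FALSE)
}

all_pts_of <- function(h) h$pt$pt

# NB trend log-likelihood (variance mu + alpha mu^2); alpha = 0 is Poisson
nb_trend_loglik <- function(y, beta0, beta1, alpha) {
  tt <- seq.int(-length(y), -1L)
  mu <- exp(beta0 + beta1 * tt)
  if (alpha > 0) sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  else sum(dpois(y, mu, log = TRUE))
}

# dense-grid oracle for the maximised log-likelihood, vectorised over the
# (beta0, beta1) grid for each dispersion value (alpha = 0 included)
grid_search_loglik <- function(y, n_beta = 60, n_alpha = 30) {
  tt <- seq.int(-length(y), -1L)
  b0 <- seq(log(mean(y) + 0.25) - 1.5, log(mean(y) + 0.25) + 1.5,
            length.out = n_beta)
  b1 <- seq(-0.9, 0.9, length.out = n_beta)
  grid <- expand.grid(b0 = b0, b1 = b1)
  eta <- outer(grid$b0, rep(1, length(tt))) +
    outer(grid$b1, tt)
  mu <- exp(eta)
  ym <- matrix(y, nrow = nrow(mu), ncol = length(y), byrow = TRUE)
  alphas <- c(0, exp(seq(log(1e-4), log(20), length.out = n_alpha)))
  best <- -Inf
  for (a in alphas) {
    ll_mat <- if (a > 0) dnbinom(ym, size = 1 / a, mu = mu, log = TRUE)
      else dpois(ym, mu, log = TRUE)
    best <- max(best, max(rowSums(ll_mat)))
  }
  best
}

# random screenable histories (not mostly-null), counts bounded
random_history <- function(max_count = 50) {
  repeat {
    kind <- sample(3, 1)
    y <- switch(kind,
      rpois(6, runif(1, 0.8, 15)),
      rnbinom(6, size = 1 / runif(1, 0.05, 1.5), mu = runif(1, 1, 12)),
      round(runif(1, 1, 6) * exp(runif(1, -0.3, 0.3) * (1:6))))
    y <- pmin(y, max_count)
    if (!is_null_history(y, 6)) return(as.integer(y))
  }
}
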