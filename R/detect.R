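# The UIF decision rule and the screen over a counting universe.
#
# For one candidate (drug, event, month): nothing is flagged below the
# minimum-count threshold tau (no fit is even attempted); mostly-null
# histories are judged by the threshold-only heuristic; otherwise the NB
# trend is fitted and the month is flagged when the observed count exceeds
# the forecast upper bound.

#' Apply the UIF decision rule to one candidate month
#'
#' @param history integer vector of the `config$window_months` counts
#'   preceding the monitored month, oldest first.
#' @param y0 observed count in the monitored month.
#' @param config a [screen_config()].
#'
#' @return `NULL` when no unexpected increase is detected; otherwise a list
#'   of class `uif_detection` with `y0`, `branch` (`"regression"` or
#'   `"heuristic"`), `threshold`, and — regression branch only — `forecast`
#'   (a `uif_forecast`).
#'
#' @details The threshold is a minimum count, so eligibility is
#'   `y0 >= threshold_tau`; the forecast bound is exceeded strictly
#'   (`y0 > upper_bound`). Which branch applies is governed solely by
#'   [is_null_history()].
#' @export
detect <- function(history, y0, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  if (length(history) != config$window_months) {
    stop("history has length ", length(history), ", expected window of ",
         config$window_months, call. = FALSE)
  }
  y0 <- as.integer(y0)
  if (is.na(y0) || y0 < 0) stop("y0 must be a non-negative count",
                                call. = FALSE)
  if (y0 < config$threshold_tau) return(NULL)
  if (is_null_history(history, config$window_months)) {
    return(structure(list(y0 = y0, branch = "heuristic",
                          threshold = config$threshold_tau,
                          forecast = NULL),
                     class = "uif_detection"))
  }
  fit <- fit_nb_trend(history)
  fc <- forecast_t0(fit, level = config$bound_level,
                    bound_type = config$bound_type)
  if (y0 > fc$upper_bound) {
    return(structure(list(y0 = y0, branch = "regression",
                          threshold = config$threshold_tau,
                          forecast = fc),
                     class = "uif_detection"))
  }
  NULL
}

#' @export
print.uif_detection <- function(x, ...) {
  if (x$branch == "heuristic") {
    cat(sprintf("UIF (heuristic): y0 = %d >= tau = %d after a mostly-null history\n",
                x$y0, x$threshold))
  } else {
    cat(sprintf("UIF (regression): y0 = %d > upper bound %.3f (y_hat %.3f), tau = %d\n",
                x$y0, x$forecast$upper_bound, x$forecast$y_hat, x$threshold))
  }
  invisible(x)
}

#' Screen every drug-event series at a monitored month
#'
#' Applies [detect()] to each drug-event combination in a `uif_counts`
#' table at month `t0`. The screening universe is every combination with at
#' least one report in `t0`; combinations whose count table does not cover
#' the full window at `t0` are skipped. Per-series fit failures are logged
#' and skipped, never aborting the screen.
#'
#' @param counts a `uif_counts` table (see [monthly_counts()]); must cover
#'   `t0` and the `config$window_months` months before it.
#' @param t0 monitored month, `"YYYY-MM"`.
#' @param config a [screen_config()].
#'
#' @return data.frame of class `uif_detections` with columns `drug_level,
#'   drug_id, event_level, event_id, month, y0, branch, y_hat, upper_bound,
#'   threshold, level, bound_type` (`y_hat`/`upper_bound` are `NA` on the
#'   heuristic branch), ordered by drug then event. Attribute `run_log`
#'   tallies candidates and detections per branch.
#' @export
screen <- function(counts, t0, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  counts <- as.data.frame(counts)
  t0 <- as_month(t0)
  w <- config$window_months
  needed <- month_seq(month_add(t0, -w), t0)
  sub <- counts[counts$month %in% needed, , drop = FALSE]
  key <- paste(sub$drug_id, sub$event_id, sep = "\r")
  pairs <- unique(data.frame(key = key, drug_level = sub$drug_level,
                             drug_id = sub$drug_id,
                             event_level = sub$event_level,
                             event_id = sub$event_id,
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$drug_id, pairs$event_id), , drop = FALSE]
  # wide matrix: one row per pair, one column per window month
  mat <- matrix(NA_integer_, nrow = nrow(pairs), ncol = length(needed),
                dimnames = list(pairs$key, needed))
  mat[cbind(match(key, pairs$key), match(sub$month, needed))] <-
    as.integer(sub$count)
  log <- list(t0 = t0, n_universe = 0L, n_candidates = 0L,
              n_regression_candidates = 0L, n_heuristic_candidates = 0L,
              n_detections_regression = 0L, n_detections_heuristic = 0L,
              n_fit_failures = 0L, n_no_coverage = 0L)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    counts_i <- mat[i, ]
    if (anyNA(counts_i)) { log$n_no_coverage <- log$n_no_coverage + 1L; next }
    y0 <- counts_i[[w + 1L]]
    if (y0 < 1L) next
    log$n_universe <- log$n_universe + 1L
    if (y0 < config$threshold_tau) next
    log$n_candidates <- log$n_candidates + 1L
    history <- counts_i[seq_len(w)]
    if (is_null_history(history, w)) {
      log$n_heuristic_candidates <- log$n_heuristic_candidates + 1L
    } else {
      log$n_regression_candidates <- log$n_regression_candidates + 1L
    }
    det <- tryCatch(detect(history, y0, config), error = function(e) e)
    if (inherits(det, "error")) {
      log$n_fit_failures <- log$n_fit_failures + 1L
      next
    }
    if (is.null(det)) next
    if (det$branch == "regression") {
      log$n_detections_regression <- log$n_detections_regression + 1L
      y_hat <- det$forecast$y_hat
      upper <- det$forecast$upper_bound
    } else {
      log$n_detections_heuristic <- log$n_detections_heuristic + 1L
      y_hat <- NA_real_
      upper <- NA_real_
    }
    rows[[i]] <- data.frame(
      drug_level = pairs$drug_level[i], drug_id = pairs$drug_id[i],
      event_level = pairs$event_level[i], event_id = pairs$event_id[i],
      month = t0, y0 = as.integer(y0), branch = det$branch,
      y_hat = y_hat, upper_bound = upper,
      threshold = config$threshold_tau, level = config$bound_level,
      bound_type = config$bound_type, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  out <- if (length(rows)) do.call(rbind, rows) else empty_detections()
  rownames(out) <- NULL
  attr(out, "run_log") <- log
  class(out) <- c("uif_detections", "data.frame")
  out
}

empty_detections <- function() {
  data.frame(drug_level = character(), drug_id = character(),
             event_level = character(), event_id = character(),
             month = character(), y0 = integer(), branch = character(),
             y_hat = numeric(), upper_bound = numeric(),
             threshold = integer(), level = numeric(),
             bound_type = character(), stringsAsFactors = FALSE)
}

#' Screen a span of monitored months
#'
#' Convenience wrapper running [screen()] for every month in
#' `[first_t0, last_t0]` and row-binding the detections.
#'
#' @param counts a `uif_counts` table.
#' @param first_t0,last_t0 first and last monitored months (`"YYYY-MM"`).
#' @param config a [screen_config()].
#' @return a `uif_detections` table covering all screened months; attribute
#'   `run_logs` holds the per-month run logs.
#' @export
screen_months <- function(counts, first_t0, last_t0,
                          config = screen_config()) {
  t0s <- month_seq(first_t0, last_t0)
  per_month <- lapply(t0s, function(t0) screen(counts, t0, config))
  out <- do.call(rbind, lapply(per_month, as.data.frame))
  if (is.null(out)) out <- empty_detections()
  rownames(out) <- NULL
  attr(out, "run_logs") <- lapply(per_month, attr, "run_log")
  class(out) <- c("uif_detections", "data.frame")
  out
}

#' @rdname screen
#' @param detections a `uif_detections` table.
#' @param path CSV destination.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(as.data.frame(detections), path, row.names = FALSE,
                   na = "")
  invisible(path)
}
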