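#' Screening configuration
#'
#' Bundles every tunable axis of the screen: the history window, the
#' minimum-count threshold, literature handling, drug and event
#' stratification, the IME/DME restriction and the forecast bound.
#'
#' @param window_months length of the history window fitted by the trend
#'   model (default 6 months; at least 3, since a two-parameter trend needs
#'   three usable points).
#' @param threshold_tau minimum observed count for a month to be eligible
#'   for detection; routine signal-detection practice puts this between 3
#'   and 5 reports. Default 5.
#' @param include_literature count reports that stem from the published
#'   literature (default `TRUE`).
#' @param drug_level `"substance"` or `"product"` (commercial product name);
#'   reports without a product name are excluded from product-level screens.
#' @param event_level `"pt"` (one series per preferred term, the routine
#'   setting), `"pooled_all"` (all PTs of a drug pooled into one series), or
#'   `"grouping"` (one series per grouping term at `grouping_level`).
#' @param grouping_level `"hlt"`, `"hlgt"` or `"smq"`; used only when
#'   `event_level = "grouping"`.
#' @param restrict_ime_dme count only PTs flagged as important or designated
#'   medical events (default `TRUE`).
#' @param bound_level nominal level of the forecast upper bound (default
#'   0.95).
#' @param bound_type `"ci_mean"` — upper confidence bound of the forecast
#'   mean (the default decision rule) — or `"prediction"`, a conservative
#'   count-scale upper quantile that also carries outcome-level variability.
#'
#' @return list of class `screen_config`.
#' @export
screen_config <- function(window_months = 6L,
                          threshold_tau = 5L,
                          include_literature = TRUE,
                          drug_level = c("substance", "product"),
                          event_level = c("pt", "pooled_all", "grouping"),
                          grouping_level = c("hlt", "hlgt", "smq"),
                          restrict_ime_dme = TRUE,
                          bound_level = 0.95,
                          bound_type = c("ci_mean", "prediction")) {
  window_months <- as.integer(window_months)
  threshold_tau <- as.integer(threshold_tau)
  if (is.na(window_months) || window_months < 3L) {
    stop("window_months must be an integer >= 3", call. = FALSE)
  }
  if (is.na(threshold_tau) || threshold_tau < 1L) {
    stop("threshold_tau must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(bound_level) || bound_level <= 0 || bound_level >= 1) {
    stop("bound_level must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(
    window_months = window_months,
    threshold_tau = threshold_tau,
    include_literature = isTRUE(include_literature),
    drug_level = match.arg(drug_level),
    event_level = match.arg(event_level),
    grouping_level = match.arg(grouping_level),
    restrict_ime_dme = isTRUE(restrict_ime_dme),
    bound_level = bound_level,
    bound_type = match.arg(bound_type)
  ), class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat("screen_config: window", x$window_months, "months, tau",
      x$threshold_tau, ",", x$drug_level, "x", x$event_level,
      if (x$event_level == "grouping") paste0("(", x$grouping_level, ")"),
      ", literature", if (x$include_literature) "in" else "out",
      ", IME/DME", if (x$restrict_ime_dme) "only" else "all",
      ", bound", x$bound_type, "@", x$bound_level, "\n")
  invisible(x)
}
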