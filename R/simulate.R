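# Synthetic spontaneous-report generator. Real EudraVigilance data is
# access-restricted and the real MedDRA dictionary is licensed, so both are
# emulated: a synthetic single-axial term hierarchy, over-dispersed monthly
# background reporting per drug-event pair, and injected concern episodes
# that elevate every PT grouped under a concern's grouping term. Counts are
# sampled from the same NB parameterisation the detector fits
# (variance = mu + alpha * mu^2), so calibration checks are exact.

#' Simulation scenario
#'
#' Describes a synthetic spontaneous-report database: a stationary (or
#' geometrically drifting) over-dispersed monthly background per drug-event
#' pair, plus a list of injected concern episodes with known ground truth.
#'
#' @param substances character vector of substance names (each is given one
#'   commercial product name, `"<substance> brand"`).
#' @param pts_per_substance number of background PTs reported per substance
#'   (sampled from the hierarchy, seeded).
#' @param baseline_mu mean monthly count per drug-event pair (default 2, a
#'   typical low-volume spontaneous-reporting background).
#' @param dispersion_alpha NB dispersion of the background (variance
#'   `mu + alpha * mu^2`; 0 gives Poisson). Default 0.3.
#' @param trend_per_month multiplicative drift of the background mean per
#'   month (1 = stationary).
#' @param literature_fraction probability a background report is flagged as
#'   stemming from the published literature.
#' @param prop_with_product probability a background report carries a
#'   product name (the remainder specify only the substance).
#' @param months length-2 `c(first_month, last_month)` span.
#' @param injections list of [injection_spec()] episodes.
#' @param seed integer seed; the whole table is reproducible from it.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(substances = sprintf("substance %02d", 1:4),
                         pts_per_substance = 8L,
                         baseline_mu = 2,
                         dispersion_alpha = 0.3,
                         trend_per_month = 1,
                         literature_fraction = 0.1,
                         prop_with_product = 0.7,
                         months = c("2009-01", "2012-12"),
                         injections = list(),
                         seed = 20080218L) {
  stopifnot(baseline_mu > 0, dispersion_alpha >= 0,
            literature_fraction >= 0, literature_fraction <= 1,
            prop_with_product >= 0, prop_with_product <= 1,
            trend_per_month > 0, length(months) == 2L)
  month_seq(months[1L], months[2L])  # validates the span
  structure(list(substances = norm_label(substances),
                 pts_per_substance = as.integer(pts_per_substance),
                 baseline_mu = baseline_mu,
                 dispersion_alpha = dispersion_alpha,
                 trend_per_month = trend_per_month,
                 literature_fraction = literature_fraction,
                 prop_with_product = prop_with_product,
                 months = months,
                 injections = injections,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' @rdname sim_scenario
#' @param substance,product_name drug affected by the episode.
#' @param grouping_level,grouping_id grouping term whose member PTs are all
#'   elevated during the episode.
#' @param start_month first episode month (`"YYYY-MM"`).
#' @param duration_months episode length, at least 1.
#' @param fold_increase expected episode count as a multiple of the
#'   background mean; must exceed 1.
#' @param concern_type `"QD"`, `"ME"` or `"AM"`.
#' @param index_date date the concern entered the issue-tracking register
#'   (ISO-8601); anchors the true-positive window.
#' @param concern_id register id.
#' @export
injection_spec <- function(concern_id, substance, grouping_level,
                           grouping_id, start_month, duration_months,
                           fold_increase, concern_type, index_date,
                           product_name = NA_character_) {
  stopifnot(duration_months >= 1, fold_increase > 1,
            concern_type %in% c("QD", "ME", "AM"))
  list(concern_id = as.character(concern_id),
       substance = norm_label(substance),
       product_name = if (is.na(product_name)) NA_character_ else
         norm_label(product_name),
       grouping_level = toupper(grouping_level),
       grouping_id = norm_label(grouping_id),
       start_month = as_month(start_month),
       duration_months = as.integer(duration_months),
       fold_increase = fold_increase,
       concern_type = concern_type,
       index_date = as.Date(index_date))
}

rcount <- function(n, mu, alpha) {
  if (alpha > 0) stats::rnbinom(n, size = 1 / alpha, mu = mu)
  else stats::rpois(n, mu)
}

make_records <- function(n_by_month, months, substance, product_name,
                         event_pt, literature_fraction, case_prefix) {
  total <- sum(n_by_month)
  if (total == 0L) return(NULL)
  month <- rep(months, n_by_month)
  ndays <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  day <- 1L + floor(stats::runif(total) *
                      ndays[as.integer(substr(month, 6, 7))])
  data.frame(
    case_id = sprintf("%s-%06d", case_prefix, seq_len(total)),
    receive_date = sprintf("%s-%02d", month, day),
    substance = substance,
    product_name = product_name,
    event_pt = event_pt,
    literature = stats::runif(total) < literature_fraction,
    module = "post_marketing",
    stringsAsFactors = FALSE)
}

#' Simulate background reporting
#'
#' Draws, for every (substance, PT) pair and month of the scenario span, a
#' count from `NB(mu = baseline_mu * trend^m, alpha)` and expands it into
#' individual report rows with a random day of month, Bernoulli literature
#' flag, and a product name present with probability `prop_with_product`.
#' Fully reproducible from the scenario seed.
#'
#' @param scenario a [sim_scenario()].
#' @param hierarchy a `term_hierarchy` to sample background PTs from.
#' @return a validated `uif_reports` table.
#' @export
simulate_background <- function(scenario, hierarchy) {
  stopifnot(inherits(scenario, "sim_scenario"),
            inherits(hierarchy, "term_hierarchy"))
  set.seed(scenario$seed)
  months <- month_seq(scenario$months[1L], scenario$months[2L])
  m_rel <- seq_along(months) - 1L
  mu <- scenario$baseline_mu * scenario$trend_per_month^m_rel
  pts_pool <- all_pts(hierarchy)
  chunks <- list()
  for (s_i in seq_along(scenario$substances)) {
    sub <- scenario$substances[s_i]
    pts <- sample(pts_pool, min(scenario$pts_per_substance,
                                length(pts_pool)))
    for (p_i in seq_along(pts)) {
      n_by_month <- rcount(length(months), mu, scenario$dispersion_alpha)
      rec <- make_records(n_by_month, months, sub, NA_character_, pts[p_i],
                          scenario$literature_fraction,
                          sprintf("BG%02d-%02d", s_i, p_i))
      if (!is.null(rec)) {
        with_prod <- stats::runif(nrow(rec)) < scenario$prop_with_product
        rec$product_name[with_prod] <- paste(sub, "brand")
        chunks[[length(chunks) + 1L]] <- rec
      }
    }
  }
  out <- if (length(chunks)) do.call(rbind, chunks) else
    data.frame(case_id = character(), receive_date = character(),
               substance = character(), product_name = character(),
               event_pt = character(), literature = logical(),
               module = character())
  validate_reports(out, hierarchy)
}

#' Inject a concern episode
#'
#' Appends reports on top of the background so that, for every PT grouped
#' under the episode's grouping term and every episode month inside the
#' simulated span, the expected count is `fold_increase` times the
#' background mean (the extra reports are Poisson with mean
#' `(fold_increase - 1) * baseline_mu`). Injection is additive, so the
#' ground truth stays unambiguous. Episodes entirely outside the span leave
#' the records unchanged with a warning.
#'
#' @param records a `uif_reports` table to extend.
#' @param spec an [injection_spec()].
#' @param hierarchy a `term_hierarchy`.
#' @param scenario the [sim_scenario()] providing the span, baseline mean
#'   and seed.
#' @param seed seed for this episode (defaults to one derived from the
#'   scenario seed and the concern id).
#' @return list with `records` (extended, validated) and `concern` (the
#'   matching register rows for evaluation ground truth).
#' @export
inject_concern <- function(records, spec, hierarchy, scenario,
                           seed = NULL) {
  stopifnot(inherits(hierarchy, "term_hierarchy"),
            inherits(scenario, "sim_scenario"))
  if (is.null(seed)) {
    seed <- (scenario$seed + sum(utf8ToInt(spec$concern_id))) %% 2147483647L
  }
  set.seed(seed)
  pts <- expand_grouping(hierarchy,
                         data.frame(level = spec$grouping_level,
                                    id = spec$grouping_id))
  if (length(pts) == 0L) {
    stop("injection grouping ", spec$grouping_level, " ", spec$grouping_id,
         " expands to no PTs", call. = FALSE)
  }
  concern <- data.frame(
    concern_id = spec$concern_id,
    substance = spec$substance,
    product_names = if (is.na(spec$product_name)) "" else spec$product_name,
    index_date = spec$index_date,
    concern_type = spec$concern_type,
    grouping_level = spec$grouping_level,
    grouping_id = spec$grouping_id,
    stringsAsFactors = FALSE)
  span_months <- month_seq(scenario$months[1L], scenario$months[2L])
  episode <- month_seq(spec$start_month,
                       month_add(spec$start_month,
                                 spec$duration_months - 1L))
  episode <- intersect(episode, span_months)
  if (length(episode) == 0L) {
    warning("episode for concern ", spec$concern_id,
            " lies entirely outside the simulated span; nothing injected",
            call. = FALSE)
    return(list(records = records, concern = concern))
  }
  extra_mu <- (spec$fold_increase - 1) * scenario$baseline_mu
  chunks <- list()
  for (p_i in seq_along(pts)) {
    n_by_month <- stats::rpois(length(episode), extra_mu)
    rec <- make_records(n_by_month, episode, spec$substance,
                        spec$product_name, pts[p_i], 0,
                        sprintf("INJ-%s-%02d", spec$concern_id, p_i))
    if (!is.null(rec)) chunks[[length(chunks) + 1L]] <- rec
  }
  if (length(chunks)) {
    extra <- validate_reports(do.call(rbind, chunks), hierarchy)
    records <- rbind(as.data.frame(records), as.data.frame(extra))
    class(records) <- c("uif_reports", "data.frame")
  }
  list(records = records, concern = concern)
}

#' Simulate a full scenario
#'
#' Background plus every injected episode, returning the report table and
#' the matching concern register.
#'
#' @param scenario a [sim_scenario()].
#' @param hierarchy a `term_hierarchy`.
#' @return list with `reports` (`uif_reports`), `concerns`
#'   (`uif_concerns`), and `scenario`.
#' @export
simulate_scenario <- function(scenario, hierarchy) {
  records <- simulate_background(scenario, hierarchy)
  concern_rows <- list()
  for (spec in scenario$injections) {
    res <- inject_concern(records, spec, hierarchy, scenario)
    records <- res$records
    concern_rows[[length(concern_rows) + 1L]] <- res$concern
  }
  concerns <- if (length(concern_rows)) {
    validate_concerns(do.call(rbind, concern_rows), hierarchy)
  } else {
    structure(data.frame(concern_id = character(), substance = character(),
                         product_names = character(),
                         index_date = as.Date(character()),
                         concern_type = character(),
                         grouping_level = character(),
                         grouping_id = character()),
              class = c("uif_concerns", "data.frame"))
  }
  list(reports = records, concerns = concerns, scenario = scenario)
}
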