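# Monthly count series per drug-event combination. Counting unit: one
# distinct (case, drug, PT) triple, assigned to the calendar month of the
# receive date. Missing months are explicit zeros so that the null-history
# rule is well defined.

#' Aggregate reports into monthly count series
#'
#' Turns a validated report table into one monthly count series per observed
#' drug-event combination, under the stratification and pooling set by the
#' configuration. The counting unit is a distinct (case, drug, PT) triple;
#' a case reporting several PTs of one grouping therefore contributes one
#' unit per PT, which keeps pooled series equal to the sum of their PT-level
#' series. Months with no reports appear as explicit zero counts across the
#' requested span.
#'
#' @param reports a `uif_reports` table (see [load_reports()]).
#' @param config a [screen_config()].
#' @param hierarchy a `term_hierarchy`.
#' @param span length-2 character vector `c(first_month, last_month)` of
#'   `"YYYY-MM"` keys; must cover at least `window_months + 1` months.
#'
#' @return data.frame of class `uif_counts` in long format with columns
#'   `drug_level, drug_id, event_level, event_id, month, count`, sorted by
#'   drug, event, month; attribute `n_units` holds the number of counted
#'   units in the span.
#' @export
monthly_counts <- function(reports, config, hierarchy, span) {
  stopifnot(inherits(config, "screen_config"),
            inherits(hierarchy, "term_hierarchy"))
  if (length(span) != 2L) stop("span must be c(first_month, last_month)",
                               call. = FALSE)
  months <- month_seq(span[1L], span[2L])
  if (length(months) < config$window_months + 1L) {
    stop("span covers ", length(months), " month(s); need at least ",
         config$window_months + 1L, call. = FALSE)
  }
  df <- as.data.frame(reports)
  df <- df[df$module == "post_marketing", , drop = FALSE]
  if (!config$include_literature) df <- df[!df$literature, , drop = FALSE]
  if (config$restrict_ime_dme) {
    serious <- hierarchy$pt$pt[hierarchy$pt$ime | hierarchy$pt$dme]
    df <- df[df$event_pt %in% serious, , drop = FALSE]
  }
  if (config$drug_level == "product") {
    df <- df[!is.na(df$product_name), , drop = FALSE]
    df$drug_id <- df$product_name
  } else {
    df$drug_id <- df$substance
  }
  # one unit per distinct (case, drug, PT); keep the earliest receive month
  df <- df[order(df$receive_date), , drop = FALSE]
  df <- df[!duplicated(df[c("case_id", "drug_id", "event_pt")]), , drop = FALSE]
  df$month <- as_month(df$receive_date)
  df <- df[df$month %in% months, , drop = FALSE]
  n_units <- nrow(df)

  if (config$event_level == "pt") {
    df$event_id <- df$event_pt
  } else if (config$event_level == "pooled_all") {
    df$event_id <- "ALL"
  } else {
    df <- switch(config$grouping_level,
      hlt = transform(df, event_id = hierarchy$pt$hlt[
        match(df$event_pt, hierarchy$pt$pt)]),
      hlgt = transform(df, event_id = hierarchy$pt$hlgt[
        match(df$event_pt, hierarchy$pt$pt)]),
      smq = {
        m <- merge(df, hierarchy$smq[c("smq_id", "pt")],
                   by.x = "event_pt", by.y = "pt")
        m$event_id <- m$smq_id
        m
      })
  }
  event_level <- config$event_level
  if (event_level == "grouping") {
    event_level <- config$grouping_level
  }
  if (nrow(df) == 0L) {
    out <- data.frame(drug_level = character(), drug_id = character(),
                      event_level = character(), event_id = character(),
                      month = character(), count = integer())
  } else {
    tallied <- stats::aggregate(
      list(count = rep(1L, nrow(df))),
      by = list(drug_id = df$drug_id, event_id = df$event_id,
                month = df$month),
      FUN = sum)
    pairs <- unique(tallied[c("drug_id", "event_id")])
    grid <- merge(pairs, data.frame(month = months))
    out <- merge(grid, tallied,
                 by = c("drug_id", "event_id", "month"), all.x = TRUE)
    out$count[is.na(out$count)] <- 0L
    out$count <- as.integer(out$count)
    out$drug_level <- config$drug_level
    out$event_level <- event_level
    out <- out[c("drug_level", "drug_id", "event_level", "event_id",
                 "month", "count")]
    out <- out[order(out$drug_id, out$event_id, out$month), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "span") <- c(months[1L], months[length(months)])
  attr(out, "n_units") <- n_units
  class(out) <- c("uif_counts", "data.frame")
  out
}

#' Slice one series at a monitored month
#'
#' Extracts the history window and the monitored count from one
#' drug-event count series.
#'
#' @param series the rows of a `uif_counts` table for a single drug-event
#'   combination (columns `month`, `count`), or any data.frame with those
#'   columns.
#' @param t0 the monitored month (`"YYYY-MM"`).
#' @param window number of preceding months to return as history.
#'
#' @return list with `history` (integer vector of length `window`, in time
#'   order ending the month before `t0`) and `y0` (count at `t0`).
#' @export
slice_for_month <- function(series, t0, window) {
  series <- as.data.frame(series)
  stopifnot(all(c("month", "count") %in% names(series)))
  if (!is.null(series[["drug_id"]]) &&
      nrow(unique(series[c("drug_id", "event_id")])) > 1L) {
    stop("series contains more than one drug-event combination", call. = FALSE)
  }
  window <- as.integer(window)
  needed <- month_seq(month_add(t0, -window), t0)
  pos <- match(needed, series$month)
  if (anyNA(pos)) {
    stop("series does not cover month(s): ",
         paste(needed[is.na(pos)], collapse = ", "), call. = FALSE)
  }
  counts <- as.integer(series$count[pos])
  list(history = counts[seq_len(window)], y0 = counts[window + 1L])
}

#' @rdname monthly_counts
#' @param counts a `uif_counts` table.
#' @param path CSV destination / source.
#' @export
write_counts <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname monthly_counts
#' @export
read_counts <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug_level", "drug_id", "event_level", "event_id", "month",
            "count")
  if (!all(need %in% names(out))) {
    stop("counts table lacks required column(s): ",
         paste(setdiff(need, names(out)), collapse = ", "), call. = FALSE)
  }
  out$month <- as_month(out$month)
  out$count <- as.integer(out$count)
  class(out) <- c("uif_counts", "data.frame")
  out
}
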