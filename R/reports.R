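# Individual case safety report (ICSR) tables. One row is one
# report-drug-event observation: the atom of all counting. Study-module
# reports are dropped at load time and never reach the counting code.

REPORT_COLUMNS <- c("case_id", "receive_date", "substance", "product_name",
                    "event_pt", "literature", "module")

#' Load and validate a report table
#'
#' Reads a CSV of individual case safety reports (one row per
#' report-drug-event triple) and validates it against a term hierarchy.
#' Rows from the study module are excluded — routine screening uses
#' post-marketing spontaneous reports only — and the number excluded is
#' recorded in the attached load report.
#'
#' @param path CSV file with columns
#'   `case_id,receive_date,substance,product_name,event_pt,literature,module`.
#'   `receive_date` is ISO-8601 (`YYYY-MM-DD`); `module` is
#'   `post_marketing` or `study`; `product_name` may be empty.
#' @param hierarchy a `term_hierarchy`; every `event_pt` must be a known PT.
#'
#' @return A data.frame of class `uif_reports` with the columns above
#'   (`receive_date` as `Date`, labels normalised) plus an attribute
#'   `load_report`: a list with `n_loaded`, `n_excluded_study`.
#'
#' @details Validation failures are errors naming the offending rows:
#'   unparseable dates, unknown `module` values, and PTs absent from the
#'   hierarchy. A missing required column is a format error.
#' @export
load_reports <- function(path, hierarchy) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  validate_reports(raw, hierarchy)
}

#' @rdname load_reports
#' @param reports a data.frame with the report columns (as from a simulator
#'   or an external extract) to validate without a file round trip.
#' @export
validate_reports <- function(reports, hierarchy) {
  stopifnot(inherits(hierarchy, "term_hierarchy"))
  reports <- as.data.frame(reports)
  missing_cols <- setdiff(REPORT_COLUMNS, names(reports))
  if (length(missing_cols)) {
    stop("report table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  reports <- reports[REPORT_COLUMNS]
  if (nrow(reports) == 0L) {
    out <- reports
    out$receive_date <- as.Date(character())
    out$literature <- logical()
    attr(out, "load_report") <- list(n_loaded = 0L, n_excluded_study = 0L)
    class(out) <- c("uif_reports", "data.frame")
    return(out)
  }
  reports$case_id <- as.character(reports$case_id)
  dates <- as.Date(as.character(reports$receive_date), format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  if (length(bad)) {
    stop("unparseable receive_date in row(s): ",
         paste(utils::head(bad, 20L), collapse = ", "), call. = FALSE)
  }
  reports$receive_date <- dates
  reports$substance <- norm_label(reports$substance)
  prod <- norm_label(reports$product_name)
  prod[is.na(prod) | prod == ""] <- NA_character_
  reports$product_name <- prod
  reports$event_pt <- norm_label(reports$event_pt)
  unknown <- which(!reports$event_pt %in% all_pts(hierarchy))
  if (length(unknown)) {
    stop("event_pt not in hierarchy in row(s): ",
         paste(utils::head(unknown, 20L), collapse = ", "),
         " (PT ", paste(unique(reports$event_pt[utils::head(unknown, 5L)]),
                        collapse = ", "), ")", call. = FALSE)
  }
  lit <- reports$literature
  if (is.character(lit)) lit <- tolower(trimws(lit)) %in% c("true", "t", "1", "yes")
  reports$literature <- as.logical(lit)
  module <- norm_label(reports$module)
  bad_mod <- which(!module %in% c("post_marketing", "study"))
  if (length(bad_mod)) {
    stop("unknown module value in row(s): ",
         paste(utils::head(bad_mod, 20L), collapse = ", "), call. = FALSE)
  }
  reports$module <- module
  keep <- module == "post_marketing"
  out <- reports[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "load_report") <- list(n_loaded = sum(keep),
                                   n_excluded_study = sum(!keep))
  class(out) <- c("uif_reports", "data.frame")
  out
}

#' @rdname load_reports
#' @export
write_reports <- function(reports, path) {
  out <- as.data.frame(reports)[REPORT_COLUMNS]
  out$receive_date <- format(out$receive_date, "%Y-%m-%d")
  out$literature <- ifelse(out$literature, "true", "false")
  out$product_name[is.na(out$product_name)] <- ""
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Load a historical-concern register
#'
#' A concern is a historical safety issue (quality defect, medication error,
#' or abuse/misuse) with the date it was first recorded in the issue-tracking
#' system (the index date) and the grouping terms whose member PTs constitute
#' its case definition. The register is the ground truth against which
#' detections are labelled true/false positive.
#'
#' @param path CSV with columns `concern_id,substance,product_names,
#'   index_date,concern_type,grouping_level,grouping_id` — one row per
#'   grouping term; `product_names` is `;`-separated and may be empty
#'   (substance-wide scope, e.g. abuse/misuse concerns); `concern_type` is
#'   `QD`, `ME` or `AM`.
#' @param hierarchy a `term_hierarchy` used to check that every concern's
#'   grouping terms resolve to a non-empty PT set.
#'
#' @return data.frame of class `uif_concerns`, one row per
#'   (concern, grouping term), with `index_date` as `Date`.
#' @export
load_concerns <- function(path, hierarchy) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  validate_concerns(raw, hierarchy)
}

#' @rdname load_concerns
#' @param concerns data.frame with the concern columns.
#' @export
validate_concerns <- function(concerns, hierarchy) {
  stopifnot(inherits(hierarchy, "term_hierarchy"))
  concerns <- as.data.frame(concerns)
  need <- c("concern_id", "substance", "product_names", "index_date",
            "concern_type", "grouping_level", "grouping_id")
  missing_cols <- setdiff(need, names(concerns))
  if (length(missing_cols)) {
    stop("concern table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  concerns <- concerns[need]
  concerns$concern_id <- as.character(concerns$concern_id)
  concerns$substance <- norm_label(concerns$substance)
  dates <- as.Date(as.character(concerns$index_date), format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop("unparseable index_date for concern(s): ",
         paste(unique(concerns$concern_id[is.na(dates)]), collapse = ", "),
         call. = FALSE)
  }
  concerns$index_date <- dates
  ctype <- toupper(trimws(concerns$concern_type))
  bad <- setdiff(unique(ctype), c("QD", "ME", "AM"))
  if (length(bad)) {
    stop("unknown concern_type value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  concerns$concern_type <- ctype
  concerns$grouping_level <- toupper(trimws(concerns$grouping_level))
  concerns$grouping_id <- norm_label(concerns$grouping_id)
  pn <- as.character(concerns$product_names)
  pn[is.na(pn)] <- ""
  concerns$product_names <- pn
  # per-concern consistency + resolvable, non-empty case definition
  for (id in unique(concerns$concern_id)) {
    rows <- concerns[concerns$concern_id == id, , drop = FALSE]
    if (length(unique(rows$index_date)) != 1L ||
        length(unique(rows$concern_type)) != 1L ||
        length(unique(rows$substance)) != 1L) {
      stop("concern ", id, " has inconsistent substance/date/type across rows",
           call. = FALSE)
    }
    pts <- expand_grouping(hierarchy,
                           data.frame(level = rows$grouping_level,
                                      id = rows$grouping_id))
    if (length(pts) == 0L) {
      stop("concern ", id, " expands to an empty PT set", call. = FALSE)
    }
  }
  class(concerns) <- c("uif_concerns", "data.frame")
  concerns
}

#' @rdname load_concerns
#' @export
write_concerns <- function(concerns, path) {
  out <- as.data.frame(concerns)
  out$index_date <- format(out$index_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

concern_products <- function(product_names) {
  p <- norm_label(strsplit(product_names, ";", fixed = TRUE)[[1]])
  p[p != ""]
}

#' Case-definition PT set of one concern
#'
#' Expands a concern's grouping terms to member PTs, optionally restricted
#' to IME/DME terms. For quality-defect (QD) concerns, product-quality-issue
#' PTs are always excluded from the case definition: a quality defect must be
#' detectable from the reported harms alone, since explicit quality-issue
#' reports trigger regulatory action through other channels.
#'
#' @param hierarchy a `term_hierarchy`.
#' @param concern_rows the rows of a `uif_concerns` table for one concern id.
#' @param restrict_ime_dme passed to [expand_grouping()].
#' @return character vector of PT ids.
#' @export
expand_concern <- function(hierarchy, concern_rows, restrict_ime_dme = TRUE) {
  stopifnot(length(unique(concern_rows$concern_id)) == 1L)
  pts <- expand_grouping(hierarchy,
                         data.frame(level = concern_rows$grouping_level,
                                    id = concern_rows$grouping_id),
                         restrict_ime_dme = restrict_ime_dme)
  if (concern_rows$concern_type[1L] == "QD") {
    quality <- hierarchy$pt$pt[hierarchy$pt$quality_issue]
    pts <- setdiff(pts, quality)
  }
  pts
}
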