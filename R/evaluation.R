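# Labelling detections against the historical-concern register and the
# positive predictive value summary. A detection is a true positive when a
# concern covers its drug, its event falls in the concern's case
# definition, and the detection month lies within one year before to six
# months after the concern's index date (month granularity, both ends
# inclusive). Detections on drugs outside the register are out of the
# evaluation universe and excluded from the PPV denominator.

concern_window <- function(index_date, t0) {
  idx <- month_index(as_month(index_date))
  m <- month_index(t0)
  m >= idx - 12L & m <= idx + 6L
}

detection_pts <- function(det_event_level, det_event_id, hierarchy) {
  lvl <- toupper(det_event_level)
  if (lvl == "PT") return(det_event_id)
  if (det_event_id == "ALL") return(all_pts(hierarchy))
  expand_grouping(hierarchy, data.frame(level = lvl, id = det_event_id))
}

#' Label detections against the concern register
#'
#' Assigns each detection exactly one label: `true_positive` when some
#' concern matches its drug scope, case definition and time window;
#' `false_positive` when its drug is covered by the register but no concern
#' matches; `out_of_universe` when no concern covers its drug at all (such
#' detections cannot be adjudicated and are excluded from the PPV
#' denominator).
#'
#' @param detections a `uif_detections` table (see [screen()]).
#' @param concerns a `uif_concerns` register (see [load_concerns()]).
#' @param hierarchy a `term_hierarchy`.
#' @param config the [screen_config()] the detections were produced under;
#'   its `drug_level` decides substance vs product scope and its
#'   `restrict_ime_dme` is applied to the concern case definitions.
#'
#' @return data.frame of class `uif_labeled`: the detection columns plus
#'   `label`, `concern_id` and `concern_type` (`NA` unless true positive).
#'
#' @details Drug scope at substance level is the concern's substance; at
#'   product level it is the concern's listed product names. Abuse/misuse
#'   concerns are substance-wide and define no product scope, so they are
#'   skipped in product-level screens. Event matching compares the
#'   detection's PT (or, for grouped/pooled screens, the PT expansion of
#'   its event key) with the concern's case definition from
#'   [expand_concern()]. The time window is month-granular and inclusive:
#'   `index month - 12` to `index month + 6`.
#' @export
label_detections <- function(detections, concerns, hierarchy,
                             config = screen_config()) {
  stopifnot(inherits(hierarchy, "term_hierarchy"),
            inherits(config, "screen_config"))
  detections <- as.data.frame(detections)
  concerns <- as.data.frame(concerns)
  ids <- sort(unique(concerns$concern_id))
  info <- lapply(ids, function(id) {
    rows <- concerns[concerns$concern_id == id, , drop = FALSE]
    scope <- if (config$drug_level == "substance") {
      rows$substance[1L]
    } else if (rows$concern_type[1L] == "AM") {
      character()  # abuse/misuse is not product specific
    } else {
      concern_products(rows$product_names[1L])
    }
    list(id = id, type = rows$concern_type[1L], scope = scope,
         index_date = rows$index_date[1L],
         pts = expand_concern(hierarchy, rows,
                              restrict_ime_dme = config$restrict_ime_dme))
  })
  in_scope_drugs <- unique(unlist(lapply(info, `[[`, "scope")))

  n <- nrow(detections)
  label <- character(n)
  concern_id <- rep(NA_character_, n)
  concern_type <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    drug <- detections$drug_id[i]
    if (!drug %in% in_scope_drugs) {
      label[i] <- "out_of_universe"
      next
    }
    det_pts <- detection_pts(detections$event_level[i],
                             detections$event_id[i], hierarchy)
    hit <- NULL
    for (ci in info) {
      if (!drug %in% ci$scope) next
      if (!concern_window(ci$index_date, detections$month[i])) next
      if (!any(det_pts %in% ci$pts)) next
      hit <- ci
      break
    }
    if (is.null(hit)) {
      label[i] <- "false_positive"
    } else {
      label[i] <- "true_positive"
      concern_id[i] <- hit$id
      concern_type[i] <- hit$type
    }
  }
  out <- cbind(detections,
               data.frame(label = label, concern_id = concern_id,
                          concern_type = concern_type,
                          stringsAsFactors = FALSE))
  class(out) <- c("uif_labeled", "data.frame")
  out
}

ppv_ratio <- function(tp, fp) {
  if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
}

#' Positive predictive value summary
#'
#' The PPV is the share of true positives among all in-universe detections
#' — detections on drugs covered by the concern register. It is reported
#' overall and separately for the regression and heuristic branches, as a
#' pooled ratio. A branch with no in-universe detections has an undefined
#' PPV, reported as `NA` (never 0/0 = 0).
#'
#' @param labeled a `uif_labeled` table from [label_detections()].
#' @return list of class `uif_eval`: `ppv_overall`, `ppv_regression`,
#'   `ppv_heuristic` (proportions in `[0, 1]` or `NA`), `detected_concerns`
#'   (ids with at least one true positive), `detections_by_type`
#'   (true-positive counts per concern type QD/ME/AM), `n_true_positive`,
#'   `n_false_positive`, `n_out_of_universe`, and `first_detection_month`
#'   (named by concern id).
#' @export
compute_ppv <- function(labeled) {
  labeled <- as.data.frame(labeled)
  in_univ <- labeled[labeled$label != "out_of_universe", , drop = FALSE]
  tp <- in_univ$label == "true_positive"
  branch_ppv <- function(b) {
    sub <- in_univ$branch == b
    ppv_ratio(sum(tp & sub), sum(!tp & sub))
  }
  tps <- in_univ[tp, , drop = FALSE]
  first_month <- if (nrow(tps)) {
    vapply(split(tps$month, tps$concern_id), min, character(1L))
  } else {
    stats::setNames(character(), character())
  }
  by_type <- table(factor(tps$concern_type, levels = c("QD", "ME", "AM")))
  structure(list(
    ppv_overall = ppv_ratio(sum(tp), sum(!tp)),
    ppv_regression = branch_ppv("regression"),
    ppv_heuristic = branch_ppv("heuristic"),
    detected_concerns = sort(unique(tps$concern_id)),
    detections_by_type = stats::setNames(as.integer(by_type),
                                         names(by_type)),
    n_true_positive = sum(tp),
    n_false_positive = sum(!tp),
    n_out_of_universe = nrow(labeled) - nrow(in_univ),
    first_detection_month = first_month
  ), class = "uif_eval")
}

#' @export
print.uif_eval <- function(x, ...) {
  fmt <- function(p) if (is.na(p)) "undefined" else sprintf("%.2f%%", 100 * p)
  cat("UIF evaluation\n",
      "  PPV overall:    ", fmt(x$ppv_overall), "\n",
      "  PPV regression: ", fmt(x$ppv_regression), "\n",
      "  PPV heuristic:  ", fmt(x$ppv_heuristic), "\n",
      "  true positives: ", x$n_true_positive,
      " | false positives: ", x$n_false_positive,
      " | out of universe: ", x$n_out_of_universe, "\n",
      "  concerns detected: ", length(x$detected_concerns),
      " (QD ", x$detections_by_type[["QD"]],
      ", ME ", x$detections_by_type[["ME"]],
      ", AM ", x$detections_by_type[["AM"]], " true positives)\n", sep = "")
  invisible(x)
}

#' @rdname compute_ppv
#' @param eval_report a `uif_eval` object.
#' @param path JSON destination.
#' @export
write_evaluation <- function(eval_report, path) {
  out <- unclass(eval_report)
  out$detections_by_type <- as.list(out$detections_by_type)
  out$first_detection_month <- as.list(out$first_detection_month)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
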