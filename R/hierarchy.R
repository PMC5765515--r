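# Term hierarchy: a simplified, single-axial MedDRA-style dictionary.
# Each PT has exactly one HLT -> HLGT -> SOC path; SMQs are curated PT sets
# with broad/narrow scope; IME/DME flags mark clinically serious terms and
# quality_issue marks product-quality terms (excluded from quality-defect
# case definitions).

norm_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("\\s+", " ", x)
}

#' Construct and validate a term hierarchy
#'
#' Builds the simplified MedDRA-style dictionary used by all counting and
#' evaluation code. The hierarchy is single-axial: each preferred term (PT)
#' has exactly one HLT, HLGT and SOC; multi-axiality is deliberately out of
#' scope since the screening algorithm only needs PT-to-grouping membership.
#'
#' @param pt_table data.frame with columns `pt`, `hlt`, `hlgt`, `soc` and
#'   logical `ime`, `dme`, `quality_issue`.
#' @param smq_table data.frame with columns `smq_id`, `pt`, `scope`
#'   (`"broad"` or `"narrow"`). May have zero rows.
#'
#' @return An object of class `term_hierarchy`: a list with elements `pt`
#'   (the PT table, labels normalised) and `smq`.
#'
#' @details Validation enforces: unique PT ids; no missing parents; a single
#'   parent per HLT and HLGT (dangling or ambiguous parents are integrity
#'   errors); no term id reused at two levels (which also rules out cycles in
#'   the level maps); SMQ members must be known PTs.
#' @export
term_hierarchy <- function(pt_table, smq_table = NULL) {
  need <- c("pt", "hlt", "hlgt", "soc", "ime", "dme", "quality_issue")
  missing_cols <- setdiff(need, names(pt_table))
  if (length(missing_cols)) {
    stop("pt table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  pt_table <- as.data.frame(pt_table)[need]
  for (col in c("pt", "hlt", "hlgt", "soc")) {
    pt_table[[col]] <- norm_label(pt_table[[col]])
    if (anyNA(pt_table[[col]]) || any(pt_table[[col]] == "")) {
      bad <- pt_table$pt[is.na(pt_table[[col]]) | pt_table[[col]] == ""]
      stop("hierarchy integrity error: missing ", col, " for PT(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
  }
  for (col in c("ime", "dme", "quality_issue")) {
    pt_table[[col]] <- as.logical(pt_table[[col]])
    if (anyNA(pt_table[[col]])) {
      stop("hierarchy integrity error: non-logical ", col, " flag", call. = FALSE)
    }
  }
  if (anyDuplicated(pt_table$pt)) {
    stop("hierarchy integrity error: duplicated PT id(s): ",
         paste(unique(pt_table$pt[duplicated(pt_table$pt)]), collapse = ", "),
         call. = FALSE)
  }
  # single-axial nesting: one parent per term at every level
  one_parent <- function(child, parent, what) {
    m <- unique(data.frame(child = child, parent = parent))
    dup <- unique(m$child[duplicated(m$child)])
    if (length(dup)) {
      stop("hierarchy integrity error: ", what, " with multiple parents: ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
  }
  one_parent(pt_table$hlt, pt_table$hlgt, "HLT")
  one_parent(pt_table$hlgt, pt_table$soc, "HLGT")
  # a term id reused across levels would make the level maps cyclic/ambiguous
  lvl <- list(PT = unique(pt_table$pt), HLT = unique(pt_table$hlt),
              HLGT = unique(pt_table$hlgt), SOC = unique(pt_table$soc))
  for (i in seq_along(lvl)) {
    for (j in seq_along(lvl)) {
      if (i < j) {
        shared <- intersect(lvl[[i]], lvl[[j]])
        if (length(shared)) {
          stop("hierarchy integrity error: term id(s) used at both ",
               names(lvl)[i], " and ", names(lvl)[j], " level: ",
               paste(shared, collapse = ", "), call. = FALSE)
        }
      }
    }
  }
  if (is.null(smq_table)) {
    smq_table <- data.frame(smq_id = character(), pt = character(),
                            scope = character())
  }
  need_smq <- c("smq_id", "pt", "scope")
  if (!all(need_smq %in% names(smq_table))) {
    stop("smq table lacks column(s): ",
         paste(setdiff(need_smq, names(smq_table)), collapse = ", "),
         call. = FALSE)
  }
  smq_table <- as.data.frame(smq_table)[need_smq]
  smq_table$smq_id <- norm_label(smq_table$smq_id)
  smq_table$pt <- norm_label(smq_table$pt)
  smq_table$scope <- norm_label(smq_table$scope)
  unknown <- setdiff(smq_table$pt, pt_table$pt)
  if (length(unknown)) {
    stop("hierarchy integrity error: SMQ member PT(s) not in PT table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_scope <- setdiff(unique(smq_table$scope), c("broad", "narrow"))
  if (length(bad_scope)) {
    stop("hierarchy integrity error: unknown SMQ scope(s): ",
         paste(bad_scope, collapse = ", "), call. = FALSE)
  }
  structure(list(pt = pt_table, smq = smq_table), class = "term_hierarchy")
}

#' @export
print.term_hierarchy <- function(x, ...) {
  cat("term_hierarchy:", nrow(x$pt), "PTs,",
      length(unique(x$pt$hlt)), "HLTs,",
      length(unique(x$pt$hlgt)), "HLGTs,",
      length(unique(x$pt$soc)), "SOCs,",
      length(unique(x$smq$smq_id)), "SMQs;",
      sum(x$pt$ime), "IME,", sum(x$pt$dme), "DME,",
      sum(x$pt$quality_issue), "quality-issue PTs\n")
  invisible(x)
}

#' Read / write a term hierarchy bundle
#'
#' The on-disk form is a directory with two CSV files: `pt.csv`
#' (`pt,hlt,hlgt,soc,ime,dme,quality_issue`) and `smq.csv`
#' (`smq_id,pt,scope`). `smq.csv` may be absent (no SMQs).
#'
#' @param path directory containing the bundle.
#' @param h a `term_hierarchy`.
#' @return `load_hierarchy()` returns a validated `term_hierarchy`;
#'   `write_hierarchy()` returns `path` invisibly.
#' @export
load_hierarchy <- function(path) {
  pt_file <- file.path(path, "pt.csv")
  if (!file.exists(pt_file)) {
    stop("hierarchy bundle lacks pt.csv under ", path, call. = FALSE)
  }
  pt_table <- utils::read.csv(pt_file, stringsAsFactors = FALSE)
  smq_file <- file.path(path, "smq.csv")
  smq_table <- if (file.exists(smq_file)) {
    utils::read.csv(smq_file, stringsAsFactors = FALSE)
  } else NULL
  term_hierarchy(pt_table, smq_table)
}

#' @rdname load_hierarchy
#' @export
write_hierarchy <- function(h, path) {
  stopifnot(inherits(h, "term_hierarchy"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(h$pt, file.path(path, "pt.csv"), row.names = FALSE)
  utils::write.csv(h$smq, file.path(path, "smq.csv"), row.names = FALSE)
  invisible(path)
}

all_pts <- function(h) h$pt$pt

#' Expand grouping terms to their member PTs
#'
#' A safety concern is defined at a higher level of the hierarchy (HLT, HLGT
#' or SMQ, or the special level `ALL`): an increase in any PT grouped under
#' one of its grouping terms is indicative of the concern. This returns the
#' union of member PTs over the listed grouping terms.
#'
#' @param h a `term_hierarchy`.
#' @param terms data.frame with columns `level` (`"HLT"`, `"HLGT"`, `"SMQ"`,
#'   `"SOC"` or `"ALL"`) and `id` (grouping-term id; ignored for `ALL`).
#' @param restrict_ime_dme if `TRUE`, intersect the result with the set of
#'   IME or DME PTs (only clinically serious terms are screened).
#' @param smq_scope `"broad"` (all members) or `"narrow"` for SMQ terms.
#'
#' @return character vector of PT ids (possibly empty), sorted.
#' @export
expand_grouping <- function(h, terms, restrict_ime_dme = FALSE,
                            smq_scope = c("broad", "narrow")) {
  stopifnot(inherits(h, "term_hierarchy"))
  smq_scope <- match.arg(smq_scope)
  if (is.null(terms) || NROW(terms) == 0L) return(character())
  terms <- as.data.frame(terms)
  if (!all(c("level", "id") %in% names(terms))) {
    stop("terms must have columns level and id", call. = FALSE)
  }
  level <- toupper(trimws(terms$level))
  id <- norm_label(terms$id)
  out <- character()
  for (k in seq_along(level)) {
    members <- switch(level[k],
      HLT = h$pt$pt[h$pt$hlt == id[k]],
      HLGT = h$pt$pt[h$pt$hlgt == id[k]],
      SOC = h$pt$pt[h$pt$soc == id[k]],
      SMQ = {
        if (!id[k] %in% h$smq$smq_id) {
          stop("unknown SMQ grouping id: ", id[k], call. = FALSE)
        }
        rows <- h$smq$smq_id == id[k] &
          (smq_scope == "broad" | h$smq$scope == "narrow")
        h$smq$pt[rows]
      },
      ALL = all_pts(h),
      stop("unknown grouping level: ", level[k], call. = FALSE)
    )
    if (level[k] %in% c("HLT", "HLGT", "SOC") && length(members) == 0L) {
      stop("unknown ", level[k], " grouping id: ", id[k], call. = FALSE)
    }
    out <- union(out, members)
  }
  if (restrict_ime_dme) {
    serious <- h$pt$pt[h$pt$ime | h$pt$dme]
    out <- intersect(out, serious)
  }
  sort(out)
}
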