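#' Declare which columns play which role in the analysis
#'
#' Maps column names of a cohort CSV onto the roles the estimator needs:
#' a continuous exposure score, an optional pre-assigned exposure category,
#' exactly three mediators (ordered), one continuous outcome, and one or more
#' confounders. The defaults match the columns written by
#' [generate_cohort()].
#'
#' @param exposure_score name of the continuous polygenic-score column.
#' @param exposure_category name of the 5-level category column (may be
#'   absent from the file; it is then assigned with
#'   [assign_exposure_quintiles()]).
#' @param mediators character vector of exactly three mediator columns, in a
#'   fixed order.
#' @param outcome name of the continuous outcome column (kg/m^2).
#' @param confounders character vector (length >= 1) of confounder columns.
#'   Binary confounders must be coded 0/1.
#' @param id name of the unique row-identifier column; synthesised if the
#'   file lacks it.
#' @return an object of class `variable_roles`.
#' @export
variable_roles <- function(exposure_score = "pgs",
                           exposure_category = "exposure_category",
                           mediators = c("med_emotional", "med_restriction",
                                         "med_pressure"),
                           outcome = "outcome_bmi",
                           confounders = c("sex", "maternal_education",
                                           "maternal_bmi"),
                           id = "id") {
  if (length(mediators) != 3L) {
    stop("exactly three mediator columns are required", call. = FALSE)
  }
  if (length(outcome) != 1L) stop("exactly one outcome column", call. = FALSE)
  if (length(confounders) < 1L) {
    stop("at least one confounder column is required", call. = FALSE)
  }
  structure(list(exposure_score = exposure_score,
                 exposure_category = exposure_category,
                 mediators = mediators, outcome = outcome,
                 confounders = confounders, id = id),
            class = "variable_roles")
}

## Analysis columns whose completeness the estimator requires.
analysis_columns <- function(roles) {
  c(roles$exposure_score, roles$mediators, roles$outcome, roles$confounders)
}

cohort_roles <- function(table) attr(table, "roles") %||% variable_roles()

#' Construct a cohort table from a data frame
#'
#' Validates column presence, numeric types, id uniqueness and (when present)
#' that the exposure category only takes values 1..5.
#'
#' @param df a data frame, one row per individual.
#' @param roles a [variable_roles()] object.
#' @return a `cohort_table` (a data.frame carrying its roles as an attribute).
#' @export
cohort_table <- function(df, roles = variable_roles()) {
  needed <- analysis_columns(roles)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!roles$id %in% names(df)) df[[roles$id]] <- seq_len(nrow(df))
  ids <- df[[roles$id]]
  if (anyDuplicated(ids)) stop("ids are not unique", call. = FALSE)
  for (col in needed) {
    if (!is.numeric(df[[col]])) {
      stop("column '", col, "' is not numeric", call. = FALSE)
    }
  }
  cat_col <- roles$exposure_category
  if (cat_col %in% names(df)) {
    cats <- df[[cat_col]]
    ok <- is.na(cats) | (cats %in% 1:5)
    if (!all(ok)) {
      stop("exposure_category must take values in 1..5", call. = FALSE)
    }
  }
  structure(df, roles = roles, class = c("cohort_table", "data.frame"))
}

#' Load a cohort table from CSV
#'
#' Reads an RFC-4180 CSV with a header row, checks that every column named in
#' `roles` exists, and that analysis columns parse as numbers ("NA" and empty
#' cells become missing values, to be removed later by [complete_cases()]).
#'
#' @param path path to the CSV file.
#' @param roles a [variable_roles()] object.
#' @param quiet suppress the rows-loaded message.
#' @return a `cohort_table`, row order as in the file.
#' @export
load_cohort <- function(path, roles = variable_roles(), quiet = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- analysis_columns(roles)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  check_cols <- intersect(c(needed, roles$exposure_category), names(raw))
  for (col in check_cols) {
    vals <- raw[[col]]
    if (is.numeric(vals) || is.logical(vals)) next
    chr <- trimws(as.character(vals))
    num <- suppressWarnings(as.numeric(chr))
    bad <- which(!is.na(chr) & chr != "" & chr != "NA" & is.na(num))
    if (length(bad) > 0) {
      stop(sprintf("cannot parse '%s' as a number (column '%s', row %d)",
                   chr[bad[1]], col, bad[1]), call. = FALSE)
    }
    raw[[col]] <- num
  }
  tab <- cohort_table(raw, roles)
  if (!quiet) message(sprintf("loaded %d rows from %s", nrow(tab), path))
  tab
}

#' Write a cohort table to CSV
#'
#' @param table a `cohort_table`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Drop rows with any missing analysis value
#'
#' The completeness rule covers the exposure score, all three mediators, the
#' outcome and every confounder: rows with a missing confounder cannot enter
#' the fitted models, so they are excluded as well.
#'
#' @param table a `cohort_table`.
#' @param min_rows smallest admissible number of surviving rows; the full
#'   estimation pipeline requires 50.
#' @return the filtered `cohort_table`, with the number of removed rows in
#'   attribute `n_removed`. Idempotent.
#' @export
complete_cases <- function(table, min_rows = 1L) {
  roles <- cohort_roles(table)
  cols <- analysis_columns(roles)
  keep <- stats::complete.cases(as.data.frame(table)[, cols, drop = FALSE])
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) < min_rows) {
    stop(sprintf(
      "only %d complete rows remain (need at least %d): model fitting is infeasible",
      nrow(out), min_rows), call. = FALSE)
  }
  out <- cohort_table(out, roles)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Assign exposure categories as quintiles of the score distribution
#'
#' Categories 1 (lowest) to 5 (highest) by ascending rank of the exposure
#' score. Category `j` holds the ranks up to `ceiling(n * j / 5)`, so group
#' sizes differ by at most one; ties are broken by stable input order. Being
#' rank-based, the assignment is invariant to order-preserving transforms of
#' the score.
#'
#' @param table a `cohort_table` with a complete exposure-score column.
#' @return the table with its exposure-category column (re)filled.
#' @export
assign_exposure_quintiles <- function(table) {
  roles <- cohort_roles(table)
  pgs <- table[[roles$exposure_score]]
  if (anyNA(pgs)) {
    stop("exposure score has missing values; run complete_cases() first",
         call. = FALSE)
  }
  n <- length(pgs)
  if (n < 5) stop("need at least 5 rows to form quintiles", call. = FALSE)
  r <- rank(pgs, ties.method = "first")
  cuts <- ceiling(n * (1:4) / 5)
  cat <- findInterval(r, cuts + 0.5) + 1L
  out <- as.data.frame(table)
  out[[roles$exposure_category]] <- cat
  cohort_table(out, roles)
}

## Internal accessors -------------------------------------------------------

conf_matrix <- function(table) {
  roles <- cohort_roles(table)
  as.matrix(as.data.frame(table)[, roles$confounders, drop = FALSE])
}

med_matrix <- function(table) {
  roles <- cohort_roles(table)
  as.matrix(as.data.frame(table)[, roles$mediators, drop = FALSE])
}

category_vector <- function(table) {
  roles <- cohort_roles(table)
  cat <- table[[roles$exposure_category]]
  if (is.null(cat) || anyNA(cat)) {
    stop("exposure_category is not assigned; run assign_exposure_quintiles()",
         call. = FALSE)
  }
  as.integer(cat)
}

outcome_vector <- function(table) {
  roles <- cohort_roles(table)
  table[[roles$outcome]]
}
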