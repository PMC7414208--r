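#' 2x2 contingency table for a two-arm discrimination test
#'
#' The atomic analysis input.  The table is oriented once for the whole
#' package: the tap-water arm is the "positive" class (sensitivity) and the
#' filtered-water arm the "negative" class (specificity).
#'
#' @param a tap-arm participants replying "tap" (correct).
#' @param b tap-arm participants replying "filtered" (incorrect).
#' @param c filtered-arm participants replying "tap" (incorrect).
#' @param d filtered-arm participants replying "filtered" (correct).
#' @return An object of class `table2x2`: a list with elements `a`, `b`,
#'   `c`, `d` and derived arm sizes `n1 = a + b`, `n2 = c + d`, `n`.
#' @export
#' @examples
#' table2x2(106, 33, 110, 29)
table2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("table2x2 cells must be non-negative integers", call. = FALSE)
  n1 <- a + b
  n2 <- c + d
  ## an empty arm is representable (e.g. a one-record stratum); estimators
  ## require both arms non-empty and error there
  if (n1 + n2 < 1L) stop("table has no observations", call. = FALSE)
  structure(
    list(a = as.integer(a), b = as.integer(b),
         c = as.integer(c), d = as.integer(d),
         n1 = as.integer(n1), n2 = as.integer(n2),
         n = as.integer(n1 + n2)),
    class = "table2x2"
  )
}

#' @export
print.table2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), nrow = 2, byrow = TRUE,
              dimnames = list(response = c("tap", "filtered"),
                              arm = c("tap", "filtered")))
  cat("2x2 discrimination table (n =", x$n, ")\n")
  print(m)
  invisible(x)
}

#' @export
as.matrix.table2x2 <- function(x, ...) {
  matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
         dimnames = list(arm = c("tap", "filtered"),
                         response = c("tap", "filtered")))
}

is_table2x2 <- function(x) inherits(x, "table2x2")

#' Participant-level study dataset
#'
#' Wraps a data frame of participant records (one row per interview) with a
#' provenance label.  Columns: `participant_id`, `gender`, `position`,
#' `dispenser_last_month`, `fountain_before`, `arm`, `response`.
#' Correctness is never stored; it is derivable as `response == arm`, which
#' prevents internally inconsistent files.
#'
#' @param records data frame with the columns above.
#' @param provenance free-text label (e.g. `"simulated, seed=7"`).
#' @return An object of class `study_dataset` (a data frame).
#' @export
study_dataset <- function(records, provenance = "unspecified") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing <- setdiff(PARTICIPANT_COLUMNS, names(records))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  records <- records[PARTICIPANT_COLUMNS]
  for (col in PARTICIPANT_COLUMNS) records[[col]] <- as.character(records[[col]])
  levels <- c(COVARIATE_LEVELS, list(arm = ARM_LEVELS, response = ARM_LEVELS))
  for (col in names(levels)) {
    bad <- which(!records[[col]] %in% levels[[col]])
    if (length(bad))
      stop(sprintf("unknown %s label '%s' at row %d", col,
                   records[[col]][bad[1]], bad[1]), call. = FALSE)
  }
  dup <- anyDuplicated(records$participant_id)
  if (dup)
    stop("duplicate participant_id '", records$participant_id[dup],
         "' at row ", dup, call. = FALSE)
  structure(records, provenance = provenance,
            class = c("study_dataset", "data.frame"))
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("study_dataset:", nrow(x), "participants (",
      sum(x$arm == "tap"), "tap /", sum(x$arm == "filtered"), "filtered )\n")
  cat("provenance:", attr(x, "provenance"), "\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Read participant records from CSV
#'
#' One row per participant; lower-case label vocabulary.  Row order is
#' preserved.  Errors name the offending column or row.
#'
#' @param path path to a CSV file with header
#'   `participant_id, gender, position, dispenser_last_month,
#'   fountain_before, arm, response`.
#' @return A [study_dataset()] with provenance set to the file path.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  study_dataset(df, provenance = path)
}

#' Write participant records to CSV
#'
#' Inverse of [read_participants()]: a write followed by a read reproduces
#' the records exactly (order and labels).
#'
#' @param ds a [study_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(ds, path) {
  stopifnot(inherits(ds, "study_dataset"))
  utils::write.csv(as.data.frame(ds)[PARTICIPANT_COLUMNS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an aggregated 2x2 table as JSON
#'
#' The JSON schema is `{"a": int, "b": int, "c": int, "d": int}` with the
#' package's fixed orientation (see [table2x2()]).
#'
#' @param path JSON file path.
#' @return [read_table_json()] returns a [table2x2()];
#'   [write_table_json()] returns `path` invisibly.
#' @export
read_table_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("a", "b", "c", "d")
  if (!all(need %in% names(x)))
    stop("JSON table must have fields a, b, c, d", call. = FALSE)
  table2x2(x$a, x$b, x$c, x$d)
}

#' @param t a [table2x2()].
#' @rdname read_table_json
#' @export
write_table_json <- function(t, path) {
  stopifnot(is_table2x2(t))
  jsonlite::write_json(list(a = t$a, b = t$b, c = t$c, d = t$d), path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Aggregate participant records into 2x2 tables
#'
#' Counts correct/incorrect responses per arm, optionally within strata of
#' one covariate.  Stratified tables sum cell-wise to the unstratified
#' table; every record contributes to exactly one stratum.
#'
#' @param ds a [study_dataset()].
#' @param stratify_by optional covariate name: one of `"gender"`,
#'   `"position"`, `"dispenser_last_month"`, `"fountain_before"`.
#' @return A named list of [table2x2()]; the unstratified call returns a
#'   single table under the name `"all"`.
#' @export
#' @examples
#' ds <- taipei_participants()
#' aggregate_tables(ds)$all
#' aggregate_tables(ds, "gender")
aggregate_tables <- function(ds, stratify_by = NULL) {
  stopifnot(inherits(ds, "study_dataset"))
  if (nrow(ds) == 0L)
    stop("cannot aggregate an empty dataset", call. = FALSE)
  count_table <- function(rows) {
    table2x2(
      a = sum(rows$arm == "tap" & rows$response == "tap"),
      b = sum(rows$arm == "tap" & rows$response == "filtered"),
      c = sum(rows$arm == "filtered" & rows$response == "tap"),
      d = sum(rows$arm == "filtered" & rows$response == "filtered")
    )
  }
  if (is.null(stratify_by)) return(list(all = count_table(ds)))
  if (!stratify_by %in% names(COVARIATE_LEVELS))
    stop("unknown covariate: ", stratify_by, call. = FALSE)
  out <- lapply(COVARIATE_LEVELS[[stratify_by]], function(lev) {
    rows <- ds[ds[[stratify_by]] == lev, , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    count_table(rows)
  })
  names(out) <- COVARIATE_LEVELS[[stratify_by]]
  out[!vapply(out, is.null, logical(1))]
}
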