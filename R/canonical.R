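#' Canonical variable names
#'
#' The pipeline's canonical schema: a subject identifier, self-reported
#' gender coded \code{M}/\code{F}, and the 25 SANS item ratings
#' (\code{sans_item_01} ... \code{sans_item_25}, integers 0-5). Item indices
#' are zero-padded to two digits so configuration files sort and diff
#' stably. \code{age} and \code{duration_illness} are optional covariates.
#'
#' @return Character vector of canonical names.
#' @export
canonical_variables <- function() {
  c("subject_id", "gender", sans_item_names())
}

#' @rdname canonical_variables
#' @export
sans_item_names <- function() sprintf("sans_item_%02d", 1:25)

#' Optional canonical covariates recognised by the schema
#' @keywords internal
optional_variables <- function() c("age", "duration_illness")

#' The eight analysis outcomes, in reporting order
#' @return Character vector: Total, the two composites, then the five factors.
#' @export
outcome_names <- function() {
  c("Total", "MAP", "EXP",
    "Anhedonia", "Asociality", "Avolition", "BluntedAffect", "Alogia")
}

#' Construct a canonical site table
#'
#' A `canonical_table` is an ordinary data.frame carrying the canonical
#' columns plus a `site_id` attribute. Structural invariants (required
#' columns present, at least one record, unique subject identifiers) are
#' enforced here; value-level checks (rating ranges, gender codes) are the
#' job of [validate_canonical()], which reports rather than throws.
#'
#' @param df data.frame with the canonical columns.
#' @param site_id Site label attached to every downstream result.
#' @return The data.frame, classed `canonical_table`.
#' @export
canonical_table <- function(df, site_id) {
  stopifnot(is.data.frame(df), is.character(site_id), length(site_id) == 1L)
  missing_cols <- setdiff(canonical_variables(), names(df))
  if (length(missing_cols)) {
    stop("canonical table for site '", site_id, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) < 1L) {
    stop("canonical table for site '", site_id, "' has no records",
         call. = FALSE)
  }
  ids <- as.character(df$subject_id)
  if (anyDuplicated(ids)) {
    stop("duplicate subject_id within site '", site_id, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  df$subject_id <- ids
  df$gender <- as.character(df$gender)
  for (it in sans_item_names()) df[[it]] <- as.numeric(df[[it]])
  attr(df, "site_id") <- site_id
  class(df) <- c("canonical_table", "data.frame")
  df
}

#' @export
print.canonical_table <- function(x, ...) {
  cat("Canonical site table: site '", site_id(x), "', ",
      nrow(x), " subjects (", sum(x$gender == "M"), " M / ",
      sum(x$gender == "F"), " F)\n", sep = "")
  invisible(x)
}

#' Site identifier of a canonical table
#' @param x A `canonical_table`.
#' @export
site_id <- function(x) attr(x, "site_id")

#' Extract the 25-column item matrix from a canonical table
#' @keywords internal
item_matrix <- function(table) {
  m <- as.matrix(as.data.frame(table)[, sans_item_names()])
  storage.mode(m) <- "double"
  rownames(m) <- table$subject_id
  m
}

#' Validate a canonical table against the schema's value rules
#'
#' Checks every cell and reports violations with row/column coordinates;
#' the table itself is never modified and violations never throw. Errors
#' are cells that make a record unusable (gender outside \{M, F\}, item
#' rating outside 0-5 or non-integer, missing/duplicated subject id);
#' missing item ratings are warnings whose effect depends on the
#' missing-data `policy` used downstream.
#'
#' @param table A [canonical_table()].
#' @param policy Missing-item policy the scoring stage will apply:
#'   `"error"` (default; a record with any missing required item is
#'   unusable), `"drop"` (same records excluded, silently), or
#'   `"prorate"` (factor scores use the mean of present items, so records
#'   with partial items remain usable).
#' @return A `validation_report`: list with `issues` (data.frame of row,
#'   column, severity, message), `n_usable`, `n_records`, `policy`.
#' @export
validate_canonical <- function(table, policy = c("error", "drop", "prorate")) {
  policy <- match.arg(policy)
  stopifnot(inherits(table, "canonical_table"))
  issues <- list()
  add <- function(row, column, severity, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      row = row, column = column, severity = severity, message = message,
      stringsAsFactors = FALSE)
  }
  bad_gender <- which(!(table$gender %in% c("M", "F")))
  for (r in bad_gender) {
    add(r, "gender", "error",
        sprintf("gender '%s' not in {M, F}", table$gender[r]))
  }
  items <- item_matrix(table)
  missing_rows <- logical(nrow(table))
  for (j in seq_len(ncol(items))) {
    col <- items[, j]
    nm <- colnames(items)[j]
    bad <- which(!is.na(col) & (col < 0 | col > 5 | col != round(col)))
    for (r in bad) {
      add(r, nm, "error",
          sprintf("item rating %s outside integer range 0-5", format(col[r])))
    }
    miss <- which(is.na(col))
    for (r in miss) add(r, nm, "warning", "missing item rating")
    missing_rows[miss] <- TRUE
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(row = integer(), column = character(),
               severity = character(), message = character(),
               stringsAsFactors = FALSE)
  error_rows <- unique(issues$row[issues$severity == "error"])
  unusable <- seq_len(nrow(table)) %in% error_rows
  if (policy %in% c("error", "drop")) unusable <- unusable | missing_rows
  out <- list(site_id = site_id(table), issues = issues,
              n_records = nrow(table), n_usable = sum(!unusable),
              policy = policy)
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  n_err <- sum(x$issues$severity == "error")
  n_warn <- sum(x$issues$severity == "warning")
  cat("Validation of site '", x$site_id, "': ", x$n_usable, "/",
      x$n_records, " usable records under policy '", x$policy, "' (",
      n_err, " errors, ", n_warn, " warnings)\n", sep = "")
  if (nrow(x$issues)) {
    print(utils::head(x$issues, 20L), row.names = FALSE)
    if (nrow(x$issues) > 20L) cat("... and", nrow(x$issues) - 20L, "more\n")
  }
  invisible(x)
}
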