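#' Site-local variable map ("Maps")
#'
#' Heterogeneous sites keep their own column names and category codings; a
#' `variable_map` binds each canonical variable the pipeline needs to the
#' site's source column, and each source gender code to canonical `M`/`F`.
#' Mapping relabels in place — it never moves or rewrites the site's file.
#'
#' @param site_id Site label.
#' @param column_bindings Named character vector: names are canonical
#'   variable names (see [canonical_variables()]), values are source column
#'   names. Every required canonical variable must be bound exactly once and
#'   bound source columns must be distinct. Optional covariates
#'   (`age`, `duration_illness`) may additionally be bound.
#' @param gender_value_bindings Named character vector mapping source gender
#'   codes to `"M"` or `"F"` (default: identity on `M`/`F`).
#' @return A `variable_map` object.
#' @export
variable_map <- function(site_id, column_bindings,
                         gender_value_bindings = c(M = "M", F = "F")) {
  stopifnot(is.character(site_id), length(site_id) == 1L)
  column_bindings <- unlist(column_bindings)
  gender_value_bindings <- unlist(gender_value_bindings)
  required <- canonical_variables()
  allowed <- c(required, optional_variables())
  unknown <- setdiff(names(column_bindings), allowed)
  if (length(unknown)) {
    stop("variable map for site '", site_id,
         "' binds unknown canonical variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unbound <- setdiff(required, names(column_bindings))
  if (length(unbound)) {
    stop("variable map for site '", site_id,
         "' leaves required canonical variable(s) unbound: ",
         paste(unbound, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(column_bindings))) {
    stop("variable map for site '", site_id,
         "' binds a canonical variable more than once", call. = FALSE)
  }
  if (anyDuplicated(column_bindings)) {
    dup <- unique(column_bindings[duplicated(column_bindings)])
    stop("variable map for site '", site_id,
         "' binds source column(s) to more than one canonical variable: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!all(gender_value_bindings %in% c("M", "F"))) {
    stop("gender_value_bindings must map into {M, F}", call. = FALSE)
  }
  structure(list(site_id = site_id,
                 column_bindings = column_bindings,
                 gender_value_bindings = gender_value_bindings),
            class = "variable_map")
}

#' @export
print.variable_map <- function(x, ...) {
  cat("Variable map for site '", x$site_id, "': ",
      length(x$column_bindings), " column bindings, gender codes {",
      paste(names(x$gender_value_bindings), collapse = ", "), "} -> {M, F}\n",
      sep = "")
  invisible(x)
}

#' Apply a variable map to a raw site table
#'
#' Pure relabeling: bound source columns are renamed to their canonical
#' names with row order and cell values untouched; gender codes are recoded
#' through the map's value bindings. Unbound source columns are dropped.
#'
#' @param raw_table data.frame read from the site's delimited file.
#' @param vmap A [variable_map()].
#' @return A [canonical_table()].
#' @export
apply_variable_map <- function(raw_table, vmap) {
  stopifnot(is.data.frame(raw_table), inherits(vmap, "variable_map"))
  if (nrow(raw_table) < 1L) {
    stop("raw table for site '", vmap$site_id, "' is empty", call. = FALSE)
  }
  absent <- setdiff(unname(vmap$column_bindings), names(raw_table))
  if (length(absent)) {
    stop("mapping error for site '", vmap$site_id,
         "': bound source column(s) not present in the data: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- raw_table[, unname(vmap$column_bindings), drop = FALSE]
  names(out) <- names(vmap$column_bindings)
  src_gender <- as.character(out$gender)
  idx <- match(src_gender, names(vmap$gender_value_bindings))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("value error for site '", vmap$site_id, "': gender code '",
         src_gender[bad], "' at row ", bad,
         " has no binding to {M, F}", call. = FALSE)
  }
  out$gender <- unname(vmap$gender_value_bindings[idx])
  rownames(out) <- NULL
  canonical_table(out, vmap$site_id)
}

#' Read / write a variable map as a YAML or JSON config file
#'
#' The on-disk schema has three keys: `site_id`, `column_bindings`
#' (canonical name -> source column), `gender_value_bindings`
#' (source code -> M/F). Format is chosen by file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param path Config file path.
#' @return `read_variable_map()` returns a [variable_map()];
#'   `write_variable_map()` returns `path` invisibly.
#' @export
read_variable_map <- function(path) {
  cfg <- read_config(path)
  for (field in c("site_id", "column_bindings")) {
    if (is.null(cfg[[field]])) {
      stop("variable map file '", path, "' lacks field '", field, "'",
           call. = FALSE)
    }
  }
  gvb <- cfg$gender_value_bindings
  if (is.null(gvb)) gvb <- list(M = "M", F = "F")
  variable_map(cfg$site_id,
               column_bindings = unlist(cfg$column_bindings),
               gender_value_bindings = unlist(gvb))
}

#' @rdname read_variable_map
#' @param vmap A [variable_map()] to serialize.
#' @export
write_variable_map <- function(vmap, path) {
  stopifnot(inherits(vmap, "variable_map"))
  obj <- list(site_id = vmap$site_id,
              column_bindings = as.list(vmap$column_bindings),
              gender_value_bindings = as.list(vmap$gender_value_bindings))
  write_config(obj, path)
}

# Format-dispatching config helpers shared by maps and consortium specs.
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be .yaml/.yml or .json: ", path, call. = FALSE)
  }
}

write_config <- function(obj, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path, precision = 15L)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    stop("config file must be .yaml/.yml or .json: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read a site's delimited data file
#'
#' RFC-4180 CSV with a header row, UTF-8. A thin wrapper over
#' [utils::read.csv()] that keeps strings as characters.
#'
#' @param path CSV file path.
#' @return data.frame with the site's source columns.
#' @export
read_site_csv <- function(path) {
  if (!file.exists(path)) stop("site file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  fileEncoding = "UTF-8")
}
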