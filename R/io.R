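#' Read and write screening cohorts as CSV
#'
#' Cohorts interchange as UTF-8 comma-delimited CSV with a header of exactly
#' the screening-record column names (see [ais_variables()]) and categorical
#' levels as their canonical lower-case strings. `write_cohort()` /
#' `read_cohort()` round-trip losslessly. On reading, level strings that
#' differ from the canonical ones only by case (e.g. `"Left"`) are
#' normalized with a warning; unknown levels, missing columns, duplicated
#' header names, non-numeric ages, and empty files are errors that name the
#' offending row or column.
#'
#' @param records a screening cohort
#' @param path file path
#' @return `read_cohort()`: a validated cohort `data.frame`;
#'   `write_cohort()`: the path, invisibly
#' @export
write_cohort <- function(records, path) {
  records <- validate_cohort(records)
  out <- records[, .ais_columns]
  for (v in names(.ais_levels)) out[[v]] <- as.character(out[[v]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty cohort file: ", path, call. = FALSE)
  header <- as.character(utils::read.csv(path, nrows = 1, header = FALSE,
                                         stringsAsFactors = FALSE)[1, ])
  if (anyDuplicated(header)) {
    stop("duplicated column name(s) in header: ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(.ais_columns, header)
  if (length(missing) > 0) {
    stop("cohort file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("cohort file has a header but no records: ", path,
                          call. = FALSE)
  # case-normalize level strings, warning once per variable
  for (v in names(.ais_levels)) {
    col <- as.character(df[[v]])
    canon <- .ais_levels[[v]]
    fixable <- !col %in% canon & tolower(col) %in% canon
    if (any(fixable)) {
      warning("normalized letter case of ", sum(fixable), " value(s) in '",
              v, "'", call. = FALSE)
      col[fixable] <- tolower(col[fixable])
      df[[v]] <- col
    }
  }
  if (!is.numeric(df$age)) {
    suppressWarnings(age <- as.numeric(df$age))
    if (anyNA(age)) {
      stop("non-numeric age in row(s) ",
           paste(utils::head(which(is.na(age)), 5L), collapse = ", "),
           call. = FALSE)
    }
    df$age <- age
  }
  validate_cohort(df)
}

# internal: write a data.frame report as both TSV and JSON next to each other
write_report <- function(df, path_base) {
  utils::write.table(df, paste0(path_base, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "")
  jsonlite::write_json(df, paste0(path_base, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path_base)
}

#' Serialize a prediction model to JSON
#'
#' Writes (or returns) a model as JSON with its intercept, coefficients,
#' encoding, scheme and provenance — the interchange format in which the
#' published equations also ship.
#'
#' @param model a [prediction_model]
#' @param path optional output path; if `NULL` the JSON string is returned
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "prediction_model"))
  obj <- list(intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              encoding = model$encoding, scheme = model$scheme,
              provenance = model$provenance)
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
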