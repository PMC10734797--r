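# Delimited-text input/output. All tables are comma-separated with a header
# row, UTF-8, dates as ISO-8601 strings, EDSS scores as decimals with one
# fractional digit. Every writer's output is re-readable by the matching
# reader.

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " file ", path, " missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read a claims events table
#'
#' Expects columns `patient_id`, `date` (ISO-8601), `code_system`, `code`,
#' `setting`, `qualifier`. Codes are normalized on read; a trailing German
#' qualifier letter on an ICD code fills the qualifier column when that
#' column holds `"none"`.
#'
#' @param path CSV file path.
#' @return data.frame of normalized claims events.
#' @export
read_events <- function(path) {
  df <- read_table_checked(path, c("patient_id", "date", "code_system", "code",
                                   "setting", "qualifier"), "events")
  if (nrow(df)) {
    check_vocab(df$code_system, CODE_SYSTEMS, "code_system")
    check_vocab(df$setting, SETTINGS, "setting")
    check_vocab(df$qualifier, QUALIFIERS, "qualifier")
    from_suffix <- code_qualifier(df$code)
    take <- df$qualifier == "none" & from_suffix != "none" &
      df$setting == "outpatient_dx"
    df$qualifier[take] <- from_suffix[take]
    df$code <- vapply(seq_len(nrow(df)),
                      function(i) normalize_code(df$code[i], df$code_system[i]),
                      character(1))
    df$date <- parse_iso_date(df$date, path)
  } else df$date <- as.Date(character(0))
  df
}

#' Read a reference EDSS measurements table (`patient_id`, `date`, `score`)
#' @param path CSV file path.
#' @return data.frame with `date` as `Date` and numeric `score` validated
#'   against the half-point grid.
#' @export
read_edss <- function(path) {
  df <- read_table_checked(path, c("patient_id", "date", "score"), "EDSS")
  df$date <- parse_iso_date(df$date, path)
  df$score <- as.numeric(df$score)
  if (nrow(df) && any(is.na(df$score) | df$score < 0 | df$score > 9.5 |
                      (df$score * 2) %% 1 != 0))
    stop("EDSS file ", path, " contains scores off the 0.0-9.5 half-point grid")
  df
}

#' Read an insurance coverage table (`patient_id`, `start`, `end`)
#' @param path CSV file path.
#' @return data.frame with `Date` columns; rejects intervals with start > end.
#' @export
read_coverage <- function(path) {
  df <- read_table_checked(path, c("patient_id", "start", "end"), "coverage")
  df$start <- parse_iso_date(df$start, path)
  df$end <- parse_iso_date(df$end, path)
  if (nrow(df) && any(df$start > df$end))
    stop("coverage file ", path, " contains interval(s) with start > end")
  df
}

#' Read a deaths table (`patient_id`, `date`)
#' @param path CSV file path.
#' @return data.frame with `date` as `Date`.
#' @export
read_deaths <- function(path) {
  df <- read_table_checked(path, c("patient_id", "date"), "deaths")
  df$date <- parse_iso_date(df$date, path)
  df
}

#' Read an index dates table (`patient_id`, `date`)
#' @param path CSV file path.
#' @return data.frame with `date` as `Date`.
#' @export
read_index_dates <- function(path) {
  df <- read_table_checked(path, c("patient_id", "date"), "index dates")
  df$date <- parse_iso_date(df$date, path)
  df
}

parse_iso_date <- function(x, path) {
  d <- as.Date(x, format = "%Y-%m-%d")
  if (any(is.na(d) & !is.na(x)))
    stop("file ", path, " contains non-ISO-8601 date(s): ",
         paste(utils::head(x[is.na(d)], 3), collapse = ", "))
  d
}

#' Write a table as CSV (ISO dates, one fractional digit for scores)
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_claims_table <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (inherits(out[[nm]], "Date")) out[[nm]] <- format(out[[nm]], "%Y-%m-%d")
    if (nm == "score") out[[nm]] <- sprintf("%.1f", as.numeric(out[[nm]]))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
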