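#' Write a monthly panel to CSV
#'
#' The header is fixed: `practice_id, month_index, list_size, ed_rate,
#' adm_rate, readm_rate, em_los`, followed by the covariate columns.
#'
#' @param panel a monthly panel data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  utils::write.csv(panel[, PANEL_COLS], path, row.names = FALSE)
  invisible(path)
}

#' Load and validate a monthly panel from CSV
#'
#' Rejects files with a wrong header, negative rates, duplicate
#' (practice, month) keys, or ragged month coverage, naming the offending
#' row and column in the error.
#'
#' @param path CSV file path.
#' @return a validated panel data.frame.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stopf("panel file not found: %s", path)
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(PANEL_COLS, names(panel))
  if (length(missing))
    stopf("panel is missing required column(s): %s",
          paste(missing, collapse = ", "))
  validate_panel(panel)
  panel[, PANEL_COLS]
}

validate_panel <- function(panel) {
  for (col in c(OUTCOME_COLS, "em_los", "list_size")) {
    bad <- which(!is.finite(panel[[col]]) | panel[[col]] < 0)
    if (length(bad))
      stopf("invalid value in column '%s' at row %d (practice %s, month %s): %s",
            col, bad[1], panel$practice_id[bad[1]],
            panel$month_index[bad[1]], panel[[col]][bad[1]])
  }
  key <- paste(panel$practice_id, panel$month_index)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stopf("duplicate (practice_id, month_index) key: %s", d)
  }
  months <- sort(unique(panel$month_index))
  full <- seq(min(months), max(months))
  if (!identical(as.integer(months), as.integer(full)))
    stopf("panel months are not contiguous: missing %s",
          paste(setdiff(full, months), collapse = ", "))
  tab <- table(panel$practice_id)
  if (length(unique(tab)) > 1L) {
    short <- names(tab)[tab != max(tab)]
    pr <- short[1]
    miss <- setdiff(full, panel$month_index[panel$practice_id == pr])
    stopf("ragged month coverage: practice %s is missing month(s) %s",
          pr, paste(miss, collapse = ", "))
  }
  invisible(panel)
}

#' Write or read an intervention schedule as YAML
#'
#' The schedule maps each treated practice id to its join month and an
#' optional exit month (`~` for none).
#'
#' @param schedule named list: id -> `list(join_month, exit_month)`.
#' @param path YAML file path.
#' @return `path` (write) or the schedule list (read).
#' @export
write_schedule <- function(schedule, path) {
  ser <- lapply(schedule, function(s) {
    list(join_month = as.integer(s$join_month),
         exit_month = if (is.null(s$exit_month) || is.na(s$exit_month)) NULL
                      else as.integer(s$exit_month))
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(s) {
    list(join_month = as.integer(s$join_month),
         exit_month = if (is.null(s$exit_month)) NA_integer_
                      else as.integer(s$exit_month))
  })
}
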