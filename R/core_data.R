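# Shared tabular containers: long-format longitudinal panels, per-subject
# survival records, and counting-process (start, stop] tables, plus CSV
# readers/writers for each. All times are continuous years from study entry
# (t = 0 at the first exam); intervals are half-open (start, stop] with events
# at stop.

#' Construct a validated longitudinal panel
#'
#' A long panel is a long-format `data.frame` with one row per
#' (subject, measurement): columns `id` (character), `time` (years from entry,
#' >= 0), `y` (measurement, e.g. a log-scale biomarker), `age` (baseline age,
#' years) and `sex` (0/1, default coding 0 = male, 1 = female). Rows are
#' sorted by subject then time; measurement times must be strictly increasing
#' within subject and baseline covariates constant within subject.
#'
#' @param data data.frame holding the columns (any order, any extra columns
#'   are dropped).
#' @param columns named character vector mapping the canonical names
#'   `id`, `time`, `y`, `age`, `sex` to the columns of `data`.
#' @return A `data.frame` of class `long_panel`.
#' @export
long_panel <- function(data, columns = c(id = "id", time = "time", y = "y",
                                         age = "age", sex = "sex")) {
  need <- c("id", "time", "y", "age", "sex")
  if (!all(need %in% names(columns)))
    stop("`columns` must map all of: ", paste(need, collapse = ", "))
  missing_cols <- setdiff(unname(columns[need]), names(data))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  out <- data.frame(id   = as.character(data[[columns[["id"]]]]),
                    time = as.numeric(data[[columns[["time"]]]]),
                    y    = as.numeric(data[[columns[["y"]]]]),
                    age  = as.numeric(data[[columns[["age"]]]]),
                    sex  = as.numeric(data[[columns[["sex"]]]]),
                    stringsAsFactors = FALSE)
  bad <- which(!is.finite(out$time) | !is.finite(out$y))
  if (length(bad))
    stop("non-numeric time/y value at row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  out <- out[order(out$id, out$time), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$time < 0)) stop("measurement times must be >= 0")
  dup <- stats::ave(out$time, out$id, FUN = function(t) c(0, diff(t)))
  if (any(dup[stats::ave(out$time, out$id, FUN = seq_along) > 1] <= 0))
    stop("measurement times must be strictly increasing within subject")
  for (v in c("age", "sex")) {
    rng <- tapply(out[[v]], out$id, function(x) diff(range(x)))
    if (any(rng > 0)) stop("baseline covariate '", v, "' varies within subject")
  }
  if (!all(out$sex %in% c(0, 1))) stop("sex must be coded 0/1")
  class(out) <- c("long_panel", "data.frame")
  out
}

#' Construct validated survival records
#'
#' One row per subject: `id`, `time` (observed follow-up, > 0) and `event`
#' (1 = event at `time`, 0 = censored).
#'
#' @param data data.frame with the columns.
#' @param columns named mapping as in [long_panel()].
#' @return A `data.frame` of class `surv_records`.
#' @export
surv_records <- function(data, columns = c(id = "id", time = "time", event = "event")) {
  need <- c("id", "time", "event")
  missing_cols <- setdiff(unname(columns[need]), names(data))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  out <- data.frame(id    = as.character(data[[columns[["id"]]]]),
                    time  = as.numeric(data[[columns[["time"]]]]),
                    event = as.numeric(data[[columns[["event"]]]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) stop("duplicate subject id in survival records")
  if (any(!is.finite(out$time) | out$time <= 0)) stop("follow-up time must be > 0")
  if (!all(out$event %in% c(0, 1))) stop("event must be 0/1")
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("surv_records", "data.frame")
  out
}

#' Check a panel against its survival records
#'
#' Validates that every panel subject has a survival record and that no
#' measurement time exceeds the subject's observed follow-up time.
#'
#' @param panel a [long_panel()].
#' @param survival a [surv_records()].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_pairing <- function(panel, survival) {
  miss <- setdiff(unique(panel$id), survival$id)
  if (length(miss)) stop("subjects missing survival record: ", paste(utils::head(miss, 5), collapse = ", "))
  tt <- survival$time[match(panel$id, survival$id)]
  if (any(panel$time > tt + 1e-12))
    stop("measurement time exceeds follow-up time for subject(s): ",
         paste(utils::head(unique(panel$id[panel$time > tt + 1e-12]), 5), collapse = ", "))
  invisible(TRUE)
}

#' Validate a counting-process table
#'
#' Rows are (id, start, stop] intervals with interval-constant covariates and
#' `status` 1 only on a subject's last row. A subject is at risk at event time
#' t iff it has a row with start < t <= stop.
#'
#' @param table data.frame with columns `id`, `start`, `stop`, `status` and at
#'   least one covariate column.
#' @return The table, classed `counting_process`, rows ordered by id and start.
#' @export
counting_process <- function(table) {
  need <- c("id", "start", "stop", "status")
  if (!all(need %in% names(table)))
    stop("counting-process table needs columns: ", paste(need, collapse = ", "))
  table$id <- as.character(table$id)
  table$start <- as.numeric(table$start)
  table$stop <- as.numeric(table$stop)
  table$status <- as.numeric(table$status)
  table <- table[order(table$id, table$start), , drop = FALSE]
  rownames(table) <- NULL
  if (nrow(table)) {
    if (any(table$start >= table$stop)) stop("start must be < stop on every row")
    if (!all(table$status %in% c(0, 1))) stop("status must be 0/1")
    by_id <- split(seq_len(nrow(table)), table$id)
    for (rows in by_id) {
      if (length(rows) > 1) {
        gaps <- table$start[rows][-1] - table$stop[rows][-length(rows)]
        if (any(gaps < -1e-12)) stop("overlapping intervals within subject")
      }
      if (any(table$status[rows][-length(rows)] == 1))
        stop("status = 1 allowed only on a subject's last interval")
    }
  }
  class(table) <- c("counting_process", "data.frame")
  table
}

#' Read a long-format panel CSV
#'
#' @param path CSV with header; one row per (subject, exam).
#' @param columns column mapping as in [long_panel()].
#' @return A [long_panel()].
#' @export
read_long_panel <- function(path, columns = c(id = "id", time = "time", y = "y",
                                              age = "age", sex = "sex")) {
  long_panel(utils::read.csv(path, stringsAsFactors = FALSE), columns = columns)
}

#' Read a survival CSV (id, time, event)
#' @param path CSV path.
#' @param columns column mapping as in [surv_records()].
#' @return A [surv_records()].
#' @export
read_survival <- function(path, columns = c(id = "id", time = "time", event = "event")) {
  surv_records(utils::read.csv(path, stringsAsFactors = FALSE), columns = columns)
}

#' Write a long panel / survival records to CSV
#' @param x the object.
#' @param path output path.
#' @return Invisibly `path`.
#' @export
write_long_panel <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_long_panel
#' @export
write_survival <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a counting-process table
#'
#' Columns `id,start,stop,status,<covariates>`; read-back equals input at full
#' double precision (15 significant digits are written).
#'
#' @param table a [counting_process()] table.
#' @param path CSV path.
#' @return Invisibly `path` (writer); the table (reader).
#' @export
write_counting_process <- function(table, path) {
  table <- counting_process(as.data.frame(table))
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counting_process
#' @export
read_counting_process <- function(path) {
  counting_process(utils::read.csv(path, stringsAsFactors = FALSE))
}
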