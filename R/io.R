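#' Read a dose-event log from CSV
#'
#' The expected dialect has one row per actuation with columns `patient_id`,
#' `timestamp` (ISO-8601, e.g. `2024-01-05T08:02:00`), `error_labels`
#' (semicolon-separated technique-error tokens, empty for correct use) and
#' optionally `delta_override` (a dose fraction in \[0, 1\] taking precedence
#' over the rule table). Malformed rows are never silently dropped: they are
#' collected into a rejects table with the row number and a reason.
#'
#' Each patient's clock starts at midnight of their first event day; event
#' times are hours since that origin. The monitoring span runs from 0 to
#' `span_days` days (extended if events run longer).
#'
#' @param path Path to the CSV file.
#' @param rules Technique rule table, see [technique_rules()].
#' @param span_days Monitoring span per patient in days (default 90).
#' @return A list with `records` (list of [patient_record()]s, events
#'   time-sorted), `rejects` (tibble of `row`, `patient_id`, `reason`) and
#'   `origins` (named POSIXct vector of per-patient time origins).
#' @export
read_event_log <- function(path, rules = technique_rules(), span_days = 90) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("patient_id", "timestamp", "error_labels")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop(sprintf("event log is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  fallback <- is.na(ts)
  ts[fallback] <- as.POSIXct(raw$timestamp[fallback],
                             format = "%Y-%m-%d %H:%M:%S", tz = "UTC")

  reasons <- rep(NA_character_, nrow(raw))
  reasons[is.na(ts)] <- "bad timestamp"

  labels <- strsplit(ifelse(is.na(raw$error_labels), "", raw$error_labels),
                     ";", fixed = TRUE)
  labels <- lapply(labels, function(l) trimws(l[nzchar(trimws(l))]))
  delta <- vapply(seq_along(labels), function(i) {
    if (!is.na(reasons[i])) return(NA_real_)
    tryCatch(delta_for_errors(labels[[i]], rules), error = function(e) NA_real_)
  }, numeric(1))
  unknown <- is.na(reasons) & is.na(delta)
  reasons[unknown] <- "unknown error label"

  if ("delta_override" %in% names(raw)) {
    ov <- suppressWarnings(as.numeric(raw$delta_override))
    has_ov <- !is.na(raw$delta_override) & nzchar(raw$delta_override)
    bad_ov <- has_ov & (is.na(ov) | ov < 0 | ov > 1)
    reasons[is.na(reasons) & bad_ov] <- "invalid delta_override"
    use <- is.na(reasons) & has_ov & !bad_ov
    delta[use] <- ov[use]
  }

  ok <- is.na(reasons)
  rejects <- tibble::tibble(row = which(!ok),
                            patient_id = raw$patient_id[!ok],
                            reason = reasons[!ok])

  ids <- unique(raw$patient_id[ok])
  origins <- as.POSIXct(rep(NA_real_, length(ids)), origin = "1970-01-01", tz = "UTC")
  names(origins) <- ids
  records <- lapply(ids, function(id) {
    sel <- ok & raw$patient_id == id
    origin <- trunc(min(ts[sel]), units = "days")
    origins[id] <<- origin
    hours <- as.numeric(difftime(ts[sel], origin, units = "hours"))
    span <- max(span_days * 24, max(hours))
    patient_record(id,
                   dose_events(hours, delta[sel], error_labels = labels[sel]),
                   span_hours = span)
  })
  names(records) <- ids
  list(records = records, rejects = rejects, origins = origins)
}

#' Write patient records back to the event-log CSV dialect
#'
#' Inverse of [read_event_log()]: serialises the events of a list of
#' records, reconstructing ISO-8601 timestamps from each patient's time
#' origin.
#'
#' @param records List of [patient_record()]s.
#' @param path Output CSV path.
#' @param origins Named POSIXct vector of per-patient origins (as returned
#'   by [read_event_log()]); defaults to `2000-01-01 00:00 UTC` for all.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(records, path, origins = NULL) {
  rows <- lapply(records, function(rec) {
    origin <- if (!is.null(origins) && rec$patient_id %in% names(origins)) {
      origins[[rec$patient_id]]
    } else {
      as.POSIXct("2000-01-01 00:00:00", tz = "UTC")
    }
    ev <- rec$events
    labs <- if ("error_labels" %in% names(ev)) {
      vapply(ev$error_labels, paste, character(1), collapse = ";")
    } else rep("", nrow(ev))
    data.frame(
      patient_id = rec$patient_id,
      timestamp = format(origin + ev$time * 3600, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      error_labels = labs,
      delta_override = ev$delta,
      stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a Stata dataset and map its columns
#'
#' Thin adapter for supplementary datasets distributed in Stata `.dta`
#' format. Reads the file and optionally renames columns via a mapping so
#' downstream code can use the package's standard column names.
#'
#' @param path Path to a `.dta` file.
#' @param mapping Optional named character vector, `c(standard_name =
#'   "file_column", ...)`; every mapped column must exist.
#' @return A tibble (mapped columns renamed, others kept).
#' @export
read_stata_dataset <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- foreign::read.dta(path)
  if (!is.null(mapping)) {
    missing <- setdiff(unname(mapping), names(df))
    if (length(missing)) {
      stop(sprintf("mapped column(s) not present in %s: %s",
                   basename(path), paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    idx <- match(unname(mapping), names(df))
    names(df)[idx] <- names(mapping)
  }
  tibble::as_tibble(df)
}
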