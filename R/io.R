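#' Read a defibrillator event log
#'
#' The package defines an open event-log dialect with two encodings:
#'
#' * **JSONL** (`.jsonl`/`.json`): one JSON object per line with integer
#'   `time_ms`, string `kind`, and, for shock entries, `energy_j` and
#'   `impedance_ohm`. The first line must be the header entry
#'   `kind = "power on"` carrying the wall-clock `timestamp`
#'   (`"YYYY-MM-DD HH:MM:SS"`, or `null` when unknown).
#' * **CSV**: columns `time_ms, kind, energy_j, impedance_ohm, timestamp`
#'   with the same header-row requirement.
#'
#' Entry kinds are matched case-insensitively after trimming. `"shock
#' delivered"` entries become shock records, `"modeSwitchMonitor"` /
#' `"modeSwitchAED"` become mode switches to manual and advisory mode
#' respectively, and an optional `"recording end"` entry marks the end of
#' the recording (the episode span end); unknown kinds are skipped with a
#' message (forward compatibility).
#'
#' @param path File path (`.jsonl`, `.json` or `.csv`).
#' @return A list of class `rore_event_log`: `power_on` (string or `NA`),
#'   `shocks` (tibble `time`, `energy_j`, `impedance_ohm`), `mode_switches`
#'   (tibble `time`, `mode`), `span_end` (seconds, or `NULL` when no
#'   `"recording end"` entry is present), and `entries` (the raw entry
#'   tibble).
#' @export
read_event_log <- function(path) {
  entries <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    purrr::imap(lines, function(l, i) {
      rec <- tryCatch(jsonlite::fromJSON(l), error = function(e) {
        abort(sprintf("event log line %d: not valid JSON (%s)", i, conditionMessage(e)))
      })
      as_tibble(rec[!vapply(rec, is.null, logical(1))])
    }) |> list_rbind()
  }
  required <- c("time_ms", "kind")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0L) {
    abort(paste0(
      "event log is missing required field(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in c("energy_j", "impedance_ohm", "timestamp")) {
    if (!col %in% names(entries)) entries[[col]] <- NA
  }
  kind_norm <- tolower(trimws(entries$kind))
  if (kind_norm[1L] != "power on") {
    abort("event log must start with the 'power on' header entry.")
  }
  if (is.unsorted(entries$time_ms)) {
    abort("event log entries must be sorted ascending by time_ms.")
  }
  power_on <- entries$timestamp[1L]
  if (is.null(power_on) || length(power_on) == 0L || is.na(power_on) ||
      identical(power_on, "")) {
    power_on <- NA
  }
  known <- c(
    "power on", "shock delivered", "modeswitchmonitor", "modeswitchaed",
    "recording end"
  )
  unknown <- unique(entries$kind[!kind_norm %in% known])
  if (length(unknown) > 0L) {
    inform(paste0(
      "skipping unknown event-log entry kind(s): ",
      paste(unknown, collapse = ", ")
    ))
  }
  shock_rows <- entries[kind_norm == "shock delivered", ]
  if (nrow(shock_rows) > 0L &&
      (anyNA(shock_rows$energy_j) || anyNA(shock_rows$impedance_ohm))) {
    abort("every 'shock delivered' entry must carry energy_j and impedance_ohm.")
  }
  shocks <- tibble(
    time = shock_rows$time_ms / 1000,
    energy_j = as.numeric(shock_rows$energy_j),
    impedance_ohm = as.numeric(shock_rows$impedance_ohm)
  )
  ms_rows <- kind_norm %in% c("modeswitchmonitor", "modeswitchaed")
  mode_switches <- tibble(
    time = entries$time_ms[ms_rows] / 1000,
    mode = ifelse(kind_norm[ms_rows] == "modeswitchmonitor", "manual", "advisory")
  )
  span_end <- if (any(kind_norm == "recording end")) {
    max(entries$time_ms[kind_norm == "recording end"]) / 1000
  } else {
    NULL
  }
  structure(
    list(
      power_on = power_on, shocks = shocks,
      mode_switches = mode_switches, span_end = span_end,
      entries = as_tibble(entries)
    ),
    class = "rore_event_log"
  )
}

#' Write an event log in the JSONL dialect
#'
#' @param log A `rore_event_log` (or a list with `power_on`, `shocks`,
#'   `mode_switches`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  header <- list(time_ms = 0L, kind = "power on")
  header$timestamp <- if (length(log$power_on) == 1L && is.na(log$power_on[[1L]])) {
    NULL
  } else {
    as.character(log$power_on)
  }
  body <- bind_rows(
    tibble(
      time_ms = as.integer(round(log$shocks$time * 1000)),
      kind = "shock delivered",
      energy_j = log$shocks$energy_j,
      impedance_ohm = log$shocks$impedance_ohm
    ),
    tibble(
      time_ms = as.integer(round(log$mode_switches$time * 1000)),
      kind = ifelse(log$mode_switches$mode == "manual",
        "modeSwitchMonitor", "modeSwitchAED"
      ) |> as.character()
    )
  )
  if (!is.null(log$span_end)) {
    body <- bind_rows(body, tibble(
      time_ms = as.integer(round(log$span_end * 1000)),
      kind = "recording end"
    ))
  }
  body <- body |> arrange(.data$time_ms)
  lines <- c(
    jsonlite::toJSON(header, auto_unbox = TRUE),
    vapply(seq_len(nrow(body)), function(i) {
      rec <- as.list(body[i, ])
      rec <- rec[!vapply(rec, function(v) is.na(v[[1L]]), logical(1))]
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read and write annotation tables
#'
#' Annotations are CSV with a mandatory header and two columns: `time_s`
#' (elapsed seconds) and `code` (one of `c1,c2,d1,d2` for therapy or
#' `vf,vt,as,pe,pr,un` for rhythm transitions).
#'
#' @param path File path.
#' @return A tibble with `time` and `code`, sorted by time.
#' @export
read_annotations <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_s", "code") %in% names(x))) {
    abort("annotation file must have columns time_s and code.")
  }
  bad <- !x$code %in% c(therapy_codes, response_codes)
  if (any(bad)) {
    abort(sprintf(
      "annotation line %d: unknown event code '%s'",
      which(bad)[1L] + 1L, x$code[which(bad)[1L]]
    ))
  }
  if (anyNA(x$time_s) || any(x$time_s < 0)) {
    abort("annotation times must be non-negative seconds.")
  }
  tibble(time = as.numeric(x$time_s), code = x$code) |> arrange(.data$time)
}

#' @rdname read_annotations
#' @param events A tibble with `time` and `code`.
#' @export
write_annotations <- function(events, path) {
  readr::write_csv(
    tibble(time_s = events$time, code = events$code), path, progress = FALSE
  )
  invisible(path)
}

# Canonical database column order: per-shock review variables as stored in
# the registry sheet (hr/mn/sc triplet per time variable).
database_columns <- function() {
  trip <- function(p) paste0(p, c("hr", "mn", "sc"))
  c(
    "episode", "shkn",
    trip("ecg"), trip("fc"), trip("lc"), trip("shk"),
    trip("vfonset"), trip("rsc"),
    "init_rhy", "rhyb4", "r10", "r30", "r60", "r120",
    "vfpr", "orgpr", "rosc",
    "ssrecord", "shks", "mode", "cpr", "imp", "enrgy"
  )
}

#' Read and write review databases
#'
#' A review database (manual or derived) is CSV with one row per shock and
#' the registry's per-shock variables: the `episode` id, `shkn`, six time
#' variables as hr/mn/sc integer triplets (`ecg`, `fc`, `lc`, `shk`,
#' `vfonset`, `rsc` prefixes), the response codes (`init_rhy`, `rhyb4`,
#' `r10`-`r120`, `vfpr`, `orgpr`, `rosc`) and the device/therapy variables
#' (`ssrecord`, `shks`, `mode`, `cpr`, `imp`, `enrgy`).
#'
#' @param path File path.
#' @return A tibble of database rows.
#' @export
read_database <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(database_columns(), names(x))
  if (length(missing_cols) > 0L) {
    abort(paste0(
      "database is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  num_cols <- setdiff(database_columns(), "episode")
  x |> mutate(across(dplyr::all_of(num_cols), as.integer))
}

#' @rdname read_database
#' @param rows A tibble of database rows.
#' @export
write_database <- function(rows, path) {
  keep <- intersect(database_columns(), names(rows))
  readr::write_csv(rows[, keep], path, progress = FALSE)
  invisible(path)
}

# ---- RORE text rendering --------------------------------------------------

format_block <- function(x) {
  if (is.null(x) || nrow(x) == 0L) {
    return("(undefined)")
  }
  sprintf("%.1f–%.1f: %s", x$start, x$end, x$label)
}

#' Render and parse the human-readable episode representation
#'
#' `format_rore()` renders an episode as three blocks — the therapy domain,
#' the response domain, and the combined episode representation — with one
#' `start–end: LABEL` line per state, times printed at 0.1 s. `write_rore()`
#' writes it to a file, and `read_rore()` parses the text back into the
#' three sequences (an exact round trip at 0.1 s resolution).
#'
#' @param episode A [rore_episode()].
#' @return `format_rore()`: a character vector of lines; `read_rore()`: a
#'   list with `therapy`, `response` and `combined` sequences.
#' @export
format_rore <- function(episode) {
  combined <- tryCatch(episode_representation(episode), error = function(e) NULL)
  c(
    "therapy domain:",
    format_block(episode$therapy),
    "",
    "response domain:",
    format_block(episode$response),
    "",
    "episode representation:",
    format_block(combined)
  )
}

#' @rdname format_rore
#' @param path File path.
#' @export
write_rore <- function(episode, path) {
  writeLines(enc2utf8(format_rore(episode)), path, useBytes = TRUE)
  invisible(path)
}

parse_block <- function(lines, domain) {
  if (length(lines) == 0L || identical(lines, "(undefined)")) {
    return(NULL)
  }
  m <- regmatches(
    lines, regexec("^([0-9.]+)–([0-9.]+): ([A-Z]+)$", lines)
  )
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    abort(paste0("cannot parse representation line: ", lines[which(bad)[1L]]))
  }
  intervals <- tibble(
    start = vapply(m, function(v) as.numeric(v[2]), double(1)),
    end = vapply(m, function(v) as.numeric(v[3]), double(1)),
    label = vapply(m, function(v) v[4], character(1))
  )
  new_sequence(intervals, domain)
}

#' @rdname format_rore
#' @export
read_rore <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  heads <- c("therapy domain:", "response domain:", "episode representation:")
  idx <- match(heads, lines)
  if (anyNA(idx)) {
    abort("representation file must contain the three standard blocks.")
  }
  block <- function(i) {
    from <- idx[i] + 1L
    to <- if (i < 3L) idx[i + 1L] - 1L else length(lines)
    body <- lines[from:to]
    body[nzchar(trimws(body))]
  }
  list(
    therapy = parse_block(block(1L), "therapy"),
    response = parse_block(block(2L), "response"),
    combined = parse_block(block(3L), "combined")
  )
}
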