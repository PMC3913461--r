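#' Labeled-interval state sequences
#'
#' A `rore_sequence` is a tibble of contiguous half-open intervals
#' `[start, end)` with a state `label` column, carrying the domain
#' (`"therapy"`, `"response"` or `"combined"`) and the covered span as
#' attributes. Intervals tile the span with no gaps or overlaps; in the
#' therapy and response domains adjacent intervals never share a label
#' (maximal runs). Zero-length intervals are never stored.
#'
#' Half-open intervals make point queries unambiguous: a transition time
#' belongs to the state it opens, not the one it closes.
#'
#' @param intervals A data frame with numeric `start`, `end` and character
#'   `label` columns.
#' @param domain One of `"therapy"`, `"response"`, `"combined"`.
#' @param span_start,span_end Covered span in elapsed seconds. Default to the
#'   first interval's start and the last interval's end.
#' @return A `rore_sequence` tibble.
#' @export
#' @examples
#' new_sequence(
#'   tibble::tibble(start = c(0, 10), end = c(10, 25), label = c("H", "C")),
#'   domain = "therapy"
#' )
new_sequence <- function(intervals, domain,
                         span_start = NULL, span_end = NULL) {
  domain <- match.arg(domain, c("therapy", "response", "combined"))
  intervals <- as_tibble(intervals)[, c("start", "end", "label")]
  if (nrow(intervals) == 0L) {
    if (is.null(span_start) || is.null(span_end)) {
      span_start <- NA_real_
      span_end <- NA_real_
    }
  } else {
    span_start <- span_start %||% intervals$start[1]
    span_end <- span_end %||% intervals$end[nrow(intervals)]
  }
  out <- tibble::new_tibble(
    intervals,
    domain = domain,
    span_start = as.numeric(span_start),
    span_end = as.numeric(span_end),
    class = "rore_sequence"
  )
  validate_sequence(out)
  out
}

validate_sequence <- function(x, tol = 1e-9) {
  if (nrow(x) == 0L) {
    return(invisible(x))
  }
  if (any(x$end - x$start <= 0)) {
    abort("rore_sequence intervals must have start < end (no zero-length states).")
  }
  if (nrow(x) > 1L) {
    gap <- x$start[-1L] - x$end[-nrow(x)]
    if (any(abs(gap) > tol)) {
      abort("rore_sequence intervals must be contiguous (no gaps or overlaps).")
    }
  }
  dom <- seq_domain(x)
  allowed <- switch(dom,
    therapy = therapy_states,
    response = response_states,
    combined = as.vector(outer(therapy_states, response_states, paste0))
  )
  bad <- setdiff(unique(x$label), allowed)
  if (length(bad) > 0L) {
    abort(paste0(
      "invalid ", dom, " state label(s): ", paste(bad, collapse = ", ")
    ))
  }
  if (dom != "combined" && nrow(x) > 1L) {
    if (any(x$label[-1L] == x$label[-nrow(x)])) {
      abort("adjacent intervals in a domain sequence must not share a label.")
    }
  }
  sp <- seq_span(x)
  if (abs(x$start[1L] - sp[1L]) > tol || abs(x$end[nrow(x)] - sp[2L]) > tol) {
    abort("sequence span attributes must match the first start and last end.")
  }
  invisible(x)
}

#' @rdname new_sequence
#' @param x A `rore_sequence`.
#' @export
seq_domain <- function(x) attr(x, "domain")

#' @rdname new_sequence
#' @export
seq_span <- function(x) c(attr(x, "span_start"), attr(x, "span_end"))

#' @export
print.rore_sequence <- function(x, ...) {
  sp <- seq_span(x)
  cat(sprintf(
    "<rore_sequence: %s domain, %d state(s), span [%.1f, %.1f)>\n",
    seq_domain(x), nrow(x), sp[1], sp[2]
  ))
  NextMethod()
}

# Merge adjacent intervals that carry the same label (maximal runs).
merge_runs <- function(intervals) {
  if (nrow(intervals) <= 1L) {
    return(intervals)
  }
  run <- cumsum(c(TRUE, intervals$label[-1L] != intervals$label[-nrow(intervals)]))
  intervals |>
    mutate(.run = run) |>
    group_by(.data$.run) |>
    summarise(
      start = first(.data$start), end = last(.data$end),
      label = first(.data$label), .groups = "drop"
    ) |>
    select("start", "end", "label")
}

# Pair start/stop therapy events of one kind (c1/c2 or d1/d2) into intervals.
pair_events <- function(events, open_code, close_code, state) {
  ev <- events |> filter(.data$code %in% c(open_code, close_code))
  if (nrow(ev) == 0L) {
    return(tibble(start = double(), end = double(), label = character()))
  }
  expected <- rep(c(open_code, close_code), length.out = nrow(ev))
  mismatch <- which(ev$code != expected)
  if (length(mismatch) > 0L || nrow(ev) %% 2L != 0L) {
    t_bad <- if (length(mismatch) > 0L) ev$time[mismatch[1L]] else ev$time[nrow(ev)]
    abort(sprintf(
      "unpaired %s/%s annotation at t = %.3f s", open_code, close_code, t_bad
    ))
  }
  starts <- ev$time[ev$code == open_code]
  ends <- ev$time[ev$code == close_code]
  if (any(ends <= starts)) {
    bad <- which(ends <= starts)[1L]
    abort(sprintf(
      "%s at t = %.3f s is not followed by a later %s",
      open_code, starts[bad], close_code
    ))
  }
  tibble(start = starts, end = ends, label = state)
}

#' Build the therapy-domain sequence from paired annotations
#'
#' Therapy events are `c1`/`c2` (start and end of a compression sequence) and
#' `d1`/`d2` (start and end of a defibrillation discharge). Each pair becomes
#' a `C` or `D` interval; every part of the span not covered by a pair is a
#' hands-off (`H`) interval. Adjacent same-label intervals are merged.
#'
#' @param events A data frame with numeric `time` (elapsed seconds) and
#'   character `code` columns, sorted by time; codes restricted to
#'   `c1`, `c2`, `d1`, `d2`.
#' @param span_start,span_end Episode span covered by the sequence, in
#'   elapsed seconds.
#' @return A therapy-domain [new_sequence()] over `[span_start, span_end)`.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   time = c(805.2, 887.2, 903.3, 908.3, 938.8, 1062.0),
#'   code = c("c1", "c2", "d1", "d2", "c1", "c2")
#' )
#' build_therapy_sequence(ev, 740.8, 1062.0)
build_therapy_sequence <- function(events, span_start, span_end) {
  events <- as_tibble(events)
  if (span_start >= span_end) {
    abort("span_start must be less than span_end.")
  }
  bad <- setdiff(unique(events$code), therapy_codes)
  if (length(bad) > 0L) {
    abort(paste0("unknown therapy event code(s): ", paste(bad, collapse = ", ")))
  }
  if (is.unsorted(events$time)) {
    abort("therapy events must be sorted by time.")
  }
  if (nrow(events) > 0L &&
      (min(events$time) < span_start || max(events$time) > span_end)) {
    abort("therapy events must lie within [span_start, span_end].")
  }
  cc <- pair_events(events, "c1", "c2", "C")
  dd <- pair_events(events, "d1", "d2", "D")
  covered <- bind_rows(cc, dd) |> arrange(.data$start)
  if (nrow(covered) > 1L) {
    overlap <- covered$start[-1L] < covered$end[-nrow(covered)]
    if (any(overlap)) {
      i <- which(overlap)[1L]
      abort(sprintf(
        "overlapping therapy annotations at t = %.3f s (corrupt annotations?)",
        covered$start[i + 1L]
      ))
    }
  }
  # Fill every uncovered region with H.
  bounds <- c(span_start, rbind(covered$start, covered$end), span_end)
  gaps <- tibble(
    start = bounds[seq(1L, length(bounds) - 1L, by = 2L)],
    end = bounds[seq(2L, length(bounds), by = 2L)],
    label = "H"
  ) |> filter(.data$end - .data$start > 0)
  intervals <- bind_rows(covered, gaps) |>
    arrange(.data$start) |>
    merge_runs()
  new_sequence(intervals, "therapy", span_start, span_end)
}

#' Build the response-domain sequence from rhythm-transition annotations
#'
#' Each annotation (`vf`, `vt`, `as`, `pe`, `pr`, `un`) opens the
#' corresponding upper-case rhythm state, which lasts until the next
#' annotation or `span_end`. The response domain starts at the first
#' annotation: it is undefined before the rhythm is first read, and is not
#' padded with UN.
#'
#' @param events A data frame with numeric `time` and character `code`
#'   columns; times strictly increasing.
#' @param span_end End of the episode in elapsed seconds.
#' @return A response-domain [new_sequence()].
#' @export
#' @examples
#' ev <- tibble::tibble(time = c(793.6, 908.3, 944.0), code = c("vf", "pe", "vf"))
#' build_response_sequence(ev, 1062.0)
build_response_sequence <- function(events, span_end) {
  events <- as_tibble(events)
  if (nrow(events) == 0L) {
    abort("response domain needs at least one rhythm annotation.")
  }
  bad <- setdiff(unique(events$code), response_codes)
  if (length(bad) > 0L) {
    abort(paste0("unknown rhythm event code(s): ", paste(bad, collapse = ", ")))
  }
  if (any(diff(events$time) <= 0)) {
    i <- which(diff(events$time) <= 0)[1L]
    abort(sprintf(
      "rhythm annotations must be strictly increasing in time (t = %.3f s)",
      events$time[i + 1L]
    ))
  }
  if (any(events$time >= span_end)) {
    abort("rhythm annotation at or after span_end.")
  }
  intervals <- tibble(
    start = events$time,
    end = c(events$time[-1L], span_end),
    label = toupper(events$code)
  ) |> merge_runs()
  new_sequence(intervals, "response", intervals$start[1L], span_end)
}

#' Recover the transition events that generated a sequence
#'
#' Inverse of the builders: the therapy domain yields `c1`/`c2` and `d1`/`d2`
#' pairs (H is implicit), the response domain one lower-case rhythm event per
#' state onset.
#'
#' @param x A therapy- or response-domain `rore_sequence`.
#' @return A tibble with `time` and `code` columns.
#' @export
sequence_events <- function(x) {
  stopifnot(inherits(x, "rore_sequence"))
  dom <- seq_domain(x)
  if (dom == "response") {
    return(tibble(time = x$start, code = tolower(x$label)))
  }
  if (dom != "therapy") {
    abort("sequence_events() is defined for therapy and response domains only.")
  }
  pieces <- x |> filter(.data$label != "H")
  open <- ifelse(pieces$label == "C", "c1", "d1")
  close <- ifelse(pieces$label == "C", "c2", "d2")
  tibble(
    time = c(rbind(pieces$start, pieces$end)),
    code = c(rbind(open, close))
  )
}
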