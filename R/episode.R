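#' Resuscitation episode
#'
#' Bundles everything known about one episode: the device power-on timestamp
#' (wall clock, or `NA` when unknown), the therapy and response domain
#' sequences, the shock records read from the device event log (time, energy
#' in J, transthoracic impedance in ohms) and the mode-switch records
#' (time, target mode `"manual"` or `"advisory"`).
#'
#' Every `D` interval of the therapy domain must correspond to exactly one
#' shock record (times within 1 ms): the defibrillation annotation and the
#' device's own "shock delivered" log line describe the same discharge.
#'
#' @param therapy,response Domain sequences from [build_therapy_sequence()]
#'   and [build_response_sequence()].
#' @param shocks Tibble with `time` (s), `energy_j`, `impedance_ohm`.
#' @param power_on Power-on timestamp (string or `POSIXct`), or `NA`.
#' @param mode_switches Tibble with `time` (s) and `mode`
#'   (`"manual"`/`"advisory"`). Default: none.
#' @param id Episode identifier carried through derived and audited tables.
#' @return A `rore_episode` object.
#' @export
rore_episode <- function(therapy, response, shocks,
                         power_on = NA, mode_switches = NULL, id = "episode") {
  stopifnot(inherits(therapy, "rore_sequence"), inherits(response, "rore_sequence"))
  shocks <- as_tibble(shocks)
  if (nrow(shocks) > 0L && is.unsorted(shocks$time)) {
    abort("shock records must be sorted ascending by time.")
  }
  d_starts <- therapy$start[therapy$label == "D"]
  if (length(d_starts) != nrow(shocks) ||
      (nrow(shocks) > 0L && any(abs(d_starts - shocks$time) > 1e-3))) {
    abort("each D interval in the therapy domain must match one shock record (1 ms tolerance).")
  }
  mode_switches <- as_tibble(
    mode_switches %||% tibble(time = double(), mode = character())
  )
  structure(
    list(
      id = id,
      power_on = power_on,
      therapy = therapy,
      response = response,
      shocks = shocks,
      mode_switches = mode_switches
    ),
    class = "rore_episode"
  )
}

#' @export
print.rore_episode <- function(x, ...) {
  sp <- seq_span(x$therapy)
  cat(sprintf(
    "<rore_episode '%s': span [%.1f, %.1f) s, %d shock(s), power on %s>\n",
    x$id, sp[1], sp[2], nrow(x$shocks),
    if (length(x$power_on) == 1L && is.na(x$power_on[[1L]])) "unknown" else as.character(x$power_on)
  ))
  invisible(x)
}

#' Assemble an episode from an event log and an annotation table
#'
#' The event log contributes the power-on timestamp, the shock records and
#' the mode switches; the annotation table contributes the therapy and
#' rhythm transition events. The therapy domain runs from power-on (elapsed
#' 0 s) to `span_end`; hands-off is assumed wherever nothing is annotated.
#'
#' @param log An event-log object from [read_event_log()] (or a list with
#'   `power_on`, `shocks`, `mode_switches`).
#' @param annotations A tibble of events (`time`, `code`) mixing therapy and
#'   rhythm codes.
#' @param span_end Episode end in elapsed seconds; defaults to the log's
#'   `"recording end"` entry, or failing that the latest annotated or
#'   logged time.
#' @param id Episode identifier.
#' @return A [rore_episode()].
#' @export
build_episode <- function(log, annotations, span_end = NULL, id = "episode") {
  annotations <- as_tibble(annotations) |> arrange(.data$time)
  therapy_ev <- annotations |> filter(.data$code %in% therapy_codes)
  rhythm_ev <- annotations |> filter(.data$code %in% response_codes)
  span_end <- span_end %||% log$span_end %||%
    max(annotations$time, log$shocks$time, 0)
  therapy <- build_therapy_sequence(therapy_ev, 0, span_end)
  response <- build_response_sequence(rhythm_ev, span_end)
  rore_episode(
    therapy, response, log$shocks,
    power_on = log$power_on, mode_switches = log$mode_switches, id = id
  )
}

#' Combined episode representation
#'
#' @param episode A [rore_episode()].
#' @return The combined-domain sequence ([combine_domains()] of the two
#'   domains).
#' @export
episode_representation <- function(episode) {
  combine_domains(episode$therapy, episode$response)
}
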