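#' Combine the therapy and response domains into the episode representation
#'
#' A change in either domain is a change of the combined state. The combined
#' sequence covers the intersection of the two spans; its transition times
#' are the union of both domains' transition times inside that window, and
#' each combined label is the therapy label concatenated with the rhythm
#' label active there (therapy first, e.g. `"HVF"`). Boundary coincidences
#' produce a single transition; zero-length pieces are discarded.
#'
#' @param therapy A therapy-domain [new_sequence()].
#' @param response A response-domain [new_sequence()].
#' @return A combined-domain `rore_sequence` over the span intersection.
#' @export
#' @examples
#' th <- build_therapy_sequence(
#'   tibble::tibble(
#'     time = c(805.2, 887.2, 903.3, 908.3, 938.8, 1062.0),
#'     code = c("c1", "c2", "d1", "d2", "c1", "c2")
#'   ),
#'   740.8, 1062.0
#' )
#' rs <- build_response_sequence(
#'   tibble::tibble(time = c(793.6, 908.3, 944.0), code = c("vf", "pe", "vf")),
#'   1062.0
#' )
#' combine_domains(th, rs)
combine_domains <- function(therapy, response) {
  stopifnot(inherits(therapy, "rore_sequence"), inherits(response, "rore_sequence"))
  if (nrow(therapy) == 0L || nrow(response) == 0L) {
    abort("both domain sequences must be non-empty.")
  }
  sp_t <- seq_span(therapy)
  sp_r <- seq_span(response)
  w0 <- max(sp_t[1], sp_r[1])
  w1 <- min(sp_t[2], sp_r[2])
  if (w0 >= w1) {
    abort("the therapy and response domains do not overlap in time.")
  }
  cuts <- sort(unique(c(
    w0, w1,
    therapy$start[therapy$start > w0 & therapy$start < w1],
    response$start[response$start > w0 & response$start < w1]
  )))
  starts <- cuts[-length(cuts)]
  intervals <- tibble(
    start = starts,
    end = cuts[-1L],
    label = paste0(state_at(therapy, starts), state_at(response, starts))
  )
  new_sequence(intervals, "combined", w0, w1)
}

#' Restrict a sequence to a time window
#'
#' Intervals are clipped to `[window_start, window_end)`; partially
#' overlapping intervals are truncated with their labels preserved. An empty
#' overlap is a valid outcome and yields an empty sequence.
#'
#' @param x A `rore_sequence`.
#' @param window_start,window_end Window bounds in elapsed seconds.
#' @return A `rore_sequence` of the same domain over the clipped window
#'   (empty, with NA span, when the window misses the sequence).
#' @export
restrict_sequence <- function(x, window_start, window_end) {
  stopifnot(inherits(x, "rore_sequence"))
  if (window_start >= window_end) {
    abort("window_start must be less than window_end.")
  }
  clipped <- x |>
    as_tibble() |>
    mutate(
      start = pmax(.data$start, window_start),
      end = pmin(.data$end, window_end)
    ) |>
    filter(.data$end - .data$start > 0)
  new_sequence(clipped, seq_domain(x))
}

#' State active at a time point
#'
#' Returns the label of the interval satisfying `start <= t < end`
#' (half-open convention: a boundary time belongs to the state that starts
#' there), or `NA` when `t` falls outside the sequence span.
#'
#' @param x A `rore_sequence`.
#' @param t Numeric vector of elapsed seconds.
#' @return Character vector of labels, `NA` where undefined.
#' @export
state_at <- function(x, t) {
  stopifnot(inherits(x, "rore_sequence"))
  if (nrow(x) == 0L) {
    return(rep(NA_character_, length(t)))
  }
  idx <- findInterval(t, x$start)
  out <- rep(NA_character_, length(t))
  hit <- idx >= 1L & t < x$end[pmax(idx, 1L)]
  out[hit] <- x$label[idx[hit]]
  out
}

#' Find the first or last interval carrying a label
#'
#' @param x A `rore_sequence`.
#' @param label State label to match exactly.
#' @param which `"first"` or `"last"` occurrence.
#' @return A one-row tibble (`start`, `end`, `label`), or `NULL` when the
#'   label is absent.
#' @export
find_label <- function(x, label, which = c("first", "last")) {
  stopifnot(inherits(x, "rore_sequence"))
  which <- match.arg(which)
  hits <- which(x$label == label)
  if (length(hits) == 0L) {
    return(NULL)
  }
  i <- if (which == "first") hits[1L] else hits[length(hits)]
  as_tibble(x)[i, c("start", "end", "label")]
}
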