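# Shared fixtures: the published worked example and oracle helpers.

# Therapy events and span of the worked tracing example.
worked_therapy_events <- function() {
  tibble::tibble(
    time = c(805.2, 887.2, 903.3, 908.3, 938.8, 1062.0),
    code = c("c1", "c2", "d1", "d2", "c1", "c2")
  )
}

worked_therapy <- function() {
  build_therapy_sequence(worked_therapy_events(), 740.8, 1062.0)
}

worked_response <- function() {
  build_response_sequence(
    tibble::tibble(time = c(793.6, 908.3, 944.0), code = c("vf", "pe", "vf")),
    1062.0
  )
}

# The published 7-state combined sequence for that tracing.
worked_combined_expected <- function() {
  tibble::tibble(
    start = c(793.6, 805.2, 887.2, 903.3, 908.3, 938.8, 944.0),
    end = c(805.2, 887.2, 903.3, 908.3, 938.8, 944.0, 1062.0),
    label = c("HVF", "CVF", "HVF", "DVF", "HPE", "CPE", "CVF")
  )
}

# Brute-force per-point therapy classifier: inside a c-pair -> C, inside a
# d-pair -> D, else H. Independent of the sequence builders.
brute_therapy_at <- function(t, events) {
  c1 <- events$time[events$code == "c1"]
  c2 <- events$time[events$code == "c2"]
  d1 <- events$time[events$code == "d1"]
  d2 <- events$time[events$code == "d2"]
  vapply(t, function(x) {
    if (any(c1 <= x & x < c2)) "C" else if (any(d1 <= x & x < d2)) "D" else "H"
  }, character(1))
}

# Brute-force response classifier: the state opened by the latest event at
# or before t.
brute_response_at <- function(t, events, span_end) {
  vapply(t, function(x) {
    if (x < events$time[1L] || x >= span_end) {
      return(NA_character_)
    }
    toupper(events$code[max(which(events$time <= x))])
  }, character(1))
}

# Random valid therapy annotations over [0, span]: alternating H/C blocks
# with occasional D insertions inside H.
random_therapy_events <- function(span = 60) {
  t <- round(runif(1, 0, span / 6), 1)
  out <- list()
  while (t < span - 2) {
    kind <- sample(c("c", "d"), 1, prob = c(0.8, 0.2))
    len <- round(runif(1, 0.5, span / 4), 1)
    t2 <- min(span, t + len)
    if (t2 - t > 0.05) {
      out[[length(out) + 1L]] <- tibble::tibble(
        time = c(t, t2), code = paste0(kind, c("1", "2"))
      )
    }
    t <- t2 + round(runif(1, 0.3, span / 6), 1)
  }
  if (length(out) == 0L) {
    tibble::tibble(time = numeric(), code = character())
  } else {
    dplyr::arrange(purrr::list_rbind(out), time)
  }
}

# Random strictly-increasing rhythm annotations over [start, span).
random_response_events <- function(span = 60) {
  n <- sample(1:6, 1)
  times <- round(sort(runif(n, 0, span - 1)), 1)
  times <- unique(times)
  tibble::tibble(
    time = times,
    code = sample(c("vf", "vt", "as", "pe", "pr", "un"), length(times), replace = TRUE)
  )
}
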