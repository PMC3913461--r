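#' Review-engine configuration
#'
#' Tunables of the derivation rules, all in seconds:
#'
#' * `shock_end_offset_s`: added to the shock time before the post-shock
#'   rhythm checkpoints are placed. `0` takes checkpoints from the moment of
#'   discharge; `3` treats the end of the shock as three seconds after
#'   delivery. Both are legitimate conventions; `0` is the default.
#' * `checkpoint_offsets_s`: post-shock rhythm checkpoint offsets
#'   (default 10, 30, 60, 120).
#' * `window_halfwidth_s`: half-width of the rhythm-reading window around
#'   each checkpoint (default 5): a transition into VF inside the window
#'   overrides the checkpoint rhythm, and a recent known rhythm may stand in
#'   for UN.
#' * `time_tolerance_s`: audit tolerance for time comparisons (default 1).
#'
#' @param shock_end_offset_s,checkpoint_offsets_s,window_halfwidth_s,time_tolerance_s
#'   See above.
#' @return A list of class `rore_config`.
#' @export
rore_config <- function(shock_end_offset_s = 0,
                        checkpoint_offsets_s = c(10, 30, 60, 120),
                        window_halfwidth_s = 5,
                        time_tolerance_s = 1) {
  stopifnot(
    shock_end_offset_s >= 0, window_halfwidth_s >= 0,
    length(checkpoint_offsets_s) == 4L, time_tolerance_s >= 0
  )
  structure(
    list(
      shock_end_offset_s = shock_end_offset_s,
      checkpoint_offsets_s = checkpoint_offsets_s,
      window_halfwidth_s = window_halfwidth_s,
      time_tolerance_s = time_tolerance_s
    ),
    class = "rore_config"
  )
}

#' @rdname rore_config
#' @param path A YAML or JSON file whose top-level keys are the arguments of
#'   `rore_config()`.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(rore_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(rore_config, vals)
}

#' Segment an episode into per-shock contexts
#'
#' Each shock gets a pre-shock window (from the previous shock, or the
#' beginning of the episode, BOE) and a post-shock window (to the next
#' shock, or the end of the episode, EOE). Windows are half-open at the
#' shock time, so a state opening exactly at the shock belongs to the
#' post-shock period, and the windows tile the episode span.
#'
#' @param episode A [rore_episode()].
#' @return A tibble with one row per shock: `shock_index`, `shock_time`,
#'   `pre_start`, `post_end`, and the boundary markers `pre_boundary`
#'   (`"BOE"`/`"shock"`) and `post_boundary` (`"shock"`/`"EOE"`).
#' @export
segment_shocks <- function(episode) {
  st <- episode$shocks$time
  sp <- seq_span(episode$therapy)
  if (length(st) == 0L) {
    inform("episode has no shocks; nothing to segment.")
    return(tibble(
      shock_index = integer(), shock_time = double(),
      pre_start = double(), post_end = double(),
      pre_boundary = character(), post_boundary = character()
    ))
  }
  tibble(
    shock_index = seq_along(st),
    shock_time = st,
    pre_start = c(sp[1], st[-length(st)]),
    post_end = c(st[-1L], sp[2]),
    pre_boundary = c("BOE", rep("shock", length(st) - 1L)),
    post_boundary = c(rep("shock", length(st) - 1L), "EOE")
  )
}

# Response label at q with the +/- window rules:
#  (a) a transition into VF within the window overrides to VF;
#  (b) UN at q falls back to the last known rhythm if that rhythm is still
#      present inside the window;
#  (c) q outside the response span reads as UN.
checkpoint_rhythm <- function(response, q, halfwidth) {
  lab <- state_at(response, q)
  vf_onsets <- response$start[response$label == "VF" &
    response$start > seq_span(response)[1]]
  if (any(vf_onsets >= q - halfwidth & vf_onsets <= q + halfwidth)) {
    return("VF")
  }
  if (is.na(lab)) {
    return("UN")
  }
  if (lab == "UN") {
    i <- findInterval(q, response$start)
    if (i >= 2L && response$label[i - 1L] != "UN" &&
        response$end[i - 1L] >= q - halfwidth) {
      return(response$label[i - 1L])
    }
  }
  lab
}

derive_time_variables <- function(ctx, episode, config = rore_config()) {
  th_pre <- restrict_sequence(episode$therapy, ctx$pre_start, ctx$shock_time)
  rs_post <- restrict_sequence(episode$response, ctx$shock_time, ctx$post_end)
  clk <- function(elapsed) elapsed_to_clock(elapsed, episode$power_on)

  ecgtm <- clk(0)
  shktm <- clk(ctx$shock_time)

  first_c <- find_label(th_pre, "C", "first")
  last_c <- find_label(th_pre, "C", "last")
  fc_ongoing <- FALSE
  if (is.null(first_c)) {
    fctm <- triplet_sentinel("no_cpr")
    lctm <- triplet_sentinel("no_cpr")
  } else {
    fctm <- clk(first_c$start)
    # last compression end == start of the last hands-off before the shock
    lctm <- clk(last_c$end)
    fc_ongoing <- abs(first_c$start - seq_span(episode$therapy)[1]) < 1e-9
  }

  resp_codes <- derive_response_variables(ctx, episode, config)
  if (nrow(rs_post) == 0L) {
    vfonsettm <- triplet_sentinel("no_data")
    rsctm <- triplet_sentinel("no_data")
  } else {
    persistent_vf <- resp_codes$rhyb4 == 2L && resp_codes$r10 == 2L &&
      resp_codes$r30 == 2L && resp_codes$r60 == 2L
    vf_onset <- response_onset(episode$response, "VF", ctx$shock_time, ctx$post_end)
    vfonsettm <- if (persistent_vf) {
      triplet_sentinel("unknown") # "no onset, patient remained in VF"
    } else if (is.na(vf_onset)) {
      triplet_sentinel("no_cpr") # no VF onset found in the post-shock window
    } else {
      clk(vf_onset)
    }
    pr_onset <- response_onset(episode$response, "PR", ctx$shock_time, ctx$post_end)
    rsctm <- if (is.na(pr_onset)) triplet_sentinel("unknown") else clk(pr_onset)
  }

  tibble(
    ecgtm = list(ecgtm), shktm = list(shktm),
    fctm = list(fctm), lctm = list(lctm),
    vfonsettm = list(vfonsettm), rsctm = list(rsctm),
    fc_ongoing = fc_ongoing
  )
}

# First transition INTO `state` strictly inside (after, before): an interval
# of that label whose own start lies in the open window. A state already
# ongoing at `after` is not an onset, and neither is the domain's first
# interval (its start marks where annotation begins, not a transition).
response_onset <- function(response, state, after, before) {
  cand <- response$start[response$label == state &
    response$start > seq_span(response)[1] &
    response$start > after & response$start < before]
  if (length(cand) == 0L) NA_real_ else cand[1L]
}

derive_response_variables <- function(ctx, episode, config = rore_config()) {
  response <- episode$response
  rs_post <- restrict_sequence(response, ctx$shock_time, ctx$post_end)

  init_lab <- response$label[1L]
  rhyb4_lab <- state_at(response, ctx$shock_time - 1e-9)
  rhyb4_lab <- if (is.na(rhyb4_lab)) "UN" else rhyb4_lab

  q0 <- ctx$shock_time + config$shock_end_offset_s
  checks <- vapply(
    config$checkpoint_offsets_s,
    function(d) checkpoint_rhythm(response, q0 + d, config$window_halfwidth_s),
    character(1)
  )

  # presence variables over the open post-shock window (shock_time, post_end)
  post_open <- rs_post |> filter(.data$end > ctx$shock_time)
  labs <- post_open$label
  presence <- function(targets) {
    if (any(labs %in% targets)) {
      1L
    } else if (any(labs != "UN")) {
      2L
    } else {
      9L
    }
  }
  vfpr <- presence("VF")
  orgpr <- presence(c("PE", "PR"))
  rosc <- if (length(labs) == 0L) {
    9L
  } else if (any(labs == "PR")) {
    1L
  } else {
    2L
  }

  tibble(
    init_rhy = rhythm_code_map[[init_lab]],
    rhyb4 = rhythm_code_map[[rhyb4_lab]],
    r10 = rhythm_code_map[[checks[1L]]],
    r30 = rhythm_code_map[[checks[2L]]],
    r60 = rhythm_code_map[[checks[3L]]],
    r120 = rhythm_code_map[[checks[4L]]],
    vfpr = vfpr, orgpr = orgpr, rosc = rosc
  )
}

derive_device_variables <- function(ctx, episode, config = rore_config()) {
  shocks <- episode$shocks
  k <- ctx$shock_index
  th_pre <- restrict_sequence(episode$therapy, ctx$pre_start, ctx$shock_time)

  # stacked-shock runs: successive shocks belong to one run when no
  # compression interval lies between them
  runs <- shock_runs(episode)

  mode <- if (nrow(episode$mode_switches) == 0L) {
    "advisory"
  } else {
    before <- episode$mode_switches |> filter(.data$time < ctx$shock_time)
    if (nrow(before) == 0L) "advisory" else before$mode[nrow(before)]
  }

  cpr <- if (!is.null(find_label(th_pre, "C", "first"))) 1L else 2L

  tibble(
    shkn = k,
    ssrecord = nrow(shocks),
    shks = runs$run_size[k],
    mode = if (mode == "manual") 1L else 2L,
    cpr = cpr,
    imp = ifelse(is.na(shocks$impedance_ohm[k]), 999L,
      as.integer(round(shocks$impedance_ohm[k]))
    ),
    enrgy = ifelse(is.na(shocks$energy_j[k]), 999L,
      as.integer(round(shocks$energy_j[k]))
    )
  )
}

# Decompose the shock train into maximal runs of consecutive shocks with no
# compression between successive members; every member reports the run size.
shock_runs <- function(episode) {
  st <- episode$shocks$time
  n <- length(st)
  if (n == 0L) {
    return(tibble(run_id = integer(), run_size = integer()))
  }
  c_iv <- episode$therapy |> filter(.data$label == "C")
  linked <- vapply(seq_len(max(n - 1L, 0L)), function(i) {
    !any(c_iv$start < st[i + 1L] & c_iv$end > st[i])
  }, logical(1))
  run_id <- cumsum(c(TRUE, !linked))
  sizes <- as.integer(table(run_id))
  tibble(run_id = run_id, run_size = sizes[run_id])
}

#' Derive the review database from an episode
#'
#' Runs the full automated review: segments the episode around each shock,
#' and derives for every shock the six time variables (as hr/mn/sc
#' triplets), the nine response variables (registry codes), and the seven
#' device/therapy variables. Derivation is a pure function of the episode
#' and the configuration.
#'
#' @param episode A [rore_episode()].
#' @param config A [rore_config()].
#' @return A tibble with one row per shock in the review-database column
#'   layout (see [read_database()]), plus the `fc_ongoing` flag marking a
#'   first compression already ongoing at the start of recording.
#' @export
#' @examples
#' ep <- simulate_episode(seed = 7)$episode
#' derive_review(ep)
derive_review <- function(episode, config = rore_config()) {
  contexts <- segment_shocks(episode)
  if (nrow(contexts) == 0L) {
    return(tibble())
  }
  rows <- purrr::map(seq_len(nrow(contexts)), function(i) {
    ctx <- as.list(contexts[i, ])
    tv <- derive_time_variables(ctx, episode, config)
    rv <- derive_response_variables(ctx, episode, config)
    dv <- derive_device_variables(ctx, episode, config)
    trip_cols <- function(t, prefix) {
      setNames(as.list(t[1, ]), paste0(prefix, c("hr", "mn", "sc")))
    }
    as_tibble(c(
      list(episode = episode$id),
      list(shkn = dv$shkn),
      trip_cols(tv$ecgtm[[1L]], "ecg"),
      trip_cols(tv$fctm[[1L]], "fc"),
      trip_cols(tv$lctm[[1L]], "lc"),
      trip_cols(tv$shktm[[1L]], "shk"),
      trip_cols(tv$vfonsettm[[1L]], "vfonset"),
      trip_cols(tv$rsctm[[1L]], "rsc"),
      as.list(rv),
      as.list(dv[, c("ssrecord", "shks", "mode", "cpr", "imp", "enrgy")]),
      list(fc_ongoing = tv$fc_ongoing)
    ))
  })
  list_rbind(rows)
}
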