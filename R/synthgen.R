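#' Simulate a resuscitation episode with ground truth
#'
#' Generates an internally consistent synthetic episode: an alternating
#' compression / hands-off therapy timeline with defibrillations placed
#' inside hands-off intervals (compressions pause for a shock), a
#' semi-Markov rhythm process over \{VF, VT, AS, PE, PR\} with
#' state-specific exponential dwell times and an optional forced transition
#' shortly after a shock, optionally an unknown-rhythm tail when the
#' recording is cut short, and a device event log (power-on timestamp,
#' shock energies and impedances, mode switches). All generated times are on
#' a 0.1 s grid.
#'
#' The ground-truth review rows are computed analytically from the raw
#' generated timeline (compression table, shock table, rhythm segment
#' table), by a code path independent of the state-sequence algebra and the
#' reasoning engine, so recovery tests compare two genuinely separate
#' derivations.
#'
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param duration_range_s Episode duration drawn uniformly from this range.
#' @param shock_count_range Range of the number of shocks (uniform over the
#'   integers; capped by the available hands-off room).
#' @param stacked_shock_prob Probability that a shock is followed by a
#'   second, stacked shock with no intervening compressions.
#' @param rhythm_dwell_means_s Named vector of mean dwell times (s) per
#'   rhythm state.
#' @param compression_mean_s,handsoff_mean_s Mean compression-sequence and
#'   hands-off durations (s) of the therapy duty cycle.
#' @param defib_duration_s Duration of the defibrillation (D) state.
#' @param post_shock_transition_prob Probability that a shock forces a
#'   rhythm transition 1-8 s after delivery.
#' @param unknown_tail_prob Probability that the rhythm annotation ends
#'   before the episode does, leaving an UN tail.
#' @param energy_levels_j Shock energies sampled uniformly from this set.
#' @param impedance_range_ohm Impedance drawn uniformly (whole ohms).
#' @param manual_mode_prob Probability of a switch into manual mode before
#'   the first shock (the device starts in advisory mode).
#' @param power_on Wall-clock power-on timestamp; `NULL` draws one.
#' @param config [rore_config()] used for the ground-truth rules.
#' @param id Episode identifier.
#' @return A list: `episode` ([rore_episode()]), `log` (event-log list),
#'   `annotations` (events tibble), `truth` (ground-truth database rows) and
#'   `timeline` (the raw generated components).
#' @export
#' @examples
#' sim <- simulate_episode(seed = 1)
#' sim$episode
#' sim$truth
simulate_episode <- function(seed = NULL,
                             duration_range_s = c(600, 1800),
                             shock_count_range = c(1, 5),
                             stacked_shock_prob = 0.2,
                             rhythm_dwell_means_s = c(
                               VF = 120, VT = 60, AS = 90, PE = 80, PR = 150
                             ),
                             compression_mean_s = 90,
                             handsoff_mean_s = 15,
                             defib_duration_s = 5,
                             post_shock_transition_prob = 0.6,
                             unknown_tail_prob = 0.3,
                             energy_levels_j = c(150, 200, 360),
                             impedance_range_ohm = c(50, 150),
                             manual_mode_prob = 0.15,
                             power_on = NULL,
                             config = rore_config(),
                             id = "episode") {
  if (!is.null(seed)) set.seed(seed)
  if (shock_count_range[1] < 1) {
    abort("shock_count_range must allow at least one shock.")
  }
  duration <- round(runif(1, duration_range_s[1], duration_range_s[2]), 1)

  # therapy duty cycle: leading hands-off, then alternating C / H
  t <- round(runif(1, 45, 70), 1)
  comps <- list()
  hoffs <- list(tibble(start = 0, end = t))
  repeat {
    c_end <- min(duration, t + round(pmax(20, pmin(180, rexp(1, 1 / compression_mean_s))), 1))
    if (c_end - t > 0.05) comps[[length(comps) + 1L]] <- tibble(start = t, end = c_end)
    if (c_end >= duration) break
    h_end <- min(duration, c_end + round(runif(1, 8, max(8.1, 2 * handsoff_mean_s)), 1))
    if (h_end - c_end > 0.05) {
      hoffs[[length(hoffs) + 1L]] <- tibble(start = c_end, end = h_end)
    }
    if (h_end >= duration) break
    t <- h_end
  }
  comps <- list_rbind(comps)
  hoffs <- list_rbind(hoffs)

  # rhythm annotation begins once the leads are on
  rhythm_start <- round(runif(1, 20, 40), 1)

  # shocks inside hands-off intervals long enough for the discharge, and
  # only after the rhythm is being read (the device analyses before it
  # advises a shock)
  room <- defib_duration_s + 2
  eligible <- hoffs |> filter(
    .data$end - .data$start >= room + 6,
    .data$end - room - 5 > rhythm_start + 5
  )
  n_target <- sample(seq(shock_count_range[1], shock_count_range[2]), 1)
  if (nrow(eligible) == 0L) {
    abort("infeasible parameters: no hands-off interval can host a shock.")
  }
  n_slots <- min(n_target, nrow(eligible))
  slots <- eligible[sort(sample(nrow(eligible), n_slots)), ]
  shock_times <- double()
  for (i in seq_len(nrow(slots))) {
    lo <- max(slots$start[i] + 1, rhythm_start + 5)
    s <- round(runif(1, lo, max(lo, slots$end[i] - room - 5)), 1)
    shock_times <- c(shock_times, s)
    if (runif(1) < stacked_shock_prob &&
        slots$end[i] - (s + defib_duration_s) >= room + 2) {
      shock_times <- c(
        shock_times,
        round(s + defib_duration_s + runif(1, 1, 2), 1)
      )
    }
  }
  shock_times <- sort(shock_times)
  defibs <- tibble(start = shock_times, end = shock_times + defib_duration_s)
  shocks <- tibble(
    time = shock_times,
    energy_j = sample(energy_levels_j, length(shock_times), replace = TRUE),
    impedance_ohm = round(runif(
      length(shock_times), impedance_range_ohm[1], impedance_range_ohm[2]
    ))
  )

  # semi-Markov rhythm process, with optional forced post-shock transition
  init_probs <- c(VF = 0.7, AS = 0.15, PE = 0.15)
  trans <- list(
    VF = c(AS = 0.3, PE = 0.4, VT = 0.1, PR = 0.2),
    VT = c(VF = 0.5, PE = 0.3, PR = 0.2),
    AS = c(VF = 0.3, PE = 0.5, PR = 0.2),
    PE = c(VF = 0.3, AS = 0.2, PR = 0.5),
    PR = c(PE = 0.5, VF = 0.3, AS = 0.2)
  )
  post_shock_probs <- c(AS = 0.4, PE = 0.4, PR = 0.2)
  draw <- function(p) sample(names(p), 1, prob = p)

  tr <- rhythm_start
  state <- draw(init_probs)
  seg <- list()
  while (tr < duration) {
    dwell <- round(pmax(15, pmin(400, rexp(1, 1 / rhythm_dwell_means_s[[state]]))), 1)
    t_next <- tr + dwell
    forced <- FALSE
    hit <- shock_times[shock_times > tr & shock_times < min(t_next, duration)]
    if (length(hit) > 0L && runif(1) < post_shock_transition_prob) {
      cand <- round(hit[1L] + runif(1, 1, 8), 1)
      if (cand > tr && cand < duration) {
        t_next <- cand
        forced <- TRUE
      }
    }
    seg[[length(seg) + 1L]] <- tibble(
      start = tr, end = min(t_next, duration), state = state
    )
    tr <- t_next
    state <- if (forced) {
      p <- post_shock_probs[names(post_shock_probs) != state]
      draw(p)
    } else {
      draw(trans[[state]])
    }
  }
  rhythm <- list_rbind(seg)

  if (runif(1) < unknown_tail_prob && duration - rhythm$start[1L] > 60) {
    cut <- round(runif(1, 0.7, 0.95) * duration, 1)
    if (cut > rhythm$start[1L] + 1) {
      rhythm <- rhythm |> filter(.data$start < cut) |>
        mutate(end = pmin(.data$end, cut))
      rhythm <- bind_rows(rhythm, tibble(start = cut, end = duration, state = "UN"))
    }
  }

  mode_switches <- tibble(time = double(), mode = character())
  if (runif(1) < manual_mode_prob) {
    mode_switches <- tibble(
      time = round(runif(1, 5, max(6, shock_times[1L] - 2)), 1),
      mode = "manual"
    )
  }

  if (is.null(power_on)) {
    power_on <- sprintf(
      "2012-%02d-%02d %02d:%02d:%02d",
      sample(12, 1), sample(28, 1), sample(0:23, 1), sample(0:59, 1), sample(0:59, 1)
    )
  }

  timeline <- list(
    id = id, duration = duration, power_on = power_on,
    compressions = comps, defibs = defibs, shocks = shocks,
    rhythm = rhythm, mode_switches = mode_switches
  )

  annotations <- bind_rows(
    tibble(
      time = c(rbind(comps$start, comps$end)),
      code = rep(c("c1", "c2"), nrow(comps))
    ),
    tibble(
      time = c(rbind(defibs$start, defibs$end)),
      code = rep(c("d1", "d2"), nrow(defibs))
    ),
    tibble(time = rhythm$start, code = tolower(rhythm$state))
  ) |> arrange(.data$time)

  log <- structure(
    list(
      power_on = power_on, shocks = shocks,
      mode_switches = mode_switches, span_end = duration,
      entries = NULL
    ),
    class = "rore_event_log"
  )

  episode <- build_episode(log, annotations, span_end = duration, id = id)
  truth <- timeline_truth(timeline, config)
  list(
    episode = episode, log = log, annotations = annotations,
    truth = truth, timeline = timeline
  )
}

# Ground-truth review rows computed directly from the raw timeline tables.
# Deliberately does NOT use rore_sequence objects, restrict/state_at or the
# reasoning engine: this is the independent oracle the recovery tests
# compare against.
timeline_truth <- function(tl, config = rore_config()) {
  st <- tl$shocks$time
  n <- length(st)
  pre_start <- c(0, st[-n])
  post_end <- c(st[-1L], tl$duration)
  rh <- tl$rhythm
  h <- config$window_halfwidth_s

  r_at <- function(q) {
    i <- which(rh$start <= q & q < rh$end)
    if (length(i) == 0L) NA_character_ else rh$state[i[1L]]
  }
  vf_onset_times <- rh$start[rh$state == "VF" & seq_len(nrow(rh)) > 1L]
  check_rhythm <- function(q) {
    if (any(vf_onset_times >= q - h & vf_onset_times <= q + h)) {
      return("VF")
    }
    s <- r_at(q)
    if (is.na(s)) {
      return("UN")
    }
    if (s == "UN") {
      i <- which(rh$start <= q & q < rh$end)[1L]
      if (i >= 2L && rh$state[i - 1L] != "UN" && rh$end[i - 1L] >= q - h) {
        return(rh$state[i - 1L])
      }
    }
    s
  }
  clk <- function(elapsed) elapsed_to_clock(elapsed, tl$power_on)
  code_of <- function(s) rhythm_code_map[[s]]

  rows <- purrr::map(seq_len(n), function(k) {
    w0 <- pre_start[k]
    s_t <- st[k]
    w1 <- post_end[k]

    comps_in <- tl$compressions |>
      filter(.data$start >= w0, .data$start < s_t)
    if (nrow(comps_in) == 0L) {
      fctm <- triplet_sentinel("no_cpr")
      lctm <- triplet_sentinel("no_cpr")
      cpr <- 2L
    } else {
      fctm <- clk(min(comps_in$start))
      lctm <- clk(max(comps_in$end))
      cpr <- 1L
    }

    b4 <- r_at(s_t - 1e-9)
    rhyb4 <- code_of(if (is.na(b4)) "UN" else b4)
    q0 <- s_t + config$shock_end_offset_s
    cks <- vapply(
      config$checkpoint_offsets_s, function(d) check_rhythm(q0 + d), character(1)
    )
    r10 <- code_of(cks[1L]); r30 <- code_of(cks[2L])
    r60 <- code_of(cks[3L]); r120 <- code_of(cks[4L])

    inter <- rh |> filter(.data$end > s_t, .data$start < w1)
    covered <- nrow(inter) > 0L
    vfpr <- if (any(inter$state == "VF")) 1L else if (any(inter$state != "UN")) 2L else 9L
    orgpr <- if (any(inter$state %in% c("PE", "PR"))) 1L else if (any(inter$state != "UN")) 2L else 9L
    rosc <- if (!covered) 9L else if (any(inter$state == "PR")) 1L else 2L

    if (!covered) {
      vfonsettm <- triplet_sentinel("no_data")
      rsctm <- triplet_sentinel("no_data")
    } else {
      persistent <- rhyb4 == 2L && r10 == 2L && r30 == 2L && r60 == 2L
      vf_on <- vf_onset_times[vf_onset_times > s_t & vf_onset_times < w1]
      vfonsettm <- if (persistent) {
        triplet_sentinel("unknown")
      } else if (length(vf_on) == 0L) {
        triplet_sentinel("no_cpr")
      } else {
        clk(vf_on[1L])
      }
      pr_on <- rh$start[rh$state == "PR" & seq_len(nrow(rh)) > 1L &
        rh$start > s_t & rh$start < w1]
      rsctm <- if (length(pr_on) == 0L) triplet_sentinel("unknown") else clk(pr_on[1L])
    }

    # stacked-shock run containing shock k, by brute-force linkage
    linked_prev <- function(i) {
      !any(tl$compressions$start < st[i] & tl$compressions$end > st[i - 1L])
    }
    lo <- k
    while (lo > 1L && linked_prev(lo)) lo <- lo - 1L
    hi <- k
    while (hi < n && linked_prev(hi + 1L)) hi <- hi + 1L

    ms <- tl$mode_switches |> filter(.data$time < s_t)
    mode <- if (nrow(ms) == 0L) 2L else if (ms$mode[nrow(ms)] == "manual") 1L else 2L

    trip_cols <- function(t, prefix) {
      setNames(as.list(t[1, ]), paste0(prefix, c("hr", "mn", "sc")))
    }
    as_tibble(c(
      list(episode = tl$id, shkn = k),
      trip_cols(clk(0), "ecg"),
      trip_cols(fctm, "fc"),
      trip_cols(lctm, "lc"),
      trip_cols(clk(s_t), "shk"),
      trip_cols(vfonsettm, "vfonset"),
      trip_cols(rsctm, "rsc"),
      list(
        init_rhy = code_of(rh$state[1L]), rhyb4 = rhyb4,
        r10 = r10, r30 = r30, r60 = r60, r120 = r120,
        vfpr = vfpr, orgpr = orgpr, rosc = rosc,
        ssrecord = n, shks = hi - lo + 1L, mode = mode, cpr = cpr,
        imp = as.integer(round(tl$shocks$impedance_ohm[k])),
        enrgy = as.integer(round(tl$shocks$energy_j[k]))
      )
    ))
  })
  list_rbind(rows)
}

#' Simulate a cohort of episodes
#'
#' Convenience wrapper: simulates `n` episodes (ids `ep001`, `ep002`, ...),
#' stacks their ground-truth rows, and runs the review engine over each
#' episode to produce the derived database.
#'
#' @param n Number of episodes.
#' @param seed Integer seed for the whole cohort.
#' @param config [rore_config()] shared by truth and derivation.
#' @param ... Passed on to [simulate_episode()].
#' @return A list: `episodes` (list of per-episode bundles), `truth` and
#'   `derived` (stacked database tibbles).
#' @export
simulate_cohort <- function(n, seed = 1, config = rore_config(), ...) {
  set.seed(seed)
  episodes <- purrr::map(seq_len(n), function(i) {
    simulate_episode(seed = NULL, config = config, id = sprintf("ep%03d", i), ...)
  })
  truth <- list_rbind(map(episodes, "truth"))
  derived <- list_rbind(map(episodes, function(e) derive_review(e$episode, config)))
  list(episodes = episodes, truth = truth, derived = derived)
}

#' Inject sentinel and placeholder codes into a review database
#'
#' Emulates the missing-value habits of manual registries: time-variable
#' triplets are replaced by `99:99:99`, `88:88:88` or `66:66:66` sentinels
#' or by the `00:00:00` placeholder literal, and optionally jittered by a
#' few whole seconds to create near-miss deviations. Used to exercise the
#' audit coder's missing taxonomy and tolerance behaviour.
#'
#' @param rows A review-database tibble.
#' @param rates Named numeric vector of per-cell injection probabilities for
#'   `unknown`, `no_cpr`, `no_data`, `literal` and `jitter`.
#' @param jitter_range_s Whole-second deviation range used for `jitter`.
#' @param seed Integer seed.
#' @return A list: `rows` (the corrupted copy) and `injected` (a tibble of
#'   `episode`, `shkn`, `variable`, `kind` naming every touched cell).
#' @export
corrupt_database <- function(rows,
                             rates = c(
                               unknown = 0.05, no_cpr = 0.02, no_data = 0.01,
                               literal = 0.01, jitter = 0.05
                             ),
                             jitter_range_s = c(2, 5),
                             seed = 1) {
  set.seed(seed)
  rows <- as_tibble(rows)
  kinds <- c("unknown", "no_cpr", "no_data", "literal", "jitter")
  rates <- rates[kinds]
  rates[is.na(rates)] <- 0
  injected <- list()
  for (var in names(time_variable_prefixes)) {
    p <- time_variable_prefixes[[var]]
    cols <- paste0(p, c("hr", "mn", "sc"))
    for (i in seq_len(nrow(rows))) {
      u <- runif(1)
      kind <- kinds[findInterval(u, cumsum(rates)) + 1L][1L]
      if (is.na(kind)) next
      trip <- clock_triplet(rows[[cols[1]]][i], rows[[cols[2]]][i], rows[[cols[3]]][i])
      new <- switch(kind,
        unknown = triplet_sentinel("unknown"),
        no_cpr = triplet_sentinel("no_cpr"),
        no_data = triplet_sentinel("no_data"),
        literal = clock_triplet(0, 0, 0),
        jitter = {
          if (classify_triplet(trip) != "valid") next
          s <- (triplet_seconds(trip) +
            sample(c(-1L, 1L), 1) * sample(seq(jitter_range_s[1], jitter_range_s[2]), 1)) %% 86400L
          clock_triplet(s %/% 3600L, (s %% 3600L) %/% 60L, s %% 60L)
        }
      )
      rows[[cols[1]]][i] <- new$hr
      rows[[cols[2]]][i] <- new$mn
      rows[[cols[3]]][i] <- new$sc
      injected[[length(injected) + 1L]] <- tibble(
        episode = rows$episode[i], shkn = rows$shkn[i],
        variable = var, kind = kind
      )
    }
  }
  list(
    rows = rows,
    injected = if (length(injected) == 0L) {
      tibble(episode = character(), shkn = integer(),
             variable = character(), kind = character())
    } else {
      list_rbind(injected)
    }
  )
}
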