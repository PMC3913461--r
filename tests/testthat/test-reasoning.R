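# A small hand-built episode mirroring the published case-study segment:
# power on 14:30:00, VF from 46 s, shock at 198 s, compressions 201-322 s,
# AS at 208 s, PE at 258 s, VF recurring at 283 s, trace to 343 s.
case_study_episode <- function() {
  ann <- tibble::tibble(
    time = c(46, 198, 203, 201, 322, 208, 258, 283),
    code = c("vf", "d1", "d2", "c1", "c2", "as", "pe", "vf")
  )
  # compressions annotated 204-322 so they do not overlap the discharge
  ann <- tibble::tibble(
    time = c(46, 208, 258, 283, 198, 203, 204, 322),
    code = c("vf", "as", "pe", "vf", "d1", "d2", "c1", "c2")
  )
  log <- list(
    power_on = "2012-03-01 14:30:00",
    shocks = tibble::tibble(time = 198, energy_j = 150, impedance_ohm = 85),
    mode_switches = tibble::tibble(time = double(), mode = character())
  )
  build_episode(log, ann, span_end = 343, id = "case")
}

test_that("shock segmentation tiles the episode between BOE and EOE", {
  ep <- case_study_episode()
  ctx <- segment_shocks(ep)
  expect_equal(nrow(ctx), 1L)
  expect_identical(ctx$pre_boundary, "BOE")
  expect_identical(ctx$post_boundary, "EOE")
  expect_equal(ctx$pre_start, 0)
  expect_equal(ctx$post_end, 343)

  set.seed(50)
  for (i in 1:20) {
    sim <- simulate_episode(seed = NULL)
    ctx <- segment_shocks(sim$episode)
    sp <- seq_span(sim$episode$therapy)
    # windows tile: pre of shock 1 starts at BOE, post of last ends at EOE,
    # and post of k abuts pre of k+1 at the shock time
    expect_equal(ctx$pre_start[1], sp[1])
    expect_equal(ctx$post_end[nrow(ctx)], sp[2])
    if (nrow(ctx) > 1L) {
      expect_equal(ctx$post_end[-nrow(ctx)], ctx$shock_time[-1L])
      expect_equal(ctx$pre_start[-1L], ctx$shock_time[-nrow(ctx)])
    }
  }
})

test_that("first/last compression times follow the published pre-shock search", {
  # pre-shock window of the worked tracing: first C starts 805.2, last ends 887.2
  log <- list(
    power_on = "2012-03-01 14:30:00",
    shocks = tibble::tibble(time = 903.3, energy_j = 200, impedance_ohm = 90),
    mode_switches = tibble::tibble(time = double(), mode = character())
  )
  ev <- dplyr::bind_rows(
    worked_therapy_events(),
    tibble::tibble(time = c(793.6, 908.3, 944.0), code = c("vf", "pe", "vf"))
  )
  ep <- build_episode(log, ev, span_end = 1062.0)
  row <- derive_review(ep)
  # 805.2 s and 887.2 s after 14:30:00 (round-half-up to whole seconds)
  expect_equal(unlist(row[, c("fchr", "fcmn", "fcsc")], use.names = FALSE),
    c(14L, 43L, 25L)) # 805.2 -> 805 s -> 14:43:25
  expect_equal(unlist(row[, c("lchr", "lcmn", "lcsc")], use.names = FALSE),
    c(14L, 44L, 47L)) # 887.2 -> 887 s -> 14:44:47
  expect_false(row$fc_ongoing)
})

test_that("the case-study checkpoints and VF onset are derived as published", {
  ep <- case_study_episode()
  row <- derive_review(ep) # default shock-end offset 0
  expect_equal(row$rhyb4, 2L) # VF immediately pre-shock
  expect_equal(row$r10, 1L) # asystole at 208 s
  expect_equal(row$r30, 1L) # still asystole at 228 s
  expect_equal(row$r60, 4L) # organized (PE) at 258 s
  expect_equal(row$r120, 2L) # VF again at 318 s
  # VF onset = recurrence at 283 s -> 14:34:43
  expect_equal(
    unlist(row[, c("vfonsethr", "vfonsetmn", "vfonsetsc")], use.names = FALSE),
    c(14L, 34L, 43L)
  )
  expect_equal(row$vfpr, 1L)
  expect_equal(row$orgpr, 1L)
  expect_equal(row$rosc, 2L) # no pulse-giving rhythm annotated
  expect_equal(row$cpr, 2L) # no compressions before this first shock
})

test_that("persistent VF yields the 99 sentinel for VF onset", {
  ann <- tibble::tibble(
    time = c(10, 100, 105, 110, 300),
    code = c("vf", "d1", "d2", "c1", "c2")
  )
  log <- list(
    power_on = "2012-03-01 14:30:00",
    shocks = tibble::tibble(time = 100, energy_j = 200, impedance_ohm = 70),
    mode_switches = tibble::tibble(time = double(), mode = character())
  )
  ep <- build_episode(log, ann, span_end = 400)
  row <- derive_review(ep)
  expect_equal(c(row$rhyb4, row$r10, row$r30, row$r60), rep(2L, 4))
  expect_equal(
    unlist(row[, c("vfonsethr", "vfonsetmn", "vfonsetsc")], use.names = FALSE),
    c(99L, 99L, 99L)
  )

  # but VF pre-shock with unknown at 10 s is NOT persistent VF (the unknown
  # starts early enough that no window rule can bridge it)
  ann2 <- tibble::tibble(
    time = c(10, 100, 103, 105, 250),
    code = c("vf", "d1", "un", "d2", "vf")
  )
  ep2 <- build_episode(log, ann2, span_end = 400)
  row2 <- derive_review(ep2)
  expect_equal(row2$r10, 9L)
  # VF onset found at its 250 s recurrence instead
  expect_equal(
    unlist(row2[, c("vfonsethr", "vfonsetmn", "vfonsetsc")], use.names = FALSE),
    c(14L, 34L, 10L)
  )
})

test_that("checkpoint window rules override to VF and bridge unknown gaps", {
  cfg <- rore_config(window_halfwidth_s = 5)
  log <- list(
    power_on = "2012-03-01 14:30:00",
    shocks = tibble::tibble(time = 100, energy_j = 200, impedance_ohm = 70),
    mode_switches = tibble::tibble(time = double(), mode = character())
  )
  # VF onset at 113 s: within +/-5 s of the 10 s checkpoint (110 s)
  ann <- tibble::tibble(
    time = c(10, 100, 105, 106, 113),
    code = c("vf", "d1", "d2", "as", "vf")
  )
  ep <- build_episode(log, ann, span_end = 400)
  expect_equal(derive_review(ep, cfg)$r10, 2L)

  # UN starting 158 s: at the 60 s checkpoint (160 s) the last known rhythm
  # (PE) is still inside the window, so it stands in for UN
  ann2 <- tibble::tibble(
    time = c(10, 100, 105, 106, 158),
    code = c("vf", "d1", "d2", "pe", "un")
  )
  ep2 <- build_episode(log, ann2, span_end = 400)
  row2 <- derive_review(ep2, cfg)
  expect_equal(row2$r60, 4L)
  # at 120 s the UN tail started long before the window: unknown
  expect_equal(row2$r120, 9L)
})

test_that("a recording that ends before a checkpoint reads as unknown", {
  log <- list(
    power_on = "2012-03-01 14:30:00",
    shocks = tibble::tibble(time = 100, energy_j = 200, impedance_ohm = 70),
    mode_switches = tibble::tibble(time = double(), mode = character())
  )
  ann <- tibble::tibble(
    time = c(10, 100, 105, 106),
    code = c("vf", "d1", "d2", "pe")
  )
  ep <- build_episode(log, ann, span_end = 211) # ends 111 s after the shock
  row <- derive_review(ep)
  expect_equal(row$r60, 4L)
  expect_equal(row$r120, 9L)
})

test_that("the shock-end offset shifts the checkpoints", {
  # transition to AS at 211 s: 10 s checkpoint reads VF at offset 0 (210 s
  # is still VF and no VF onset window hit) but AS at offset 3 (213 s)
  log <- list(
    power_on = "2012-03-01 14:30:00",
    shocks = tibble::tibble(time = 198, energy_j = 150, impedance_ohm = 85),
    mode_switches = tibble::tibble(time = double(), mode = character())
  )
  ann <- tibble::tibble(
    time = c(46, 198, 203, 211),
    code = c("vf", "d1", "d2", "as")
  )
  ep <- build_episode(log, ann, span_end = 343)
  expect_equal(derive_review(ep, rore_config(shock_end_offset_s = 0))$r10, 2L)
  expect_equal(derive_review(ep, rore_config(shock_end_offset_s = 3))$r10, 1L)
})

test_that("stacked-shock runs are decomposed as maximal runs", {
  # three shocks, no compressions between 1 and 2, compressions before 3
  ann <- tibble::tibble(
    time = c(10, 100, 105, 107, 112, 150, 200, 220, 225, 400),
    code = c("vf", "d1", "d2", "d1", "d2", "c1", "c2", "d1", "d2", "un")
  )
  log <- list(
    power_on = "2012-03-01 14:30:00",
    shocks = tibble::tibble(
      time = c(100, 107, 220),
      energy_j = c(150, 200, 360), impedance_ohm = c(70, 72, 75)
    ),
    mode_switches = tibble::tibble(time = double(), mode = character())
  )
  ep <- build_episode(log, ann, span_end = 500)
  rows <- derive_review(ep)
  expect_equal(rows$shks, c(2L, 2L, 1L))
  expect_equal(rows$shkn, 1:3)
  expect_equal(rows$ssrecord, rep(3L, 3))
  # cpr per pre-shock window
  expect_equal(rows$cpr, c(2L, 2L, 1L))
})

test_that("mode is taken from the latest switch before the shock", {
  ann <- tibble::tibble(
    time = c(10, 100, 105), code = c("vf", "d1", "d2")
  )
  base_log <- function(ms) {
    list(
      power_on = "2012-03-01 14:30:00",
      shocks = tibble::tibble(time = 100, energy_j = 150, impedance_ohm = 85),
      mode_switches = ms
    )
  }
  ep_adv <- build_episode(
    base_log(tibble::tibble(time = 5, mode = "advisory")), ann, span_end = 200
  )
  expect_equal(derive_review(ep_adv)$mode, 2L)
  ep_man <- build_episode(
    base_log(tibble::tibble(time = c(5, 50), mode = c("advisory", "manual"))),
    ann, span_end = 200
  )
  expect_equal(derive_review(ep_man)$mode, 1L)
  ep_none <- build_episode(
    base_log(tibble::tibble(time = double(), mode = character())),
    ann, span_end = 200
  )
  expect_equal(derive_review(ep_none)$mode, 2L)
})

test_that("a constant rhythm gives identical pre-shock and checkpoint codes", {
  ann <- tibble::tibble(
    time = c(5, 100, 105), code = c("pe", "d1", "d2")
  )
  log <- list(
    power_on = "2012-03-01 14:30:00",
    shocks = tibble::tibble(time = 100, energy_j = 150, impedance_ohm = 85),
    mode_switches = tibble::tibble(time = double(), mode = character())
  )
  row <- derive_review(build_episode(log, ann, span_end = 400))
  expect_equal(row$rhyb4, 4L)
  expect_true(all(c(row$r10, row$r30, row$r60, row$r120) == 4L))
})

test_that("derivation is deterministic and keeps post/pre rhythm consistency", {
  set.seed(51)
  for (i in 1:15) {
    sim <- simulate_episode(seed = NULL)
    r1 <- derive_review(sim$episode)
    r2 <- derive_review(sim$episode)
    expect_identical(r1, r2)
    # rhyb4 of shock k+1 equals the response label at the end of shock k's
    # post window (consistency by construction)
    ctx <- segment_shocks(sim$episode)
    if (nrow(ctx) > 1L) {
      for (k in seq_len(nrow(ctx) - 1L)) {
        lab <- state_at(sim$episode$response, ctx$shock_time[k + 1L] - 1e-9)
        lab <- if (is.na(lab)) "UN" else lab
        code <- c(AS = 1L, VF = 2L, VT = 3L, PE = 4L, PR = 4L, UN = 9L)[[lab]]
        expect_equal(r1$rhyb4[k + 1L], code)
      }
    }
  }
})

test_that("unknown power-on propagates sentinels through the time variables", {
  ann <- tibble::tibble(time = c(10, 100, 105), code = c("vf", "d1", "d2"))
  log <- list(
    power_on = NA,
    shocks = tibble::tibble(time = 100, energy_j = 150, impedance_ohm = 85),
    mode_switches = tibble::tibble(time = double(), mode = character())
  )
  row <- derive_review(build_episode(log, ann, span_end = 200))
  expect_equal(unlist(row[, c("ecghr", "ecgmn", "ecgsc")], use.names = FALSE),
    rep(99L, 3))
  expect_equal(unlist(row[, c("shkhr", "shkmn", "shksc")], use.names = FALSE),
    rep(99L, 3))
})
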