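test_that("time comparison codes correct, wrong and missing with 1 s tolerance", {
  r <- compare_time(clock_triplet(14, 33, 18), clock_triplet(14, 33, 19))
  expect_equal(r$code, 1L)
  expect_equal(r$deviation, 1)

  r2 <- compare_time(clock_triplet(14, 33, 18), clock_triplet(14, 33, 21))
  expect_equal(r2$code, 2L)
  expect_equal(r2$deviation, 3)

  r3 <- compare_time(triplet_sentinel("unknown"), clock_triplet(14, 33, 18))
  expect_equal(r3$code, 3L)
  expect_true(is.na(r3$deviation))
  expect_false(r3$missing_match)

  # missing if EITHER side is a sentinel, and class agreement is tracked
  r4 <- compare_time(triplet_sentinel("no_cpr"), triplet_sentinel("no_cpr"))
  expect_equal(r4$code, 3L)
  expect_true(r4$missing_match)
  r5 <- compare_time(triplet_sentinel("no_cpr"), triplet_sentinel("unknown"))
  expect_equal(r5$code, 3L)
  expect_false(r5$missing_match)

  ident <- compare_time(clock_triplet(8, 0, 0), clock_triplet(8, 0, 0))
  expect_equal(ident$code, 1L)
  expect_equal(ident$deviation, 0)

  # cross-midnight times compare by minimal difference modulo 24 h
  wrap <- compare_time(clock_triplet(23, 59, 59), clock_triplet(0, 0, 0))
  expect_equal(wrap$code, 1L)
  expect_equal(wrap$deviation, 1)

  # flagged placeholder literals count as missing
  lit <- compare_time(
    clock_triplet(0, 0, 0), clock_triplet(14, 0, 0),
    manual_flagged = TRUE
  )
  expect_equal(lit$code, 3L)
})

test_that("categorical comparison requires identity; imp/enrgy zero deviation", {
  expect_equal(compare_categorical(2L, 2L)$code, 1L)
  expect_equal(compare_categorical(2L, 4L)$code, 2L)
  r <- compare_categorical(c(85L, 150L), c(85L, 151L))
  expect_equal(r$code, c(1L, 2L))
  expect_equal(r$deviation, c(0L, 1L))
})

test_that("summaries count codes and compute the published-style match rate", {
  # 138 correct + 2 wrong -> 98.6% correct/(correct+wrong)
  res <- tibble::tibble(
    episode = "e", shkn = 1:140, variable = "shktm",
    code = c(rep(1L, 138), rep(2L, 2)),
    deviation = 0, missing_match = NA
  )
  class(res) <- c("rore_audit", class(res))
  s <- summarize_audit(res)
  expect_equal(s$correct, 138L)
  expect_equal(s$wrong, 2L)
  expect_equal(round(s$match_rate, 1), 98.6)

  # an all-missing column has an undefined match rate
  res2 <- res |> dplyr::mutate(code = 3L, missing_match = TRUE)
  s2 <- summarize_audit(res2)
  expect_true(is.na(s2$match_rate))
  expect_equal(s2$missing_agreement, 100)
})

test_that("databases are aligned by episode and shock number, not file order", {
  sim <- simulate_cohort(3, seed = 52)
  shuffled <- sim$derived[sample(nrow(sim$derived)), ]
  aud <- compare_databases(sim$truth, shuffled)
  expect_equal(sum(summarize_audit(aud)$wrong), 0L)

  dropped <- sim$derived[-2, ]
  expect_error(compare_databases(sim$truth, dropped), "misaligned")

  dup <- dplyr::bind_rows(sim$derived, sim$derived[1, ])
  expect_error(compare_databases(sim$truth, dup), "duplicate")
})

test_that("a clean synthetic round trip audits as fully correct", {
  sim <- simulate_cohort(10, seed = 53)
  aud <- compare_databases(sim$truth, sim$derived)
  s <- summarize_audit(aud)
  expect_equal(sum(s$wrong), 0L)
  expect_true(all(s$match_rate[!is.na(s$match_rate)] == 100))
  expect_true(all(s$missing_agreement[!is.na(s$missing_agreement)] == 100))
  g <- glance(aud)
  expect_equal(g$overall_match_rate, 100)
  expect_identical(as.data.frame(tidy(aud)), as.data.frame(s))
})

test_that("raising the tolerance never decreases correct counts", {
  sim <- simulate_cohort(8, seed = 54)
  manual <- corrupt_database(
    sim$truth,
    rates = c(jitter = 0.3, unknown = 0.05), seed = 55
  )$rows
  correct_at <- vapply(c(1, 2, 3, 5), function(tol) {
    sum(summarize_audit(compare_databases(manual, sim$derived, tolerance = tol))$correct)
  }, double(1))
  expect_true(all(diff(correct_at) >= 0))
  # jitter deviations were drawn in 2-5 s, so widening 1 -> 5 s must help
  expect_gt(correct_at[4], correct_at[1])
})

test_that("the reconciliation rule reads unknown fc/lc as CPR given", {
  # no compressions before the only shock, so the derivation codes cpr = no
  ann <- tibble::tibble(
    time = c(10, 100, 105, 110, 300),
    code = c("vf", "d1", "d2", "c1", "c2")
  )
  log <- list(
    power_on = "2012-03-01 14:30:00",
    shocks = tibble::tibble(time = 100, energy_j = 200, impedance_ohm = 70),
    mode_switches = tibble::tibble(time = double(), mode = character())
  )
  derived <- derive_review(build_episode(log, ann, span_end = 400))
  expect_equal(derived$cpr, 2L)
  # a manual row where the reviewer knew CPR happened but could not time it
  manual <- derived
  manual[, c("fchr", "fcmn", "fcsc", "lchr", "lcmn", "lcsc")] <- 99L
  manual$cpr <- 1L
  aud <- compare_databases(manual, derived, reconcile_unknown_cpr = TRUE)
  expect_equal(aud$code[aud$variable == "cpr"], 1L)
  aud2 <- compare_databases(manual, derived, reconcile_unknown_cpr = FALSE)
  expect_equal(aud2$code[aud2$variable == "cpr"], 2L)
})
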