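#' Compare one time variable between manual and derived databases
#'
#' Codes the pair as correct (1), wrong (2) or missing (3). A pair is
#' missing when either triplet is a sentinel (`66:66:66`, `88:88:88`,
#' `99:99:99`) or a flagged placeholder literal. Otherwise the pair is
#' correct when the absolute deviation is at most `tolerance` seconds,
#' computed as the minimal difference modulo 24 h so that times of day just
#' either side of midnight compare as close.
#'
#' @param manual,derived Triplet tibbles (columns `hr`, `mn`, `sc`), one row
#'   each or equal lengths.
#' @param tolerance Seconds (default 1).
#' @param manual_flagged,derived_flagged Logical: placeholder-literal flags
#'   for `00:00:00` / `12:00:00` (see [classify_triplet()]).
#' @return A tibble with `code` (1/2/3), `deviation` (seconds, `NA` for
#'   missing pairs) and `missing_match` (`TRUE` when both sides carry the
#'   same sentinel class, `NA` for non-missing pairs).
#' @export
#' @examples
#' compare_time(clock_triplet(14, 33, 18), clock_triplet(14, 33, 19))
#' compare_time(triplet_sentinel("unknown"), clock_triplet(14, 33, 18))
compare_time <- function(manual, derived, tolerance = 1,
                         manual_flagged = FALSE, derived_flagged = FALSE) {
  n <- max(nrow(manual), nrow(derived))
  mc <- classify_triplet(manual, manual_flagged)
  dc <- classify_triplet(derived, derived_flagged)
  missing_pair <- mc != "valid" | dc != "valid"
  dev <- rep(NA_real_, n)
  ok <- !missing_pair
  if (any(ok)) {
    d <- abs(triplet_seconds(manual)[ok] - triplet_seconds(derived)[ok])
    dev[ok] <- pmin(d, 86400 - d)
  }
  tibble(
    code = ifelse(missing_pair, 3L, ifelse(dev <= tolerance, 1L, 2L)),
    deviation = dev,
    missing_match = ifelse(missing_pair, mc == dc, NA)
  )
}

#' Compare categorical and numeric-exact variables
#'
#' Categorical review codes are correct only when identical; the impedance
#' and energy readings are compared as integers with zero deviation required
#' for a correct coding.
#'
#' @param manual,derived Integer vectors.
#' @return A tibble with `code` (1 correct / 2 wrong) and `deviation`.
#' @export
compare_categorical <- function(manual, derived) {
  dev <- abs(as.integer(manual) - as.integer(derived))
  tibble(code = ifelse(dev == 0L, 1L, 2L), deviation = dev)
}

time_variable_prefixes <- c(
  ecgtm = "ecg", shktm = "shk", fctm = "fc", lctm = "lc",
  vfonsettm = "vfonset", rsctm = "rsc"
)
categorical_variables <- c(
  "init_rhy", "rhyb4", "r10", "r30", "r60", "r120",
  "vfpr", "orgpr", "rosc",
  "shkn", "ssrecord", "shks", "mode", "cpr", "imp", "enrgy"
)

#' Audit a derived review database against a manual one
#'
#' Aligns rows by (`episode`, `shkn`) — never by file order, so dropped or
#' duplicated shock registrations surface as an alignment error — and codes
#' every compared cell as correct (1), wrong (2) or missing (3).
#'
#' When `reconcile_unknown_cpr` is `TRUE`, a derived `cpr = 2` (no
#' compressions found) is read as CPR present before comparison whenever the
#' manual first- and last-compression triplets are both coded unknown: a
#' manual reviewer who could not time the compressions still witnessed them.
#'
#' @param manual,derived Database tibbles (see [read_database()]).
#' @param tolerance Time tolerance in seconds (default 1).
#' @param flag_literals Treat manual `00:00:00` / `12:00:00` triplets as
#'   flagged placeholder edits (default `FALSE`).
#' @param reconcile_unknown_cpr See above (default `TRUE`).
#' @return A `rore_audit` object: a long tibble with one row per
#'   (episode, shkn, variable) holding `code`, `deviation` and
#'   `missing_match`.
#' @export
#' @examples
#' sim <- simulate_cohort(3, seed = 11)
#' aud <- compare_databases(sim$truth, sim$derived)
#' summarize_audit(aud)
compare_databases <- function(manual, derived, tolerance = 1,
                              flag_literals = FALSE,
                              reconcile_unknown_cpr = TRUE) {
  manual <- as_tibble(manual)
  derived <- as_tibble(derived)
  key_m <- paste(manual$episode, manual$shkn)
  key_d <- paste(derived$episode, derived$shkn)
  if (anyDuplicated(key_m) || anyDuplicated(key_d)) {
    abort("duplicate (episode, shkn) keys; cannot align the databases.")
  }
  if (length(key_m) != length(key_d) || !setequal(key_m, key_d)) {
    off <- c(setdiff(key_m, key_d), setdiff(key_d, key_m))
    abort(paste0(
      "databases are misaligned at (episode, shkn): ",
      paste(head(off, 5L), collapse = "; ")
    ))
  }
  derived <- derived[match(key_m, key_d), ]

  if (reconcile_unknown_cpr) {
    fc_unk <- manual$fchr == 99L & manual$fcmn == 99L & manual$fcsc == 99L
    lc_unk <- manual$lchr == 99L & manual$lcmn == 99L & manual$lcsc == 99L
    derived$cpr[fc_unk & lc_unk & derived$cpr == 2L] <- 1L
  }

  trip <- function(db, p) clock_triplet(db[[paste0(p, "hr")]],
    db[[paste0(p, "mn")]], db[[paste0(p, "sc")]])
  time_res <- imap(time_variable_prefixes, function(p, var) {
    compare_time(
      trip(manual, p), trip(derived, p), tolerance,
      manual_flagged = flag_literals
    ) |>
      mutate(variable = var, episode = manual$episode, shkn = manual$shkn)
  }) |> list_rbind()

  cat_res <- map(categorical_variables, function(var) {
    compare_categorical(manual[[var]], derived[[var]]) |>
      mutate(
        variable = var, episode = manual$episode, shkn = manual$shkn,
        missing_match = NA
      )
  }) |> list_rbind()

  out <- bind_rows(time_res, cat_res) |>
    select("episode", "shkn", "variable", "code", "deviation", "missing_match")
  class(out) <- c("rore_audit", class(out))
  attr(out, "tolerance") <- tolerance
  out
}

#' Summarise an audit into per-variable counts and match rates
#'
#' @param results A `rore_audit` from [compare_databases()].
#' @return A tibble with one row per variable: `n`, `correct`, `wrong`,
#'   `missing`, `match_rate` (percent, correct / (correct + wrong), `NA`
#'   when every pair is missing) and `missing_agreement` (percent of missing
#'   pairs whose sentinel classes agree, `NA` when none are missing).
#' @export
summarize_audit <- function(results) {
  results |>
    as_tibble() |>
    group_by(.data$variable) |>
    summarise(
      n = n(),
      correct = sum(.data$code == 1L),
      wrong = sum(.data$code == 2L),
      missing = sum(.data$code == 3L),
      .matched_missing = sum(.data$missing_match %in% TRUE),
      .groups = "drop"
    ) |>
    mutate(
      match_rate = ifelse(.data$correct + .data$wrong == 0L, NA_real_,
        100 * .data$correct / (.data$correct + .data$wrong)
      ),
      missing_agreement = ifelse(.data$missing == 0L, NA_real_,
        100 * .data$.matched_missing / .data$missing
      )
    ) |>
    select(-".matched_missing") |>
    arrange(match(
      .data$variable,
      c(names(time_variable_prefixes), categorical_variables)
    ))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname summarize_audit
#' @param x A `rore_audit`.
#' @param ... Unused.
#' @export
tidy.rore_audit <- function(x, ...) {
  summarize_audit(x)
}

#' @rdname summarize_audit
#' @export
glance.rore_audit <- function(x, ...) {
  s <- summarize_audit(x)
  tibble(
    n_shocks = length(unique(paste(x$episode, x$shkn))),
    n_variables = nrow(s),
    n_compared = sum(s$n),
    overall_match_rate = 100 * sum(s$correct) / max(sum(s$correct + s$wrong), 1L),
    fraction_missing = sum(s$missing) / sum(s$n),
    tolerance_s = attr(x, "tolerance") %||% 1
  )
}

#' Plot audit match rates
#'
#' Per-variable match rates (correct / (correct + wrong), in percent) with
#' the missing-code agreement overlaid for the time variables, in the spirit
#' of a registry concordance report.
#'
#' @param object A `rore_audit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rore_audit <- function(object, ...) {
  s <- summarize_audit(object) |>
    mutate(variable = factor(.data$variable, levels = rev(.data$variable)))
  long <- s |>
    tidyr::pivot_longer(
      c("match_rate", "missing_agreement"),
      names_to = "measure", values_to = "percent"
    ) |>
    filter(!is.na(.data$percent))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$variable, y = .data$percent, fill = .data$measure
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(
      values = c(match_rate = "grey25", missing_agreement = "grey65"),
      labels = c(
        match_rate = "correct / (correct + wrong)",
        missing_agreement = "missing-code agreement"
      )
    ) +
    ggplot2::labs(
      x = NULL, y = "percent", fill = NULL,
      title = "Derived vs manual review database"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
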