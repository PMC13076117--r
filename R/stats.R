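# Encounter-level aggregation and exact inference: sign-flip permutation
# tests on paired differences, Holm-Bonferroni multiplicity control, and
# similarity-threshold sensitivity reanalysis.

#' Aggregate note-level outcomes to encounter level
#'
#' Because every scenario of an encounter shares the same underlying
#' clinical content, the encounter is the unit of inference. Rates are
#' means of binary note flags over each encounter's scored scenarios.
#'
#' @param reports Tibble of scored notes (from [score_leakage()],
#'   optionally joined with quality columns); must contain
#'   `encounter_id` plus logical `generic`, `specific`, `knowing`.
#' @param by Extra grouping columns (e.g. model and condition flags).
#' @return Tibble of condition results: one row per group x encounter
#'   with `leak_rate_any`, `leak_rate_specific`, `knowing_rate`, `n_notes`
#'   and means of any numeric quality columns present.
#' @export
aggregate_by_encounter <- function(reports, by = c("privacy", "soap")) {
  stopifnot(all(c("encounter_id", "generic", "specific", "knowing") %in% names(reports)))
  by <- intersect(by, names(reports))
  quality_cols <- intersect(c("rouge1", "completeness", "conciseness"), names(reports))
  grouped <- dplyr::group_by(reports, dplyr::across(dplyr::all_of(c(by, "encounter_id"))))
  out <- dplyr::summarise(
    grouped,
    leak_rate_any = mean(.data$generic),
    leak_rate_specific = mean(.data$specific),
    knowing_rate = mean(.data$knowing),
    n_notes = dplyr::n(),
    dplyr::across(dplyr::all_of(quality_cols), mean),
    .groups = "drop"
  )
  out
}

#' Encounter-level paired differences for a binary condition effect
#'
#' For each encounter, the difference is
#' mean(outcome | effect absent) - mean(outcome | effect present), i.e. a
#' positive value is a reduction attributable to the condition. Nuisance
#' conditions (e.g. structure when testing the privacy effect) are
#' averaged over by the mean.
#'
#' @param results Encounter-level tibble from [aggregate_by_encounter()].
#' @param effect Name of the logical effect column (e.g. "privacy").
#' @param outcome Outcome column (default "leak_rate_any").
#' @return Tibble with `encounter_id` and `diff`.
#' @export
paired_differences <- function(results, effect = "privacy",
                               outcome = "leak_rate_any") {
  stopifnot(effect %in% names(results), outcome %in% names(results))
  grouped <- dplyr::group_by(results, .data$encounter_id)
  dplyr::summarise(
    grouped,
    diff = mean(.data[[outcome]][!.data[[effect]]]) -
      mean(.data[[outcome]][.data[[effect]]]),
    .groups = "drop"
  )
}

#' Exact two-sided sign-flip permutation test on paired differences
#'
#' Enumerates all 2^n assignments of signs to the n paired differences;
#' the statistic is the mean difference, and the two-sided p-value is the
#' proportion of assignments whose |mean| is at least the observed |mean|
#' (ties counted, so p >= 2^-n always, and p = 1 when all differences are
#' zero).
#'
#' @param differences Numeric vector of paired differences, 1 <= n <= 20.
#' @return A `perm_test` list: `statistic` (observed mean), `p_value`,
#'   `n`, `enumeration` (2^n).
#' @export
#' @examples
#' exact_sign_flip_test(rep(0.072, 10))$p_value # 2/1024
exact_sign_flip_test <- function(differences) {
  stopifnot(is.numeric(differences), length(differences) >= 1L)
  n <- length(differences)
  if (n > 20L) {
    stop("full enumeration supported for n <= 20 only; ",
         "Monte-Carlo approximation is out of scope", call. = FALSE)
  }
  obs <- mean(differences)
  total <- 2L^n
  count <- 0L
  chunk <- 2L^min(n, 14L)
  for (start in seq(0L, total - 1L, by = chunk)) {
    ids <- seq(start, min(start + chunk - 1L, total - 1L))
    signs <- matrix(1, nrow = length(ids), ncol = n)
    for (j in seq_len(n)) {
      signs[, j] <- 1 - 2 * (floor(ids / 2^(j - 1)) %% 2)
    }
    means <- as.numeric(signs %*% differences) / n
    count <- count + sum(abs(means) >= abs(obs) - 1e-12)
  }
  structure(
    list(statistic = obs, p_value = count / total, n = n, enumeration = total),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "Exact sign-flip permutation test: mean difference = %.4g, n = %d, p = %.4g (2^%d assignments)\n",
    x$statistic, x$n, x$p_value, x$n
  ))
  invisible(x)
}

#' Holm-Bonferroni step-down multiplicity control
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param alpha Family-wise error level.
#' @return Tibble with `p`, `p_holm`, `p_bonferroni` and `reject`
#'   (Holm-adjusted p <= alpha), rows in input order.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  stopifnot(is.numeric(p_values), length(p_values) >= 1L)
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(
    p = p_values,
    p_holm = stats::p.adjust(p_values, method = "holm"),
    p_bonferroni = stats::p.adjust(p_values, method = "bonferroni"),
    reject = stats::p.adjust(p_values, method = "holm") <= alpha
  )
}

#' Leak rates across a grid of similarity thresholds
#'
#' Recomputes note-level generic-leak flags from the per-sentence
#' similarities cached in the leak reports (no re-embedding) at each
#' threshold of the grid, then averages within groups. Since the leaking
#' set shrinks as the threshold grows, rates are non-increasing in tau.
#'
#' @param scored Tibble from [score_leakage()] (needs the `report`
#'   list-column).
#' @param tau_grid Thresholds, all in (0, 1); default is the five-point
#'   sensitivity grid 0.30-0.50.
#' @param by Grouping columns (e.g. condition flags); rates are overall
#'   when empty.
#' @return Tibble: one row per tau x group with `leak_rate_any`.
#' @export
threshold_sensitivity <- function(scored,
                                  tau_grid = c(0.30, 0.35, 0.40, 0.45, 0.50),
                                  by = character(0)) {
  stopifnot("report" %in% names(scored))
  if (any(tau_grid <= 0 | tau_grid >= 1)) {
    stop("all thresholds must lie strictly inside (0, 1)", call. = FALSE)
  }
  sims <- lapply(scored$report, `[[`, "similarities")
  rows <- lapply(tau_grid, function(tau) {
    flags <- vapply(sims, function(s) any(s > tau), logical(1))
    d <- scored[, intersect(by, names(scored)), drop = FALSE]
    d$generic_tau <- flags
    d$tau <- tau
    d
  })
  d <- dplyr::bind_rows(rows)
  grouped <- dplyr::group_by(d, dplyr::across(dplyr::all_of(c("tau", intersect(by, names(d))))))
  dplyr::summarise(grouped, leak_rate_any = mean(.data$generic_tau), .groups = "drop")
}
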