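# independent brute-force oracle: enumerate sign assignments via expand.grid
oracle_sign_flip_p <- function(d) {
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  means <- abs(signs %*% d) / n
  mean(means >= abs(mean(d)) - 1e-12)
}

test_that("encounter aggregation reproduces independent tabulation", {
  # 42 notes, 21 generic leaks -> rate 0.5
  flags <- tibble::tibble(
    encounter_id = "enc01",
    privacy = FALSE, soap = FALSE,
    generic = rep(c(TRUE, FALSE), 21),
    specific = rep(c(TRUE, FALSE, FALSE), 14),
    knowing = FALSE
  )
  agg <- aggregate_by_encounter(flags)
  expect_equal(agg$leak_rate_any, 0.5)
  expect_equal(agg$leak_rate_specific, 14 / 42)
  expect_equal(agg$knowing_rate, 0.0)
  expect_equal(agg$n_notes, 42L)

  # spreadsheet-style oracle on a random two-condition table
  withr::with_seed(13, {
    tbl <- tibble::tibble(
      encounter_id = rep(sprintf("e%02d", 1:4), each = 20),
      privacy = rep(c(TRUE, FALSE), 40),
      soap = FALSE,
      generic = sample(c(TRUE, FALSE), 80, replace = TRUE),
      specific = FALSE,
      knowing = FALSE
    )
  })
  agg2 <- aggregate_by_encounter(tbl)
  for (i in seq_len(nrow(agg2))) {
    sub <- tbl[tbl$encounter_id == agg2$encounter_id[i] & tbl$privacy == agg2$privacy[i], ]
    expect_equal(agg2$leak_rate_any[i], sum(sub$generic) / nrow(sub))
  }
})

test_that("exact sign-flip test matches enumeration oracles and edge cases", {
  # all-zero differences: every assignment ties, p = 1
  expect_equal(exact_sign_flip_test(rep(0, 6))$p_value, 1.0)

  # ten same-sign equal differences: p = 2/1024
  res <- exact_sign_flip_test(rep(0.072, 10))
  expect_equal(res$p_value, 2 / 1024)
  expect_equal(res$statistic, 0.072)
  expect_equal(res$enumeration, 1024)

  # n = 3, d = {1,2,3}: brute-force enumeration gives 2/8
  expect_equal(exact_sign_flip_test(c(1, 2, 3))$p_value, 0.25)
  expect_equal(oracle_sign_flip_p(c(1, 2, 3)), 0.25)

  # random vectors agree with the independent oracle
  withr::with_seed(31, {
    for (rep_i in 1:10) {
      d <- round(stats::rnorm(sample(4:9, 1)), 2)
      expect_equal(exact_sign_flip_test(d)$p_value, oracle_sign_flip_p(d))
    }
  })

  expect_error(exact_sign_flip_test(stats::rnorm(21)), "n <= 20")
})

test_that("p-values are integer multiples of 2^-n", {
  withr::with_seed(17, {
    for (rep_i in 1:20) {
      n <- sample(3:10, 1)
      res <- exact_sign_flip_test(stats::rnorm(n))
      expect_equal(res$p_value * 2^n, round(res$p_value * 2^n))
      expect_lte(res$p_value, 1)
      expect_gte(res$p_value, 2^-n)
    }
  })
})

test_that("type-I error of the exact test is controlled under a symmetric null", {
  n_rep <- 2000L
  n <- 10L
  signs <- matrix(1, nrow = 1024L, ncol = n)
  for (j in seq_len(n)) signs[, j] <- 1 - 2 * (floor((0:1023) / 2^(j - 1)) %% 2)
  rejections <- withr::with_seed(2024, {
    vapply(seq_len(n_rep), function(i) {
      d <- stats::rnorm(n)
      means <- abs(as.numeric(signs %*% d)) / n
      p <- mean(means >= abs(mean(d)) - 1e-12)
      p <= 0.05
    }, logical(1))
  })
  rate <- mean(rejections)
  # exact test is conservative-or-exact: alpha + 3 binomial SEs of slack
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("Holm adjustment dominates raw p and is dominated by Bonferroni", {
  # single p-value: adjusted equals raw
  expect_equal(holm_bonferroni(0.03)$p_holm, 0.03)

  # hand step-down: (0.01, 0.04) -> (0.02, 0.04), both rejected at 0.05
  hb <- holm_bonferroni(c(0.01, 0.04), alpha = 0.05)
  expect_equal(hb$p_holm, c(0.02, 0.04))
  expect_true(all(hb$reject))

  # all p = 1: nothing rejected
  expect_false(any(holm_bonferroni(rep(1, 5))$reject))

  # dominance on random p-vectors
  withr::with_seed(8, {
    for (rep_i in 1:10) {
      p <- stats::runif(sample(2:8, 1))
      hb <- holm_bonferroni(p)
      expect_true(all(hb$p_holm >= p - 1e-15))
      expect_true(all(hb$p_holm <= hb$p_bonferroni + 1e-15))
    }
  })
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("threshold sensitivity recomputes rates from cached similarities", {
  scored <- score_leakage(small_suite$notes, small_suite$scenarios)
  tab <- threshold_sensitivity(scored)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$tau, c(0.30, 0.35, 0.40, 0.45, 0.50))
  # leak rate non-increasing in tau
  expect_true(all(diff(tab$leak_rate_any) <= 0))
  # the single-threshold grid at 0.4 reproduces the detector output exactly
  tab04 <- threshold_sensitivity(scored, tau_grid = 0.4)
  expect_equal(tab04$leak_rate_any, mean(scored$generic))
  expect_error(threshold_sensitivity(scored, tau_grid = c(0.4, 1.2)), "inside")
})

test_that("paired differences feed the privacy-effect test end to end", {
  scen <- small_suite$scenarios
  # program: privacy eliminates leakage, no-privacy always leaks
  program <- list("nopriv-nosoap" = "generic", "nopriv-soap" = "generic",
                  "priv-nosoap" = "none", "priv-soap" = "none")
  grid <- run_condition_grid(scen, backend = scripted_model_backend(program))
  scored <- score_leakage(grid, scen)
  agg <- aggregate_by_encounter(scored, by = c("privacy", "soap"))
  diffs <- paired_differences(agg, effect = "privacy")
  expect_equal(nrow(diffs), 2L) # two fixture encounters
  expect_true(all(diffs$diff > 0))
  res <- exact_sign_flip_test(diffs$diff)
  # consistent reduction in every encounter: minimal two-sided p = 2 * 2^-n
  expect_equal(res$p_value, 2 * 2^-res$n)
})
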