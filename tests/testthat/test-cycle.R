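flags_tbl <- function(flags, participant = "P01") {
  tibble::tibble(participant = participant, day = seq_along(flags),
                 menses = flags)
}

test_that("menses imputation follows the both-neighbors rule and is idempotent", {
  got <- impute_menses(flags_tbl(c("menses", NA, "menses")))
  expect_equal(got$menses, c("menses", "menses", "menses"))

  got <- impute_menses(flags_tbl(c("menses", NA, "not_menses")))
  expect_equal(got$menses, c("menses", "not_menses", "not_menses"))

  # nearest reported neighbors decide even across a run of missing days
  got <- impute_menses(flags_tbl(c("menses", NA, NA, "menses", NA)))
  expect_equal(got$menses,
               c("menses", "menses", "menses", "menses", "not_menses"))

  full <- flags_tbl(c("not_menses", "menses", "menses", "not_menses"))
  expect_equal(impute_menses(full), full)
  expect_equal(impute_menses(impute_menses(flags_tbl(c(NA, "menses", NA)))),
               impute_menses(flags_tbl(c(NA, "menses", NA))))
})

test_that("cycle segmentation finds onsets, m, and eligibility", {
  f <- rep("not_menses", 40)
  f[c(3:7, 31:35)] <- "menses"
  seg <- segment_cycles(flags_tbl(f))
  expect_equal(seg$onsets[[1]], c(3, 31))
  expect_equal(seg$m, 28)
  expect_true(seg$eligible)

  f1 <- rep("not_menses", 40)
  f1[3:7] <- "menses" # a single onset: one bout, not five
  seg1 <- segment_cycles(flags_tbl(f1))
  expect_equal(seg1$n_onsets, 1)
  expect_false(seg1$eligible)
})

test_that("day normalization matches r * 28/m and its identities", {
  expect_equal(normalize_days(1, 28), 1)
  expect_equal(normalize_days(14, 21), 18.66667, tolerance = 1e-5)
  expect_equal(normalize_days(35, 28), 35) # non-reset crosses day 28
  expect_error(normalize_days(3, 0), "m")
  # a full first cycle maps onto (0, 28]
  m <- 25
  n <- normalize_days(seq_len(m), m)
  expect_true(all(n > 0 & n <= 28))
  expect_equal(max(n), 28)
})

test_that("cycle-day columns reset at onsets; the non-reset axis does not", {
  f <- rep("not_menses", 60)
  f[c(5:9, 33:37)] <- "menses" # onsets at 5 and 33, m = 28
  cohort <- flags_tbl(f)
  cohort$sample_id <- sprintf("s%d", cohort$day)
  got <- add_cycle_days(cohort)
  expect_true(all(is.na(got$r[got$day < 5])))
  expect_equal(got$r[got$day == 5], 1)
  expect_equal(got$r[got$day == 33], 1) # reset at second onset
  expect_equal(got$r[got$day == 60], 28) # trailing days keep counting
  expect_equal(got$n, got$r * 28 / 28)
  expect_equal(got$r_prime[got$day >= 5], (5:60) - 4) # never resets
  expect_true(all(diff(got$n_prime[!is.na(got$n_prime)]) > 0))
})

test_that("loess trajectory reproduces polynomials of its degree", {
  withr::local_seed(2)
  d <- tibble::tibble(
    participant = rep(sprintf("P%02d", 1:5), each = 28),
    n = rep(seq(1, 28, length.out = 28), 5)
  )
  d$value <- 2 * d$n
  tr <- fit_trajectory(d, "value", nboot = 0)
  expect_equal(tr$grid$estimate, 2 * (1:28), tolerance = 1e-6)

  # constant input: flat at c with a collapsed band
  d$value <- 3.5
  trc <- fit_trajectory(d, "value", nboot = 25, seed = 1)
  expect_equal(trc$grid$estimate, rep(3.5, 28), tolerance = 1e-8)
  expect_lt(max(trc$grid$upper - trc$grid$lower), 1e-6)
})

test_that("loess trajectory recovers a noisy sinusoid", {
  withr::local_seed(14)
  d <- tibble::tibble(
    participant = rep(sprintf("P%02d", 1:8), each = 28),
    n = rep(1:28, 8)
  )
  truth <- sin(2 * pi * d$n / 28)
  d$value <- truth + rnorm(nrow(d), 0, 0.4)
  tr <- fit_trajectory(d, "value", nboot = 0)
  rho <- suppressWarnings(
    cor(tr$grid$estimate, sin(2 * pi * (1:28) / 28), method = "spearman")
  )
  expect_gt(rho, 0.9)
  # band from the participant bootstrap contains the estimate
  trb <- fit_trajectory(d, "value", nboot = 50, seed = 3)
  expect_true(all(trb$grid$lower <= trb$grid$estimate + 1e-12))
  expect_true(all(trb$grid$upper >= trb$grid$estimate - 1e-12))

  expect_error(fit_trajectory(d[1:5, ], "value"), "10 points")
})

test_that("reference correlation hits +/-1 at identity and reversal", {
  d <- tibble::tibble(participant = "P01", n = rep(1:28, 3))
  h <- hormone_template()
  d$value <- h$value[d$n]
  tr <- fit_trajectory(d, "value", nboot = 0)
  # reference equal to the trajectory itself: rho exactly +/- 1
  self_ref <- tibble::tibble(day = 1:28, value = tr$grid$estimate)
  expect_equal(correlate_reference(tr, self_ref)$rho, 1)
  rev_ref <- tibble::tibble(day = 1:28, value = -tr$grid$estimate)
  expect_equal(correlate_reference(tr, rev_ref)$rho, -1)
  # and the underlying curve is recovered to near rank-equality
  expect_gt(correlate_reference(tr, h)$rho, 0.95)

  d$value <- 1
  trc <- fit_trajectory(d, "value", nboot = 0)
  expect_warning(out <- correlate_reference(trc, h), "constant")
  expect_true(is.na(out$rho))
})

test_that("species screen flags boosted blood taxa and filters by prevalence", {
  cfg <- responder_config(n = 17, seed = 10, menses_report_missing_rate = 0)
  cohort <- sim_cohort(cfg)
  scr <- species_menses_screen(cohort)
  blood <- attr(default_taxa_catalog(), "blood")
  hits <- scr[scr$species %in% blood, ]
  expect_equal(nrow(hits), 3)
  expect_true(all(hits$fold_change > 2))
  expect_true(all(hits$flagged))
  # BH never decreases a P-value and keeps order
  expect_true(all(scr$p_adj >= scr$p_value - 1e-15))
  expect_true(all(diff(scr$p_adj[order(scr$p_value)]) >= -1e-15))
  # Lactobacillus species trend downward during menses
  dom <- scr[scr$species == "Lactobacillus crispatus", ]
  if (nrow(dom) == 1) {
    expect_lt(mean(dom$cube_root_diff[[1]]), 0)
  }

  # prevalence rule: a species present in few participants is not tested
  rare_cohort <- cohort
  rare <- "Sneathia amnii"
  keep_one <- rare_cohort$participant == "P01"
  rare_cohort[[rare]][!keep_one] <- 0
  scr2 <- species_menses_screen(rare_cohort)
  expect_false(rare %in% scr2$species)
})
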