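test_that("config validation names the offending field", {
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(group_weights = c(NONE = 0.5, C_SYSTEMIC = 0.5,
                                               P_LOCAL = 0.5)),
               "group_weights")
  expect_error(cohort_config(missing_rate = 1.2), "missing_rate")
  expect_error(cohort_config(cycle_length_range = c(30, 20)),
               "cycle_length_range")
  expect_error(cohort_config(dirichlet_concentration = 0),
               "dirichlet_concentration")
  expect_error(cohort_config(taxa_catalog = c("a", "b", "c")), "taxa_catalog")
  expect_error(
    cohort_config(transitions = data.frame(participant = 1,
                                           target_cst = "VI",
                                           cycle_index = 1)),
    "transitions"
  )
})

test_that("hormone template is a 28-day nonnegative curve, low during menses", {
  h <- hormone_template()
  expect_equal(nrow(h), 28)
  expect_true(all(h$value >= 0))
  expect_equal(which.max(h$value), 13)
  expect_lt(mean(h$value[1:5]), mean(h$value[6:28]))
})

test_that("no missingness and no gap gives one row per participant-day", {
  cfg <- cohort_config(n_participants = 2, n_days = 70, missing_rate = 0,
                       gap = c(32, 0), seed = 4)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$abundance), 140)
  expect_equal(nrow(sim$samples), 140)
})

test_that("the gap and missingness remove exactly the expected days", {
  cfg <- cohort_config(n_participants = 3, missing_rate = 0,
                       gap = c(30, 7), seed = 4)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$samples), 3 * (70 - 7))
  expect_false(any(sim$samples$day %in% 30:36))
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n_participants = 3, seed = 99)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("every abundance row is a composition", {
  sim <- simulate_cohort(cohort_config(n_participants = 5, seed = 2))
  mat <- as.matrix(sim$abundance[-1])
  expect_true(all(mat >= 0))
  expect_true(all(abs(rowSums(mat) - 1) < 1e-9))
})

test_that("menses flags agree with ground-truth onsets and durations", {
  cfg <- cohort_config(n_participants = 4, missing_rate = 0, gap = c(32, 0),
                       menses_report_missing_rate = 0, seed = 8)
  sim <- simulate_cohort(cfg)
  for (i in seq_len(4)) {
    tp <- sim$truth$participants[i, ]
    s <- sim$samples[sim$samples$participant == tp$participant, ]
    expect_setequal(s$day[s$menses == "menses"], tp$menses_days[[1]])
  }
})

test_that("configured menses Shannon boost is realized by responders", {
  # delta = 1.0 at concentration 50, Monte-Carlo over 20 hormone-responsive
  # Lactobacillus-dominated participants
  cfg <- cohort_config(
    n_participants = 20, missing_rate = 0, gap = c(32, 0),
    menses_diversity_boost = 1.0, dirichlet_concentration = 50,
    group_weights = c(NONE = 0.7, C_SYSTEMIC = 0.3, P_LOCAL = 0),
    cst_weights = c(I = 0.5, II = 0.1, III = 0.2, IV = 0, V = 0.2),
    menses_report_missing_rate = 0, seed = 7
  )
  cohort <- add_diversity(sim_cohort(cfg))
  gap <- mean(cohort$shannon[cohort$menses == "menses"]) -
    mean(cohort$shannon[cohort$menses == "not_menses"])
  expect_equal(gap, 1.0, tolerance = 0.2)
})

test_that("menses days carry elevated blood-associated taxa", {
  cfg <- responder_config(n = 10, seed = 12, menses_report_missing_rate = 0)
  cohort <- sim_cohort(cfg)
  blood <- attr(default_taxa_catalog(), "blood")
  bl <- rowSums(as.matrix(cohort[blood]))
  expect_gt(mean(bl[cohort$menses == "menses"]),
            3 * mean(bl[cohort$menses == "not_menses"]))
})

test_that("hormone forcing localizes the dominant-weight minimum in days 1-5", {
  cfg <- cohort_config(seed = 1)
  for (grp in c("NONE", "C_SYSTEMIC")) {
    prof <- dominant_weight_profile(cfg, grp)
    expect_true(which.min(prof$weight) %in% 1:5)
  }
  pl <- dominant_weight_profile(cfg, "P_LOCAL")
  expect_lt(sd(pl$weight) / mean(pl$weight), 0.05)
})

test_that("programmed transitions are recorded with a plausible window end", {
  cfg <- responder_config(
    n = 3, seed = 5,
    transitions = data.frame(participant = "P01", target_cst = "V",
                             cycle_index = 2, ramp_days = 5)
  )
  sim <- simulate_cohort(cfg)
  tr <- sim$truth$transitions
  expect_equal(nrow(tr), 1)
  expect_equal(tr$target_cst, "V")
  expect_gte(tr$window_end_true, tr$onset_day)
  expect_lte(tr$window_end_true, tr$onset_day + 15)
})

test_that("inject_transition ramps to the target dominance", {
  taxa <- default_taxa_catalog()
  k <- length(taxa)
  base <- matrix(rep(c(0.7, rep(0.3 / (k - 1), k - 1)), each = 30),
                 nrow = 30, dimnames = list(NULL, taxa))
  menses <- rep("not_menses", 30)
  menses[c(3:6, 20:23)] <- "menses"
  series <- toy_series(base, menses = menses)

  out <- inject_transition(series, "III", onset_index = 2, ramp_days = 5)
  taxcols <- taxa_names(out)
  post <- as.matrix(out[out$day >= 25, taxcols])
  expect_true(all(apply(post, 1, function(p) {
    taxcols[which.max(p)] == "Lactobacillus iners"
  })))
  expect_true(all(abs(rowSums(as.matrix(out[taxcols])) - 1) < 1e-9))

  # ramp 0 switches on the onset day itself
  out0 <- inject_transition(series, "III", onset_index = 2, ramp_days = 0)
  row20 <- as.matrix(out0[out0$day == 20, taxcols])
  expect_equal(taxcols[which.max(row20)], "Lactobacillus iners")

  # before the onset nothing changes
  expect_equal(out[out$day < 20, taxcols], series[series$day < 20, taxcols])

  # no-op with warning when the target equals the current CST
  expect_warning(same <- inject_transition(series, "I", onset_index = 2),
                 "unchanged")
  expect_equal(same, dplyr::arrange(series, day))

  expect_error(inject_transition(series, "III", onset_index = 5), "onset")
})
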