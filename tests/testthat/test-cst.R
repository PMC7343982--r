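mk_abund <- function(...) {
  v <- c(...)
  m <- matrix(v, nrow = 1, dimnames = list(NULL, names(v)))
  m / sum(m)
}

test_that("CST labels follow the dominant-species mapping", {
  ab <- rbind(
    c(0.6, 0.1, 0.1, 0.1, 0.1, 0),    # crispatus dominant -> I
    c(0.1, 0.5, 0.2, 0.1, 0.1, 0),    # gasseri -> II
    c(0.1, 0.1, 0.6, 0.1, 0.1, 0),    # iners -> III
    c(0.1, 0.1, 0.1, 0.5, 0.1, 0.1),  # jensenii -> V
    c(0.2, 0.1, 0.1, 0.1, 0.3, 0.2)   # Gardnerella max -> IV
  )
  colnames(ab) <- c("Lactobacillus crispatus", "Lactobacillus gasseri",
                    "Lactobacillus iners", "Lactobacillus jensenii",
                    "Gardnerella vaginalis", "Atopobium vaginae")
  got <- assign_cst(toy_series(ab))
  expect_equal(got$cst, c("I", "II", "III", "V", "IV"))
  expect_false(any(got$cst_tie))
})

test_that("exact ties break alphabetically and are flagged", {
  ab <- rbind(c(0.4, 0.4, 0.2))
  colnames(ab) <- c("Lactobacillus iners", "Lactobacillus gasseri",
                    "Gardnerella vaginalis")
  got <- assign_cst(toy_series(ab))
  expect_equal(got$cst, "II") # L. gasseri sorts first
  expect_true(got$cst_tie)
})

test_that("CST assignment is scale-invariant", {
  withr::local_seed(21)
  taxa <- default_taxa_catalog()
  for (rep in 1:25) {
    p <- rgamma(length(taxa), 0.4)
    ab <- matrix(p / sum(p), nrow = 1, dimnames = list(NULL, taxa))
    ab2 <- ab * 7 # not renormalized
    s1 <- assign_cst(toy_series(ab))
    s2 <- assign_cst(toy_series(ab2))
    expect_equal(s1$cst, s2$cst)
  }
})

test_that("constant series and short excursions emit no transition", {
  taxa <- c("Lactobacillus crispatus", "Gardnerella vaginalis",
            "Atopobium vaginae")
  const <- matrix(rep(c(0.8, 0.1, 0.1), each = 30), ncol = 3,
                  dimnames = list(NULL, taxa))
  expect_equal(nrow(detect_transitions(toy_series(const))), 0)

  # 5-day excursion to IV then back: still nothing
  exc <- const
  exc[10:14, ] <- matrix(rep(c(0.1, 0.5, 0.4), each = 5), ncol = 3)
  expect_equal(nrow(detect_transitions(toy_series(exc))), 0)
})

test_that("a programmed switch yields one event with the right window end", {
  cfg <- responder_config(
    n = 2, seed = 15,
    cst_weights = c(I = 1, II = 0, III = 0, IV = 0, V = 0),
    dirichlet_concentration = 150,
    vegetarian_fraction = 0, exercise_diversity_slope = 0,
    transitions = data.frame(participant = "P01", target_cst = "III",
                             cycle_index = 2, ramp_days = 5)
  )
  sim <- simulate_cohort(cfg)
  cohort <- assign_cst(suppressMessages(
    build_cohort(sim$abundance, sim$samples)
  ))
  ev <- detect_transitions(cohort)
  ev1 <- ev[ev$participant == "P01", ]
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$former, "I")
  expect_equal(ev1$latter, "III")
  expect_equal(ev1$latter_species, "Lactobacillus iners")
  truth <- sim$truth$transitions
  expect_lte(abs(ev1$window_end - truth$window_end_true), 1)
  expect_lte(ev1$window_start, ev1$window_end)
  # persistence re-checked naively: the latter label spans > 10 days
  sub <- cohort[cohort$participant == "P01" & cohort$cst == "III", ]
  expect_gt(max(sub$day) - min(sub$day) + 1, 10)
})

test_that("events never overlap within a participant", {
  cfg <- responder_config(
    n = 1, seed = 33, n_days = 70,
    cst_weights = c(I = 1, II = 0, III = 0, IV = 0, V = 0),
    transitions = data.frame(participant = "P01", target_cst = "V",
                             cycle_index = 1, ramp_days = 3)
  )
  cohort <- assign_cst(sim_cohort(cfg))
  ev <- detect_transitions(cohort)
  if (nrow(ev) > 1) {
    ev <- dplyr::arrange(ev, window_start)
    expect_true(all(ev$window_start[-1] >= head(ev$window_end, -1)))
  }
  expect_true(all(ev$former != ev$latter))
})

test_that("poisson-binomial dynamic programming equals 2^n enumeration", {
  withr::local_seed(5)
  for (n in c(1, 4, 9, 15)) {
    p <- runif(n)
    for (x in c(0, 1, ceiling(n / 2), n)) {
      expect_equal(ppoisbinom_upper(x, p), enum_poisbinom_upper(x, p),
                   tolerance = 1e-12)
    }
  }
  # closed forms
  expect_equal(ppoisbinom_upper(5, rep(0.2, 5)), 0.2^5)
  expect_equal(ppoisbinom_upper(0, rep(0.2, 5)), 1)
  expect_equal(ppoisbinom_upper(2, c(0.1, 0.2, 0.3)), 0.098)
  expect_equal(ppoisbinom_upper(3, rep(1, 3)), 1)
  p <- c(0.4, 0.7, 0.2)
  expect_equal(ppoisbinom_upper(3, p), prod(p))
})

test_that("menses association test builds the uniform-placement null", {
  # two participants, hand-checkable windows
  taxa <- c("Lactobacillus crispatus", "Lactobacillus iners",
            "Gardnerella vaginalis")
  mk_series <- function(pid, switch_day, onset_days, n_days = 40) {
    ab <- matrix(rep(c(0.8, 0.1, 0.1), n_days), ncol = 3, byrow = TRUE,
                 dimnames = list(NULL, taxa))
    ramp <- pmin(1, pmax(0, (seq_len(n_days) - switch_day) / 3))
    ab <- (1 - ramp) * ab +
      ramp %o% c(0.05, 0.9, 0.05)
    menses <- rep("not_menses", n_days)
    for (o in onset_days) menses[o:(o + 4)] <- "menses"
    toy_series(ab, menses = menses, participant = pid)
  }
  s1 <- mk_series("P01", switch_day = 10, onset_days = c(9, 30))
  s2 <- mk_series("P02", switch_day = 20, onset_days = c(5, 33))
  cohort <- dplyr::bind_rows(s1, s2)
  ev <- detect_transitions(assign_cst(cohort))
  expect_equal(nrow(ev), 2)
  res <- menses_association_test(ev, cohort)
  tab <- tidy(res)
  expect_equal(tab$d, c(40, 40))
  expect_equal(tab$k, c(2, 2))
  expect_equal(tab$p, pmin(1, 2 * tab$w / 40))
  expect_equal(res$p_value, ppoisbinom_upper(res$x, tab$p))
  # the placement null is a valid probability and matches brute force
  res2 <- menses_association_test(ev, cohort, null_method = "placement")
  expect_true(all(tidy(res2)$p >= 0 & tidy(res2)$p <= 1))
  g <- glance(res2)
  expect_equal(g$n, 2)
})
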