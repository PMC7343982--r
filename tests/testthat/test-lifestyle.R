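test_that("anxiety rating matches its fixed points and monotonicity", {
  expect_equal(anxiety_score(100, 100), 0)
  expect_equal(anxiety_score(0, 73), 100)
  expect_equal(anxiety_score(50, 50), 75)
  expect_error(anxiety_score(120, 50), "0, 100")
  withr::local_seed(4)
  h <- runif(50, 0, 99)
  r <- runif(50, 0, 99)
  expect_true(all(anxiety_score(h + 1, r) <= anxiety_score(h, r)))
  expect_true(all(anxiety_score(h, r + 1) <= anxiety_score(h, r)))
  a <- anxiety_score(h, r)
  expect_true(all(a >= 0 & a <= 100))
})

test_that("nutrient proportions drop low-calorie days and divide by kcal", {
  diet <- tibble::tibble(
    participant = "P01", day = 1:3,
    calories = c(2000, 400, 1500),
    sugar_g = c(50, 10, 30), fiber_g = c(24, 2, 18),
    protein_g = c(80, 10, 60), fat_g = c(70, 5, 50)
  )
  expect_message(out <- nutrient_proportions(diet), "1 day")
  expect_equal(nrow(out), 2)
  expect_equal(out$p_sugar[1], 0.025)
  expect_equal(out$p_fiber, c(24, 18) / c(2000, 1500))
  expect_equal(nrow(attr(out, "dropped")), 1)
  # zero grams give proportion zero, not NA
  diet$sugar_g <- 0
  out0 <- suppressMessages(nutrient_proportions(diet))
  expect_true(all(out0$p_sugar == 0))
})

test_that("exercise summary divides by study days and applies the 1.5 rule", {
  s <- tibble::tibble(
    participant = rep(c("A", "B", "C"), each = 3),
    day = rep(1:3, 3),
    exercise_minutes = c(700, NA, NA, NA, NA, NA, 30, 30, 30),
    exercise_intensity = c(2L, NA, NA, NA, NA, NA, 1L, 2L, 3L)
  )
  got <- exercise_summary(s, n_study_days = 70)
  expect_equal(got$minutes_per_day[got$participant == "A"], 10)
  expect_true(is.na(got$mean_intensity[got$participant == "B"]))
  expect_false(got$intense[got$participant == "B"])
  expect_equal(got$mean_intensity[got$participant == "C"], 2)
  expect_true(got$intense[got$participant == "C"])
})

test_that("eligibility filters are per-track, conservative and idempotent", {
  cohort <- sim_cohort(cohort_config(n_participants = 8, seed = 31))
  f1 <- eligibility_filters(cohort)
  expect_true(all(f1$report$n_after <= f1$report$n_before))
  for (i in seq_len(nrow(f1$report))) {
    expect_equal(f1$report$n_before[i] - f1$report$n_after[i],
                 length(f1$report$excluded[[i]]))
  }
  f2 <- eligibility_filters(f1$cohort)
  expect_setequal(f2$tracks$main, f1$tracks$main)
  expect_setequal(f2$tracks$cycle, intersect(f1$tracks$cycle, f1$tracks$main))
})

test_that("van Elteren with one stratum reduces to the rank-sum test", {
  withr::local_seed(6)
  x <- rnorm(12)
  y <- rnorm(10, 0.8)
  ve <- van_elteren(c(x, y), rep(c("a", "b"), c(12, 10)), rep(1, 22))
  wt <- wilcox.test(y, x, correct = FALSE, exact = FALSE)
  expect_equal(ve$p_value, wt$p.value, tolerance = 1e-10)

  expect_error(van_elteren(1:4, rep("a", 4), rep(1, 4)), "two levels")
  expect_error(van_elteren(1:4, c("a", "a", "b", "b"), c(1, 1, 2, 2)),
               "both groups")
})

test_that("van Elteren detects a stratified shift masked by batch effects", {
  withr::local_seed(12)
  # group effect +1 inside strata, stratum effect +5 confounds the pooled test
  strata <- rep(c("Y1", "Y2"), each = 20)
  grp <- rep(rep(c("veg", "not"), each = 10), 2)
  y <- rnorm(40) + (grp == "veg") * 1 + (strata == "Y2") * 5
  ve <- van_elteren(y, grp, strata)
  expect_lt(ve$p_value, 0.05)
  expect_equal(ve$strata_used, 2)
})

test_that("stratified PERMANOVA matches exhaustive permutation on a toy", {
  # 6 samples, 3 subjects x 2 days, menses-like labels within subject
  pts <- rbind(
    c(0, 0), c(2.0, 0.1), c(0.1, 0.2), c(2.1, -0.1), c(-0.2, 0), c(1.9, 0.2)
  )
  d <- dist(pts)
  labels <- rep(c("m", "n"), 3)
  strata <- rep(c("s1", "s2", "s3"), each = 2)
  got <- permanova_stratified(d, labels, strata, n_perm = 999, seed = 9)

  # oracle: enumerate all 2^3 within-stratum label swaps
  dm <- as.matrix(d)^2
  sst <- sum(dm[upper.tri(dm)]) / 6
  f_of <- function(lab) {
    ssw <- sum(sapply(unique(lab), function(g) {
      i <- lab == g
      sum(dm[i, i][upper.tri(dm[i, i])]) / sum(i)
    }))
    ((sst - ssw) / 1) / (ssw / 4)
  }
  fs <- sapply(0:7, function(m) {
    bits <- as.integer(intToBits(m))[1:3]
    lab <- labels
    for (s in 1:3) if (bits[s]) lab[(2 * s - 1):(2 * s)] <- rev(lab[(2 * s - 1):(2 * s)])
    f_of(lab)
  })
  exact_p <- mean(fs >= f_of(labels) - 1e-12)
  expect_equal(got$p_value, exact_p, tolerance = 0.05)
  expect_equal(got$f, f_of(labels), tolerance = 1e-12)
})

test_that("PERMANOVA pseudo-F agrees with vegan and rejects separation", {
  withr::local_seed(23)
  x <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 4), ncol = 2))
  d <- dist(x)
  lab <- rep(c("a", "b"), each = 20)
  got <- permanova_stratified(d, lab, n_perm = 999, seed = 2)
  expect_equal(got$p_value, 0.001)
  skip_if_not_installed("vegan")
  vg <- vegan::adonis2(d ~ lab, permutations = 99)
  expect_equal(got$f, vg$F[1], tolerance = 1e-10)

  expect_error(permanova_stratified(d, rep("a", 40)), "identical")
})

test_that("group contrasts recover the generator's group structure", {
  # Lactobacillus-dominated base states, so the contraceptive effect on
  # dominance is the only group difference and the contrast is identifiable
  cfg <- cohort_config(n_participants = 24, seed = 17,
                       group_weights = c(NONE = 0.45, C_SYSTEMIC = 0.3,
                                         P_LOCAL = 0.25),
                       cst_weights = c(I = 0.5, II = 0.1, III = 0.25,
                                       IV = 0, V = 0.15))
  cohort <- sim_cohort(cfg)
  summ <- participant_summaries(cohort)
  res <- suppressWarnings(group_contrasts(summ))
  w <- res[res$analysis == "menses_wilcoxon" & res$term == "shannon", ]
  expect_lt(w$p_value, 0.05)
  expect_gt(w$estimate, 0)
  lw <- res[res$analysis == "menses_wilcoxon" & res$term == "lactobacillus", ]
  expect_lt(lw$estimate, 0)
  tk <- res[res$analysis == "tukey_contraceptive" &
              res$term == "P_LOCAL-NONE", ]
  if (nrow(tk) == 1) expect_lt(tk$estimate, 0) # less Lactobacillus on P_LOCAL
})
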