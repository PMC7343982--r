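## Lifestyle covariates, eligibility filters, and the cross-sectional and
## group statistics.

#' Composite anxiety rating
#'
#' `100 - happy * relax / 100`: 0 for a fully happy and relaxed day, 100
#' when either rating is 0. Monotone decreasing in both arguments.
#'
#' @param happy,relax Ratings in `[0, 100]` (vectorized; `NA` passes
#'   through).
#' @return Anxiety rating in `[0, 100]`.
#' @export
#' @examples
#' anxiety_score(50, 50) # 75
anxiety_score <- function(happy, relax) {
  if (any(happy < 0 | happy > 100, na.rm = TRUE) ||
      any(relax < 0 | relax > 100, na.rm = TRUE)) {
    abort("happy and relax ratings must lie in [0, 100]")
  }
  100 - happy * relax / 100
}

#' Daily nutrient intake as proportions of caloric intake
#'
#' Converts per-day nutrient grams to grams per kcal (e.g.
#' `p_sugar = sugar_g / calories`). Days reporting fewer than
#' `min_calories` kcal are removed (low counts reflect missing entries) and
#' reported in the `"dropped"` attribute.
#'
#' @param diet Tibble with `participant`, `day`, `calories` and any of
#'   `sugar_g`, `fiber_g`, `protein_g`, `fat_g`.
#' @param min_calories Minimum credible daily intake (default 500 kcal).
#' @return Tibble of retained days with `p_*` columns appended.
#' @export
nutrient_proportions <- function(diet, min_calories = 500) {
  diet <- diet[!is.na(diet$calories), ]
  low <- diet$calories < min_calories
  if (any(low)) {
    inform(sprintf("dropping %d day(s) reporting < %g kcal", sum(low),
                   min_calories))
  }
  out <- diet[!low, ]
  for (g in c("sugar_g", "fiber_g", "protein_g", "fat_g")) {
    if (g %in% names(out)) {
      out[[sub("_g$", "", sprintf("p_%s", g))]] <- out[[g]] / out$calories
    }
  }
  attr(out, "dropped") <- diet[low, c("participant", "day")]
  out
}

#' Per-participant exercise summary
#'
#' Average exercise minutes per study day (total reported minutes divided by
#' the number of study days, so non-exercise days count as zeros), the mean
#' self-reported intensity over sessions (1 = low, 2 = moderate, 3 = high),
#' and the eligibility flag `mean intensity > 1.5` used by the
#' exercise-diversity regression.
#'
#' @param samples Samples or cohort tibble with `exercise_minutes` and
#'   `exercise_intensity`.
#' @param n_study_days Denominator in days (default: max observed day).
#' @return Tibble: `participant`, `minutes_per_day`, `mean_intensity`,
#'   `intense` (logical; `FALSE` when no exercise was reported).
#' @export
exercise_summary <- function(samples, n_study_days = NULL) {
  n_study_days <- n_study_days %||% max(samples$day)
  stopifnot(n_study_days >= 1)
  samples |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      minutes_per_day = sum(.data$exercise_minutes, na.rm = TRUE) /
        .env$n_study_days,
      mean_intensity = if (all(is.na(.data$exercise_intensity))) NA_real_
        else mean(.data$exercise_intensity, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(intense = !is.na(.data$mean_intensity) &
                    .data$mean_intensity > 1.5)
}

#' Apply per-analysis eligibility filters
#'
#' Applies the study's compliance rules, each gating its own analysis track:
#' at least `min_samples` swab samples (main analyses), at least
#' `min_onsets` menses onsets (cycle-normalized analyses), at least
#' `min_diet_days` complete diet days (diet analyses), more than
#' `min_mood_entries` mood entries (mood analyses), and mean exercise
#' intensity above `min_intensity` (exercise regression). Tracks are
#' independent: exclusion from one never affects another, and the operation
#' is idempotent.
#'
#' @param cohort Cohort tibble.
#' @param min_samples,min_onsets,min_diet_days,min_mood_entries,min_intensity
#'   Thresholds (defaults 12, 2, 3, 10, 1.5).
#' @return List of class `"cyclo_filters"`: `cohort` (restricted to
#'   main-track participants), `tracks` (named list of retained participant
#'   IDs per track), and `report` (tibble: filter, threshold, n_before,
#'   n_after, excluded list-column).
#' @export
eligibility_filters <- function(cohort, min_samples = 12, min_onsets = 2,
                                min_diet_days = 3, min_mood_entries = 10,
                                min_intensity = 1.5) {
  by_p <- cohort |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      diet_days = sum(!is.na(.data$calories) & !is.na(.data$sugar_g) &
                        !is.na(.data$fiber_g) & !is.na(.data$protein_g) &
                        !is.na(.data$fat_g)),
      mood_entries = sum(!is.na(.data$happy) & !is.na(.data$relax)),
      .groups = "drop"
    )
  cyc <- segment_cycles(cohort)
  ex <- exercise_summary(cohort)
  all_ids <- by_p$participant

  track <- function(keep_ids, name, threshold) {
    list(ids = keep_ids,
         row = tibble::tibble(
           filter = name, threshold = threshold,
           n_before = length(all_ids), n_after = length(keep_ids),
           excluded = list(setdiff(all_ids, keep_ids))
         ))
  }
  main <- track(by_p$participant[by_p$n_samples >= min_samples],
                "min_samples", min_samples)
  cycle <- track(cyc$participant[cyc$n_onsets >= min_onsets],
                 "min_onsets", min_onsets)
  dietf <- track(by_p$participant[by_p$diet_days >= min_diet_days],
                 "min_diet_days", min_diet_days)
  mood <- track(by_p$participant[by_p$mood_entries > min_mood_entries],
                "min_mood_entries", min_mood_entries)
  exf <- track(ex$participant[ex$intense], "min_intensity", min_intensity)

  report <- dplyr::bind_rows(main$row, cycle$row, dietf$row, mood$row, exf$row)
  out <- cohort[cohort$participant %in% main$ids, ]
  if (nrow(out) == 0) abort("no participants left after filter min_samples")
  structure(
    list(cohort = out,
         tracks = list(main = main$ids, cycle = cycle$ids, diet = dietf$ids,
                       mood = mood$ids, exercise = exf$ids),
         report = report),
    class = "cyclo_filters"
  )
}

#' @export
print.cyclo_filters <- function(x, ...) {
  cat("<cyclo_filters>\n")
  print(x$report[c("filter", "threshold", "n_before", "n_after")])
  invisible(x)
}

#' Van Elteren stratified rank test
#'
#' Two-group Wilcoxon rank-sum test stratified by a blocking factor (e.g.
#' study year), combining within-stratum rank sums with the van Elteren
#' weights `1 / (N_h + 1)` and a tie-corrected normal reference. Used here
#' as a nonparametric covariable-adjusted contrast (vegetarian vs not,
#' adjusted for year).
#'
#' @param value Numeric response.
#' @param group Two-level factor (test is of group 2 vs group 1 location).
#' @param strata Stratum labels.
#' @return Object of class `"cyclo_vanelteren"`: list with `statistic`
#'   (standard normal under the null), `p_value` (two-sided), `n`,
#'   `strata_used`. Strata containing only one group are dropped.
#' @export
van_elteren <- function(value, group, strata) {
  stopifnot(length(value) == length(group), length(value) == length(strata))
  ok <- is.finite(value) & !is.na(group) & !is.na(strata)
  value <- value[ok]; group <- as.factor(as.character(group[ok]))
  strata <- as.character(strata[ok])
  if (nlevels(group) != 2) abort("group must have exactly two levels")
  g2 <- levels(group)[2]
  num <- 0; e <- 0; v <- 0; used <- 0
  for (h in unique(strata)) {
    sel <- strata == h
    yh <- value[sel]; gh <- group[sel]
    n1 <- sum(gh == g2); n2 <- sum(gh != g2); nh <- n1 + n2
    if (n1 == 0 || n2 == 0) next
    rk <- rank(yh)
    wh <- sum(rk[gh == g2])
    ties <- table(yh)
    tie_term <- sum(ties^3 - ties) / (nh * (nh - 1))
    num <- num + wh / (nh + 1)
    e <- e + n1 * (nh + 1) / 2 / (nh + 1)
    v <- v + n1 * n2 / 12 * ((nh + 1) - tie_term) / (nh + 1)^2
    used <- used + 1
  }
  if (used == 0 || v <= 0) abort("no stratum contains both groups")
  z <- (num - e) / sqrt(v)
  structure(list(statistic = z, p_value = 2 * pnorm(-abs(z)),
                 n = length(value), strata_used = used, group_tested = g2),
            class = "cyclo_vanelteren")
}

#' @export
print.cyclo_vanelteren <- function(x, ...) {
  cat(sprintf("Van Elteren stratified rank test: Z = %.3f, P = %.4g (%d strata)\n",
              x$statistic, x$p_value, x$strata_used))
  invisible(x)
}

#' PERMANOVA with permutations restricted to strata
#'
#' One-way permutational multivariate analysis of variance from a distance
#' matrix: pseudo-F from among- vs within-group sums of squared distances,
#' with the permutation null built by shuffling labels only within strata
#' (e.g. within subject, so the test respects repeated sampling). The
#' P-value is `(1 + #{F* >= F}) / (1 + n_perm)`.
#'
#' @param d A `dist` or square symmetric distance matrix.
#' @param labels Grouping to test (one per sample).
#' @param strata Stratum labels (one per sample); a stratum with a single
#'   sample contributes no permutation.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed.
#' @return Object of class `"cyclo_permanova"`: list with `f`, `p_value`,
#'   `n_perm`, `df`.
#' @export
permanova_stratified <- function(d, labels, strata = NULL, n_perm = 999,
                                 seed = NULL) {
  dm <- as.matrix(d)
  nn <- nrow(dm)
  stopifnot(length(labels) == nn)
  if (is.null(strata)) strata <- rep(1, nn)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    abort("labels are identical for all samples: pseudo-F undefined")
  }
  d2 <- dm^2
  sst <- sum(d2[upper.tri(d2)]) / nn
  a <- length(unique(labels))
  lev <- unique(labels)
  pseudo_f <- function(lab) {
    m <- matrix(0, nn, a)
    m[cbind(seq_len(nn), match(lab, lev))] <- 1
    sizes <- colSums(m)
    ssw <- sum(colSums((d2 %*% m) * m) / (2 * sizes))
    ((sst - ssw) / (a - 1)) / (ssw / (nn - a))
  }
  f_obs <- pseudo_f(labels)
  if (!is.null(seed)) withr::local_seed(seed)
  idx_by_stratum <- split(seq_len(nn), strata)
  count <- 0
  for (b in seq_len(n_perm)) {
    perm <- seq_len(nn)
    for (i in idx_by_stratum) {
      if (length(i) > 1) perm[i] <- i[sample.int(length(i))]
    }
    if (pseudo_f(labels[perm]) >= f_obs - 1e-12) count <- count + 1
  }
  structure(
    list(f = f_obs, p_value = (1 + count) / (1 + n_perm), n_perm = n_perm,
         df = c(length(unique(labels)) - 1, nn - length(unique(labels)))),
    class = "cyclo_permanova"
  )
}

#' @export
print.cyclo_permanova <- function(x, ...) {
  cat(sprintf("Stratified PERMANOVA: pseudo-F(%d, %d) = %.3f, P = %.4g (%d permutations)\n",
              x$df[1], x$df[2], x$f, x$p_value, x$n_perm))
  invisible(x)
}

#' Per-participant summary table for cross-sectional statistics
#'
#' Collapses a cohort to one row per participant: mean Shannon diversity and
#' *Lactobacillus* abundance (overall and split by menses status), group
#' labels and the exercise summary - the input [group_contrasts()] expects.
#'
#' @param cohort Cohort tibble (diversity columns added if absent).
#' @return One-row-per-participant tibble.
#' @export
participant_summaries <- function(cohort) {
  if (!"shannon" %in% names(cohort)) cohort <- add_diversity(cohort)
  cohort <- impute_menses(cohort)
  base <- cohort |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      year = .data$year[1], contraceptive = .data$contraceptive[1],
      vegetarian = .data$vegetarian[1],
      mean_shannon = mean(.data$shannon),
      mean_lacto = mean(.data$lactobacillus),
      shannon_menses = mean(.data$shannon[.data$menses == "menses"]),
      shannon_not = mean(.data$shannon[.data$menses == "not_menses"]),
      lacto_menses = mean(.data$lactobacillus[.data$menses == "menses"]),
      lacto_not = mean(.data$lactobacillus[.data$menses == "not_menses"]),
      .groups = "drop"
    )
  dplyr::left_join(base, exercise_summary(cohort), by = "participant")
}

#' Cross-sectional and group contrasts
#'
#' Runs the study's cross-sectional battery on a per-participant summary
#' table: (i) paired Wilcoxon signed rank of within-participant mean Shannon
#' (and *Lactobacillus*) during menses vs not; (ii) ANOVA of mean
#' *Lactobacillus* on year + contraceptive followed by Tukey's HSD on the
#' contraceptive factor; (iii) the van Elteren test of vegetarian vs not,
#' stratified by year; (iv) linear regression of mean Shannon on exercise
#' minutes/day among intense exercisers (mean intensity > 1.5), with and
#' without the year interaction. Contrasts whose groups have fewer than two
#' members are skipped with a warning.
#'
#' @param summaries Output of [participant_summaries()].
#' @return Tidy tibble: `analysis`, `term`, `estimate`, `statistic`,
#'   `p_value`, `n`.
#' @export
group_contrasts <- function(summaries) {
  out <- list()
  add <- function(analysis, term, estimate, statistic, p_value, n) {
    out[[length(out) + 1]] <<- tibble::tibble(
      analysis = analysis, term = term, estimate = estimate,
      statistic = statistic, p_value = p_value, n = n
    )
  }

  ## (i) menses vs not, within participant
  for (pair in list(c("shannon_menses", "shannon_not", "shannon"),
                    c("lacto_menses", "lacto_not", "lactobacillus"))) {
    d <- summaries[complete.cases(summaries[pair[1:2]]), ]
    if (nrow(d) >= 2) {
      wt <- suppressWarnings(wilcox.test(d[[pair[1]]], d[[pair[2]]],
                                         paired = TRUE))
      add("menses_wilcoxon", pair[3], mean(d[[pair[1]]] - d[[pair[2]]]),
          unname(wt$statistic), wt$p.value, nrow(d))
    } else {
      warn(sprintf("menses contrast for %s skipped: < 2 paired participants",
                   pair[3]))
    }
  }

  ## (ii) ANOVA year + contraceptive, Tukey HSD on contraceptive
  dd <- summaries[!is.na(summaries$contraceptive) &
                    summaries$contraceptive != "OTHER", ]
  tab <- table(dd$contraceptive)
  if (length(tab) >= 2 && all(tab >= 2)) {
    fit <- aov(mean_lacto ~ factor(year) + factor(contraceptive), data = dd)
    an <- summary(fit)[[1]]
    add("anova_contraceptive", "contraceptive", NA_real_,
        an["factor(contraceptive)", "F value"],
        an["factor(contraceptive)", "Pr(>F)"], nrow(dd))
    tk <- TukeyHSD(fit, "factor(contraceptive)")[[1]]
    for (cmp in rownames(tk)) {
      add("tukey_contraceptive", cmp, tk[cmp, "diff"], NA_real_,
          tk[cmp, "p adj"], nrow(dd))
    }
  } else {
    warn("contraceptive ANOVA skipped: a group has < 2 participants")
  }

  ## (iii) vegetarian vs not, stratified by year
  dv <- summaries[!is.na(summaries$vegetarian), ]
  if (length(unique(dv$vegetarian)) == 2 && min(table(dv$vegetarian)) >= 2) {
    ve <- van_elteren(dv$mean_shannon, dv$vegetarian, dv$year)
    add("vegetarian_van_elteren", "vegetarianTRUE",
        mean(dv$mean_shannon[dv$vegetarian]) -
          mean(dv$mean_shannon[!dv$vegetarian]),
        ve$statistic, ve$p_value, nrow(dv))
  } else {
    warn("vegetarian contrast skipped: a group has < 2 participants")
  }

  ## (iv) exercise regression among intense exercisers
  de <- summaries[summaries$intense %in% TRUE, ]
  if (nrow(de) >= 3) {
    f1 <- lm(mean_shannon ~ minutes_per_day, data = de)
    s1 <- summary(f1)$coefficients
    add("exercise_lm", "minutes_per_day", s1["minutes_per_day", "Estimate"],
        s1["minutes_per_day", "t value"], s1["minutes_per_day", "Pr(>|t|)"],
        nrow(de))
    if (length(unique(de$year)) == 2 && min(table(de$year)) >= 2) {
      f2 <- lm(mean_shannon ~ minutes_per_day * factor(year), data = de)
      s2 <- summary(f2)$coefficients
      for (term in rownames(s2)[-1]) {
        add("exercise_lm_year", term, s2[term, "Estimate"],
            s2[term, "t value"], s2[term, "Pr(>|t|)"], nrow(de))
      }
    }
  } else {
    warn("exercise regression skipped: < 3 intense exercisers")
  }

  dplyr::bind_rows(out)
}
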