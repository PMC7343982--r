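## Menses imputation, cycle segmentation, 28-day normalization, loess
## trajectories, reference-curve correlation, and the species-level screen.

## vector version of the imputation rule; flags are "menses" / "not_menses" /
## NA, ordered by day
impute_menses_flags <- function(flags) {
  out <- flags
  miss <- which(is.na(flags))
  if (!length(miss)) return(out)
  obs <- which(!is.na(flags))
  for (i in miss) {
    prev <- obs[obs < i]
    nxt <- obs[obs > i]
    both <- length(prev) && length(nxt) &&
      flags[max(prev)] == "menses" && flags[min(nxt)] == "menses"
    out[i] <- if (both) "menses" else "not_menses"
  }
  out
}

## positions (row indices of an ordered series) where a menses bout begins:
## a menses day whose previous observed day is not menses; a menses flag on
## the first observed day is not counted (its onset is unobservable)
onset_positions <- function(flags) {
  is_m <- flags == "menses"
  which(is_m & !dplyr::lag(is_m, default = TRUE))
}

#' Impute missing menses flags
#'
#' Days with unreported menstruation status are assumed `not_menses`, unless
#' the nearest reported days on both sides are `menses`, in which case the
#' day is imputed as `menses`. Reported values are never touched; the
#' operation is idempotent.
#'
#' @param samples Samples (or cohort) tibble with `participant`, `day`,
#'   `menses` columns.
#' @return The input with `menses` imputed (no `NA` left).
#' @export
impute_menses <- function(samples) {
  samples |>
    dplyr::group_by(.data$participant) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::mutate(menses = impute_menses_flags(.data$menses)) |>
    dplyr::ungroup()
}

#' Segment menstrual cycles
#'
#' Finds menses onsets (a menses day whose previous observed day is not
#' menses), full cycles (intervals between consecutive onsets), and each
#' participant's normalization length `m` = length of the first full cycle.
#' Participants with fewer than two onsets never complete a full cycle and
#' are flagged ineligible for cycle-normalized analyses.
#'
#' @param samples Samples or cohort tibble; `menses` is imputed first.
#' @return Tibble: `participant`, `n_onsets`, `onsets` (list-column of study
#'   days), `m`, `eligible`.
#' @export
segment_cycles <- function(samples) {
  impute_menses(samples) |>
    dplyr::group_by(.data$participant) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(
      onsets = list(.data$day[onset_positions(.data$menses)]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_onsets = lengths(.data$onsets),
      m = purrr::map_dbl(.data$onsets, function(o) {
        if (length(o) >= 2) o[2] - o[1] else NA_real_
      }),
      eligible = .data$n_onsets >= 2
    )
}

#' Normalize cycle days to a 28-day frame
#'
#' `n = r * (28 / m)`: the raw day-in-cycle `r` scaled so a cycle of length
#' `m` maps onto 28 days. All of a participant's cycles are scaled by the
#' same factor, with `m` the length of their first full cycle.
#'
#' @param r Raw day (day-in-cycle for the reset variant; running study day
#'   for the non-reset variant used by spectral analysis).
#' @param m First full cycle length in days (`>= 1`).
#' @return Normalized day(s).
#' @export
#' @examples
#' normalize_days(14, 21) # 18.667
normalize_days <- function(r, m) {
  if (any(m < 1)) abort("cycle length m must be >= 1")
  (r * 28) / m # this grouping keeps n = 28 exact at r = m
}

#' Attach cycle-day columns to a cohort
#'
#' Adds, for cycle-eligible participants: `r` (day-in-cycle, resetting to 1
#' at each menses onset; days before the first onset are `NA`), `n` (the
#' 28-day normalized day `r * 28/m`), and the non-reset pair `r_prime`
#' (running study day from the first onset) and `n_prime`, in which
#' consecutive menses onsets are not reset to 1 - the time axis for spectral
#' analysis. Trailing days after the last onset keep counting from that
#' onset. Participants without a full cycle get all-`NA` columns.
#'
#' @param cohort Cohort tibble.
#' @param cycles Optional precomputed [segment_cycles()] result.
#' @return `cohort` with `r`, `n`, `r_prime`, `n_prime` appended.
#' @export
add_cycle_days <- function(cohort, cycles = NULL) {
  if (is.null(cycles)) cycles <- segment_cycles(cohort)
  info <- cycles[c("participant", "onsets", "m", "eligible")]
  cohort |>
    dplyr::group_by(.data$participant) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      row <- info[info$participant == key$participant, ]
      if (nrow(row) == 0 || !row$eligible) {
        d$r <- NA_real_; d$n <- NA_real_
        d$r_prime <- NA_real_; d$n_prime <- NA_real_
        return(d)
      }
      onsets <- row$onsets[[1]]
      m <- row$m
      cur <- findInterval(d$day, onsets)
      d$r <- ifelse(cur >= 1, d$day - onsets[pmax(cur, 1)] + 1, NA_real_)
      d$n <- normalize_days(d$r, m)
      d$r_prime <- ifelse(d$day >= onsets[1], d$day - onsets[1] + 1, NA_real_)
      d$n_prime <- normalize_days(d$r_prime, m)
      d
    }) |>
    dplyr::ungroup()
}

#' Fit a loess trajectory over the normalized cycle
#'
#' Locally weighted regression (tricube weights, locally quadratic,
#' `span = 0.5`) of a measure against normalized cycle day, evaluated on the
#' integer grid 1-28, with a 95% pointwise confidence band obtained by
#' resampling participants with replacement (cluster bootstrap), which
#' respects within-participant correlation. Points beyond day 28 (later
#' cycles longer than the first) are dropped with a message.
#'
#' @param data Tibble with columns `participant`, `n` (normalized day) and
#'   the measure named by `value`.
#' @param value Name of the measure column (string).
#' @param span Loess span (default 0.5).
#' @param degree Local polynomial degree (default 2).
#' @param nboot Bootstrap resamples for the band (default 500).
#' @param seed Optional seed for the bootstrap.
#' @param grid Evaluation grid (default `1:28`).
#' @return Object of class `"cyclo_trajectory"`: list with `grid` tibble
#'   (`n`, `estimate`, `lower`, `upper`), the fitted points, `span`,
#'   `measure`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
fit_trajectory <- function(data, value, span = 0.5, degree = 2, nboot = 500,
                           seed = NULL, grid = 1:28) {
  stopifnot(all(c("participant", "n", value) %in% names(data)))
  pts <- tibble::tibble(participant = data$participant, n = data$n,
                        value = data[[value]])
  pts <- pts[complete.cases(pts), ]
  over <- pts$n > max(grid)
  if (any(over)) {
    inform(sprintf("dropping %d point(s) beyond normalized day %d",
                   sum(over), max(grid)))
    pts <- pts[!over, ]
  }
  if (nrow(pts) < 10) abort("need at least 10 points to fit a trajectory")
  fit_one <- function(d) {
    f <- suppressWarnings(loess(value ~ n, data = d, span = span,
                                degree = degree,
                                control = stats::loess.control(surface = "direct")))
    unname(predict(f, newdata = data.frame(n = grid)))
  }
  est <- fit_one(pts)
  ids <- unique(pts$participant)
  boots <- NULL
  if (nboot > 0 && length(ids) >= 1) {
    if (!is.null(seed)) withr::local_seed(seed)
    boots <- matrix(NA_real_, nboot, length(grid))
    for (b in seq_len(nboot)) {
      take <- sample(ids, length(ids), replace = TRUE)
      d <- dplyr::bind_rows(lapply(take, function(id) {
        pts[pts$participant == id, ]
      }))
      boots[b, ] <- tryCatch(fit_one(d), error = function(e) NA_real_)
    }
  }
  band <- if (is.null(boots)) {
    cbind(lower = est, upper = est)
  } else {
    t(apply(boots, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE))
  }
  structure(
    list(
      grid = tibble::tibble(n = grid, estimate = est,
                            lower = pmin(band[, 1], est),
                            upper = pmax(band[, 2], est)),
      points = pts, span = span, degree = degree, nboot = nboot,
      measure = value
    ),
    class = "cyclo_trajectory"
  )
}

#' @export
print.cyclo_trajectory <- function(x, ...) {
  cat(sprintf("<cyclo_trajectory> %s ~ loess(normalized day), span %.2f, %d points\n",
              x$measure, x$span, nrow(x$points)))
  invisible(x)
}

#' Correlate a fitted trajectory with a reference hormone curve
#'
#' Spearman rank correlation between the trajectory's loess estimates on
#' days 1-28 and a reference relative-estradiol curve on the same grid
#' (e.g. [hormone_template()]).
#'
#' @param trajectory A [fit_trajectory()] result.
#' @param reference Tibble with `day` (1-28) and `value`.
#' @return Tibble with `rho`, `p_value`, `n`. A constant trajectory yields
#'   missing `rho` with a warning.
#' @export
correlate_reference <- function(trajectory, reference) {
  stopifnot(inherits(trajectory, "cyclo_trajectory"))
  ref <- reference$value[match(trajectory$grid$n, reference$day)]
  est <- trajectory$grid$estimate
  ok <- is.finite(est) & is.finite(ref)
  if (sd(est[ok]) < 1e-10 || sd(ref[ok]) < 1e-10) {
    warn("constant trajectory or reference: correlation undefined")
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = sum(ok)))
  }
  ct <- suppressWarnings(cor.test(est[ok], ref[ok], method = "spearman",
                                  exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Screen species for abundance shifts during menses
#'
#' For every species present in at least one sample from more than
#' `prevalence` of participants: per-participant mean relative abundance
#' during menses vs not menses, a paired Wilcoxon signed rank test across
#' participants, the fold change of the grand means, the per-participant
#' difference in cube-root abundance (which stays defined when a species is
#' absent in one condition), and Benjamini-Hochberg adjusted P-values.
#' Volcano flags mark species with unadjusted `P < 0.05` and fold change
#' below 0.5 or above 2.
#'
#' @param cohort Cohort tibble with `menses` flags (imputed internally).
#' @param prevalence Fraction of participants a species must be found in
#'   (default 0.5, strict).
#' @return Tibble per species: `species`, `n_participants`, `mean_menses`,
#'   `mean_not`, `fold_change`, `p_value`, `p_adj`, `flagged`, plus the
#'   list-column `cube_root_diff` of per-participant differences.
#' @export
species_menses_screen <- function(cohort, prevalence = 0.5) {
  cohort <- impute_menses(cohort)
  taxa <- taxa_names(cohort)
  ## participants usable for the paired contrast
  has_both <- cohort |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(both = dplyr::n_distinct(.data$menses) == 2,
                     .groups = "drop")
  keep_p <- has_both$participant[has_both$both]
  if (length(keep_p) < 2) abort("need >= 2 participants with menses and non-menses samples")
  d <- cohort[cohort$participant %in% keep_p, ]
  n_p <- length(keep_p)
  rows <- list()
  for (sp in taxa) {
    prev <- d |>
      dplyr::group_by(.data$participant) |>
      dplyr::summarise(present = any(.data[[sp]] > 0), .groups = "drop")
    if (mean(prev$present) <= prevalence) next
    per <- d |>
      dplyr::group_by(.data$participant, .data$menses) |>
      dplyr::summarise(mean_ab = mean(.data[[sp]]), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "menses", values_from = "mean_ab")
    if (!all(c("menses", "not_menses") %in% names(per))) next
    per <- per[complete.cases(per[c("menses", "not_menses")]), ]
    if (nrow(per) < 2) next
    wt <- suppressWarnings(wilcox.test(per$menses, per$not_menses,
                                       paired = TRUE))
    gm_m <- mean(per$menses)
    gm_n <- mean(per$not_menses)
    rows[[length(rows) + 1]] <- tibble::tibble(
      species = sp, n_participants = nrow(per),
      mean_menses = gm_m, mean_not = gm_n,
      fold_change = if (gm_n > 0) gm_m / gm_n else Inf,
      p_value = wt$p.value,
      cube_root_diff = list(setNames(per$menses^(1 / 3) -
                                       per$not_menses^(1 / 3),
                                     per$participant))
    )
  }
  if (!length(rows)) abort("no species pass the prevalence rule")
  out <- dplyr::bind_rows(rows)
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out$flagged <- out$p_value < 0.05 &
    (out$fold_change < 0.5 | out$fold_change > 2)
  dplyr::relocate(out, "cube_root_diff", .after = "flagged")
}
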