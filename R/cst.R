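## Community state types, long-term transitions, and the exact
## menses-association test.

#' @keywords internal
cst_from_vector <- function(p, taxa) {
  if (all(p == 0)) abort("all-zero abundance vector")
  mx <- max(p)
  winners <- sort(taxa[p == mx]) # alphabetical tie-break, flagged
  dom <- winners[1]
  cst <- names(CST_DOMINANTS)[match(dom, CST_DOMINANTS)]
  if (is.na(cst)) cst <- "IV"
  list(cst = cst, dominant = dom, tie = length(winners) > 1)
}

#' Assign community state types
#'
#' Labels each sample by its most abundant species: CST I for
#' *L. crispatus*, II for *L. gasseri*, III for *L. iners*, V for
#' *L. jensenii*, and IV for any other species. Exact ties are broken
#' alphabetically and flagged in `cst_tie`. The label is scale-invariant:
#' renormalizing a row does not change it.
#'
#' @param cohort Cohort tibble with taxa columns.
#' @return `cohort` with `cst` and `cst_tie` columns appended.
#' @export
assign_cst <- function(cohort) {
  taxa <- taxa_names(cohort)
  mat <- as.matrix(cohort[taxa])
  res <- apply(mat, 1, cst_from_vector, taxa = taxa)
  cohort$cst <- vapply(res, `[[`, character(1), "cst")
  cohort$cst_tie <- vapply(res, `[[`, logical(1), "tie")
  cohort
}

## calendar-day span of observed days i..j
span_days <- function(days, i, j) days[j] - days[i] + 1

#' Detect long-term CST transitions
#'
#' A long-term transition is a change from one CST (former) to another
#' (latter) whose new label persists for more than `persistence_days`
#' calendar days, or to the end of the series when the change begins within
#' the final `persistence_days`. Missing collection days do not break
#' persistence. For each event, `window_end` is the first observed day on
#' which the latter CST's dominant species exceeds `dominance_threshold`
#' relative abundance while remaining the most abundant species for at least
#' `persistence_days` (or to the series end); `window_start` is found by
#' backtracking from `window_end` while the dominant species' abundance
#' strictly decreases, then stepping one observed day forward from that local
#' minimum - the day its rise began. Shorter excursions emit nothing.
#'
#' @param cohort Cohort tibble with `participant`, `day`, taxa columns (and
#'   optionally `menses`, used to mark windows covering a menses onset).
#' @param persistence_days Persistence cutoff in days (default 10, chosen so
#'   long-term means persisting beyond a typical menses).
#' @param dominance_threshold Relative abundance the incoming dominant must
#'   exceed (default 0.5).
#' @return Tibble of events: `participant`, `former`, `latter`,
#'   `latter_species`, `window_start`, `window_end`, `persisted_days`,
#'   `covers_menses_onset`.
#' @export
detect_transitions <- function(cohort, persistence_days = 10,
                               dominance_threshold = 0.5) {
  if (!"cst" %in% names(cohort)) cohort <- assign_cst(cohort)
  if (!"participant" %in% names(cohort)) cohort$participant <- "P01"
  taxa <- taxa_names(cohort)

  one <- function(d, key) {
    if (is.unsorted(d$day, strictly = TRUE)) {
      abort(sprintf("days not strictly increasing for participant %s",
                    key$participant))
    }
    n <- nrow(d)
    empty <- tibble::tibble(former = character(), latter = character(),
                            latter_species = character(),
                            window_start = integer(), window_end = integer(),
                            persisted_days = double(),
                            covers_menses_onset = logical())
    if (n < 2) return(empty)
    mat <- as.matrix(d[taxa])
    days <- d$day
    last_day <- days[n]
    onsets <- if ("menses" %in% names(d)) {
      days[onset_positions(impute_menses_flags(d$menses))]
    } else {
      integer()
    }

    ## runs of identical CST
    r <- rle(d$cst)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1

    events <- list()
    stable <- NA_character_
    for (k in seq_along(r$values)) {
      i <- starts[k]; j <- ends[k]
      persisted <- span_days(days, i, j)
      reaches_end <- days[j] == last_day &&
        days[i] > last_day - persistence_days
      ok <- persisted > persistence_days || reaches_end
      if (!ok) next
      lab <- r$values[k]
      if (is.na(stable)) {
        stable <- lab
        next
      }
      if (lab == stable) next
      dom <- if (lab == "IV") {
        ## diverse state: its "dominant" is the run's modal top species
        tops <- apply(mat[i:j, , drop = FALSE], 1, function(p) {
          taxa[which.max(p)]
        })
        names(sort(table(tops), decreasing = TRUE))[1]
      } else {
        CST_DOMINANTS[[lab]]
      }
      abv <- mat[, dom]
      ## window_end: first observed day with dominance above threshold that
      ## stays most abundant for persistence_days (or to series end)
      w_end_idx <- NA_integer_
      for (ii in i:j) {
        if (abv[ii] <= dominance_threshold) next
        jj <- ii
        while (jj < n && taxa[which.max(mat[jj + 1, ])] == dom) {
          jj <- jj + 1
        }
        if (span_days(days, ii, jj) >= persistence_days ||
            days[jj] == last_day) {
          w_end_idx <- ii
          break
        }
      }
      if (is.na(w_end_idx)) w_end_idx <- i # threshold never crossed: run start
      ## window_start: backtrack while abundance strictly decreases backward
      kk <- w_end_idx
      while (kk > 1 && abv[kk - 1] < abv[kk]) kk <- kk - 1
      w_start_idx <- min(kk + 1, w_end_idx)
      ws <- days[w_start_idx]; we <- days[w_end_idx]
      events[[length(events) + 1]] <- tibble::tibble(
        former = stable, latter = lab, latter_species = dom,
        window_start = ws, window_end = we,
        persisted_days = persisted,
        covers_menses_onset = any(onsets >= ws & onsets <= we)
      )
      stable <- lab
    }
    if (length(events)) dplyr::bind_rows(events) else empty
  }

  cohort |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(one) |>
    dplyr::ungroup()
}

#' Upper tail of the Poisson-binomial distribution
#'
#' `Pr(X >= x)` where `X` is the number of successes among independent
#' Bernoulli trials with probabilities `p`, computed exactly by the standard
#' dynamic-programming convolution (no approximation).
#'
#' @param x Number of observed successes.
#' @param p Vector of success probabilities in `[0, 1]`.
#' @return Exact tail probability.
#' @export
#' @examples
#' ppoisbinom_upper(5, rep(0.2, 5)) # 0.2^5
ppoisbinom_upper <- function(x, p) {
  stopifnot(all(p >= 0 & p <= 1), x >= 0)
  if (x <= 0) return(1)
  f <- 1 # distribution of 0 trials
  for (pi in p) {
    f <- c(f * (1 - pi), 0) + c(0, f * pi)
  }
  sum(f[seq.int(x + 1, length(f))])
}

#' Exact test of CST transition-menses association
#'
#' Tests whether long-term CST transition windows cover the first day of a
#' menses more often than chance. Under the null that transitions are placed
#' independently of menses, the probability that participant `s`'s window of
#' `w_s` days covers one of their `k_s` menses onsets among `d_s` observed
#' days is `p_s = min(1, k_s * w_s / d_s)` (`"uniform"` placement), or the
#' exact fraction of contiguous `w_s`-day placements covering an onset
#' (`"placement"`). With heterogeneous `p_s` the number of covering
#' participants is Poisson-binomial; the reported P-value is the exact upper
#' tail `Pr(X >= x)`, which reduces to the ordinary binomial test when all
#' `p_s` are equal.
#'
#' @param events Transition events from [detect_transitions()].
#' @param cohort Cohort tibble with `participant`, `day` and `menses`
#'   columns (used for observed-day counts and menses onsets).
#' @param null_method `"uniform"` (default) or `"placement"`.
#' @return Object of class `"cyclo_menses_assoc"`: a list with `x`, `n`,
#'   per-participant table `participants` (`w`, `d`, `k`, `p`, `success`)
#'   and `p_value`. Has [tidy()] and [glance()] methods.
#' @export
menses_association_test <- function(events, cohort,
                                    null_method = c("uniform", "placement")) {
  null_method <- match.arg(null_method)
  if (nrow(events) == 0) abort("no transition events supplied")
  per <- events |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      w = sum(.data$window_end - .data$window_start + 1),
      success = any(.data$covers_menses_onset),
      windows = list(cbind(.data$window_start, .data$window_end)),
      .groups = "drop"
    )
  rows <- list()
  for (ii in seq_len(nrow(per))) {
    pid <- per$participant[ii]
    d <- cohort[cohort$participant == pid, ]
    if (nrow(d) == 0 || all(is.na(d$menses))) {
      warn(sprintf("participant %s lacks menses data; excluded from test", pid))
      next
    }
    d <- dplyr::arrange(d, .data$day)
    flags <- impute_menses_flags(d$menses)
    onset_days <- d$day[onset_positions(flags)]
    k <- length(onset_days)
    dd <- nrow(d)
    w <- per$w[ii]
    p <- if (null_method == "uniform") {
      min(1, k * w / dd)
    } else {
      ## exhaustive placement: windows of w consecutive observed days
      n_pos <- max(1, dd - w + 1)
      onset_idx <- match(onset_days, d$day)
      hits <- sum(vapply(seq_len(n_pos), function(s) {
        any(onset_idx >= s & onset_idx <= s + w - 1)
      }, logical(1)))
      hits / n_pos
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      participant = pid, w = w, d = dd, k = k, p = p,
      success = per$success[ii]
    )
  }
  if (!length(rows)) abort("no participants with menses data to test")
  tab <- dplyr::bind_rows(rows)
  x <- sum(tab$success)
  structure(
    list(x = x, n = nrow(tab), participants = tab,
         p_value = ppoisbinom_upper(x, tab$p), null_method = null_method),
    class = "cyclo_menses_assoc"
  )
}

#' @export
print.cyclo_menses_assoc <- function(x, ...) {
  cat("Exact Poisson-binomial test of CST transition-menses association\n")
  cat(sprintf("  %d of %d transitioning participants' windows cover a menses onset\n",
              x$x, x$n))
  cat(sprintf("  null: %s placement; Pr(X >= %d) = %.4g\n",
              x$null_method, x$x, x$p_value))
  invisible(x)
}
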