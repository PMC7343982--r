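#' Shannon diversity index
#'
#' `-sum(p * log(p))` with the convention `0 * log(0) = 0`. Natural
#' logarithms by default, so the index is in nats and the Jensen-Shannon
#' bound `log(2)` is exact; pass `base = 2` for bits.
#'
#' @param p Nonnegative abundance vector summing to 1.
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index (scalar).
#' @export
#' @examples
#' shannon(rep(0.25, 4)) # log(4)
shannon <- function(p, base = exp(1)) {
  if (any(p < 0)) abort("negative entry in abundance vector")
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(pmin(p, q)) / (sum(p) + sum(q))`, which reduces to
#' `1 - sum(pmin(p, q))` for unit-sum compositions; 0 for identical vectors,
#' 1 for disjoint supports.
#'
#' @param p,q Nonnegative abundance vectors of equal length.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(p, q) {
  if (length(p) != length(q)) abort("length mismatch between compositions")
  if (any(p < 0) || any(q < 0)) abort("negative entry in abundance vector")
  1 - 2 * sum(pmin(p, q)) / (sum(p) + sum(q))
}

#' Jensen-Shannon divergence
#'
#' `KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`; symmetric and bounded
#' by `log(2)` (natural logs by default).
#'
#' @inheritParams bray_curtis
#' @param base Logarithm base (default `exp(1)`).
#' @return Divergence in `[0, log(2, base)]`.
#' @export
jensen_shannon <- function(p, q, base = exp(1)) {
  if (length(p) != length(q)) abort("length mismatch between compositions")
  if (any(p < 0) || any(q < 0)) abort("negative entry in abundance vector")
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log(a[i] / m[i], base = base))
  }
  (kl(p) + kl(q)) / 2
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' For unit-sum composition rows, Bray-Curtis equals half the Manhattan (L1)
#' distance, so the matrix is computed through [stats::dist()]. Rows are
#' renormalized first.
#'
#' @param cohort Cohort tibble (or abundance tibble) with taxa columns.
#' @return A `dist` object over the rows.
#' @export
bray_curtis_matrix <- function(cohort) {
  mat <- as.matrix(cohort[taxa_names(cohort)])
  mat <- mat / rowSums(mat)
  stats::dist(mat, method = "manhattan") / 2
}

#' Add per-sample diversity columns to a cohort table
#'
#' Appends `shannon` (alpha diversity, nats) and `lactobacillus` (summed
#' relative abundance of all `"Lactobacillus "` species) to each row.
#'
#' @param cohort Cohort tibble from [build_cohort()].
#' @param base Logarithm base for the Shannon index.
#' @return `cohort` with two extra columns.
#' @export
add_diversity <- function(cohort, base = exp(1)) {
  taxa <- taxa_names(cohort)
  mat <- as.matrix(cohort[taxa])
  lp <- log(mat, base = base)
  lp[!is.finite(lp)] <- 0
  cohort$shannon <- -rowSums(mat * lp)
  lacto <- taxa[startsWith(taxa, "Lactobacillus ")]
  cohort$lactobacillus <- rowSums(mat[, lacto, drop = FALSE])
  cohort
}

#' Log Jensen-Shannon rate of change between consecutive samples
#'
#' The community stability statistic: for each pair of consecutive samples
#' within a participant, the Jensen-Shannon divergence `d_js`, the spacing
#' `delta_t` in days, and `rate = log(d_js / delta_t)`. Lower rates mean a
#' more stable community. Pairs of identical samples (`d_js = 0`) get a
#' missing rate (with one warning) rather than `-Inf`, so downstream
#' smoothers stay finite.
#'
#' @param cohort Cohort tibble (one row per sample, `participant` + `day` +
#'   taxa columns), or one participant's slice.
#' @param base Logarithm base for both the divergence and the rate.
#' @return Tibble with columns `participant`, `day_from`, `day_to`,
#'   `delta_t`, `d_js`, `rate`.
#' @export
js_rate <- function(cohort, base = exp(1)) {
  taxa <- taxa_names(cohort)
  if (!"participant" %in% names(cohort)) cohort$participant <- "P01"
  out <- cohort |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(function(d, key) {
      if (is.unsorted(d$day, strictly = TRUE)) {
        abort(sprintf("days not strictly increasing for participant %s",
                      key$participant))
      }
      if (nrow(d) < 2) {
        return(tibble::tibble(day_from = integer(), day_to = integer(),
                              delta_t = integer(), d_js = double()))
      }
      mat <- as.matrix(d[taxa])
      idx <- seq_len(nrow(d) - 1)
      tibble::tibble(
        day_from = d$day[idx], day_to = d$day[idx + 1],
        delta_t = d$day[idx + 1] - d$day[idx],
        d_js = vapply(idx, function(i) {
          jensen_shannon(mat[i, ], mat[i + 1, ], base = base)
        }, numeric(1))
      )
    }) |>
    dplyr::ungroup()
  if (any(out$d_js == 0)) {
    warn(sprintf("%d consecutive pair(s) identical (d_js = 0): rate set to NA",
                 sum(out$d_js == 0)))
  }
  out$rate <- ifelse(out$d_js > 0, log(out$d_js / out$delta_t, base = base), NA)
  out
}

#' Taxon introduction and extinction counts
#'
#' For each participant-day after the first collected sample: the number of
#' taxa present that day but absent on the previous collection day
#' (introductions) and present previously but absent that day (extinctions).
#' Presence means abundance strictly greater than `min_abundance`.
#'
#' @param cohort Cohort tibble.
#' @param min_abundance Presence threshold (default 0: any nonzero count).
#' @return Tibble with `participant`, `day`, `prev_day`, `introduction`,
#'   `extinction`, `richness`.
#' @export
migration_counts <- function(cohort, min_abundance = 0) {
  taxa <- taxa_names(cohort)
  if (!"participant" %in% names(cohort)) cohort$participant <- "P01"
  cohort |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$day)
      pres <- as.matrix(d[taxa]) > min_abundance
      if (nrow(d) < 2) {
        return(tibble::tibble(day = integer(), prev_day = integer(),
                              introduction = integer(), extinction = integer(),
                              richness = integer()))
      }
      idx <- 2:nrow(d)
      tibble::tibble(
        day = d$day[idx], prev_day = d$day[idx - 1],
        introduction = vapply(idx, function(i) {
          sum(pres[i, ] & !pres[i - 1, ])
        }, integer(1)),
        extinction = vapply(idx, function(i) {
          sum(!pres[i, ] & pres[i - 1, ])
        }, integer(1)),
        richness = rowSums(pres)[idx]
      )
    }) |>
    dplyr::ungroup()
}
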