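## broom-style tidiers for the package's fitted objects.

#' @describeIn menses_association_test Per-participant null probabilities
#'   and window coverage as a tibble.
#' @param x A `"cyclo_menses_assoc"` object.
#' @param ... Unused.
#' @export
tidy.cyclo_menses_assoc <- function(x, ...) {
  x$participants
}

#' @describeIn menses_association_test One-row summary: `x`, `n`,
#'   `p_value`, `null_method`.
#' @export
glance.cyclo_menses_assoc <- function(x, ...) {
  obj <- x
  tibble::tibble(x = obj$x, n = obj$n, p_value = obj$p_value,
                 null_method = obj$null_method)
}

#' @describeIn fit_trajectory Grid of loess estimates with the bootstrap
#'   band as a tibble.
#' @param x A `"cyclo_trajectory"` object.
#' @param ... Unused.
#' @export
tidy.cyclo_trajectory <- function(x, ...) {
  x$grid
}

#' @describeIn fit_trajectory One-row summary: measure, span, degree,
#'   number of points/participants, bootstrap size.
#' @export
glance.cyclo_trajectory <- function(x, ...) {
  tibble::tibble(measure = x$measure, span = x$span, degree = x$degree,
                 n_points = nrow(x$points),
                 n_participants = length(unique(x$points$participant)),
                 nboot = x$nboot)
}

#' @describeIn van_elteren Statistic and P-value as a one-row tibble.
#' @param x A `"cyclo_vanelteren"` object.
#' @param ... Unused.
#' @export
tidy.cyclo_vanelteren <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value, n = x$n,
                 strata_used = x$strata_used)
}

#' @describeIn permanova_stratified Pseudo-F and P-value as a one-row
#'   tibble.
#' @param x A `"cyclo_permanova"` object.
#' @param ... Unused.
#' @export
tidy.cyclo_permanova <- function(x, ...) {
  tibble::tibble(pseudo_f = x$f, df_among = x$df[1], df_within = x$df[2],
                 p_value = x$p_value, n_perm = x$n_perm)
}
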