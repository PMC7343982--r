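## Synthetic daily-cohort generator.
##
## Compositions are Dirichlet draws around per-day centroid compositions.
## Centroids start from a per-CST template (one dominant species for CSTs
## I/II/III/V, a flatter anaerobe-rich profile for IV), the dominant weight is
## modulated logistically by the hormone curve (NONE / C_SYSTEMIC only), and
## effect "boosts" (menses, vegetarian, exercise) are convex blends toward a
## more even mix, calibrated so the *expected* Shannon entropy of the
## Dirichlet draw moves by the configured number of nats.

CST_DOMINANTS <- c(
  I = "Lactobacillus crispatus", II = "Lactobacillus gasseri",
  III = "Lactobacillus iners", V = "Lactobacillus jensenii"
)

## centroid template for one CST over the catalog; `dominant_weight` applies
## to the most abundant species (Gardnerella for IV, at a flatter default)
cst_centroid <- function(cst, taxa, blood, dominant_weight = 0.75) {
  k <- length(taxa)
  stopifnot(k >= 2)
  w <- numeric(k)
  names(w) <- taxa
  if (cst == "IV") {
    others <- setdiff(taxa, names(CST_DOMINANTS))
    dom <- "Gardnerella vaginalis"
    if (!dom %in% taxa) dom <- others[1]
    dw <- min(dominant_weight, 0.3) # IV is diverse: cap the dominant
    rest <- setdiff(taxa, dom)
    decay <- 0.9^seq_along(rest)
    # Lactobacillus present but minor in diverse communities
    decay[startsWith(rest, "Lactobacillus ")] <-
      decay[startsWith(rest, "Lactobacillus ")] * 0.25
    w[dom] <- dw
    w[rest] <- (1 - dw) * decay / sum(decay)
  } else {
    dom <- CST_DOMINANTS[[cst]]
    rest <- setdiff(taxa, dom)
    decay <- 0.65^seq_along(rest)
    w[dom] <- dominant_weight
    w[rest] <- (1 - dominant_weight) * decay / sum(decay)
  }
  w
}

## expected Shannon entropy (nats) of p ~ Dirichlet(conc * theta)
dirichlet_expected_entropy <- function(theta, conc) {
  keep <- theta > 0
  a <- conc * theta[keep]
  digamma(conc + 1) - sum(theta[keep] * digamma(a + 1))
}

## blend centroid toward `mix` until expected entropy rises by `delta` nats;
## lambda capped at 1 when the mix cannot supply that much entropy
entropy_blend_lambda <- function(centroid, mix, delta, conc) {
  if (delta <= 0) return(0)
  h0 <- dirichlet_expected_entropy(centroid, conc)
  f <- function(l) {
    dirichlet_expected_entropy((1 - l) * centroid + l * mix, conc) - h0 - delta
  }
  if (f(1) <= 0) return(1)
  uniroot(f, c(0, 1), tol = 1e-9)$root
}

dirichlet_row <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  out <- if (s <= 0) alpha / sum(alpha) else g / s
  names(out) <- names(alpha)
  out
}

## interpolated, standardized hormone value at normalized cycle day nd
hormone_z <- function(curve, nd) {
  nd <- ((nd - 1) %% 28) + 1
  v <- approx(curve$day, curve$value, xout = nd, rule = 2)$y
  (v - mean(curve$value)) / sd(curve$value)
}

## dominant centroid weight on normalized day nd for a participant group
group_dominant_weight <- function(config, group, nd) {
  if (group == "P_LOCAL") {
    rep(config$p_local_weight, length(nd))
  } else {
    plogis(qlogis(config$dominant_weight) +
             config$hormone_amplitude * hormone_z(config$hormone_curve, nd))
  }
}

#' Dominant-species centroid weight over the normalized cycle
#'
#' The centroid weight of the dominant *Lactobacillus* the generator uses on
#' each normalized cycle day for a given contraceptive group, including the
#' menses composition effect on the given menses days. Useful for inspecting
#' the generator's construction: NONE / C_SYSTEMIC weights dip during menses
#' and track the hormone curve; P_LOCAL weights are flat.
#'
#' @param config A [cohort_config()].
#' @param group `"NONE"`, `"C_SYSTEMIC"` or `"P_LOCAL"`.
#' @param cst Base CST of the hypothetical participant (default `"I"`).
#' @param menses_days Normalized days treated as menses (default 1-5).
#' @return Tibble with columns `day` (1-28) and `weight`.
#' @export
dominant_weight_profile <- function(config, group = "NONE", cst = "I",
                                    menses_days = 1:5) {
  stopifnot(inherits(config, "cyclo_config"))
  nd <- 1:28
  w <- group_dominant_weight(config, group, nd)
  dom <- if (cst == "IV") "Gardnerella vaginalis" else CST_DOMINANTS[[cst]]
  mix <- menses_mix(config)
  delta <- config$menses_diversity_boost *
    if (group == "P_LOCAL") config$p_local_menses_factor else 1
  out <- vapply(nd, function(d) {
    cen <- cst_centroid(cst, config$taxa_catalog, config$blood_taxa, w[d])
    if (d %in% menses_days && delta > 0) {
      lam <- entropy_blend_lambda(cen, mix, delta,
                                  config$dirichlet_concentration *
                                    config$menses_concentration_factor)
      cen <- (1 - lam) * cen + lam * mix
    }
    cen[[dom]]
  }, numeric(1))
  tibble::tibble(day = nd, weight = out)
}

## blood-heavy even mix used for the menses blend
menses_mix <- function(config) {
  taxa <- config$taxa_catalog
  mix <- numeric(length(taxa))
  names(mix) <- taxa
  blood <- config$blood_taxa
  diverse <- setdiff(taxa, c(names(CST_DOMINANTS), blood))
  mix[blood] <- 0.5 / length(blood)
  mix[diverse] <- 0.5 / length(diverse)
  mix
}

## even non-blood anaerobe mix used for vegetarian / exercise blends
diverse_mix <- function(config) {
  taxa <- config$taxa_catalog
  mix <- numeric(length(taxa))
  names(mix) <- taxa
  diverse <- setdiff(taxa, c(names(CST_DOMINANTS), config$blood_taxa))
  mix[diverse] <- 1 / length(diverse)
  mix
}

#' Generate a synthetic daily cohort
#'
#' Simulates one row per retained participant-day: a species-level
#' relative-abundance vector (rows sum to 1), a metadata row (participant,
#' study day, year batch, menses flag, contraceptive group, lifestyle
#' covariates), and a ground-truth record of everything that was injected
#' (group, cycle length, menses onsets, programmed CST transitions, effect
#' sizes). Identical `config` (including its seed) gives identical output.
#'
#' @param config A [cohort_config()].
#' @return A list of class `"cyclo_cohort_sim"` with elements `abundance`
#'   (tibble: `sample_id` + one column per taxon), `samples` (metadata
#'   tibble), and `truth` (list with per-participant tibble and programmed
#'   transition table).
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_config(n_participants = 2, seed = 42))
#' nrow(sim$abundance)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cyclo_config"))
  withr::local_seed(config$seed)

  taxa <- config$taxa_catalog
  n_days <- config$n_days
  gap_days <- if (config$gap[["length"]] > 0) {
    seq(config$gap[["start_day"]],
        length.out = config$gap[["length"]])
  } else {
    integer()
  }
  m_mix <- menses_mix(config)
  d_mix <- diverse_mix(config)
  groups <- c("NONE", "C_SYSTEMIC", "P_LOCAL")

  truth_rows <- list()
  trans_rows <- list()
  abund_rows <- list()
  meta_rows <- list()

  for (i in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", i)
    group <- sample(groups, 1, prob = config$group_weights)
    year <- if (i %% 2 == 1) "Y1" else "Y2"
    vegetarian <- runif(1) < config$vegetarian_fraction
    ## a participant with a programmed switch starts in a different CST
    forbidden <- if (!is.null(config$transitions)) {
      config$transitions$target_cst[config$transitions$participant %in% c(i, pid)]
    } else character()
    cst_w <- config$cst_weights
    cst_w[names(cst_w) %in% forbidden] <- 0
    if (sum(cst_w) <= 0) cst_w <- setNames(as.numeric(!names(cst_w) %in% forbidden),
                                           names(cst_w))
    base_cst <- sample(names(cst_w), 1, prob = cst_w)
    m <- sample(seq(config$cycle_length_range[1], config$cycle_length_range[2]), 1)
    dur <- sample(seq(config$menses_duration_range[1],
                      config$menses_duration_range[2]), 1)
    first_onset <- sample.int(m, 1)
    onsets <- seq(first_onset, n_days, by = m)
    menses_days <- unique(unlist(lapply(onsets, function(o) o:(o + dur - 1))))
    menses_days <- menses_days[menses_days >= 1 & menses_days <= n_days]
    # cycle starts extended backward so pre-onset days have a phase
    starts <- seq(first_onset - m * ceiling(first_onset / m), n_days, by = m)

    ## participant-level lifestyle propensities
    ex_mean <- rgamma(1, shape = 4, scale = config$exercise$mean_minutes / 4)
    ex_center <- sample(1:3, 1, prob = c(0.3, 0.4, 0.3))
    happy_mu <- rnorm(1, config$mood$happy_mean, 10)
    relax_mu <- rnorm(1, config$mood$relax_mean, 10)
    cal_mu <- rnorm(1, config$diet$calories_mean, config$diet$calories_sd / 2)

    ## days actually collected
    keep <- setdiff(seq_len(n_days), gap_days)
    keep <- keep[runif(length(keep)) >= config$missing_rate]

    ## daily exercise draws (on all days; reported only on kept days)
    ex_day <- runif(n_days) < config$exercise$p_exercise_day
    ex_min <- pmax(5, rnorm(n_days, ex_mean, config$exercise$sd_minutes))
    ex_int <- pmin(3L, pmax(1L, ex_center + sample(c(-1L, 0L, 1L), n_days,
                                                   replace = TRUE,
                                                   prob = c(0.2, 0.6, 0.2))))
    mean_intensity <- if (any(ex_day)) mean(ex_int[ex_day]) else NA_real_

    ## effect-size blends fixed per participant (calibrated at base centroid)
    base_centroid <- cst_centroid(base_cst, taxa, config$blood_taxa,
                                  if (group == "P_LOCAL") config$p_local_weight
                                  else config$dominant_weight)
    lam_veg <- if (vegetarian && config$vegetarian_diversity_shift > 0) {
      entropy_blend_lambda(base_centroid, d_mix,
                           config$vegetarian_diversity_shift,
                           config$dirichlet_concentration)
    } else 0
    ex_delta <- if (!is.na(mean_intensity) && mean_intensity > 1.5) {
      min(1.5, config$exercise_diversity_slope *
            sum(ex_min[ex_day]) / n_days)
    } else 0
    lam_ex <- if (ex_delta > 0) {
      entropy_blend_lambda(base_centroid, d_mix, ex_delta,
                           config$dirichlet_concentration)
    } else 0

    ## programmed transition for this participant, if any
    ptrans <- NULL
    if (!is.null(config$transitions)) {
      hit <- config$transitions[config$transitions$participant %in% c(i, pid), ]
      if (nrow(hit) > 0) {
        ptrans <- hit[1, ]
        if (ptrans$cycle_index > length(onsets)) {
          ptrans <- NULL # onset never occurs; skip silently, recorded in truth
        }
      }
    }
    t_onset <- if (!is.null(ptrans)) onsets[ptrans$cycle_index] else NA_integer_

    ## daily baseline centroids (hormone forcing + participant-level blends,
    ## before menses and programmed-transition effects)
    cen_list <- vector("list", n_days)
    nd_all <- numeric(n_days)
    menses_delta <- config$menses_diversity_boost *
      if (group == "P_LOCAL") config$p_local_menses_factor else 1
    for (t in seq_len(n_days)) {
      cstart <- max(starts[starts <= t])
      nd <- (t - cstart + 1) * 28 / m
      nd_all[t] <- nd
      wdom <- group_dominant_weight(config, group, nd)
      cen <- cst_centroid(base_cst, taxa, config$blood_taxa, wdom)
      if (lam_veg > 0) cen <- (1 - lam_veg) * cen + lam_veg * d_mix
      if (lam_ex > 0) cen <- (1 - lam_ex) * cen + lam_ex * d_mix
      cen_list[[t]] <- cen
    }

    ## menses blend targeted so E[Shannon] on menses days sits `delta` nats
    ## above the participant's mean non-menses expected entropy
    conc <- config$dirichlet_concentration
    conc_m <- conc * config$menses_concentration_factor
    if (menses_delta > 0 && length(menses_days) > 0) {
      h_non <- mean(vapply(setdiff(seq_len(n_days), menses_days), function(t) {
        dirichlet_expected_entropy(cen_list[[t]], conc)
      }, numeric(1)))
      for (t in menses_days) {
        cen <- cen_list[[t]]
        h_t <- dirichlet_expected_entropy(cen, conc_m)
        gap <- h_non + menses_delta - h_t
        if (gap > 0) {
          lam <- entropy_blend_lambda(cen, m_mix, gap, conc_m)
          cen_list[[t]] <- (1 - lam) * cen + lam * m_mix
        }
      }
    }

    ## programmed transition: the incoming community replaces the current
    ## (possibly menses-perturbed) state in proportion alpha, at its own
    ## hormone-modulated dominance, so the dominance crossing stays sharp
    if (!is.null(ptrans)) {
      for (t in seq(t_onset, n_days)) {
        # the incoming state begins rising on the onset day itself
        alpha <- if (ptrans$ramp_days <= 0) 1 else
          min(1, (t - t_onset + 1) / ptrans$ramp_days)
        tgt <- cst_centroid(ptrans$target_cst, taxa, config$blood_taxa,
                            group_dominant_weight(config, group, nd_all[t]))
        if (lam_veg > 0) tgt <- (1 - lam_veg) * tgt + lam_veg * d_mix
        if (lam_ex > 0) tgt <- (1 - lam_ex) * tgt + lam_ex * d_mix
        cen_list[[t]] <- (1 - alpha) * cen_list[[t]] + alpha * tgt
      }
    }

    ## true transition window end: first retained day the target's dominant
    ## centroid weight exceeds 0.5
    if (!is.null(ptrans)) {
      dom_t <- if (ptrans$target_cst == "IV") "Gardnerella vaginalis"
               else CST_DOMINANTS[[ptrans$target_cst]]
      cand <- keep[keep >= t_onset]
      cross <- cand[vapply(cand, function(t) cen_list[[t]][[dom_t]] > 0.5,
                           logical(1))]
      trans_rows[[length(trans_rows) + 1]] <- tibble::tibble(
        participant = pid, target_cst = ptrans$target_cst,
        onset_day = t_onset, ramp_days = ptrans$ramp_days,
        window_end_true = if (length(cross)) cross[1] else NA_integer_
      )
    }

    ## draw compositions for retained days
    for (t in keep) {
      conc_t <- if (t %in% menses_days) conc_m else conc
      p <- dirichlet_row(conc_t * cen_list[[t]])
      abund_rows[[sprintf("%s_D%03d", pid, t)]] <- p
    }

    ## metadata for retained days
    report_diet <- runif(n_days) < config$diet$report_rate
    low_cal <- runif(n_days) < config$diet$low_cal_rate
    cals <- pmax(600, rnorm(n_days, cal_mu, config$diet$calories_sd))
    cals[low_cal] <- runif(sum(low_cal), 100, 450)
    p_sug <- pmax(0, rnorm(n_days, 0.055, 0.012))
    p_fib <- pmax(0, rnorm(n_days, 0.012, 0.003))
    p_pro <- pmax(0, rnorm(n_days, 0.040, 0.008))
    p_fat <- pmax(0, rnorm(n_days, 0.035, 0.007))
    report_mood <- year == "Y2" & runif(n_days) < config$mood$report_rate
    happy <- pmin(100, pmax(0, rnorm(n_days, happy_mu, config$mood$sd)))
    relax <- pmin(100, pmax(0, rnorm(n_days, relax_mu, config$mood$sd)))
    menses_missing <- runif(n_days) < config$menses_report_missing_rate

    meta_rows[[i]] <- tibble::tibble(
      sample_id = sprintf("%s_D%03d", pid, keep),
      participant = pid, day = keep, year = year,
      menses = ifelse(menses_missing[keep], NA_character_,
                      ifelse(keep %in% menses_days, "menses", "not_menses")),
      contraceptive = group, vegetarian = vegetarian,
      exercise_minutes = ifelse(ex_day[keep], ex_min[keep], NA_real_),
      exercise_intensity = ifelse(ex_day[keep], as.integer(ex_int[keep]),
                                  NA_integer_),
      happy = ifelse(report_mood[keep], happy[keep], NA_real_),
      relax = ifelse(report_mood[keep], relax[keep], NA_real_),
      calories = ifelse(report_diet[keep], cals[keep], NA_real_),
      sugar_g = ifelse(report_diet[keep], p_sug[keep] * cals[keep], NA_real_),
      fiber_g = ifelse(report_diet[keep], p_fib[keep] * cals[keep], NA_real_),
      protein_g = ifelse(report_diet[keep], p_pro[keep] * cals[keep], NA_real_),
      fat_g = ifelse(report_diet[keep], p_fat[keep] * cals[keep], NA_real_)
    )

    truth_rows[[i]] <- tibble::tibble(
      participant = pid, group = group, year = year, vegetarian = vegetarian,
      base_cst = base_cst, cycle_length = m, menses_duration = dur,
      n_retained = length(keep), mean_intensity = mean_intensity,
      onsets = list(onsets), menses_days = list(sort(menses_days))
    )
  }

  abundance <- dplyr::bind_cols(
    tibble::tibble(sample_id = names(abund_rows)),
    tibble::as_tibble(do.call(rbind, abund_rows))
  )
  samples <- dplyr::bind_rows(meta_rows)
  truth <- list(
    participants = dplyr::bind_rows(truth_rows),
    transitions = if (length(trans_rows)) dplyr::bind_rows(trans_rows)
                  else tibble::tibble(participant = character(),
                                      target_cst = character(),
                                      onset_day = integer(),
                                      ramp_days = integer(),
                                      window_end_true = integer()),
    effects = list(
      menses_diversity_boost = config$menses_diversity_boost,
      vegetarian_diversity_shift = config$vegetarian_diversity_shift,
      exercise_diversity_slope = config$exercise_diversity_slope,
      hormone_amplitude = config$hormone_amplitude
    ),
    seed = config$seed
  )
  structure(list(abundance = abundance, samples = samples, truth = truth),
            class = "cyclo_cohort_sim")
}

#' @export
print.cyclo_cohort_sim <- function(x, ...) {
  cat("<cyclo_cohort_sim>\n")
  cat(sprintf("  %d samples from %d participants, %d taxa\n",
              nrow(x$abundance), nrow(x$truth$participants),
              ncol(x$abundance) - 1))
  invisible(x)
}

#' Inject a long-term CST transition into a participant's series
#'
#' Deterministically rewrites one participant's daily compositions so that,
#' starting from a chosen menses onset, the community blends linearly toward
#' the target CST's centroid over `ramp_days` days and then stays there: a
#' testing utility for transition detection with known ground truth.
#'
#' @param series One participant's rows of a cohort table: must contain
#'   `day`, a `menses` column, and one column per taxon.
#' @param target_cst Target CST label (`"I"`-`"V"`).
#' @param onset_index Which menses onset (1-based) the switch starts at.
#' @param ramp_days Length of the linear ramp; 0 switches on the onset day.
#' @param dominant_weight Dominant-species weight of the target centroid.
#' @return `series` with taxa columns rewritten from the onset onward. If the
#'   target equals the current CST the series is returned unchanged with a
#'   warning.
#' @export
inject_transition <- function(series, target_cst, onset_index, ramp_days = 5,
                              dominant_weight = 0.75) {
  stopifnot(is.data.frame(series), "day" %in% names(series),
            "menses" %in% names(series),
            target_cst %in% c("I", "II", "III", "IV", "V"))
  series <- dplyr::arrange(series, .data$day)
  taxa <- taxa_names(series)
  flags <- impute_menses_flags(series$menses)
  onsets <- series$day[onset_positions(flags)]
  if (onset_index < 1 || onset_index > length(onsets)) {
    abort(sprintf("onset_index %d does not address an existing menses onset (%d found)",
                  onset_index, length(onsets)))
  }
  onset <- onsets[onset_index]
  mat <- as.matrix(series[taxa])
  pre <- which(series$day < onset)
  cur_row <- if (length(pre)) mat[max(pre), ] else mat[1, ]
  current <- cst_from_vector(cur_row, taxa)$cst
  if (identical(current, target_cst)) {
    warn("target CST equals the current CST; series returned unchanged")
    return(series)
  }
  blood <- intersect(attr(default_taxa_catalog(), "blood"), taxa)
  tgt <- cst_centroid(target_cst, taxa, blood, dominant_weight)
  for (j in which(series$day >= onset)) {
    a <- if (ramp_days <= 0) 1 else
      min(1, (series$day[j] - onset + 1) / ramp_days)
    mat[j, ] <- (1 - a) * mat[j, ] + a * tgt[taxa]
  }
  series[taxa] <- as.data.frame(mat)
  series
}
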