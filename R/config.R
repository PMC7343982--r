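#' Default species catalog for the synthetic cohort
#'
#' Nineteen species-level taxa: the four cycle-associated *Lactobacillus*
#' species that define community state types (CSTs) I, II, III and V, a set of
#' anaerobic / diverse-community taxa typical of CST IV, and three taxa often
#' cultured on blood agar whose abundance rises while menstrual blood is
#' present.
#'
#' @return Character vector of species names. Blood-associated taxa carry the
#'   attribute `"blood"`.
#' @export
#' @examples
#' default_taxa_catalog()
default_taxa_catalog <- function() {
  lacto <- c(
    "Lactobacillus crispatus", "Lactobacillus gasseri",
    "Lactobacillus iners", "Lactobacillus jensenii"
  )
  diverse <- c(
    "Gardnerella vaginalis", "Atopobium vaginae", "Prevotella bivia",
    "Prevotella timonensis", "Megasphaera genomosp.", "Sneathia amnii",
    "Mobiluncus mulieris", "Dialister micraerophilus",
    "Aerococcus christensenii", "Finegoldia magna",
    "Corynebacterium coyleae", "Veillonella montpellierensis"
  )
  blood <- c(
    "Streptococcus agalactiae", "Peptostreptococcus anaerobius",
    "Anaerococcus tetradius"
  )
  out <- c(lacto, diverse, blood)
  attr(out, "blood") <- blood
  out
}

#' Template relative-estradiol curve over a 28-day cycle
#'
#' A two-peak template for circulating estradiol across an idealized 28-day
#' menstrual cycle: low during days 1-5 (menses), a dominant pre-ovulatory
#' peak, and a smaller luteal rise. Values are relative (unitless) and
#' amplitude-normalized to `[baseline, 1]`. Day 28 is adjacent to day 1, so
#' the curve can be read periodically. Any user-supplied 28-row
#' `(day, value)` table with nonnegative values can be used in its place
#' wherever a reference curve is accepted.
#'
#' @param baseline Relative level far from both peaks (default 0.2).
#' @param peak_day,peak_width Day and Gaussian width (days) of the
#'   pre-ovulatory peak (defaults 13 and 2.5).
#' @param luteal_day,luteal_height,luteal_width Day, relative height and width
#'   of the secondary luteal rise (defaults 22, 0.6, 3).
#' @return A tibble with columns `day` (1-28) and `value` (relative
#'   estradiol, in `[0, 1]`).
#' @export
#' @examples
#' hormone_template()
hormone_template <- function(baseline = 0.2, peak_day = 13, peak_width = 2.5,
                             luteal_day = 22, luteal_height = 0.6,
                             luteal_width = 3) {
  stopifnot(baseline >= 0, baseline < 1, peak_width > 0, luteal_width > 0)
  day <- 1:28
  bump <- function(center, height, width) {
    height * exp(-((day - center)^2) / (2 * width^2))
  }
  v <- baseline +
    (1 - baseline) * exp(-((day - peak_day)^2) / (2 * peak_width^2)) +
    bump(luteal_day, luteal_height * (1 - baseline), luteal_width)
  v <- pmin(v, 1)
  tibble::tibble(day = day, value = v)
}

#' Configure the synthetic daily-cohort generator
#'
#' Bundles and validates every knob of [simulate_cohort()]. Defaults mirror a
#' 10-week daily-swab college cohort: 70 study days with a 7-day mid-study
#' break when no samples are collected, moderate day-to-day missingness,
#' 25-32-day menstrual cycles, contraceptive groups NONE / C_SYSTEMIC
#' (combined, systemic release) / P_LOCAL (progestin-only, local release),
#' hormone-modulated *Lactobacillus* dominance, a menses diversity boost with
#' elevated blood-associated taxa, and lifestyle covariates (diet, exercise,
#' mood, vegetarian flag).
#'
#' @param n_participants Number of participants.
#' @param taxa_catalog Species names; must contain the four CST-defining
#'   *Lactobacillus* species, at least 10 other (diverse/anaerobic) taxa and
#'   at least 3 blood-associated taxa (attribute `"blood"`, as produced by
#'   [default_taxa_catalog()]).
#' @param group_weights Named proportions over `NONE`, `C_SYSTEMIC`,
#'   `P_LOCAL`; must sum to 1.
#' @param n_days Study length in days.
#' @param gap Length-2 vector `(start_day, length)` of a no-collection break
#'   (the "spring break"); `length = 0` disables it.
#' @param missing_rate Probability that a non-break day's sample is absent.
#' @param cycle_length_range,menses_duration_range Integer ranges (days) from
#'   which each participant's cycle length and menses duration are drawn.
#' @param dirichlet_concentration Dirichlet concentration around the daily
#'   centroid composition; larger is less noisy.
#' @param menses_diversity_boost Target Shannon-entropy increase (nats) of the
#'   centroid on menses days (`delta >= 0`).
#' @param menses_concentration_factor Multiplier (< 1 loosens) applied to the
#'   Dirichlet concentration on menses days.
#' @param hormone_amplitude Dimensionless logistic modulation of the dominant
#'   *Lactobacillus* centroid weight by the hormone curve (0 disables).
#' @param hormone_curve 28-row `(day, value)` tibble, e.g.
#'   [hormone_template()].
#' @param dominant_weight Centroid weight of the dominant species for CSTs
#'   I/II/III/V at the hormone-curve mean.
#' @param p_local_weight Flat (cycle-independent) dominant weight used for
#'   P_LOCAL participants.
#' @param p_local_menses_factor Scaling in `[0, 1]` of the menses composition
#'   effect for P_LOCAL participants. The default 0 reproduces the flat
#'   cycle profile this group shows in daily-cohort data.
#' @param cst_weights Named sampling weights over base CSTs I-V.
#' @param transitions `NULL`, or a data frame with columns `participant`,
#'   `target_cst`, `cycle_index` and optionally `ramp_days` describing
#'   programmed long-term CST switches starting at the given menses onset;
#'   such participants draw their base CST excluding the target.
#' @param vegetarian_fraction Probability a participant is vegetarian.
#' @param vegetarian_diversity_shift Target Shannon increase (nats) of
#'   vegetarian participants' centroids.
#' @param exercise_diversity_slope Shannon increase (nats) per reported
#'   exercise minute/day, applied for participants whose mean intensity
#'   exceeds 1.5.
#' @param exercise,mood,diet Lists of distribution parameters for the
#'   lifestyle covariates (see defaults).
#' @param menses_report_missing_rate Probability a collected day's menses
#'   status is left unreported.
#' @param seed Integer seed; the same config and seed give identical cohorts.
#' @return A validated list of class `"cyclo_config"`.
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 2, missing_rate = 0, seed = 1)
cohort_config <- function(n_participants = 17,
                          taxa_catalog = default_taxa_catalog(),
                          group_weights = c(NONE = 0.52, C_SYSTEMIC = 0.30,
                                            P_LOCAL = 0.18),
                          n_days = 70,
                          gap = c(start_day = 32, length = 7),
                          missing_rate = 0.15,
                          cycle_length_range = c(25L, 32L),
                          menses_duration_range = c(4L, 6L),
                          dirichlet_concentration = 50,
                          menses_diversity_boost = 0.8,
                          menses_concentration_factor = 0.7,
                          hormone_amplitude = 0.6,
                          hormone_curve = hormone_template(),
                          dominant_weight = 0.75,
                          p_local_weight = 0.55,
                          p_local_menses_factor = 0,
                          cst_weights = c(I = 0.45, II = 0.05, III = 0.2,
                                          IV = 0.2, V = 0.1),
                          transitions = NULL,
                          vegetarian_fraction = 0.24,
                          vegetarian_diversity_shift = 0.4,
                          exercise_diversity_slope = 0.026,
                          exercise = list(mean_minutes = 25, sd_minutes = 15,
                                          p_exercise_day = 0.35),
                          mood = list(happy_mean = 70, relax_mean = 65,
                                      sd = 15, report_rate = 0.8),
                          diet = list(calories_mean = 2000, calories_sd = 300,
                                      low_cal_rate = 0.03, report_rate = 0.85),
                          menses_report_missing_rate = 0.05,
                          seed = 1L) {
  bad <- function(field, msg) {
    abort(sprintf("invalid config field `%s`: %s", field, msg),
          class = "cyclo_config_error")
  }
  if (!is.numeric(n_participants) || n_participants < 1) {
    bad("n_participants", "must be a positive count")
  }
  taxa <- as.character(taxa_catalog)
  if (anyDuplicated(taxa)) bad("taxa_catalog", "names must be unique")
  lacto_needed <- c("Lactobacillus crispatus", "Lactobacillus gasseri",
                    "Lactobacillus iners", "Lactobacillus jensenii")
  if (!all(lacto_needed %in% taxa)) {
    bad("taxa_catalog", "must contain the four CST-defining Lactobacillus species")
  }
  blood <- attr(taxa_catalog, "blood") %||% character()
  if (length(blood) < 3 || !all(blood %in% taxa)) {
    bad("taxa_catalog", "needs >= 3 blood-associated taxa (attribute \"blood\")")
  }
  if (length(setdiff(taxa, c(lacto_needed, blood))) < 10) {
    bad("taxa_catalog", "needs >= 10 anaerobic/diverse taxa")
  }
  if (!setequal(names(group_weights), c("NONE", "C_SYSTEMIC", "P_LOCAL"))) {
    bad("group_weights", "must be named NONE, C_SYSTEMIC, P_LOCAL")
  }
  if (any(group_weights < 0) || abs(sum(group_weights) - 1) > 1e-8) {
    bad("group_weights", "must be nonnegative and sum to 1")
  }
  if (n_days < 1) bad("n_days", "must be >= 1")
  if (length(gap) != 2 || gap[2] < 0) bad("gap", "must be (start_day, length >= 0)")
  if (missing_rate < 0 || missing_rate >= 1) bad("missing_rate", "must be in [0, 1)")
  rng_ok <- function(r) length(r) == 2 && r[1] >= 1 && r[2] >= r[1]
  if (!rng_ok(cycle_length_range)) bad("cycle_length_range", "empty range")
  if (!rng_ok(menses_duration_range)) bad("menses_duration_range", "empty range")
  if (dirichlet_concentration <= 0) bad("dirichlet_concentration", "must be > 0")
  if (menses_diversity_boost < 0) bad("menses_diversity_boost", "must be >= 0")
  if (hormone_amplitude < 0) bad("hormone_amplitude", "must be >= 0")
  if (!is.data.frame(hormone_curve) || nrow(hormone_curve) != 28 ||
      !all(c("day", "value") %in% names(hormone_curve)) ||
      any(hormone_curve$value < 0)) {
    bad("hormone_curve", "must be a 28-row (day, value) table with values >= 0")
  }
  if (dominant_weight <= 0 || dominant_weight >= 1) {
    bad("dominant_weight", "must be in (0, 1)")
  }
  if (p_local_weight <= 0 || p_local_weight >= 1) {
    bad("p_local_weight", "must be in (0, 1)")
  }
  if (p_local_menses_factor < 0 || p_local_menses_factor > 1) {
    bad("p_local_menses_factor", "must be in [0, 1]")
  }
  if (!setequal(names(cst_weights), c("I", "II", "III", "IV", "V")) ||
      any(cst_weights < 0) || sum(cst_weights) <= 0) {
    bad("cst_weights", "must be nonnegative weights named I..V")
  }
  if (!is.null(transitions)) {
    transitions <- tibble::as_tibble(transitions)
    need <- c("participant", "target_cst", "cycle_index")
    if (!all(need %in% names(transitions))) {
      bad("transitions", "needs columns participant, target_cst, cycle_index")
    }
    if (!all(transitions$target_cst %in% c("I", "II", "III", "IV", "V"))) {
      bad("transitions", "target_cst must be one of I..V")
    }
    if (!"ramp_days" %in% names(transitions)) transitions$ramp_days <- 5L
  }
  if (vegetarian_fraction < 0 || vegetarian_fraction > 1) {
    bad("vegetarian_fraction", "must be in [0, 1]")
  }
  if (vegetarian_diversity_shift < 0) bad("vegetarian_diversity_shift", "must be >= 0")
  if (length(seed) != 1 || is.na(seed)) bad("seed", "must be a single integer")

  structure(
    list(
      n_participants = as.integer(n_participants), taxa_catalog = taxa,
      blood_taxa = blood, group_weights = group_weights,
      n_days = as.integer(n_days),
      gap = c(start_day = as.integer(gap[[1]]), length = as.integer(gap[[2]])),
      missing_rate = missing_rate,
      cycle_length_range = as.integer(cycle_length_range),
      menses_duration_range = as.integer(menses_duration_range),
      dirichlet_concentration = dirichlet_concentration,
      menses_diversity_boost = menses_diversity_boost,
      menses_concentration_factor = menses_concentration_factor,
      hormone_amplitude = hormone_amplitude,
      hormone_curve = tibble::as_tibble(hormone_curve[c("day", "value")]),
      dominant_weight = dominant_weight, p_local_weight = p_local_weight,
      p_local_menses_factor = p_local_menses_factor,
      cst_weights = cst_weights, transitions = transitions,
      vegetarian_fraction = vegetarian_fraction,
      vegetarian_diversity_shift = vegetarian_diversity_shift,
      exercise_diversity_slope = exercise_diversity_slope,
      exercise = exercise, mood = mood, diet = diet,
      menses_report_missing_rate = menses_report_missing_rate,
      seed = as.integer(seed)
    ),
    class = "cyclo_config"
  )
}

#' @export
print.cyclo_config <- function(x, ...) {
  cat("<cyclo_config>\n")
  cat(sprintf("  %d participants x %d days, gap %d days from day %d\n",
              x$n_participants, x$n_days, x$gap[["length"]],
              x$gap[["start_day"]]))
  cat(sprintf("  missing rate %.2f, concentration %.1f, delta %.2f nats, seed %d\n",
              x$missing_rate, x$dirichlet_concentration,
              x$menses_diversity_boost, x$seed))
  invisible(x)
}
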