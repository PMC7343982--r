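---
title: "Methods: models, parameters and design choices in cyclobiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in cyclobiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclobiome)
```

# What the package models

`cyclobiome` analyses daily-resolution vaginal microbiome time series: a
samples-by-species relative-abundance table joined to per-sample metadata
(participant, study day, menstruation status, contraceptive group, diet,
exercise, mood). The analytical chain is

1. **Community state types (CSTs).** Each sample is labelled by its most
   abundant species: I = *Lactobacillus crispatus*, II = *L. gasseri*,
   III = *L. iners*, V = *L. jensenii*, IV = anything else (the diverse,
   anaerobe-rich state). The most-abundant-species rule makes the label
   scale-invariant and deterministic; exact ties are broken alphabetically
   and flagged rather than silently resolved.
2. **Long-term transitions.** A change of CST counts as long-term when the
   new label persists more than `persistence_days` (default 10 — longer than
   a typical menses, so transient menstrual excursions never qualify), or
   reaches the end of the series when the change begins within the final
   `persistence_days`. Persistence is measured in calendar days spanned by
   observed samples, so collection gaps (e.g. a one-week break) do not
   fragment a state. The transition window runs from the day the incoming
   dominant species started rising (found by backtracking from the crossing
   while its abundance strictly decreases, a rule that is exact on monotone
   ramps) to the first day it exceeds 50% abundance while staying most
   abundant for the persistence period.
3. **Menses association.** Whether transition windows cover menses onsets
   more often than chance is tested exactly. Under the null that a
   participant's window of `w` days lands independently of menses among
   their `d` observed days with `k` onsets, the cover probability is
   `p = min(1, k w / d)` (uniform placement; an exhaustive
   placement-counting null is also implemented). Participants differ in
   `w`, `d`, `k`, so the number of covering participants is
   Poisson-binomial; the reported P-value is the exact upper tail computed
   by the dynamic-programming convolution, which reduces to an ordinary
   binomial test when all `p` are equal. The DP is verified in the test
   suite against full `2^n` enumeration to 1e-12 for `n <= 15`.
4. **Diversity and stability.** Shannon index (natural logs, so the
   Jensen-Shannon bound `ln 2` is exact; `base = 2` is available since the
   convention is not universal), Bray-Curtis dissimilarity, and the
   stability statistic `log(D_JS / dt)` between consecutive samples.
   Identical consecutive samples (`D_JS = 0`) yield a missing rate rather
   than `-Inf`, keeping downstream smoothers finite. Migration is the count
   of taxa introduced or going extinct relative to the previous collection
   day (presence = abundance above `min_abundance`, default 0).
5. **Cycle normalization.** Unreported menstruation flags are imputed as
   `not_menses` unless the nearest reported neighbours on both sides are
   menses. An onset is a menses day whose previous observed day is not
   menses (a bout starting on the first observed day is not an onset — its
   start is unobservable). Each participant's days are mapped onto a 28-day
   frame by `n = r * 28 / m` with `r` the day-in-cycle and `m` the length of
   their *first* full cycle; every cycle uses the same factor, and trailing
   days after the last onset keep counting from it. Later cycles longer
   than the first map beyond day 28 and are dropped from trajectory fits
   (not from spectral analysis, which uses the non-reset axis
   `n' = r' * 28 / m`).
6. **Trajectories.** Measures are smoothed against normalized day by loess
   (tricube weights, locally quadratic, span 0.5) on the integer grid 1-28.
   The 95% band resamples participants with replacement (cluster bootstrap,
   default 500 resamples, seeded): unlike the closed-form loess standard
   error it is honest under within-participant correlation. Spearman
   correlation against a reference relative-estradiol curve summarizes
   hormonal covariation; because published estradiol tables are not
   redistributable, the default reference is a synthetic two-peak template
   (`hormone_template()`: low days 1-5, dominant peak day 13, luteal rise
   around day 22) and any 28-row curve can be supplied.
7. **Spectral analysis.** The classic Scargle normalized periodogram of the
   mean-centered series on the non-reset axis — least-squares spectral
   analysis for unevenly sampled data. The default grid spans periods 2-56
   days at oversampling 8 (at least 400 frequencies), enough to resolve
   28- and 14-day peaks on a 70-day series. On evenly spaced data it equals
   the classical periodogram; a basis component with vanishing norm (the
   sine term at the Nyquist frequency of integer sampling) is dropped, as
   it carries no information. No false-alarm levels are computed — peaks are
   reported, not significance-tested.
8. **Lifestyle statistics.** Nutrients become proportions of caloric intake
   (days under 500 kcal are dropped as incomplete); exercise is total
   minutes over study days with the mean-intensity > 1.5 eligibility rule;
   anxiety = `100 - happy * relax / 100`. Group contrasts delegate standard
   tests (paired Wilcoxon, ANOVA + Tukey HSD, OLS) to `stats`; the van
   Elteren stratified rank test (the nonparametric covariable-adjusted
   contrast, used for vegetarian vs not stratified by study year) and
   PERMANOVA with subject-stratified permutations are implemented
   in-package, as no installed package provides them in this form. The van
   Elteren statistic uses `1/(N_h + 1)` stratum weights with tie-corrected
   variance; with one stratum it reduces to the rank-sum test. The
   PERMANOVA P-value is `(1 + #{F* >= F}) / (1 + n_perm)` with labels
   shuffled only within strata.

# The synthetic cohort generator

No raw cohort data ship with the package, so every stage is exercised
against `simulate_cohort()`, a seeded generator whose defaults emulate the
design the analyses assume: 17 participants sampled daily for 70 days, a
7-day mid-study collection break, 15% missing days, 25-32-day cycles with
4-6-day menses, two year batches, contraceptive groups NONE / C_SYSTEMIC /
P_LOCAL at 52/30/18%, and a 24% vegetarian fraction. Its construction:

* **Compositions** are Dirichlet draws (concentration 50) around per-day
  centroid compositions. Each participant has a base CST; CSTs I/II/III/V
  centroids put weight 0.75 on the dominant species with a geometric tail
  over the rest, CST IV is a flat anaerobe-rich profile capped at 0.3
  dominance.
* **Hormone forcing.** For NONE and C_SYSTEMIC participants the dominant
  weight is logistic in the standardized hormone curve:
  `w(day) = plogis(qlogis(0.75) + amplitude * z(day))`, amplitude 0.6. The
  logistic link keeps weights in (0, 1); no quantitative hormone dose-
  response is established for this system, so the link and its amplitude
  are exposed in the configuration rather than fixed. P_LOCAL participants
  get a flat weight of 0.55 — progestin-only local release suppresses both
  the cycling and the dominance level, which is the qualitative pattern
  this group shows in daily-cohort data. For the same reason the menses
  composition effect is scaled by `p_local_menses_factor` (default 0) for
  this group.
* **Menses effect** combines a concentration reduction (x0.7) with a blend
  toward a mix that places half its mass on three blood-associated taxa.
  The blend fraction is calibrated per day by root-finding so that the
  *expected* Shannon entropy of the Dirichlet draw — computable in closed
  form as `digamma(c + 1) - sum(theta * digamma(c * theta + 1))` — sits
  `menses_diversity_boost` nats (default 0.8) above the participant's mean
  non-menses expected entropy. Calibrating on the expected-entropy scale
  rather than the centroid-entropy scale makes the configured effect equal
  to the realized sample mean gap, not just an upper bound. The boost is
  achievable only where entropy headroom exists: CST IV communities sit
  near their entropy ceiling and the blend saturates, so diverse
  communities show little menses response — consistent with the effect
  being a property of *Lactobacillus*-dominated states.
* **Programmed transitions** ramp the centroid linearly (default 5 days)
  from a menses onset toward the target CST's centroid, which replaces the
  current — possibly menses-perturbed — state in proportion to the ramp.
  The ground-truth sidecar records the first retained day the target's
  centroid dominance exceeds 0.5, the quantity the detector estimates.
* **Lifestyle covariates** are draws around participant-level propensities
  (gamma exercise volume, normal mood and calorie levels, reporting rates);
  vegetarian status and intense exercise shift the centroid toward an even
  anaerobe mix using the same expected-entropy calibration (defaults: 0.4
  nats for vegetarians, 0.026 nats per exercise minute/day above intensity
  1.5). Mood is reported only by year-2 participants.

What the generator does **not** emulate: sequencing noise and compositional
zeros beyond Dirichlet sampling, sub-CST structure, anovulatory or variable-
length cycles within a participant, autocorrelated day-to-day dynamics
within a state, or any effect of sexual activity. Tests passing on this
cohort therefore demonstrate that the pipeline recovers the structure it is
designed to detect, not that real cohorts contain that structure.

# Numerical choices and degenerate inputs

* Row sums within 1e-3 of 1 are renormalized on load; farther rows are
  errors naming the sample. All-zero abundance vectors are rejected.
* `0 log 0 = 0` throughout; Jensen-Shannon of identical rows is exactly 0.
* Dominance-crossing recovery is noise-limited: at concentration 50 the
  Dirichlet sd near 50% abundance is about 0.07, comparable to a 5-day
  ramp's daily increment, so the first-crossing day is identifiable only to
  about +/-2 days. Ground-truth recovery tests therefore run at
  concentration 150, where the crossing is sharp and day-level agreement is
  a meaningful check of the detector rather than of the noise.
* Loess uses the direct surface (no interpolation cells) so fits are exact
  on polynomials up to the local degree; bootstrap refits that fail on a
  degenerate resample are dropped from the band.
* A constant series has zero spectral power at every frequency and an
  undefined (missing) Spearman correlation, each with a warning rather than
  an error where the pipeline can continue.
* Analyses run at these problem sizes by default: trajectory bands from 500
  bootstrap resamples (200 in `run_pipeline()`), PERMANOVA at 999
  permutations (199 in `run_pipeline()`), power/size simulations in the
  test suite at 50-500 replicates of 17-participant cohorts.

# Known limitations

* The uniform-placement null for the menses-association test is a modelling
  choice, not a derivation from any published procedure; the placement-
  counting alternative is provided and the two can disagree for windows
  near the ends of sparsely observed series.
* The van Elteren test is used as a stratified nonparametric adjustment; it
  is not claimed to be equivalent to other covariable-adjustment methods.
* Multi-cycle normalization scales all cycles by the first cycle's length,
  per the printed formula `n = r * (28/m)`; participants whose first cycle
  is atypically short map later cycles beyond day 28, and those points are
  excluded from trajectory fits.
* CST assignment is a hard argmax; no probabilistic or clustering-based
  sub-CST structure is modelled.
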