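## Reading, validating and writing the cohort tables.
## Canonical dialect: TSV, UTF-8, "." decimal, taxa as header columns.

RESERVED_COLS <- c(
  "sample_id", "participant", "day", "year", "menses", "contraceptive",
  "vegetarian", "exercise_minutes", "exercise_intensity", "happy", "relax",
  "calories", "sugar_g", "fiber_g", "protein_g", "fat_g",
  "shannon", "lactobacillus", "cst", "cst_tie", "r", "n", "r_prime", "n_prime"
)

#' Taxa columns of a cohort-shaped table
#'
#' @param x A data frame whose non-metadata columns are taxa abundances.
#' @return Character vector of taxon column names.
#' @export
taxa_names <- function(x) {
  setdiff(names(x), RESERVED_COLS)
}

#' Read a samples-by-taxa relative-abundance table
#'
#' Expects a TSV whose first column is the sample ID and whose remaining
#' columns are species-level taxa. Rows are validated as compositions:
#' entries must be nonnegative, and each row sum must be within `tol_renorm`
#' of 1 (such rows are renormalized to sum exactly to 1); a row further away
#' is an error naming the offending sample.
#'
#' @param path Path to the TSV.
#' @param tol_renorm Maximum tolerated deviation of a row sum from 1 before
#'   the file is rejected (default 1e-3).
#' @return Tibble: `sample_id` plus one numeric column per taxon.
#' @export
read_abundance <- function(path, tol_renorm = 1e-3) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(x) < 2) abort("malformed abundance file: need sample IDs + >= 1 taxon")
  names(x)[1] <- "sample_id"
  x$sample_id <- as.character(x$sample_id)
  taxa <- names(x)[-1]
  if (anyDuplicated(taxa)) abort("duplicate taxa names in abundance header")
  if (anyDuplicated(x$sample_id)) abort("duplicate sample IDs in abundance table")
  mat <- as.matrix(x[taxa])
  if (!is.numeric(mat)) abort("malformed abundance file: non-numeric entries")
  if (anyNA(mat)) abort("missing values in abundance table")
  neg <- which(rowSums(mat < 0) > 0)
  if (length(neg)) {
    abort(sprintf("negative abundance in sample %s", x$sample_id[neg[1]]))
  }
  rs <- rowSums(mat)
  off <- which(abs(rs - 1) > tol_renorm)
  if (length(off)) {
    abort(sprintf("row sum %.4f outside tolerance for sample %s",
                  rs[off[1]], x$sample_id[off[1]]))
  }
  x[taxa] <- mat / rs
  tibble::as_tibble(x)
}

#' Read the per-sample metadata table
#'
#' Validates the metadata schema: unique `(participant, day)`, mood ratings
#' within 0-100, exercise intensity within 1-3. Contraceptive strings other
#' than `NONE`, `C_SYSTEMIC`, `P_LOCAL` are mapped to `OTHER` with a warning.
#'
#' @param path Path to the TSV.
#' @return Tibble with one row per sample.
#' @export
read_samples <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "participant", "day", "menses", "contraceptive")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(sprintf("samples table lacks column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  x$sample_id <- as.character(x$sample_id)
  x$participant <- as.character(x$participant)
  x$day <- as.integer(x$day)
  if (any(x$day < 1, na.rm = TRUE)) abort("study day must be >= 1")
  dup <- duplicated(x[c("participant", "day")])
  if (any(dup)) {
    abort(sprintf("duplicate (participant, day): %s day %d",
                  x$participant[dup][1], x$day[dup][1]))
  }
  known <- c("NONE", "C_SYSTEMIC", "P_LOCAL", "OTHER")
  odd <- !is.na(x$contraceptive) & !(x$contraceptive %in% known)
  if (any(odd)) {
    warn(sprintf("unknown contraceptive value(s) mapped to OTHER: %s",
                 paste(unique(x$contraceptive[odd]), collapse = ", ")))
    x$contraceptive[odd] <- "OTHER"
  }
  bad_flag <- !is.na(x$menses) & !(x$menses %in% c("menses", "not_menses"))
  if (any(bad_flag)) abort("menses flag must be menses / not_menses / missing")
  for (col in c("happy", "relax")) {
    if (col %in% names(x) &&
        any(x[[col]] < 0 | x[[col]] > 100, na.rm = TRUE)) {
      abort(sprintf("%s ratings must lie in [0, 100]", col))
    }
  }
  if ("exercise_intensity" %in% names(x) &&
      any(!x$exercise_intensity %in% c(1L, 2L, 3L) &
            !is.na(x$exercise_intensity))) {
    abort("exercise intensity must be 1, 2 or 3")
  }
  tibble::as_tibble(x)
}

#' Join abundance and metadata into a cohort table
#'
#' Inner join on `sample_id`; abundance rows without metadata (and vice
#' versa) are dropped and reported via the `"orphans"` attribute and a
#' message. Rows are ordered chronologically within participant.
#'
#' @param abundance Output of [read_abundance()] (or `sim$abundance`).
#' @param samples Output of [read_samples()] (or `sim$samples`).
#' @return Cohort tibble: metadata columns followed by taxa columns.
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_config(n_participants = 2, seed = 1))
#' cohort <- build_cohort(sim$abundance, sim$samples)
build_cohort <- function(abundance, samples) {
  shared <- intersect(abundance$sample_id, samples$sample_id)
  if (length(shared) == 0) abort("no shared sample IDs between tables")
  orphans <- list(
    abundance = setdiff(abundance$sample_id, shared),
    samples = setdiff(samples$sample_id, shared)
  )
  if (length(orphans$abundance) || length(orphans$samples)) {
    inform(sprintf("dropped %d abundance / %d metadata rows without a match",
                   length(orphans$abundance), length(orphans$samples)))
  }
  out <- dplyr::inner_join(samples, abundance, by = "sample_id") |>
    dplyr::arrange(.data$participant, .data$day)
  attr(out, "orphans") <- orphans
  out
}

#' Write a simulated cohort to disk as plain-text fixtures
#'
#' Emits `abundance.tsv`, `samples.tsv` and a `truth.json` ground-truth
#' sidecar into `dir`. The TSVs round-trip losslessly through
#' [read_abundance()] / [read_samples()].
#'
#' @param cohort A `"cyclo_cohort_sim"` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cyclo_cohort_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("abundance.tsv", "samples.tsv", "truth.json"))
  readr::write_tsv(cohort$abundance, paths[1], progress = FALSE)
  readr::write_tsv(cohort$samples, paths[2], progress = FALSE)
  truth <- cohort$truth
  truth$participants <- as.list(truth$participants)
  truth$transitions <- as.list(truth$transitions)
  jsonlite::write_json(truth, paths[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
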