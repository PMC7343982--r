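# Shared fixtures, all built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# small fully-observed cohort of hormone-responsive, Lactobacillus-dominated
# participants; handy wherever cycle structure matters more than realism
responder_config <- function(n = 8, seed = 1, ...) {
  args <- list(
    n_participants = n, missing_rate = 0, gap = c(32, 0),
    group_weights = c(NONE = 1, C_SYSTEMIC = 0, P_LOCAL = 0),
    cst_weights = c(I = 0.6, II = 0, III = 0.4, IV = 0, V = 0),
    seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

sim_cohort <- function(config) {
  sim <- simulate_cohort(config)
  suppressMessages(build_cohort(sim$abundance, sim$samples))
}

# tiny hand-written cohort table: one participant, explicit compositions
toy_series <- function(abund, days = seq_len(nrow(abund)), menses = NULL,
                       participant = "P01") {
  taxa <- colnames(abund)
  out <- tibble::tibble(
    sample_id = sprintf("%s_D%03d", participant, days),
    participant = participant, day = as.integer(days),
    menses = menses %||% rep("not_menses", length(days))
  )
  dplyr::bind_cols(out, tibble::as_tibble(abund))
}

# independent Poisson-binomial upper tail by full 2^n enumeration
enum_poisbinom_upper <- function(x, p) {
  n <- length(p)
  tot <- 0
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[seq_len(n)]
    if (sum(bits) >= x) tot <- tot + prod(ifelse(bits == 1, p, 1 - p))
  }
  tot
}
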