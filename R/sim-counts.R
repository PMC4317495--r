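#' Configuration for the spectral-count simulator
#'
#' Describes a two-condition (active / inactive integrin) affinity-purification
#' experiment with biological and technical replicates and planted
#' condition-specific enrichment. Counts are drawn from a gamma-Poisson
#' (negative binomial) law: `var = mu + dispersion * mu^2`, the
#' over-dispersion typical of spectral counts.
#'
#' @param n_proteins number of proteins simulated.
#' @param n_bio_reps biological replicates per condition (default 2, the
#'   duplicate-isolation design).
#' @param n_tech_reps technical replicates per biological isolation
#'   (default 2).
#' @param baseline_mean expected spectral count of a null protein in one run.
#' @param dispersion negative-binomial over-dispersion (0 gives Poisson).
#' @param frac_active_enriched fraction of proteins with expected count
#'   multiplied by `planted_fold` in the active condition.
#' @param frac_inactive_enriched same, for the inactive condition.
#' @param planted_fold planted fold enrichment (> 1).
#' @param frac_unique_active fraction with zero expected count in the
#'   inactive condition (detection-based uniqueness).
#' @param frac_unique_inactive symmetric fraction unique to inactive.
#' @param mw_range_kda molecular-weight range; weights are drawn
#'   log-uniformly so the normalization is exercised over its dynamic range.
#' @param seed integer seed; identical seeds give identical output.
#' @return a list of class `sim_count_config`.
#' @export
sim_count_config <- function(n_proteins,
                             n_bio_reps = 2L,
                             n_tech_reps = 2L,
                             baseline_mean = 10,
                             dispersion = 0.05,
                             frac_active_enriched = 0,
                             frac_inactive_enriched = 0,
                             planted_fold = 4,
                             frac_unique_active = 0,
                             frac_unique_inactive = 0,
                             mw_range_kda = c(10, 300),
                             seed = 1L) {
  fracs <- c(frac_active_enriched, frac_inactive_enriched,
             frac_unique_active, frac_unique_inactive)
  if (any(fracs < 0) || any(fracs > 1))
    .fail("enrichment fractions must lie in [0, 1]")
  if (sum(fracs) > 1)
    .fail("enrichment/unique fractions sum to more than 1")
  .assert_scalar_number(baseline_mean, "baseline_mean", positive = TRUE)
  if (planted_fold <= 1) .fail("'planted_fold' must exceed 1")
  if (dispersion < 0) .fail("'dispersion' must be non-negative")
  if (length(mw_range_kda) != 2 || any(mw_range_kda <= 0) ||
      mw_range_kda[1] > mw_range_kda[2])
    .fail("'mw_range_kda' must be an increasing pair of positive reals")
  structure(list(n_proteins = as.integer(n_proteins),
                 n_bio_reps = as.integer(n_bio_reps),
                 n_tech_reps = as.integer(n_tech_reps),
                 baseline_mean = baseline_mean,
                 dispersion = dispersion,
                 frac_active_enriched = frac_active_enriched,
                 frac_inactive_enriched = frac_inactive_enriched,
                 planted_fold = planted_fold,
                 frac_unique_active = frac_unique_active,
                 frac_unique_inactive = frac_unique_inactive,
                 mw_range_kda = mw_range_kda,
                 seed = as.integer(seed)),
            class = "sim_count_config")
}

# NB draw that degenerates cleanly to Poisson and to exact zeros
.rcounts <- function(n, mu, dispersion) {
  out <- integer(n)
  pos <- mu > 0
  if (any(pos)) {
    out[pos] <- as.integer(if (dispersion > 0)
      stats::rnbinom(sum(pos), size = 1 / dispersion, mu = mu[pos])
    else stats::rpois(sum(pos), mu[pos]))
  }
  out
}

#' Simulate a spectral-count experiment
#'
#' Generates counts for 2 conditions x `n_bio_reps` x `n_tech_reps` samples,
#' a matching design table, protein metadata (log-uniform molecular
#' weights), and per-protein truth labels recording the planted class.
#' Proteins unique to one condition have expected count zero in the other,
#' not post-hoc zeroed counts.
#'
#' @param config a [sim_count_config()].
#' @return list with elements `counts` (integer matrix, proteins x samples),
#'   `design` (sample_id, condition, bio_rep, tech_rep, total_spectra =
#'   column sums), `meta` (accession, symbol, mw_kda, adhesome,
#'   functional_class, is_tip), and `truth` (accession, class in
#'   active_enriched / inactive_enriched / unique_active / unique_inactive /
#'   null).
#' @export
sim_counts <- function(config) {
  stopifnot(inherits(config, "sim_count_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  acc <- sprintf("P%05d", seq_len(n))

  n_cls <- round(n * c(config$frac_active_enriched,
                       config$frac_inactive_enriched,
                       config$frac_unique_active,
                       config$frac_unique_inactive))
  cls_names <- c("active_enriched", "inactive_enriched",
                 "unique_active", "unique_inactive")
  cls <- rep("null", n)
  idx <- sample.int(n)  # scatter planted proteins over the matrix
  pos <- 1L
  for (i in seq_along(n_cls)) {
    if (n_cls[i] > 0) {
      cls[idx[pos:(pos + n_cls[i] - 1L)]] <- cls_names[i]
      pos <- pos + n_cls[i]
    }
  }

  mu_active <- rep(config$baseline_mean, n)
  mu_inactive <- rep(config$baseline_mean, n)
  mu_active[cls == "active_enriched"] <-
    config$baseline_mean * config$planted_fold
  mu_inactive[cls == "inactive_enriched"] <-
    config$baseline_mean * config$planted_fold
  mu_inactive[cls == "unique_active"] <- 0
  mu_active[cls == "unique_inactive"] <- 0

  design <- expand.grid(tech_rep = paste0("t", seq_len(config$n_tech_reps)),
                        bio_rep = paste0("b", seq_len(config$n_bio_reps)),
                        condition = c("active", "inactive"),
                        stringsAsFactors = FALSE)
  design$sample_id <- paste(design$condition, design$bio_rep,
                            design$tech_rep, sep = "_")
  counts <- sapply(seq_len(nrow(design)), function(s) {
    mu <- if (design$condition[s] == "active") mu_active else mu_inactive
    .rcounts(n, mu, config$dispersion)
  })
  dimnames(counts) <- list(acc, design$sample_id)
  design$total_spectra <- pmax(colSums(counts), 1L)
  design <- design[, c("sample_id", "condition", "bio_rep",
                       "tech_rep", "total_spectra")]

  lo <- log(config$mw_range_kda[1]); hi <- log(config$mw_range_kda[2])
  meta <- data.frame(accession = acc,
                     symbol = acc,
                     mw_kda = exp(stats::runif(n, lo, hi)),
                     adhesome = "none",
                     functional_class = "none",
                     is_tip = FALSE,
                     stringsAsFactors = FALSE)
  list(counts = counts, design = design, meta = meta,
       truth = data.frame(accession = acc, class = cls,
                          stringsAsFactors = FALSE))
}
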