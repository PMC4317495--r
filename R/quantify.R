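#' Normalized spectral counts
#'
#' Converts raw spectral counts to normalized spectral counts (NSC):
#' the unweighted spectral count of a protein divided by the total number
#' of spectra observed in the whole run and by the protein's molecular
#' weight, times a fixed readability scale. Ratios and clustering are
#' invariant to the scale constant.
#'
#' @param counts integer matrix, proteins x samples (rownames = accessions).
#' @param design design data.frame with `sample_id` and `total_spectra`.
#' @param meta metadata data.frame with `accession` and `mw_kda`.
#' @param scale multiplier applied to every NSC (default 1e6).
#' @return numeric matrix of NSC values, same dimensions as `counts`.
#' @export
compute_nsc <- function(counts, design, meta, scale = 1e6) {
  missing_s <- setdiff(colnames(counts), design$sample_id)
  if (length(missing_s))
    .fail("sample(s) absent from design: ", paste(missing_s, collapse = ", "))
  mw <- meta$mw_kda[match(rownames(counts), meta$accession)]
  if (anyNA(mw))
    .fail("molecular weight missing for protein(s): ",
          paste(rownames(counts)[is.na(mw)], collapse = ", "))
  ts <- design$total_spectra[match(colnames(counts), design$sample_id)]
  sweep(sweep(counts, 2, ts, "/"), 1, mw, "/") * scale
}

#' Aggregate replicate NSC values
#'
#' Technical replicates are summed within each biological isolation, and
#' the biological replicates are then averaged per condition.
#'
#' @param nsc NSC matrix from [compute_nsc()].
#' @param design design data.frame (`sample_id`, `condition`, `bio_rep`,
#'   `tech_rep`).
#' @return list with `bio` (proteins x condition.bio_rep matrix of summed
#'   technical replicates - the clustering feature columns) and
#'   `condition_mean` (proteins x condition matrix of mean NSC).
#' @export
aggregate_replicates <- function(nsc, design) {
  design <- design[match(colnames(nsc), design$sample_id), , drop = FALSE]
  conds <- unique(design$condition)
  biokey <- paste(design$condition, design$bio_rep, sep = ".")
  ubk <- unique(biokey)
  bio <- matrix(0, nrow(nsc), length(ubk),
                dimnames = list(rownames(nsc), ubk))
  for (k in seq_along(ubk))
    bio[, k] <- rowSums(nsc[, biokey == ubk[k], drop = FALSE])
  cond_of_bio <- sub("\\..*$", "", ubk)
  condition_mean <- matrix(0, nrow(nsc), length(conds),
                           dimnames = list(rownames(nsc), conds))
  for (cc in conds)
    condition_mean[, cc] <- rowMeans(bio[, cond_of_bio == cc, drop = FALSE])
  list(bio = bio, condition_mean = condition_mean)
}

#' Minimum spectral-count filter
#'
#' Retains proteins whose total unweighted spectral count across all runs
#' is at least `min_total` (default 4).
#'
#' @param counts integer matrix, proteins x samples.
#' @param min_total minimum summed count.
#' @return character vector of retained accessions.
#' @export
filter_min_count <- function(counts, min_total = 4) {
  if (nrow(counts) == 0) return(character())
  rownames(counts)[rowSums(counts) >= min_total]
}

#' Fold enrichment between activation states
#'
#' Computes per-protein fold enrichment (active / inactive mean NSC).
#' Proteins detected in only one condition get a sentinel `status`
#' (`unique_active` / `unique_inactive`) with `fold = NA`, matching the
#' "U, unique" convention; the log2 fold change is always finite because
#' zero means are imputed with half the smallest non-zero mean NSC in the
#' table before the ratio is logged.
#'
#' @param condition_mean proteins x condition matrix with columns
#'   `active` and `inactive` (from [aggregate_replicates()]).
#' @param pseudo optional explicit pseudo-count; default half the smallest
#'   positive mean in the table.
#' @return data.frame with accession, mean_nsc_active, mean_nsc_inactive,
#'   fold, status, log2fc.
#' @export
fold_enrichment <- function(condition_mean, pseudo = NULL) {
  a <- condition_mean[, "active"]
  i <- condition_mean[, "inactive"]
  if (any(a == 0 & i == 0))
    .fail("protein(s) with zero mean NSC in both conditions: ",
          paste(rownames(condition_mean)[a == 0 & i == 0], collapse = ", "),
          " (apply filter_min_count first)")
  if (is.null(pseudo)) {
    pos <- c(a[a > 0], i[i > 0])
    pseudo <- min(pos) / 2
  }
  status <- ifelse(i == 0, "unique_active",
                   ifelse(a == 0, "unique_inactive", "both"))
  fold <- ifelse(status == "both", a / i, NA_real_)
  log2fc <- log2(pmax(a, pseudo) / pmax(i, pseudo))
  data.frame(accession = rownames(condition_mean),
             mean_nsc_active = a, mean_nsc_inactive = i,
             fold = fold, status = status, log2fc = log2fc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential-abundance flags from spectral counts
#'
#' A count-based test of differential relative abundance between the two
#' activation states, standing in for a hierarchical Bayesian spectral
#' count model: a negative-binomial exact test (edgeR) on the per-sample
#' counts with the runs' total spectra as library sizes, which accounts
#' for the over-dispersion of spectral counts. P values are adjusted by
#' Benjamini-Hochberg and flagged at the given false discovery rate.
#'
#' @param counts integer matrix, proteins x samples.
#' @param design design data.frame (`sample_id`, `condition`,
#'   `total_spectra`).
#' @param alpha FDR level for the `significant` flag (default 0.05).
#' @return data.frame with accession, p, fdr, significant.
#' @export
differential_flags <- function(counts, design, alpha = 0.05) {
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  conds <- c("active", "inactive")
  if (!all(conds %in% design$condition))
    .fail("both conditions must be present")
  grp <- factor(design$condition, levels = conds)
  y <- edgeR::DGEList(counts = counts, group = grp,
                      lib.size = design$total_spectra)
  y <- suppressMessages(edgeR::estimateDisp(y))
  et <- edgeR::exactTest(y, pair = rev(conds))  # active relative to inactive
  p <- et$table$PValue
  p[rowSums(counts) == 0] <- 1
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(accession = rownames(counts), p = p, fdr = fdr,
             significant = fdr < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Venn summary of presence sets
#'
#' Partitions the union of proteins identified in the active and inactive
#' data sets and reports counts and integer percentages of the union.
#'
#' @param active,inactive character vectors of identified proteins.
#' @return list with n_active_only, n_inactive_only, n_shared, n_total and
#'   the corresponding integer percentages (half away from zero).
#' @export
venn_summary <- function(active, inactive) {
  active <- unique(active); inactive <- unique(inactive)
  shared <- intersect(active, inactive)
  n_ao <- length(setdiff(active, inactive))
  n_io <- length(setdiff(inactive, active))
  n_sh <- length(shared)
  n_tot <- n_ao + n_io + n_sh
  pct <- function(k) if (n_tot == 0) 0 else round_half_up(100 * k / n_tot)
  list(n_active_only = n_ao, n_inactive_only = n_io, n_shared = n_sh,
       n_total = n_tot,
       pct_active_only = pct(n_ao), pct_inactive_only = pct(n_io),
       pct_shared = pct(n_sh))
}

#' Summary of known microtubule plus-end tracking proteins
#'
#' Given a registry of known +TIPs marking which were identified by MS and
#' their fold enrichments (with `"U"` for proteins unique to active
#' complexes), reports how many were identified, the percentage of the
#' known family that represents, and the percentage of identified +TIPs
#' enriched more than `threshold`-fold. Unique detections count as
#' exceeding any finite threshold.
#'
#' @param registry data.frame with columns `gene`, `identified` (logical)
#'   and `fold` (numeric as character, or `"U"`; `NA` for non-identified).
#' @param threshold fold-enrichment cut (default 2; strictly greater).
#' @return list with n_known, n_identified, pct_of_known,
#'   pct_above_threshold.
#' @export
summarize_tips <- function(registry, threshold = 2) {
  if (is.null(registry) || nrow(registry) == 0) .fail("empty +TIP registry")
  idf <- registry[registry$identified, , drop = FALSE]
  n_known <- nrow(registry)
  n_id <- nrow(idf)
  fold_chr <- as.character(idf$fold)
  above <- fold_chr == "U" |
    suppressWarnings(as.numeric(fold_chr)) > threshold
  above[is.na(above)] <- FALSE
  list(n_known = n_known,
       n_identified = n_id,
       pct_of_known = round_half_up(100 * n_id / n_known),
       pct_above_threshold = if (n_id == 0) 0 else
         round_half_up(100 * sum(above) / n_id))
}

#' Packaged +TIP registry
#'
#' The printed table of known microtubule plus-end tracking proteins:
#' the 15 family members identified in the adhesion-complex data sets with
#' their fold enrichments (active/inactive; `"U"` = unique to active
#' complexes), plus the 16 known members that were not identified.
#'
#' @return data.frame with gene, protein_name, alias, fold, identified.
#' @export
tip_registry <- function() {
  path <- system.file("extdata", "tip_registry.tsv",
                      package = "adhesomics", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = "NA")
  df$identified <- as.logical(df$identified)
  df
}
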